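---
title: "Quantifying the tropical water availability - CO2 growth rate coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the tropical water availability - CO2 growth rate coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(watercarbon)
```

## The scientific question

Interannual variability (IAV) of the atmospheric CO2 growth rate (CGR) is
dominated by tropical land-atmosphere carbon fluxes. Two climate drivers
compete for explanatory power: tropical temperature, whose anomalies
correlate positively with CGR, and tropical water availability, whose
anomalies correlate negatively (drier years weaken the land sink). This
package provides the statistical machinery to ask whether the
water-carbon arm of that coupling is *stationary*: does the interannual
relationship between tropical terrestrial water storage (WS) and CGR hold
steady across decades, or does it strengthen?

The analysis chain is:

1. **Preprocessing** - CGR from a monthly CO2 series, tropical aggregates
   of gridded WS / precipitation / temperature, linear detrending,
   exclusion of post-volcanic years.
2. **Coupling statistics** - bootstrapped correlations, partial
   correlations, univariate OLS and bivariate ridge sensitivities, over
   fixed and moving windows, with a bootstrap test for changes between
   periods.
3. **ENSO classification** - each year labelled Eastern-Pacific (EP)
   event, Central-Pacific (CP) event, or neutral, from gridded SST.
4. **Spatial coherence** - a pairwise-covariance statistic measuring
   whether WS anomalies across the tropics share one sign or compensate
   spatially, plus coupling statistics conditioned on coherence terciles.
5. **Model diagnosis** - the same metrics applied to model-ensemble
   series, with EOF decomposition of gridded soil moisture.
6. **VOD calibration** - a saturating arctangent mapping from vegetation
   optical depth (VOD) to aboveground carbon (AGC), and semi-arid AGC-CGR
   coupling per window.

A synthetic-data generator supplies all inputs with the statistical
structure the analysis assumes, so the full pipeline is testable without
any external download.

## Core definitions and conventions

**CGR.** The growth rate of year $y$ is the concentration difference
across that year. On monthly means we operationalize "end of December
minus start of January" as $\mathrm{CGR}(y) = \mathrm{CO_2}(\mathrm{Dec},
y) - \mathrm{CO_2}(\mathrm{Dec}, y-1)$; the first year, lacking a
preceding December, is flagged invalid rather than dropped. Conversion to
carbon mass uses 2.124 PgC per ppm (configurable; the airborne-fraction
convention).

**Detrending and volcano years.** All statistics operate on anomalies
after removing an OLS linear trend. The trend is fitted on *valid years
only*, so that excluded years (default 1963-1964, 1982, 1991-1993, after
the Agung, El Chichon and Pinatubo eruptions) cannot tilt the fitted
line; their anomalies are still computed but stay invalid. Window
analyses re-detrend within each window by default (`detrend =
"per_window"`), since a trend removed over the full record does not make
sub-periods trend-free; a `"none"` mode supports detrending once over the
full span.

**Tropical aggregates.** The tropical domain is vegetated land between
24S and 24N. Means are cos-latitude weighted by default (an unweighted
mode exists because equal-weighting is also defensible on a masked
tropical grid where weights vary by at most 9%). WS is additionally
offered as an area-integrated mass in teratonnes of water (Tt H2O), the
unit in which water sensitivities $\gamma_{WS}$ (PgC yr$^{-1}$ per Tt
H2O) are expressed. Lagged precipitation LagP$(y)$ sums July$(y-1)$
through June$(y)$, a proxy for the water actually available in year $y$.

**Bootstrap.** Uncertainty comes from a case (pairs) bootstrap: years are
resampled jointly across all series, preserving cross-variable
dependence, with 5,000 replicates and percentile intervals by default.
Degenerate replicates (zero variance) are redrawn, capped at ten times
the replicate count. The change between two periods is summarized by
pairing replicates: $p = 2\min(\Pr(\Delta^* \ge 0), \Pr(\Delta^* \le
0))$, capped at 1. The non-strict inequalities make identical inputs
yield $p = 1$ instead of 0.

**Ridge protocol.** With water and temperature collinear, the bivariate
sensitivity uses ridge regression on standardized predictors. The penalty
is selected by 25 random 75/25 train-validation splits; each split picks
the best of 100 penalties spaced evenly on a log scale (default range
$[10^{-4}, 10^2]$, configurable - the count and spacing are fixed by the
protocol, the range is our choice), and the arithmetic mean of the 25
winners is retained. Selection runs once on the full sample; the 5,000
bootstrap replicates re-estimate coefficients at that fixed penalty
(re-running the split search inside every replicate would multiply the
cost by 2,500 for no change in the point estimate). Coefficients are
rescaled to original units. A `mode = "ols"` variant gives the
penalty-free bivariate fit; at $\lambda = 0$ the two coincide exactly.

**Which estimator for recovery claims?** Ridge trades bias for variance:
its percentile intervals centre on a shrunken estimate, so coverage
statements about the *generating* coefficients use the unbiased bivariate
OLS mode. The ridge mode is the right tool when collinearity threatens
sign stability, which is its role in the window tables.

## The ENSO classifier

DJF of year $y$ means December$(y-1)$ + January$(y)$ + February$(y)$,
the common event-year labelling. SST anomalies are taken per cell and
calendar month relative to a climatology window (leave-in convention).
Nino3 (5S-5N, 150W-90W), Nino4 (5S-5N, 160E-150W) and Nino3.4 boxes
follow the standard NOAA definitions; only Nino3.4's box is usually
spelled out in analyses of this kind, the others are the conventional
complements. A year is EP when the largest DJF anomaly in the equatorial
scan band (2S-2N, 110E-90W) lies east of 150W *and* DJF Nino3 exceeds
one standard deviation of its series over the climatology window; CP
symmetrically with Nino4 west of 150W. Thresholds are strict: an index
exactly at 1 s.d. stays neutral. A year whose peak side and exceeding
index disagree (peak east but only Nino4 exceeding, or vice versa) is
kept neutral with a note - the rule is silent there, and we prefer the
conservative label. Anomalies are not detrended before classification
(climatology removal only); a detrend flag exists for sensitivity
checks.

## The spatial-coherence statistic

For a window, form the temporal covariance $c_{ij}$ between every pair
of distinct cells and report

$$\mathrm{coherence} = 100\,\frac{\mathrm{tcov}^+ +
\mathrm{tcov}^-}{\mathrm{tcov}},\qquad \mathrm{tcov} = \sum_{i\ne j}
|c_{ij}|,$$

the signed over absolute pairwise sums, diagonal excluded (variances are
always positive and carry no sign information). 100% means every cell
co-varies with one sign; low or negative values mean positive covariances
are counterbalanced - spatially compensating water anomalies that cancel
in the tropical aggregate. The matrix is accumulated in column blocks so
the full cells-by-cells array is never held at once.

A per-year value is not uniquely defined by a covariance formula, so we
take the single-year restriction of the same expression: with $x_i$ the
anomaly of cell $i$ in year $t$,

$$\mathrm{coherence}(t) = 100\,\frac{(\sum_i x_i)^2 - \sum_i
x_i^2}{(\sum_i |x_i|)^2 - \sum_i x_i^2},$$

i.e. the off-diagonal outer-product terms of year $t$. This reduces to
the period formula when years are identical, has an $O(\text{cells})$
closed form, and is checked against an explicit pairwise double loop in
the tests. Zero-anomaly cells contribute nothing (no sign is invented
for them); a year with fewer than two nonzero cells is invalid. Cells
are unweighted by default, matching the bare covariance definition; an
area-weighted variant multiplies each pair by $w_i w_j$. The ratio is
computed before scaling by 100 and clamped to $[-1, 1]$ so the analytic
bounds are attained exactly rather than to rounding error.

Valid years are binned at the 33.3rd/66.6th percentiles of the yearly
coherence into LOW / MEDIUM / HIGH terciles. Terciles are computed over
all valid years jointly by default (so window fractions are comparable);
a `bin_window` argument restricts the break-point estimation when
per-window binning is wanted. Bin assignment is by manual interval
comparison so tied or constant break points degrade gracefully instead
of erroring.

## The VOD-to-AGC calibration

AGC is mapped from VOD by the four-parameter saturating arctangent

$$\mathrm{AGC} = a\,\frac{\arctan(b(\mathrm{VOD}-c)) -
\arctan(-bc)}{\arctan(b(\mathrm{Inf}-c)) - \arctan(-bc)} + d,$$

with Inf fixed at $10^{10}$. For $b>0$ the mapping is monotone and
saturates at $a+d$. The fit is nonlinear least squares
(Levenberg-Marquardt) with multi-start initialization - $a$ near the AGC
range, $d$ near its minimum, $c$ near the VOD median, $b \in \{0.5, 1,
5\}$ - keeping the best converged start; a saturating arctangent has
shallow valleys in $b$, and the multi-start makes convergence robust.
The biomass-to-carbon factor 0.5 is a separate helper; the calibration
expects a benchmark already in carbon units.

Whether the semi-arid AGC-CGR coupling should use AGC *changes* (a flux
proxy) or detrended *levels* is genuinely open; both are implemented
with the change mode as default, since a carbon-stock increment is the
natural counterpart of a flux like CGR.

## What the synthetic generator emulates

`generate_study_dataset()` draws, per year: an event strength $e_y$ (zero
in neutral years, an amplitude with 25% jitter in EP/CP years); a
coherent-pattern water loading $-w_{perK}\,e_y$ plus noise in event years
(warm events dry the tropics as a whole) or a dipole loading in neutral
years (spatially compensating, area-weighted sum exactly zero, so the
tropical aggregate nearly cancels); a tropical temperature anomaly
$t_{perK}\,e_y$ plus noise; and CGR as

$$\mathrm{CGR}_y = \mathrm{base} + \mathrm{trend}\cdot y + \gamma_{WS}
W_y + \gamma_T T_y + \varepsilon_y,$$

where $W_y$ (Tt) and $T_y$ (K) are the same aggregates the preprocessing
computes. Monthly CO2 is integrated from CGR with December anchors, so
the CGR operation inverts the generator exactly (the optional seasonal
cycle, default amplitude 0, vanishes at the December sampling points).
Precipitation places each year's water anomaly into its July-June
window, making LagP track $W_y$. SST fields carry the scheduled events
as Gaussian warm pools normalized so the event's Nino box index equals
the requested amplitude; with any events present, an event index always
exceeds 1 s.d. of its series, because that s.d. is at most the amplitude
times $\sqrt{f(1-f)}$ for event fraction $f$.

Default study conditions: 1960-2018 on an 8 x 16 tropical grid,
$\gamma_{WS} = -1$ PgC yr$^{-1}$ per Tt H2O (within the range of
observational estimates), $\gamma_T = 2$ PgC yr$^{-1}$ K$^{-1}$, CGR
noise 0.5 PgC yr$^{-1}$, event amplitude 2 K, water response 0.8 Tt per
K of event amplitude, temperature response 0.12 K per K. These produce
CGR IAV of roughly 1-1.2 PgC yr$^{-1}$ and a moderate water-temperature
collinearity, both in the realistic range. The default event calendar
spreads eight EP and eight CP events over the record with CP
concentrated late, loosely patterned on the observed second half of the
twentieth century.

Two special schedules support experiments. `regime_enso_schedule()`
builds the two-era contrast: a fully neutral first era - water anomalies
purely compensating, so the aggregated water signal is noise - against a
CP-enriched second era (ten CP, two EP). This is a stylized maximal
version of a neutral-dominated-to-CP shift; a pilot power analysis
during design showed that even one or two strong events in era 1 produce
a sizeable era-1 correlation through leverage (a single large event year
dominates a 30-year window), which washes out the era contrast the
experiment is meant to create. The tests' stationary counterpart spreads
events evenly (one EP and one CP per six years).

What the generator does **not** emulate: measurement-error structure of
gravimetric water storage, station-density effects in precipitation,
ENSO dynamics beyond scripted warm events (no La Nina, no
autocorrelation, no event evolution), cross-year persistence of water
anomalies, and volcanic flux perturbations (volcano years are excluded
by the pipeline but are unremarkable in the synthetic truth). Passing
tests therefore demonstrate the statistical machinery is correct and
well-calibrated under the assumed structure, not that real observations
satisfy that structure.

## Numerical and degenerate-input choices

* Correlation p-values use the two-sided t approximation; sensitivities
  report a bootstrap sign test. No multiple-testing correction is
  applied across windows.
* `partial_corr` resolves the 0/0 case (a variable fully explained by
  the control, numerator and denominator both vanishing) to zero; true
  collinearity with a non-vanishing numerator errors.
* Bootstrap, generators and the penalty search save and restore the
  global RNG state, so calls are reproducible without clobbering the
  caller's stream.
* EOF analysis weights cells by $\sqrt{\cos\varphi}$ (so variance
  contributions scale with area), fixes each mode's sign by making its
  largest-magnitude loading positive, and truncates to the matrix rank
  with a warning.
* Windows may share boundary years; moving windows are indexed by centre
  year and skip (as `NA`) windows with fewer than 8 jointly valid years.

## Judging stationarity without guaranteed false alarms

"No spurious trend on stationary data" cannot be operationalized as
"the change p-value never falls below 0.1": under the null that p-value
is approximately uniform, so a 10% false-alarm rate per dataset is built
in and a 95% pass rate across seeds is unattainable by construction.
The package's stationarity check therefore asks whether the two
windows' statistics differ *within bootstrap noise* literally: their
95% percentile intervals must overlap, and the moving-window series'
drift (mean of the last five centre years minus the first five) must
stay below three bootstrap standard errors. Both events are rare under
the null and systematic under a genuine regime shift.

## Problem sizes used in the test suite

The suite exercises the pipeline at desk scale, chosen to keep the
statistics well-resolved: 55-60-year records on 8 x 16 tropical grids;
100 seeded repetitions for coverage and round-trip rates; 50 for
regime-shift and stationarity rates; 5,000 bootstrap replicates wherever
a rate depends on interval calibration; 1,000 random cases for the
oracle-equivalence identities (coherence closed form vs pairwise loop,
partial-correlation formula vs residual regressions, both at $10^{-12}$).

## Known limitations

* The per-year coherence is one defensible single-year restriction of
  the period formula; other reductions (e.g. leave-one-year-out
  contributions to the covariance) would differ in detail.
* The bootstrap resamples years independently, so serial dependence is
  not respected; a block bootstrap is out of scope.
* EP/CP classification is one of several methods in use; results are
  known to vary with the method, and no alternative (EMI, E/C indices)
  is provided.
* The ensemble diagnosis consumes prepared per-model series; reading
  native model archives and regridding are out of scope.
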