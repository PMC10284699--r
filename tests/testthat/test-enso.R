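# uniform DJF anomaly field: one value per labelled year over every cell
uniform_djf_sst <- function(djf_values, years) {
  lat <- seq(-10, 10, by = 5); lon <- seq(120, 280, by = 10)
  m_years <- c(years[1] - 1L, rep(years, each = 12))
  m_months <- c(12L, rep(1:12, length(years)))
  vals <- array(20, c(length(m_years), length(lat), length(lon)))
  for (k in seq_along(years)) {
    idx <- which((m_years == years[k] - 1L & m_months == 12L) |
                 (m_years == years[k] & m_months %in% 1:2))
    vals[idx, , ] <- 20 + djf_values[k]
  }
  gridded_field(vals, lat, lon, m_years, m_months, "K")
}

test_that("anomalies of a field equal to its climatology are zero", {
  sst <- uniform_djf_sst(rep(0, 12), 2000:2011)
  an <- suppressWarnings(sst_anomaly(sst))
  expect_equal(max(abs(an$values)), 0)
})

test_that("the leave-in climatology shifts a single perturbed month as
           expected", {
  yrs <- 2000:2011
  sst <- uniform_djf_sst(rep(0, 12), yrs)
  # +1 K everywhere in June 2005
  idx <- which(sst$years == 2005 & sst$months == 6)
  sst$values[idx, , ] <- sst$values[idx, , ] + 1
  an <- sst_anomaly(sst, climatology_window = c(2000, 2011))
  n <- length(yrs)
  expect_equal(unique(as.vector(an$values[idx, , ])), 1 - 1 / n,
               tolerance = 1e-12)
  other_june <- which(sst$years == 2007 & sst$months == 6)
  expect_equal(unique(as.vector(an$values[other_june, , ])), -1 / n,
               tolerance = 1e-12)
})

test_that("nino indices average the DJF box anomaly", {
  yrs <- 2000:2011
  djf <- c(0, 0, 2, rep(0, 9))
  # climatology over late, unperturbed years so DJF 2002 keeps its +2 K
  an <- suppressWarnings(sst_anomaly(uniform_djf_sst(djf, yrs),
                                     c(2004, 2011)))
  n3 <- nino_index(an, "nino3")
  expect_false(n3$valid[1])  # no December 1998 in the record
  expect_equal(n3$values[n3$years == 2002], 2, tolerance = 1e-10)
  expect_equal(n3$values[n3$years == 2005], 0, tolerance = 1e-12)
})

test_that("an anomaly confined outside the box leaves the index at zero", {
  sched <- c(rep("NEUTRAL", 5), "CP", rep("NEUTRAL", 6))
  sst <- generate_sst_with_enso(sched, amplitude_sd = 2, seed = 1,
                                years = 2000:2011)
  # climatology from years untouched by the event's December
  an <- suppressWarnings(sst_anomaly(sst, c(2007, 2011)))
  n4 <- nino_index(an, "nino4")
  expect_equal(n4$values[n4$years == 2005], 2, tolerance = 1e-10)
  # Nino3 centre is far from the CP blob: small but nonzero tail
  n3 <- nino_index(an, "nino3")
  expect_lt(abs(n3$values[n3$years == 2005]), 0.75)
})

test_that("scripted event amplitudes are recovered exactly against a
           clean climatology", {
  sched <- c(rep("NEUTRAL", 4), "EP", rep("NEUTRAL", 7))
  sst <- generate_sst_with_enso(sched, amplitude_sd = 3, seed = 2,
                                years = 2000:2011)
  an <- suppressWarnings(sst_anomaly(sst, climatology_window = c(2006,
                                                                 2011)))
  n3 <- nino_index(an, "nino3")
  expect_equal(n3$values[n3$years == 2004], 3, tolerance = 1e-10)
})

test_that("classification satisfies the EP/CP rules and exclusivity", {
  yrs <- 1960:2018
  sched <- default_enso_schedule(yrs)
  sst <- generate_sst_with_enso(sched, amplitude_sd = 2, seed = 3,
                                years = yrs, noise_sd = 0.1)
  cal <- classify_enso_years(sst_anomaly(sst, c(1960, 2018)),
                             climatology_window = c(1960, 2018))
  keep <- cal$year %in% yrs
  expect_identical(as.character(cal$label[keep]), sched)
  sd3 <- attr(cal, "sd_nino3"); sd4 <- attr(cal, "sd_nino4")
  expect_true(all(cal$nino3[cal$label == "EP"] > sd3))
  expect_true(all(cal$peak_longitude[cal$label == "EP"] >= 210))
  expect_true(all(cal$nino4[cal$label == "CP"] > sd4))
  expect_true(all(cal$peak_longitude[cal$label == "CP"] < 210))
  neutral <- cal$valid & cal$label == "NEUTRAL"
  expect_true(all(abs(cal$nino3[neutral]) <= sd3 |
                  cal$peak_longitude[neutral] < 210))
  expect_false(any(is.na(cal$label[cal$valid])))
})

test_that("an all-neutral schedule classifies as all neutral", {
  sst <- generate_sst_with_enso(rep("NEUTRAL", 15))
  cal <- classify_enso_years(sst_anomaly(sst))
  expect_true(all(cal$label == "NEUTRAL"))
})

test_that("a single strong EP year is labelled EP", {
  sched <- c(rep("NEUTRAL", 9), "EP", rep("NEUTRAL", 10))
  sst <- generate_sst_with_enso(sched, amplitude_sd = 3, seed = 1)
  cal <- classify_enso_years(sst_anomaly(sst))
  expect_identical(as.character(cal$label[cal$year == 1969]), "EP")
  expect_equal(sum(cal$label != "NEUTRAL"), 1L)
})

test_that("an index exactly at one standard deviation stays neutral", {
  # DJF values (c, -c, 0): with the n-1 denominator the series s.d. is
  # exactly c, and the strict 'exceeds' rule must not fire
  an <- suppressWarnings(sst_anomaly(uniform_djf_sst(c(1.5, -1.5, 0),
                                                     2000:2002)))
  # climatology removal shifts all DJF values equally; recentre manually
  n3 <- nino_index(an, "nino3")
  vals <- n3$values[n3$valid]
  expect_equal(max(vals) / sd(vals), 1, tolerance = 1e-10)
  cal <- suppressWarnings(
    classify_enso_years(sst_anomaly(uniform_djf_sst(c(1.5, -1.5, 0),
                                                    2000:2002))))
  expect_true(all(cal$label == "NEUTRAL"))
})

test_that("classification is invariant to a uniform SST offset", {
  sched <- c("NEUTRAL", "EP", "NEUTRAL", "CP", rep("NEUTRAL", 8))
  sst <- generate_sst_with_enso(sched, amplitude_sd = 2.5, seed = 4,
                                years = 2000:2011, noise_sd = 0.1)
  cal1 <- classify_enso_years(sst_anomaly(sst))
  sst$values <- sst$values + 3.2
  cal2 <- classify_enso_years(sst_anomaly(sst))
  expect_identical(cal1$label, cal2$label)
  expect_equal(cal1$nino3, cal2$nino3, tolerance = 1e-10)
})

test_that("generator and classifier round-trip mixed schedules", {
  yrs <- 1990:2019
  for (s in 1:5) {
    sched <- sample(c("EP", "CP", rep("NEUTRAL", 4)), 30, replace = TRUE)
    sst <- generate_sst_with_enso(sched, amplitude_sd = 2, seed = s,
                                  years = yrs, noise_sd = 0.1)
    cal <- classify_enso_years(sst_anomaly(sst))
    expect_identical(as.character(cal$label[cal$year %in% yrs]), sched)
  }
})
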