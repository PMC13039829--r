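test_that("noiseless features equal generator truth", {
  g <- make_erg_trace(erg_trace_spec(a_amplitude_uV = 200,
                                     b_amplitude_uV = 400,
                                     noise_sigma_uV = 0))
  f <- extract_erg_features(g$trace)
  expect_equal(f$a_amplitude_uV, g$truth$a_amplitude_uV)
  expect_equal(f$b_amplitude_uV, g$truth$b_amplitude_uV)
  expect_equal(f$a_implicit_ms, g$truth$a_implicit_ms)
  expect_equal(f$b_implicit_ms, g$truth$b_implicit_ms)
  expect_equal(f$b_a_ratio, 2.0)
  expect_identical(f$mode, "peak")

  flat <- make_erg_trace(erg_trace_spec(a_amplitude_uV = 0,
                                        b_amplitude_uV = 0,
                                        noise_sigma_uV = 0))
  f0 <- extract_erg_features(flat$trace)
  expect_equal(f0$a_amplitude_uV, 0)
  expect_equal(f0$b_amplitude_uV, 0)
})

test_that("reference mode equals a direct voltage lookup from the trough", {
  ## degenerate-retina style trace: residual a-wave, no b-wave peak
  g <- make_erg_trace(erg_trace_spec(a_amplitude_uV = 120,
                                     b_amplitude_uV = 40,
                                     noise_sigma_uV = 0, group = "KO"))
  tr <- g$trace
  ref <- 60  # the control group's b-wave implicit time
  f <- extract_erg_features(tr, reference_implicit_ms = ref)
  i_tr <- which.min(tr$voltage_uV)
  i_ref <- which.min(abs(tr$time_ms - (tr$flash_time_ms + ref)))
  expect_identical(f$mode, "reference")
  expect_equal(f$b_amplitude_uV,
               max(0, tr$voltage_uV[i_ref] - tr$voltage_uV[i_tr]))
  expect_error(extract_erg_features(tr, reference_implicit_ms = 1e5),
               "outside")
})

test_that("reference mode agrees with peak mode when the peak is at the reference", {
  g <- make_erg_trace(erg_trace_spec(a_amplitude_uV = 150,
                                     b_amplitude_uV = 300,
                                     b_implicit_ms = 60,
                                     noise_sigma_uV = 0))
  peak <- extract_erg_features(g$trace)
  refm <- extract_erg_features(g$trace, reference_implicit_ms = 60)
  expect_equal(refm$b_amplitude_uV, peak$b_amplitude_uV)
})

test_that("the b/a ratio is invariant to a constant offset", {
  g <- make_erg_trace(erg_trace_spec(a_amplitude_uV = 180,
                                     b_amplitude_uV = 360,
                                     noise_sigma_uV = 2, seed = 4))
  tr <- g$trace
  f1 <- extract_erg_features(tr)
  tr2 <- erg_trace(tr$time_ms, tr$voltage_uV + 250, tr$flash_time_ms,
                   tr$flash_intensity_log_photons_per_um2, tr$adaptation,
                   tr$group)
  f2 <- extract_erg_features(tr2)
  expect_equal(f1$b_a_ratio, f2$b_a_ratio)
  expect_equal(f1$a_amplitude_uV, f2$a_amplitude_uV)
})

test_that("amplitude recovery error stays within three noise sigmas", {
  sigma <- 15
  errs <- vapply(1:20, function(sd) {
    g <- make_erg_trace(erg_trace_spec(a_amplitude_uV = 250,
                                       b_amplitude_uV = 500,
                                       noise_sigma_uV = sigma, seed = sd))
    f <- extract_erg_features(g$trace)
    abs(f$a_amplitude_uV - g$truth$a_amplitude_uV)
  }, numeric(1))
  expect_lte(mean(errs), 3 * sigma)
})

test_that("intensity-response tables report group means, SEMs and t-tests", {
  mk <- function(amp, group, fi) {
    make_erg_trace(erg_trace_spec(a_amplitude_uV = amp, b_amplitude_uV = 2 * amp,
                                  flash_intensity_log_photons_per_um2 = fi,
                                  noise_sigma_uV = 0, group = group))$trace
  }
  traces <- c(lapply(c(1, 2, 3), mk, group = "WT", fi = 3.0),
              lapply(c(1, 2, 3), mk, group = "KO", fi = 3.0))
  tab <- intensity_response(traces)
  expect_equal(tab$sem, rep(sd(1:3) / sqrt(3), 2))
  expect_equal(unique(tab$p_value), 1)   # identical groups: t = 0

  ## planted separation matches the closed-form Welch tail
  wt <- c(95, 105, 100, 98, 102, 101, 99, 100)
  ko <- c(195, 205, 200, 198, 202, 201, 199, 200)
  traces2 <- c(lapply(wt, mk, group = "WT", fi = 4.0),
               lapply(ko, mk, group = "KO", fi = 4.0))
  tab2 <- intensity_response(traces2)
  v1 <- var(ko); v2 <- var(wt); n <- 8
  tstat <- (mean(ko) - mean(wt)) / sqrt(v1 / n + v2 / n)
  df <- (v1 / n + v2 / n)^2 / ((v1 / n)^2 / (n - 1) + (v2 / n)^2 / (n - 1))
  expect_equal(unique(tab2$p_value), 2 * pt(abs(tstat), df, lower.tail = FALSE),
               tolerance = 1e-10)

  ## an intensity with n < 2 in one group is flagged, not tested
  traces3 <- c(traces2, list(mk(150, "WT", 5.0)))
  tab3 <- intensity_response(traces3)
  row5 <- tab3[tab3$intensity == 5.0, ]
  expect_false(any(row5$tested))
  expect_true(all(is.na(row5$p_value)))
})

test_that("degenerate records are rejected with clear errors", {
  tr <- make_erg_trace(erg_trace_spec(noise_sigma_uV = 0))$trace
  ## no baseline window before the flash
  short <- erg_trace(tr$time_ms[tr$time_ms >= 100],
                     tr$voltage_uV[tr$time_ms >= 100], 100)
  expect_error(extract_erg_features(short), "baseline")
})
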