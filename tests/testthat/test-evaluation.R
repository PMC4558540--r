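cfg <- default_cfg()

test_that("rms_error matches hand-computed values and is permutation invariant", {
  truth <- list(x0 = 100, y0 = 50, z0 = 200)
  est <- data.frame(x_nm = c(103, 96), y_nm = c(50, 50), z_nm = c(200, 200))
  expect_equal(rms_error(est, truth, "x"), sqrt(25 / 2)) # 3.5355
  expect_equal(rms_error(est, truth, "x"),
               rms_error(est[2:1, ], truth, "x"))
  expect_equal(rms_error(est, truth, "z"), 0)
  expect_equal(rms_error(data.frame(x_nm = 100, y_nm = 50, z_nm = 200),
                         truth, "lateral"), 0)
  expect_error(rms_error(est[0, ], truth, "x"), "no estimates")
})

test_that("saddle metrics agree with the closed-form Gaussian and scale out", {
  sig <- 200
  fr <- gaussian_psf_frame(data.frame(x0 = 1020, y0 = 1020), sigma = sig,
                           frame_shape = c(21, 21))
  # both "centers" placed +-3 pixels from the peak along x, midpoint = peak
  a <- c(1020 - 3 * 102, 1020)
  b <- c(1020 + 3 * 102, 1020)
  sm <- saddle_metrics(fr, a, b)
  expect_equal(sm$peak_value, exp(-(3 * 102)^2 / (2 * sig^2)), tolerance = 1e-12)
  expect_equal(sm$midpoint_value, 1, tolerance = 1e-12)
  sm2 <- saddle_metrics(100 * fr, a, b)
  expect_equal(sm2$peak_to_saddle_ratio, sm$peak_to_saddle_ratio)
  expect_error(saddle_metrics(fr, a, a), "coincide")
})

test_that("sigma_reduction is 0 for identical frames and 0.5 for a half-width spot", {
  fr <- gaussian_psf_frame(data.frame(x0 = 1020, y0 = 1020), sigma = 200)
  expect_equal(sigma_reduction(fr, fr), 0, tolerance = 1e-8)
  narrow <- gaussian_psf_frame(data.frame(x0 = 1020, y0 = 1020), sigma = 100)
  expect_equal(sigma_reduction(fr, narrow), 0.5, tolerance = 1e-6)
})

test_that("noiseless single-emitter experiments give near-zero matched-model RMS", {
  mc <- mc_localization_experiment(
    config = cfg, photon_levels = 5000, nb = 0, L = 3,
    methods = "gaussian_raw", seed = 3, psf_model = "gaussian",
    shot_noise = FALSE)
  expect_lt(mc$rms_lateral, 0.01)
  expect_lt(mc$rms_axial, 0.01)
  expect_equal(mc$n_used, 3L)
})

test_that("mc experiments are reproducible under a fixed seed", {
  run <- function() mc_localization_experiment(
    config = cfg, photon_levels = 2000, nb = 5, L = 4,
    methods = "gaussian_raw", seed = 11, psf_model = "gaussian")
  expect_identical(as.data.frame(run()), as.data.frame(run()))
})

test_that("far-separated emitters are resolved at full rate", {
  r <- min_resolvable_distance(config = cfg, axis = "lateral", method = "raw",
                               distances = 2000, trials = 8, seed = 2,
                               psf_model = "gaussian")
  expect_equal(r$min_distance, 2000)
  expect_equal(r$scan$resolved_rate, 1)
})

test_that("an unresolvable grid reports the infinite sentinel with its scan", {
  r <- min_resolvable_distance(config = cfg, axis = "lateral", method = "raw",
                               distances = c(50, 100), trials = 5, seed = 2,
                               psf_model = "gaussian")
  expect_true(is.infinite(r$min_distance))
  expect_equal(nrow(r$scan), 2L)
})

test_that("tidy/glance/autoplot surfaces work on harness results", {
  mc <- mc_localization_experiment(
    config = cfg, photon_levels = c(1000, 2000), nb = 5, L = 3,
    methods = "gaussian_raw", seed = 5, psf_model = "gaussian")
  td <- tidy(mc)
  expect_true(all(c("photons", "method", "axis", "rms_nm") %in% names(td)))
  expect_equal(nrow(td), 4L)
  expect_equal(glance(mc)$L, 3L)
  expect_s3_class(autoplot(mc), "ggplot")
  r <- min_resolvable_distance(config = cfg, axis = "lateral", method = "raw",
                               distances = 2000, trials = 3, seed = 2,
                               psf_model = "gaussian")
  expect_s3_class(autoplot(r), "ggplot")
  expect_equal(glance(r)$min_distance_nm, 2000)
  st <- gaussian_psf_stack(one_emitter(cfg), cfg)
  f <- fit_gaussian(extract_roi(st, find_candidates(st, min_peak = 1)[1, ]), cfg)
  expect_equal(nrow(tidy(f)), 6L)
  expect_true(glance(f)$converged)
})
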