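test_that("theoretical widths reproduce the reference imaging configuration", {
  cfg <- default_cfg()
  s <- theoretical_sigmas(cfg)
  # printed reference values for NA = 1.4, lambda = 540 nm
  expect_equal(unname(round(s["sigma_xy"])), 167)
  expect_equal(unname(round(s["sigma_z"])), 413)
})

test_that("theoretical widths are homogeneous of degree one in wavelength", {
  s1 <- theoretical_sigmas(default_cfg(emission_wavelength = 540))
  s2 <- theoretical_sigmas(default_cfg(emission_wavelength = 1080))
  expect_equal(unname(s2 / s1), c(2, 2))
})

test_that("frozen regression value for a water-immersion configuration", {
  # hand evaluation of the closed forms at NA = 1.0, lambda = 500, n = 1.33:
  # sqrt(3)*500/4 = 216.5063...; 3*500/2 = 750
  s <- theoretical_sigmas(default_cfg(numerical_aperture = 1,
                                      emission_wavelength = 500,
                                      immersion_refractive_index = 1.33))
  expect_equal(unname(s), c(sqrt(3) * 125, 750), tolerance = 1e-12)
})

test_that("non-physical apertures are rejected", {
  expect_error(theoretical_sigmas(default_cfg(numerical_aperture = 1.52)),
               "numerical aperture")
  expect_error(optical_config(lateral_pixel_size = -1))
  expect_error(noise_model(background_mean = -2))
  expect_error(gibson_lanni_params(quadrature_order = 8))
})
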