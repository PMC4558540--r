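cfg <- default_cfg()

test_that("gaussian stack integrates to the photon count and is symmetric", {
  # odd grid with the emitter at the exact center voxel
  st <- gaussian_psf_stack(one_emitter(cfg), cfg)
  v <- st$voxels
  # widths ~167/413 nm on a 21x21x17 grid: the volume spans > +-6 sigma
  expect_lt(abs(sum(v) - 5000) / 5000, 1e-3)
  expect_equal(v, v[, , dim(v)[3]:1])             # x reflection
  expect_equal(v, v[, dim(v)[2]:1, ])             # y reflection
  expect_equal(which.max(v), which(v == v[9, 11, 11])) # central voxel is max
})

test_that("noiseless gaussian decays monotonically away from the center", {
  st <- gaussian_psf_stack(one_emitter(cfg), cfg)
  prof_x <- st$voxels[9, 11, 11:21]
  prof_z <- st$voxels[9:17, 11, 11]
  expect_true(all(diff(prof_x) < 0))
  expect_true(all(diff(prof_z) < 0))
})

test_that("emitters outside the volume and bad widths are rejected", {
  bad <- data.frame(x0 = -50, y0 = 1020, z0 = 1600, photons = 5000)
  expect_error(gaussian_psf_stack(bad, cfg), "outside")
  expect_error(gaussian_psf_stack(one_emitter(cfg), cfg, widths = c(-1, 400)),
               "positive")
})

test_that("poisson noise has matching mean and variance and a fixed seed reproduces", {
  flat <- image_stack(array(0, c(40, 60, 60)))
  nm <- noise_model(background_mean = 5, seed = 99)
  noisy <- add_noise(flat, nm)
  n <- length(noisy$voxels)
  expect_gte(n, 1e5)
  se_mean <- sqrt(5 / n)
  expect_lt(abs(mean(noisy$voxels) - 5), 3 * se_mean)
  # Poisson variance = mean; SE of the sample variance ~ sqrt((mu + 2 mu^2)/n)
  se_var <- sqrt((5 + 2 * 25) / n)
  expect_lt(abs(stats::var(as.vector(noisy$voxels)) - 5), 3 * se_var)
  expect_identical(noisy$voxels, add_noise(flat, nm)$voxels)
})

test_that("zero background on a zero stack stays zero and expectation is conserved", {
  flat <- image_stack(array(0, c(2, 5, 5)))
  out <- add_noise(flat, noise_model(background_mean = 0, seed = 1))
  expect_true(all(out$voxels == 0))
  st <- gaussian_psf_stack(one_emitter(cfg), cfg)
  tot <- replicate(30, sum(add_noise(st, noise_model(5))$voxels))
  expected <- sum(st$voxels) + 5 * length(st$voxels)
  # conservation of the expected photon count, 3 sigma band
  se <- sqrt((sum(st$voxels) + 5 * length(st$voxels)) / 30)
  expect_lt(abs(mean(tot) - expected), 3 * se)
})

test_that("aberration-free gibson-lanni matches the Airy pattern in focus", {
  cfg2 <- optical_config(frame_shape = c(15, 15), n_frames = 9)
  gl <- gibson_lanni_params()
  tab <- kfactor3d:::gl_table(cfg2, gl, z_max = 2000, r_max = 2000, dr = 1)
  prof <- as.vector(kfactor3d:::gl_lookup(tab, seq(0, 500, 1), 0))
  # first zero of the in-focus radial profile at ~0.61 lambda / NA
  i0 <- which(diff(sign(diff(prof))) > 0)[1] + 1
  expect_lt(abs(seq(0, 500, 1)[i0] - 0.61 * 540 / 1.4), 5)
})

test_that("aberration-free gibson-lanni stack is symmetric and normalized", {
  cfg2 <- optical_config(frame_shape = c(15, 15), n_frames = 9)
  em <- data.frame(x0 = 7 * 102, y0 = 7 * 102, z0 = 4 * 200, photons = 3000)
  st <- gibson_lanni_psf_stack(em, gibson_lanni_params(), cfg2)
  v <- st$voxels
  expect_equal(sum(v), 3000, tolerance = 1e-9)
  # mirror symmetry about the focal plane
  expect_equal(v[4, , ], v[6, , ], tolerance = 1e-6)
  # circular symmetry in focus: compare the four axis-neighbors of the peak
  ring <- c(v[5, 8, 10], v[5, 8, 6], v[5, 10, 8], v[5, 6, 8])
  expect_lt(diff(range(ring)) / max(v), 1e-6)
  expect_true(all(v >= 0))
})
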