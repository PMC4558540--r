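test_that("the default schedule has nine factors, all in (0,1), non-increasing", {
  sch <- default_schedule()
  expect_equal(sch$M, 9L)
  expect_true(all(sch$k_values > 0 & sch$k_values < 1))
  expect_true(all(diff(sch$k_values) <= 0))
  expect_error(kfactor_schedule(c(0.5, 1)), "strictly in")
  expect_error(kfactor_schedule(numeric(0)))
})

test_that("masks are binary and factors finite on random frames", {
  set.seed(42)
  for (i in 1:10) {
    fr <- matrix(stats::rexp(256) + 1e-6, 16, 16)
    dec <- kfactor_decompose(fr)
    expect_true(all(vapply(dec$masks, function(m) all(m %in% c(0, 1)), TRUE)))
    expect_true(all(vapply(dec$factors, function(f) all(is.finite(f) & f > 0), TRUE)))
  }
})

test_that("reconstruction error is non-increasing in M against the prefix-product oracle", {
  set.seed(7)
  fr <- matrix(stats::runif(64, 0.01, 1), 8, 8)
  sch <- kfactor_schedule(rep(0.6, 12)) # fixed-k schedule
  dec <- kfactor_decompose(fr, sch)
  errs <- vapply(seq_len(12), function(m) {
    sqrt(sum((prefix_reconstruction(dec, m) - fr)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  # full reconstruction agrees with the oracle and with kfactor_reconstruct
  expect_equal(kfactor_reconstruct(dec), prefix_reconstruction(dec, 12))
})

test_that("reconstruction error is bounded by the contrast-quantization step", {
  set.seed(8)
  fr <- matrix(stats::runif(64, 0.05, 1), 8, 8)
  sch <- kfactor_schedule(rep(0.5, 10))
  rec <- kfactor_reconstruct(kfactor_decompose(fr, sch))
  # quantization to the k = 0.5 contrast ladder rounds each pixel up to the
  # nearest ladder level: within a factor 2 above the value
  nf <- fr / max(fr)
  rn <- rec / max(fr)
  expect_true(all(rn >= nf - 1e-12))
  expect_true(all(rn <= nf / 0.5 + 1e-12))
})

test_that("constant and single-pixel frames decompose degenerately", {
  cf <- matrix(3.7, 5, 5)
  dec <- kfactor_decompose(cf)
  for (m in dec$masks) expect_true(all(m == m[1, 1]))
  expect_equal(kfactor_reconstruct(dec), cf)
  expect_error(kfactor_decompose(matrix(0, 4, 4)), "all zero")

  single <- matrix(0, 5, 5)
  single[3, 2] <- 2
  ds <- deshadow_frame(single)
  expect_equal(which.max(ds), which.max(single))
  expect_equal(max(ds), 2)
})

test_that("deshadowing is scale-covariant and preserves an isolated PSF argmax", {
  fr <- gaussian_psf_frame(data.frame(x0 = 1030, y0 = 1010), sigma = 200)
  d1 <- deshadow_frame(fr)
  d2 <- deshadow_frame(7.3 * fr)
  expect_equal(7.3 * d1, d2, tolerance = 1e-12)
  expect_equal(which.max(d1), which.max(fr))
  expect_true(all(d1 >= 0))
  expect_equal(max(d1), max(fr))
})

test_that("deshadowing strictly narrows noiseless Gaussian spots (sigma 1-4 px)", {
  for (sig_px in c(1, 2, 3, 4)) {
    fr <- gaussian_psf_frame(data.frame(x0 = 15 * 102, y0 = 15 * 102),
                             sigma = sig_px * 102, frame_shape = c(31, 31))
    red <- sigma_reduction(fr, deshadow_frame(fr))
    expect_gt(red, 0)
  }
})

test_that("deshadowing suppresses a constant pedestal relative to the peak", {
  fr <- gaussian_psf_frame(data.frame(x0 = 1020, y0 = 1020), sigma = 200) + 0.2
  ds <- deshadow_frame(fr)
  expect_lt(min(ds) / max(ds), min(fr) / max(fr))
})

test_that("deshadow_stack works plane-by-plane and commutes with plane permutation", {
  cfg <- default_cfg(n_frames = 5L)
  st <- gaussian_psf_stack(one_emitter(cfg, dz = -150), cfg)
  ds <- deshadow_stack(st)
  # single-plane agreement with deshadow_frame
  expect_equal(ds$voxels[2, , ], deshadow_frame(st$voxels[2, , ]))
  # permutation equivariance: processing is independent per plane
  perm <- c(3, 1, 5, 2, 4)
  stp <- image_stack(st$voxels[perm, , ], st$lateral_pixel_size, st$axial_step)
  expect_equal(deshadow_stack(stp)$voxels, ds$voxels[perm, , ])
  # degenerate single-frame stack
  st1 <- image_stack(st$voxels[3, , , drop = FALSE])
  expect_equal(deshadow_stack(st1)$voxels[1, , ], deshadow_frame(st$voxels[3, , ]))
})
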