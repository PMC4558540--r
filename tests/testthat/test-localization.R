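cfg <- default_cfg()

test_that("a noiseless PSF yields exactly one candidate at the center voxel", {
  st <- gaussian_psf_stack(one_emitter(cfg), cfg)
  cands <- find_candidates(st, min_peak = 1)
  expect_equal(nrow(cands), 1L)
  expect_equal(c(cands$ix, cands$iy, cands$iz), c(10L, 10L, 8L))
  empty <- find_candidates(image_stack(array(0, c(3, 7, 7))), min_peak = 0)
  expect_equal(nrow(empty), 0L)
})

test_that("well-separated emitters match brute-force local-maximum enumeration", {
  em <- data.frame(x0 = c(510, 1530), y0 = 1020, z0 = 1600,
                   photons = c(5000, 4000))
  st <- gaussian_psf_stack(em, cfg)
  cands <- find_candidates(st, min_peak = 1, smooth = 0)
  expect_equal(nrow(cands), 2L)
  oracle <- brute_local_maxima(st$voxels, floor_val = 1)
  expect_equal(nrow(oracle), 2L)
  got <- cbind(cands$iz + 1, cands$iy + 1, cands$ix + 1)
  expect_setequal(paste(got[, 1], got[, 2], got[, 3]),
                  paste(oracle[, 1], oracle[, 2], oracle[, 3]))
})

test_that("ROI extraction gives 9^3 interior windows and consistent clipping", {
  st <- gaussian_psf_stack(one_emitter(cfg), cfg)
  cand <- find_candidates(st, min_peak = 1)[1, ]
  roi <- extract_roi(st, cand)
  expect_equal(dim(roi$voxels), c(9L, 9L, 9L))
  expect_equal(roi$voxels[5, 5, 5],
               st$voxels[cand$iz + 1, cand$iy + 1, cand$ix + 1])
  # corner candidate: clipped but values still match the stack
  corner <- list(ix = 1L, iy = 0L, iz = 0L)
  roic <- extract_roi(st, corner)
  expect_equal(dim(roic$voxels), c(5L, 5L, 6L))
  expect_equal(unname(roic$offset), c(0L, 0L, 0L))
  expect_equal(roic$voxels[1, 1, 1], st$voxels[1, 1, 1])
})

test_that("noiseless matched-model fits recover the truth to sub-hundredth-voxel", {
  em <- one_emitter(cfg, dx = 30, dy = -40, dz = 70)
  st <- gaussian_psf_stack(em, cfg)
  loc <- localize_stack(st, cfg, min_peak = 1)
  expect_equal(nrow(loc), 1L)
  expect_true(loc$converged)
  expect_lt(abs(loc$x_nm - em$x0), 0.01)
  expect_lt(abs(loc$y_nm - em$y0), 0.01)
  expect_lt(abs(loc$z_nm - em$z0), 0.01)
  expect_lt(abs(loc$photons - em$photons) / em$photons, 1e-4)
})

test_that("flat ROIs are reported as non-converged", {
  flat <- image_stack(array(2, c(9, 9, 9)))
  roi <- extract_roi(flat, list(ix = 4L, iy = 4L, iz = 4L))
  f <- fit_gaussian(roi, cfg)
  expect_false(f$converged)
  f2 <- fit_gibson_lanni(roi, cfg, gibson_lanni_params())
  expect_false(f2$converged)
})

test_that("whole-voxel translations shift the estimates exactly", {
  em <- one_emitter(cfg, dx = 20, dy = -30, dz = 45)
  st <- gaussian_psf_stack(em, cfg)
  em2 <- em
  em2$x0 <- em$x0 + 2 * cfg$lateral_pixel_size
  em2$y0 <- em$y0 - cfg$lateral_pixel_size
  em2$z0 <- em$z0 + cfg$axial_step
  st2 <- gaussian_psf_stack(em2, cfg)
  l1 <- localize_stack(st, cfg, min_peak = 1)
  l2 <- localize_stack(st2, cfg, min_peak = 1)
  expect_equal(l2$x_nm - l1$x_nm, 2 * cfg$lateral_pixel_size, tolerance = 1e-6)
  expect_equal(l2$y_nm - l1$y_nm, -cfg$lateral_pixel_size, tolerance = 1e-6)
  expect_equal(l2$z_nm - l1$z_nm, cfg$axial_step, tolerance = 1e-6)
})

test_that("noiseless gibson-lanni fits are self-consistent within a nanometer", {
  gl <- gibson_lanni_params()
  em <- one_emitter(cfg, dx = 25, dy = -35, dz = 60)
  st <- gibson_lanni_psf_stack(em, gl, cfg)
  loc <- localize_stack(st, cfg, model = "gibson-lanni", gl = gl,
                        min_peak = 0, rel_peak = 0.3)
  best <- loc[which.max(loc$seed_peak), ]
  expect_true(best$converged)
  expect_lt(abs(best$x_nm - em$x0), 1)
  expect_lt(abs(best$y_nm - em$y0), 1)
  expect_lt(abs(best$z_nm - em$z0), 1)
})

test_that("a mismatched model leaves a larger residual than the matched one", {
  gl <- gibson_lanni_params()
  st <- gaussian_psf_stack(one_emitter(cfg), cfg)
  cand <- find_candidates(st, min_peak = 1)[1, ]
  roi <- extract_roi(st, cand)
  matched <- fit_gaussian(roi, cfg)
  mismatched <- fit_gibson_lanni(roi, cfg, gl)
  expect_true(matched$converged)
  expect_gt(mismatched$residual_norm, matched$residual_norm)
})

test_that("estimated z increases monotonically with true z across the stack", {
  gl <- gibson_lanni_params()
  zs <- seq(-400, 400, 200) # +-2 planes of defocus
  est <- vapply(zs, function(dz) {
    em <- one_emitter(cfg, dz = dz)
    st <- gibson_lanni_psf_stack(em, gl, cfg)
    loc <- localize_stack(st, cfg, model = "gibson-lanni", gl = gl,
                          min_peak = 0, rel_peak = 0.3)
    loc$z_nm[which.max(loc$seed_peak)]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("localize_stack handles empty stacks and never aborts the batch", {
  empty <- image_stack(array(0, c(3, 9, 9)))
  out <- localize_stack(empty, cfg, min_peak = 5)
  expect_equal(nrow(out), 0L)
})
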