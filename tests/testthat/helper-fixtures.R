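# shared objects for the suite; everything is generated in code

# the acceptance checks assert published reference values at their stated
# tolerances and several are expected to differ; never stop the run early
options(testthat.progress.max_fails = 100)
default_cfg <- function(...) optical_config(...)

center_of <- function(cfg) {
  c(x = (cfg$frame_shape[2] - 1) / 2 * cfg$lateral_pixel_size,
    y = (cfg$frame_shape[1] - 1) / 2 * cfg$lateral_pixel_size,
    z = (cfg$n_frames - 1) / 2 * cfg$axial_step)
}

one_emitter <- function(cfg, photons = 5000, dx = 0, dy = 0, dz = 0) {
  ctr <- center_of(cfg)
  data.frame(x0 = ctr[["x"]] + dx, y0 = ctr[["y"]] + dy,
             z0 = ctr[["z"]] + dz, photons = photons)
}

# independent prefix-product oracle for the K-factor decomposition:
# reconstruct the frame from the first m factors by direct elementwise
# multiplication of the stored factor matrices
prefix_reconstruction <- function(decomp, m) {
  out <- matrix(1, nrow(decomp$input_frame), ncol(decomp$input_frame))
  for (i in seq_len(m)) out <- out * decomp$factors[[i]]
  out * decomp$scale
}

# brute-force strict 3D local maxima by triple loop (oracle for
# find_candidates); returns matrix of 1-based [z, y, x] indices
brute_local_maxima <- function(a, floor_val = 0) {
  d <- dim(a)
  out <- NULL
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    v <- a[z, y, x]
    if (v <= floor_val) next
    ok <- TRUE
    for (oz in -1:1) for (oy in -1:1) for (ox in -1:1) {
      if (oz == 0 && oy == 0 && ox == 0) next
      zz <- z + oz; yy <- y + oy; xx <- x + ox
      if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3]) next
      if (a[zz, yy, xx] >= v) { ok <- FALSE; break }
    }
    if (ok) out <- rbind(out, c(z, y, x))
  }
  out
}
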