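#' Simulate a noiseless 3D Gaussian PSF stack
#'
#' Samples the separable 3D Gaussian emitter model on the voxel grid. For an
#' emitter with total photon count N at (x0, y0, z0), the intensity at a
#' voxel center is
#' \deqn{I(x,y,z) = \frac{N\,v}{(2\pi)^{3/2}\sigma_{xy}^2\sigma_z}
#'   \exp\!\Big(-\frac{(x-x_0)^2+(y-y_0)^2}{2\sigma_{xy}^2}
#'              -\frac{(z-z_0)^2}{2\sigma_z^2}\Big)}
#' with v the voxel volume, so the sum over an unbounded grid equals N
#' ("total collected photons" convention). Emitters are summed (incoherent
#' intensities). Values are sampled at voxel centers, not integrated over
#' the pixel area, which keeps the simulator consistent with the fitted
#' model.
#'
#' @param emitters Data frame with columns `x0`, `y0`, `z0` (nm; voxel-center
#'   origin, see [image_stack()]) and `photons` (> 0).
#' @param config An [optical_config()]; supplies sampling and grid size.
#' @param widths Numeric `c(sigma_xy, sigma_z)` in nm; defaults to
#'   [theoretical_sigmas()] of `config`.
#' @return A noiseless [image_stack()].
#' @examples
#' cfg <- optical_config()
#' em <- data.frame(x0 = 1020, y0 = 1020, z0 = 1600, photons = 5000)
#' st <- gaussian_psf_stack(em, cfg)
#' sum(st$voxels)  # ~ 5000
#' @export
gaussian_psf_stack <- function(emitters, config,
                               widths = theoretical_sigmas(config)) {
  stopifnot(inherits(config, "kf_optical_config"))
  emitters <- as.data.frame(emitters)
  check_emitters(emitters, config)
  sxy <- widths[[1]]
  sz <- widths[[2]]
  if (sxy <= 0 || sz <= 0) stop("PSF widths must be positive")

  px <- config$lateral_pixel_size
  dz <- config$axial_step
  nr <- config$frame_shape[1]
  nc <- config$frame_shape[2]
  nz <- config$n_frames
  xs <- (seq_len(nc) - 1) * px
  ys <- (seq_len(nr) - 1) * px
  zs <- (seq_len(nz) - 1) * dz

  vox <- array(0, c(nz, nr, nc))
  amp0 <- px^2 * dz / ((2 * pi)^1.5 * sxy^2 * sz)
  for (i in seq_len(nrow(emitters))) {
    gx <- exp(-(xs - emitters$x0[i])^2 / (2 * sxy^2))
    gy <- exp(-(ys - emitters$y0[i])^2 / (2 * sxy^2))
    gz <- exp(-(zs - emitters$z0[i])^2 / (2 * sz^2))
    amp <- emitters$photons[i] * amp0
    lat <- outer(gy, gx)
    for (iz in seq_len(nz)) vox[iz, , ] <- vox[iz, , ] + amp * gz[iz] * lat
  }
  image_stack(vox, lateral_pixel_size = px, axial_step = dz)
}

#' Simulate a noiseless 2D Gaussian PSF frame
#'
#' Single-plane convenience generator used for in-plane illustrations and the
#' two-emitter saddle analyses: each emitter contributes an isotropic 2D
#' Gaussian with standard deviation `sigma` (nm) and unit peak amplitude
#' scaled by `photons` (intensities sum).
#'
#' @param emitters Data frame with columns `x0`, `y0` (nm) and optionally
#'   `photons` (relative peak amplitude; default 1).
#' @param sigma Gaussian standard deviation, nm.
#' @param frame_shape `c(rows, cols)` pixels.
#' @param pixel_size Lateral pixel size, nm.
#' @return A numeric matrix.
#' @examples
#' fr <- gaussian_psf_frame(data.frame(x0 = c(918, 1118), y0 = 1020),
#'                          sigma = 200)
#' @export
gaussian_psf_frame <- function(emitters, sigma, frame_shape = c(21L, 21L),
                               pixel_size = 102) {
  emitters <- as.data.frame(emitters)
  stopifnot(sigma > 0, all(c("x0", "y0") %in% names(emitters)))
  if (is.null(emitters$photons)) emitters$photons <- 1
  xs <- (seq_len(frame_shape[2]) - 1) * pixel_size
  ys <- (seq_len(frame_shape[1]) - 1) * pixel_size
  fr <- matrix(0, frame_shape[1], frame_shape[2])
  for (i in seq_len(nrow(emitters))) {
    fr <- fr + emitters$photons[i] *
      outer(exp(-(ys - emitters$y0[i])^2 / (2 * sigma^2)),
            exp(-(xs - emitters$x0[i])^2 / (2 * sigma^2)))
  }
  fr
}

check_emitters <- function(emitters, config) {
  need <- c("x0", "y0", "z0", "photons")
  if (!all(need %in% names(emitters))) {
    stop("emitters must have columns ", paste(need, collapse = ", "))
  }
  if (any(emitters$photons <= 0)) stop("emitter photon counts must be > 0")
  px <- config$lateral_pixel_size
  dz <- config$axial_step
  xmax <- (config$frame_shape[2] - 1) * px
  ymax <- (config$frame_shape[1] - 1) * px
  zmax <- (config$n_frames - 1) * dz
  ok <- emitters$x0 >= 0 & emitters$x0 <= xmax &
    emitters$y0 >= 0 & emitters$y0 <= ymax &
    emitters$z0 >= 0 & emitters$z0 <= zmax
  if (!all(ok)) {
    stop("emitter(s) ", paste(which(!ok), collapse = ", "),
         " lie outside the simulated volume")
  }
  invisible(TRUE)
}

#' Add Poisson shot and background noise to a stack
#'
#' Each voxel is replaced by `Poisson(value) + Poisson(N_b)` (independent
#' draws); with shot noise disabled the noiseless value is kept and only the
#' Poisson background is added. With a seed in the [noise_model()] the result
#' is bit-reproducible.
#'
#' @param stack A [image_stack()].
#' @param noise A [noise_model()].
#' @return A noisy [image_stack()] (integer-valued photon counts).
#' @examples
#' st <- gaussian_psf_stack(
#'   data.frame(x0 = 1020, y0 = 1020, z0 = 1600, photons = 5000),
#'   optical_config())
#' noisy <- add_noise(st, noise_model(background_mean = 5, seed = 7))
#' @export
add_noise <- function(stack, noise) {
  stopifnot(inherits(stack, "kf_image_stack"), inherits(noise, "kf_noise_model"))
  draw <- function() {
    v <- stack$voxels
    n <- length(v)
    out <- if (noise$shot_noise_enabled) {
      stats::rpois(n, lambda = as.vector(v))
    } else {
      as.vector(v)
    }
    if (noise$background_mean > 0) {
      out <- out + stats::rpois(n, lambda = noise$background_mean)
    }
    array(as.double(out), dim(v))
  }
  vox <- if (!is.null(noise$seed)) withr::with_seed(noise$seed, draw()) else draw()
  image_stack(vox, stack$lateral_pixel_size, stack$axial_step)
}
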