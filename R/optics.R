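#' Optical configuration of the imaging system
#'
#' Bundles the acquisition parameters that every simulator and fitter needs:
#' the objective numerical aperture, the emission wavelength, the immersion
#' refractive index, and the sampling of the camera grid in the object plane.
#'
#' The defaults describe a 63x/NA 1.4 oil-immersion objective imaging at
#' 540 nm onto a camera whose pixels project to 102 nm in the object plane,
#' with 200 nm steps between optical sections.
#'
#' @param numerical_aperture Objective numerical aperture (dimensionless, > 0).
#' @param emission_wavelength Emission wavelength in nm (> 0).
#' @param immersion_refractive_index Refractive index of the immersion medium
#'   between coverslip and objective (>= 1). 1.515 is standard immersion oil.
#' @param lateral_pixel_size Pixel size in the object plane, nm.
#' @param axial_step Spacing between z planes, nm.
#' @param frame_shape Integer vector `c(rows, cols)` of each z plane.
#' @param n_frames Number of z planes in a simulated stack.
#'
#' @return An object of class `kf_optical_config` (a named list).
#' @examples
#' cfg <- optical_config()
#' theoretical_sigmas(cfg)
#' @export
optical_config <- function(numerical_aperture = 1.4,
                           emission_wavelength = 540,
                           immersion_refractive_index = 1.515,
                           lateral_pixel_size = 102,
                           axial_step = 200,
                           frame_shape = c(21L, 21L),
                           n_frames = 17L) {
  stopifnot(
    numerical_aperture > 0,
    emission_wavelength > 0,
    immersion_refractive_index >= 1,
    lateral_pixel_size > 0,
    axial_step > 0,
    length(frame_shape) == 2L, all(frame_shape >= 1),
    n_frames >= 1
  )
  structure(
    list(
      numerical_aperture = numerical_aperture,
      emission_wavelength = emission_wavelength,
      immersion_refractive_index = immersion_refractive_index,
      lateral_pixel_size = lateral_pixel_size,
      axial_step = axial_step,
      frame_shape = as.integer(frame_shape),
      n_frames = as.integer(n_frames)
    ),
    class = "kf_optical_config"
  )
}

#' @export
print.kf_optical_config <- function(x, ...) {
  cat("<optical config>  NA =", x$numerical_aperture,
      " lambda =", x$emission_wavelength, "nm",
      " n =", x$immersion_refractive_index, "\n",
      " sampling:", x$lateral_pixel_size, "nm lateral /",
      x$axial_step, "nm axial;",
      paste(x$frame_shape, collapse = "x"), "px x",
      x$n_frames, "planes\n")
  invisible(x)
}

#' Closed-form Gaussian PSF widths of an aberration-free widefield system
#'
#' Returns the standard deviations of the Gaussian approximation to the
#' in-focus widefield point-spread function,
#' \deqn{\sigma_{x,y} = \frac{\sqrt{3}\,\lambda}{4\,\mathrm{NA}}, \qquad
#'       \sigma_z = \frac{3\,\lambda}{2\,\mathrm{NA}^2},}
#' i.e. the lateral and axial diffraction scales of the objective. For a
#' 1.4 NA oil objective at 540 nm these evaluate to 167 nm laterally and
#' 413 nm axially. Both widths are homogeneous of degree one in the
#' wavelength. The formula is only meaningful when the aperture is physical
#' (NA strictly below the immersion index), which is enforced.
#'
#' @param config An [optical_config()].
#' @return Named numeric vector `c(sigma_xy, sigma_z)` in nm.
#' @examples
#' theoretical_sigmas(optical_config(numerical_aperture = 1.4,
#'                                   emission_wavelength = 540))
#' @export
theoretical_sigmas <- function(config) {
  stopifnot(inherits(config, "kf_optical_config"))
  na <- config$numerical_aperture
  n <- config$immersion_refractive_index
  lam <- config$emission_wavelength
  if (na >= n) {
    stop("non-physical configuration: numerical aperture (", na,
         ") must be smaller than the immersion refractive index (", n, ")")
  }
  c(sigma_xy = sqrt(3) * lam / (4 * na),
    sigma_z = 3 * lam / (2 * na^2))
}

#' Poisson noise model for simulated acquisitions
#'
#' Background photons arrive as a Poisson process with mean `background_mean`
#' per pixel (so its variance equals its mean), and shot noise replaces every
#' noiseless pixel value by a Poisson draw with that value as its expectation.
#'
#' @param background_mean Mean background photons per pixel (N_b, >= 0).
#' @param shot_noise_enabled If `FALSE`, the noiseless signal is kept and only
#'   background is added.
#' @param seed Optional integer seed; when set, [add_noise()] is reproducible.
#' @return An object of class `kf_noise_model`.
#' @examples
#' noise_model(background_mean = 5, seed = 1)
#' @export
noise_model <- function(background_mean = 5, shot_noise_enabled = TRUE,
                        seed = NULL) {
  if (background_mean < 0) stop("background_mean must be >= 0")
  structure(
    list(background_mean = background_mean,
         shot_noise_enabled = isTRUE(shot_noise_enabled),
         seed = seed),
    class = "kf_noise_model"
  )
}

#' Layer parameters for the Gibson-Lanni point-spread-function model
#'
#' Describes the optical path from the emitter to the objective as three
#' strata (sample, coverslip, immersion), each with a design value (what the
#' objective was corrected for) and an actual value. Index or thickness
#' mismatches, and a particle seated at depth inside the sample, produce the
#' spherical-aberration phase that shapes real defocused images. With all
#' actual values equal to design and zero depth the model reduces to the
#' aberration-free diffraction pattern of a circular aperture.
#'
#' @param ni,ni_design Actual/design immersion refractive index.
#' @param ng,ng_design Actual/design coverslip refractive index.
#' @param tg,tg_design Actual/design coverslip thickness, nm.
#' @param ns Sample refractive index.
#' @param particle_depth Depth of the emitter inside the sample, nm (>= 0).
#' @param quadrature_order Number of Gauss-Legendre nodes over the normalized
#'   pupil radius (>= 16).
#' @return An object of class `kf_gibson_lanni_params`.
#' @examples
#' gibson_lanni_params()                      # aberration-free
#' gibson_lanni_params(ns = 1.38, particle_depth = 2000)  # cell-like mismatch
#' @export
gibson_lanni_params <- function(ni = 1.515, ni_design = 1.515,
                                ng = 1.515, ng_design = 1.515,
                                tg = 170e3, tg_design = 170e3,
                                ns = 1.515,
                                particle_depth = 0,
                                quadrature_order = 64L) {
  stopifnot(
    ni >= 1, ni_design >= 1, ng >= 1, ng_design >= 1, ns >= 1,
    tg >= 0, tg_design >= 0, particle_depth >= 0,
    quadrature_order >= 16
  )
  structure(
    list(ni = ni, ni_design = ni_design, ng = ng, ng_design = ng_design,
         tg = tg, tg_design = tg_design, ns = ns,
         particle_depth = particle_depth,
         quadrature_order = as.integer(quadrature_order)),
    class = "kf_gibson_lanni_params"
  )
}
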