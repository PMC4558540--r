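#' Generate deterministic simulation fixtures on disk
#'
#' Writes a TIFF stack (with JSON sidecar) plus a ground-truth CSV for one of
#' the named test scenes, all at the default acquisition settings (102 nm
#' pixels, 200 nm z-step, N = 5000 photons per emitter, Poisson background
#' N_b = 5). The same name and seed always produce identical bytes.
#'
#' Scenes:
#' \describe{
#'   \item{`single-emitter`}{one emitter near the volume center, noisy.}
#'   \item{`two-lateral`}{two emitters 550 nm apart in x, noisy.}
#'   \item{`two-axial`}{two emitters 450 nm apart in z, noisy.}
#'   \item{`fig1-noiseless`}{single plane, two sigma = 200 nm Gaussian spots
#'     200 nm apart, noiseless.}
#'   \item{`dense-field`}{12 emitters scattered uniformly, noisy.}
#' }
#'
#' @param name One of the scene names above.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for noise and random placement.
#' @param config An [optical_config()].
#' @return Invisibly, a named list of the files written (`tiff`, `sidecar`,
#'   `truth`).
#' @export
generate_fixture <- function(name, dir = ".", seed = 1,
                             config = optical_config()) {
  choices <- c("single-emitter", "two-lateral", "two-axial",
               "fig1-noiseless", "dense-field")
  if (!name %in% choices) {
    stop("unknown fixture '", name, "'; choose one of: ",
         paste(choices, collapse = ", "))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ctr <- c(x = (config$frame_shape[2] - 1) / 2 * config$lateral_pixel_size,
           y = (config$frame_shape[1] - 1) / 2 * config$lateral_pixel_size,
           z = (config$n_frames - 1) / 2 * config$axial_step)

  noisy <- TRUE
  if (name == "single-emitter") {
    em <- data.frame(x0 = ctr[["x"]], y0 = ctr[["y"]], z0 = ctr[["z"]],
                     photons = 5000)
    st <- gibson_lanni_psf_stack(em, simulation_gl_params(), config)
  } else if (name == "two-lateral") {
    em <- data.frame(x0 = ctr[["x"]] + c(-275, 275), y0 = ctr[["y"]],
                     z0 = ctr[["z"]], photons = 5000)
    st <- gibson_lanni_psf_stack(em, simulation_gl_params(), config)
  } else if (name == "two-axial") {
    em <- data.frame(x0 = ctr[["x"]], y0 = ctr[["y"]],
                     z0 = ctr[["z"]] + c(-225, 225), photons = 5000)
    st <- gibson_lanni_psf_stack(em, simulation_gl_params(), config)
  } else if (name == "fig1-noiseless") {
    em <- data.frame(x0 = ctr[["x"]] + c(-100, 100), y0 = ctr[["y"]],
                     z0 = ctr[["z"]], photons = 5000)
    fr <- gaussian_psf_frame(em[c("x0", "y0")], sigma = 200,
                             frame_shape = config$frame_shape,
                             pixel_size = config$lateral_pixel_size)
    st <- image_stack(fr, config$lateral_pixel_size, config$axial_step)
    noisy <- FALSE
  } else { # dense-field
    em <- withr::with_seed(seed, data.frame(
      x0 = stats::runif(12, 0.15, 0.85) * 2 * ctr[["x"]],
      y0 = stats::runif(12, 0.15, 0.85) * 2 * ctr[["y"]],
      z0 = stats::runif(12, 0.25, 0.75) * 2 * ctr[["z"]],
      photons = 5000))
    st <- gibson_lanni_psf_stack(em, simulation_gl_params(), config)
  }
  if (noisy) st <- add_noise(st, noise_model(background_mean = 5, seed = seed))

  tiff_path <- file.path(dir, paste0(name, ".tif"))
  truth_path <- file.path(dir, paste0(name, "-truth.csv"))
  write_stack(st, tiff_path)
  utils::write.csv(em, truth_path, row.names = FALSE)
  invisible(list(tiff = tiff_path, sidecar = paste0(tiff_path, ".json"),
                 truth = truth_path))
}
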