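#' 3D image stack with physical sampling metadata
#'
#' A z-stack is stored as a nonnegative 3D array indexed `[z, y, x]` (one
#' matrix per optical section) together with the lateral pixel size and the
#' axial step, both in nm. All simulators return this container and all
#' filters and fitters consume it.
#'
#' Physical coordinates follow the voxel-center convention: the center of the
#' first voxel (index 0 in each axis) sits at the origin, so a voxel with
#' 0-based indices `(iz, iy, ix)` is centered at
#' `(ix * lateral_pixel_size, iy * lateral_pixel_size, iz * axial_step)` nm.
#'
#' @param voxels 3D numeric array `[z, y, x]`, finite and >= 0. A matrix is
#'   promoted to a single-plane stack.
#' @param lateral_pixel_size Lateral sampling, nm.
#' @param axial_step Axial sampling, nm.
#' @return An object of class `kf_image_stack`.
#' @examples
#' st <- image_stack(array(0, c(3, 8, 8)))
#' dim(st$voxels)
#' @export
image_stack <- function(voxels, lateral_pixel_size = 102, axial_step = 200) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L,
            lateral_pixel_size > 0, axial_step > 0)
  if (!all(is.finite(voxels))) stop("stack voxels must all be finite")
  if (any(voxels < 0)) stop("stack voxels must be >= 0")
  structure(
    list(voxels = voxels,
         lateral_pixel_size = lateral_pixel_size,
         axial_step = axial_step),
    class = "kf_image_stack"
  )
}

#' @export
print.kf_image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image stack> %d plane(s) of %d x %d px; %g nm lateral / %g nm axial; total %.4g photons\n",
              d[1], d[2], d[3], x$lateral_pixel_size, x$axial_step,
              sum(x$voxels)))
  invisible(x)
}

# voxel-center coordinates (nm) along each axis
stack_coords <- function(stack) {
  d <- dim(stack$voxels)
  list(z = (seq_len(d[1]) - 1) * stack$axial_step,
       y = (seq_len(d[2]) - 1) * stack$lateral_pixel_size,
       x = (seq_len(d[3]) - 1) * stack$lateral_pixel_size)
}

# physical center of the volume (nm), a convenient emitter anchor
stack_center <- function(stack) {
  d <- dim(stack$voxels)
  c(x = (d[3] - 1) / 2 * stack$lateral_pixel_size,
    y = (d[2] - 1) / 2 * stack$lateral_pixel_size,
    z = (d[1] - 1) / 2 * stack$axial_step)
}

#' Write / read a stack as a multi-page TIFF with a JSON sidecar
#'
#' One 32-bit page per z plane. Pages hold intensities normalized to the
#' stack maximum (32-bit samples quantize the unit interval at ~2e-10, far
#' below photon shot noise); the photon scale and the sampling metadata
#' travel in `<path>.json` (keys `intensity_scale_photons`,
#' `lateral_pixel_size_nm`, `axial_step_nm`). When the sidecar is missing on
#' read, 102 nm / 200 nm sampling and unit scale are assumed with a warning.
#'
#' @param stack A [image_stack()].
#' @param path TIFF file path.
#' @param sidecar Write/read the JSON sidecar (default `TRUE`).
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns a
#'   [image_stack()].
#' @examples
#' f <- tempfile(fileext = ".tif")
#' st <- image_stack(array(runif(32), c(2, 4, 4)))
#' write_stack(st, f)
#' st2 <- read_stack(f)
#' @export
write_stack <- function(stack, path, sidecar = TRUE) {
  stopifnot(inherits(stack, "kf_image_stack"))
  d <- dim(stack$voxels)
  scale <- max(stack$voxels)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(d[1]), function(i) {
    m <- stack$voxels[i, , , drop = TRUE] / scale
    matrix(as.double(m), d[2], d[3])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(lateral_pixel_size_nm = stack$lateral_pixel_size,
           axial_step_nm = stack$axial_step,
           intensity_scale_photons = scale),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, sidecar = TRUE) {
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = FALSE),
    error = function(e) stop("failed to read TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.matrix(pages)) pages <- list(pages)
  px <- 102
  dz <- 200
  scale <- 1
  side <- paste0(path, ".json")
  if (sidecar && file.exists(side)) {
    meta <- jsonlite::read_json(side)
    px <- as.numeric(meta$lateral_pixel_size_nm %||% px)
    dz <- as.numeric(meta$axial_step_nm %||% dz)
    scale <- as.numeric(meta$intensity_scale_photons %||% scale)
  } else if (sidecar) {
    warning("no sidecar '", side, "'; assuming 102 nm lateral / 200 nm axial sampling")
  }
  d2 <- dim(pages[[1]])
  vox <- array(0, c(length(pages), d2[1], d2[2]))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (!is.matrix(p) || !all(dim(p) == d2)) {
      stop("malformed TIFF '", path, "': page ", i,
           " does not match page 1 dimensions")
    }
    vox[i, , ] <- p * scale
  }
  image_stack(vox, lateral_pixel_size = px, axial_step = dz)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
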