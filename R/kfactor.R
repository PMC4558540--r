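#' Contrast-depth schedule for the K-factor decomposition
#'
#' The decomposition quantizes image contrast with one parameter per factor,
#' the contrast depth k_n in (0, 1). Values near 1 resolve fine contrast
#' steps (many factors needed); values near 0 make coarse steps. The
#' default schedule starts high and decreases, so the leading factors carry
#' the high-contrast image content and later factors sweep up progressively
#' lower contrast levels.
#'
#' @param k_values Numeric vector of contrast depths, each strictly in (0, 1).
#' @return An object of class `kf_schedule` with fields `k_values` and `M`.
#' @examples
#' kfactor_schedule(c(0.9, 0.5, 0.2))
#' default_schedule()
#' @export
kfactor_schedule <- function(k_values) {
  k_values <- as.numeric(k_values)
  if (length(k_values) < 1) stop("schedule needs at least one k value")
  if (any(!is.finite(k_values)) || any(k_values <= 0) || any(k_values >= 1)) {
    stop("every contrast depth k_n must lie strictly in (0, 1)")
  }
  structure(list(k_values = k_values, M = length(k_values)),
            class = "kf_schedule")
}

#' @export
print.kf_schedule <- function(x, ...) {
  cat("<K-factor schedule> M =", x$M, " k =",
      paste(format(x$k_values, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname kfactor_schedule
#' @details `default_schedule()` returns the nine-factor deshadowing
#'   schedule k_n = 1 - n/10 (0.9, 0.8, ..., 0.1), gradually reduced so that
#'   early factors quantize high-contrast content finely and later factors
#'   take large steps through the residual background.
#' @export
default_schedule <- function() {
  kfactor_schedule(seq(0.9, 0.1, by = -0.1))
}

# shared core: factor product of the quantizing decomposition.
# frame must already be normalized to max 1. Returns list(prod, factors,
# masks) with factors/masks optionally skipped for speed.
kf_core <- function(nf, k_values, keep = FALSE) {
  prodf <- matrix(1, nrow(nf), ncol(nf))
  resid <- nf
  factors <- if (keep) vector("list", length(k_values))
  masks <- if (keep) vector("list", length(k_values))
  for (n in seq_along(k_values)) {
    kn <- k_values[n]
    g <- (resid >= kn) * 1
    f <- g + kn * (1 - g)
    prodf <- prodf * f
    resid <- nf / prodf
    if (keep) {
      factors[[n]] <- f
      masks[[n]] <- g
    }
  }
  list(prod = prodf, factors = factors, masks = masks)
}

#' Decompose a frame into K-factor contrast factors
#'
#' Iterative nonlinear factorization of a nonnegative 2D image into a product
#' of M factors. The frame is first normalized to its maximum. At step n the
#' running residual (the normalized image divided by the factors found so
#' far) is thresholded at the contrast depth k_n, giving a binary mask g_n
#' (pixels at or above threshold map to 1: closed threshold); the factor is
#' \deqn{f_n = g_n + k_n (1 - g_n),}
#' i.e. 1 on the mask and k_n elsewhere, and the residual is divided by it
#' before the next iteration. Each pixel's factor product is therefore a
#' product of contrast depths that floor-quantizes its normalized intensity,
#' and the product of all factors reconstructs the image up to that
#' contrast-quantization error.
#'
#' @param frame Nonnegative, finite 2D matrix, not all zero.
#' @param schedule A [kfactor_schedule()]; default [default_schedule()].
#' @return An object of class `kf_decomposition`: list with `factors` (list
#'   of M matrices in (0, 1]), `masks` (list of M binary matrices),
#'   `input_frame` (the normalized frame) and `scale` (the input maximum).
#' @examples
#' fr <- gaussian_psf_frame(data.frame(x0 = 1020, y0 = 1020), sigma = 200)
#' dec <- kfactor_decompose(fr)
#' range(kfactor_reconstruct(dec) - fr)
#' @export
kfactor_decompose <- function(frame, schedule = default_schedule()) {
  check_frame(frame)
  stopifnot(inherits(schedule, "kf_schedule"))
  m <- max(frame)
  nf <- frame / m
  core <- kf_core(nf, schedule$k_values, keep = TRUE)
  structure(
    list(factors = core$factors, masks = core$masks,
         input_frame = nf, scale = m, schedule = schedule),
    class = "kf_decomposition"
  )
}

#' Reconstruct a frame from its K-factor decomposition
#'
#' The elementwise product of all factors, rescaled by the stored input
#' maximum. Reconstruction differs from the input only by the bounded
#' contrast-quantization error of the schedule.
#'
#' @param decomp A `kf_decomposition` from [kfactor_decompose()].
#' @return A numeric matrix of the input frame's shape.
#' @export
kfactor_reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "kf_decomposition"))
  if (length(decomp$factors) == 0) stop("decomposition has no factors")
  Reduce(`*`, decomp$factors) * decomp$scale
}

#' Deshadow a frame with the K-factor transform
#'
#' Multiplies the max-normalized frame elementwise by all M factors of its
#' K-factor decomposition and rescales the result back to the input maximum.
#' Because the factor product tracks the image itself, the transform squares
#' the effective contrast and floors low-contrast content, which narrows
#' bright peaks and pushes background toward zero while keeping the argmax
#' of an isolated symmetric PSF unchanged. The operation is
#' scale-covariant: deshadowing c * frame gives c * the deshadowed frame.
#'
#' @inheritParams kfactor_decompose
#' @return A numeric matrix, nonnegative, with the input's maximum.
#' @examples
#' fr <- gaussian_psf_frame(data.frame(x0 = 1020, y0 = 1020), sigma = 200)
#' ds <- deshadow_frame(fr)
#' which.max(ds) == which.max(fr)
#' @export
deshadow_frame <- function(frame, schedule = default_schedule()) {
  check_frame(frame)
  stopifnot(inherits(schedule, "kf_schedule"))
  m <- max(frame)
  nf <- frame / m
  out <- nf * kf_core(nf, schedule$k_values)$prod
  out / max(out) * m
}

#' Deshadow every plane of a z-stack
#'
#' Applies [deshadow_frame()] independently to each optical section; the
#' processed plane i derives only from input plane i, and shape and sampling
#' metadata are preserved. All-zero planes pass through unchanged (there is
#' no contrast to decompose).
#'
#' @param stack A [image_stack()].
#' @inheritParams kfactor_decompose
#' @return A deshadowed [image_stack()].
#' @export
deshadow_stack <- function(stack, schedule = default_schedule()) {
  stopifnot(inherits(stack, "kf_image_stack"))
  vox <- stack$voxels
  for (i in seq_len(dim(vox)[1])) {
    fr <- vox[i, , , drop = TRUE]
    if (max(fr) > 0) vox[i, , ] <- deshadow_frame(fr, schedule)
  }
  image_stack(vox, stack$lateral_pixel_size, stack$axial_step)
}

check_frame <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop("frame must be a numeric matrix")
  }
  if (!all(is.finite(frame))) stop("frame must be finite")
  if (any(frame < 0)) stop("frame must be nonnegative")
  if (max(frame) == 0) stop("frame is all zero: nothing to decompose")
  invisible(TRUE)
}
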