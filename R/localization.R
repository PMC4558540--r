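#' Detect candidate emitters as 3D local maxima
#'
#' Detection runs on a lightly smoothed copy of the stack (an edge-aware 2D
#' box mean of half-width `smooth` pixels within each plane, followed by a
#' light triangular 1-2-1 average along z that damps plane-to-plane noise
#' without flattening defocus structure), the standard guard against Poisson
#' spikes masquerading as spots: every voxel of the smoothed field that
#' strictly exceeds all of its (up to) 26 neighbors and the detection floor
#' becomes a candidate. The floor is `max(min_peak, rel_peak * max(smoothed
#' field))`. Candidates closer than `min_separation` (Euclidean distance in
#' voxel index units) are greedily pruned, keeping the brighter. Each
#' surviving candidate's seed plane is then refocused to the plane with the
#' highest smoothed peak inside a small lateral window (+/- 2 px) within
#' +/- 2 planes of the detection, approximating "the most focused image in
#' the set" while keeping axially separated candidates distinct.
#'
#' @param stack A [image_stack()].
#' @param min_peak Absolute detection floor (photons, on the smoothed field);
#'   local maxima at or below it are ignored.
#' @param min_separation Minimum candidate spacing, voxels.
#' @param smooth Half-width of the in-plane detection box filter in pixels;
#'   0 disables smoothing.
#' @param rel_peak Relative detection floor as a fraction of the smoothed
#'   field's maximum (0 disables).
#' @return A tibble with 0-based voxel indices `ix`, `iy`, `iz`, physical
#'   seed coordinates `x_nm`, `y_nm`, `z_nm`, and `peak` (the raw voxel
#'   value, photons), ordered by decreasing smoothed peak. Zero rows when
#'   nothing is detected.
#' @examples
#' cfg <- optical_config()
#' st <- gaussian_psf_stack(
#'   data.frame(x0 = 1020, y0 = 1020, z0 = 1600, photons = 5000), cfg)
#' find_candidates(st, min_peak = 1)
#' @export
find_candidates <- function(stack, min_peak = 0, min_separation = 2,
                            smooth = 1, rel_peak = 0) {
  stopifnot(inherits(stack, "kf_image_stack"))
  raw <- stack$voxels
  a <- if (smooth > 0) box_smooth3(raw, smooth) else raw
  d <- dim(a)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  ismax <- array(TRUE, d)
  for (oz in -1:1) for (oy in -1:1) for (ox in -1:1) {
    if (oz == 0 && oy == 0 && ox == 0) next
    nb <- pad[(2:(d[1] + 1)) + oz, (2:(d[2] + 1)) + oy,
              (2:(d[3] + 1)) + ox, drop = FALSE]
    ismax <- ismax & (a > nb)
  }
  floor_eff <- max(min_peak, rel_peak * max(a))
  idx <- which(ismax & a > floor_eff, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(ix = integer(), iy = integer(), iz = integer(),
                          x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
                          peak = numeric()))
  }
  vals <- a[idx]
  ord <- order(vals, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  vals <- vals[ord]
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      later <- (i + 1):nrow(idx)
      dist2 <- (idx[later, 1] - idx[i, 1])^2 + (idx[later, 2] - idx[i, 2])^2 +
        (idx[later, 3] - idx[i, 3])^2
      keep[later][dist2 < min_separation^2] <- FALSE
    }
  }
  idx <- idx[keep, , drop = FALSE]
  vals <- vals[keep]

  # refocus the seed plane inside a local window
  for (i in seq_len(nrow(idx))) {
    zw <- max(1, idx[i, 1] - 2):min(d[1], idx[i, 1] + 2)
    yw <- max(1, idx[i, 2] - 2):min(d[2], idx[i, 2] + 2)
    xw <- max(1, idx[i, 3] - 2):min(d[3], idx[i, 3] + 2)
    peaks <- apply(a[zw, yw, xw, drop = FALSE], 1, max)
    idx[i, 1] <- zw[which.max(peaks)]
  }

  tibble::tibble(
    ix = as.integer(unname(idx[, 3]) - 1L),
    iy = as.integer(unname(idx[, 2]) - 1L),
    iz = as.integer(unname(idx[, 1]) - 1L),
    x_nm = unname(idx[, 3] - 1) * stack$lateral_pixel_size,
    y_nm = unname(idx[, 2] - 1) * stack$lateral_pixel_size,
    z_nm = unname(idx[, 1] - 1) * stack$axial_step,
    peak = unname(raw[idx])
  )
}

# detection smoothing: edge-aware 2D box mean of half-width h within each
# plane (counts only in-frame pixels), then a triangular 1-2-1 average along
# z (edge-renormalized). The weak axial kernel damps plane-to-plane Poisson
# noise while keeping defocus structure and axial dips, so ring-dominated
# planes are never mistaken for the in-focus core.
box_smooth3 <- function(a, h) {
  d <- dim(a)
  acc <- array(0, d)
  cnt <- array(0, d)
  for (oy in -h:h) for (ox in -h:h) {
    sy <- max(1, 1 + oy):min(d[2], d[2] + oy)
    sx <- max(1, 1 + ox):min(d[3], d[3] + ox)
    ty <- max(1, 1 - oy):min(d[2], d[2] - oy)
    tx <- max(1, 1 - ox):min(d[3], d[3] - ox)
    acc[, ty, tx] <- acc[, ty, tx] + a[, sy, sx]
    cnt[, ty, tx] <- cnt[, ty, tx] + 1
  }
  sm <- acc / cnt
  if (d[1] == 1) return(sm)
  out <- sm * 2
  wt <- array(2, d)
  out[2:d[1], , ] <- out[2:d[1], , ] + sm[1:(d[1] - 1), , ]
  wt[2:d[1], , ] <- wt[2:d[1], , ] + 1
  out[1:(d[1] - 1), , ] <- out[1:(d[1] - 1), , ] + sm[2:d[1], , ]
  wt[1:(d[1] - 1), , ] <- wt[1:(d[1] - 1), , ] + 1
  out / wt
}

#' Extract the fit neighborhood around a candidate
#'
#' Cuts the 9 x 9 x 9 voxel window (2 * half_size + 1 per axis) centered on
#' the candidate seed, clipped at the stack borders.
#'
#' @param stack A [image_stack()].
#' @param candidate One row of [find_candidates()] output (or any list with
#'   `ix`, `iy`, `iz` 0-based indices).
#' @param half_size Window half width in voxels (default 4, giving 9^3).
#' @return A list of class `kf_roi`: `voxels` (3D array), `offset` (0-based
#'   indices of the ROI corner in the stack), and the stack sampling.
#' @export
extract_roi <- function(stack, candidate, half_size = 4) {
  stopifnot(inherits(stack, "kf_image_stack"))
  d <- dim(stack$voxels)
  cz <- candidate$iz + 1L
  cy <- candidate$iy + 1L
  cx <- candidate$ix + 1L
  stopifnot(cz >= 1, cz <= d[1], cy >= 1, cy <= d[2], cx >= 1, cx <= d[3])
  zr <- max(1, cz - half_size):min(d[1], cz + half_size)
  yr <- max(1, cy - half_size):min(d[2], cy + half_size)
  xr <- max(1, cx - half_size):min(d[3], cx + half_size)
  structure(
    list(voxels = stack$voxels[zr, yr, xr, drop = FALSE],
         offset = c(iz = zr[1] - 1L, iy = yr[1] - 1L, ix = xr[1] - 1L),
         lateral_pixel_size = stack$lateral_pixel_size,
         axial_step = stack$axial_step),
    class = "kf_roi"
  )
}

roi_coords <- function(roi) {
  d <- dim(roi$voxels)
  list(z = (roi$offset[["iz"]] + seq_len(d[1]) - 1) * roi$axial_step,
       y = (roi$offset[["iy"]] + seq_len(d[2]) - 1) * roi$lateral_pixel_size,
       x = (roi$offset[["ix"]] + seq_len(d[3]) - 1) * roi$lateral_pixel_size)
}

# separable 3D gaussian model over ROI coordinates; par in nm/photons
gauss3_model <- function(par, co, px2dz) {
  amp <- par[["photons"]] * px2dz /
    ((2 * pi)^1.5 * par[["sxy"]]^2 * par[["sz"]])
  gz <- exp(-(co$z - par[["z0"]])^2 / (2 * par[["sz"]]^2))
  gy <- exp(-(co$y - par[["y0"]])^2 / (2 * par[["sxy"]]^2))
  gx <- exp(-(co$x - par[["x0"]])^2 / (2 * par[["sxy"]]^2))
  amp * outer(gz, outer(gy, gx))
}

new_fit <- function(estimate, model, converged, residual_norm, init, info = NA_character_) {
  structure(
    list(estimate = estimate, model = model, converged = converged,
         residual_norm = residual_norm, init = init, info = info),
    class = "kf_fit"
  )
}

#' @export
print.kf_fit <- function(x, ...) {
  cat(sprintf("<%s fit> %s  residual %.4g\n  x=%.1f y=%.1f z=%.1f nm, N=%.0f\n",
              x$model, if (x$converged) "converged" else "NOT converged",
              x$residual_norm, x$estimate[["x0"]], x$estimate[["y0"]],
              x$estimate[["z0"]], x$estimate[["photons"]]))
  invisible(x)
}

#' Fit the six-parameter 3D Gaussian emitter model to an ROI
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) of the model
#' \deqn{I(x,y,z) = \frac{N v}{(2\pi)^{3/2}\sigma_{x,y}^2\sigma_z}
#'  \exp\!\big(-\tfrac{(x-x_0)^2+(y-y_0)^2}{2\sigma_{x,y}^2}
#'             -\tfrac{(z-z_0)^2}{2\sigma_z^2}\big)}
#' with free parameters N, x0, y0, z0, sigma_xy and sigma_z. Initialization:
#' position at the seed voxel center, photons from the background-subtracted
#' ROI sum, widths from [theoretical_sigmas()]. Positions are bounded to the
#' ROI (plus one voxel margin), widths and photons to positive values.
#'
#' Without a background term in the model, low-signal fits legitimately
#' stretch their widths to absorb the pedestal; fitted widths are therefore
#' reported as-is and any quality filtering is left to the caller.
#'
#' @param roi A `kf_roi` from [extract_roi()].
#' @param config The [optical_config()] (supplies initial widths).
#' @param init Optional named numeric overrides for the start values
#'   (`photons`, `x0`, `y0`, `z0`, `sxy`, `sz`), in nm/photons.
#' @param background Photons per voxel subtracted from the ROI sum for the
#'   photon start value; defaults to the ROI median.
#' @return A `kf_fit` object; see [tidy.kf_fit()] and [glance.kf_fit()].
#'   `converged = FALSE` fits still carry their estimates.
#' @export
fit_gaussian <- function(roi, config, init = NULL, background = NULL) {
  stopifnot(inherits(roi, "kf_roi"), inherits(config, "kf_optical_config"))
  co <- roi_coords(roi)
  v <- roi$voxels
  if (max(v) - min(v) <= 0) {
    est <- c(photons = 0, x0 = mean(co$x), y0 = mean(co$y), z0 = mean(co$z),
             sxy = NA_real_, sz = NA_real_)
    return(new_fit(est, "gaussian", FALSE, NA_real_, est, "flat ROI"))
  }
  px2dz <- roi$lateral_pixel_size^2 * roi$axial_step
  sig <- theoretical_sigmas(config)
  bg <- if (is.null(background)) stats::median(v) else background
  start <- c(
    photons = max(sum(v) - bg * length(v), max(v)),
    x0 = co$x[(length(co$x) + 1) / 2],
    y0 = co$y[(length(co$y) + 1) / 2],
    z0 = co$z[(length(co$z) + 1) / 2],
    sxy = sig[["sigma_xy"]],
    sz = sig[["sigma_z"]]
  )
  if (!is.null(init)) {
    keep <- intersect(names(init), names(start))
    start[keep] <- init[keep]
  }
  lower <- c(photons = 1e-6,
             x0 = min(co$x) - roi$lateral_pixel_size,
             y0 = min(co$y) - roi$lateral_pixel_size,
             z0 = min(co$z) - roi$axial_step,
             sxy = 1, sz = 1)
  upper <- c(photons = Inf,
             x0 = max(co$x) + roi$lateral_pixel_size,
             y0 = max(co$y) + roi$lateral_pixel_size,
             z0 = max(co$z) + roi$axial_step,
             sxy = Inf, sz = Inf)
  res_fun <- function(p) {
    p <- stats::setNames(p, names(start))
    as.vector(gauss3_model(p, co, px2dz) - v)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = res_fun,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ptol = 1e-8, ftol = 1e-10)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_fit(start, "gaussian", FALSE, NA_real_, start, "optimizer error"))
  }
  est <- stats::setNames(unlist(fit$par), names(start))
  conv <- fit$info %in% 1:4
  rn <- sqrt(mean(fit$fvec^2)) / max(v)
  new_fit(est, "gaussian", conv, rn, start, as.character(fit$info))
}

#' Fit the Gibson-Lanni emitter model to an ROI
#'
#' Levenberg-Marquardt least squares of the tabulated Gibson-Lanni PSF with
#' free position (x0, y0, z0) and photon count; the PSF shape parameters come
#' from `gl` and are not fitted. The axial landscape is locally multimodal
#' (the aberration-free pattern is mirror symmetric about focus and has
#' axial sidelobes that alias under noise), so the fit refines the seed
#' inside a trust region: z0 is bounded to the seed plane +/- two axial
#' steps, and three starts (seed plane and one step either side) are tried,
#' keeping the solution with the smallest residual.
#'
#' @inheritParams fit_gaussian
#' @param gl A [gibson_lanni_params()] describing the model to fit.
#' @return A `kf_fit` object (model `"gibson-lanni"`).
#' @export
fit_gibson_lanni <- function(roi, config, gl, init = NULL, background = NULL) {
  stopifnot(inherits(roi, "kf_roi"), inherits(config, "kf_optical_config"),
            inherits(gl, "kf_gibson_lanni_params"))
  co <- roi_coords(roi)
  v <- roi$voxels
  if (max(v) - min(v) <= 0) {
    est <- c(photons = 0, x0 = mean(co$x), y0 = mean(co$y), z0 = mean(co$z))
    return(new_fit(est, "gibson-lanni", FALSE, NA_real_, est, "flat ROI"))
  }
  zspan <- (config$n_frames + 4) * config$axial_step
  rmax <- sqrt(2) * (max(config$frame_shape) + 2) * config$lateral_pixel_size
  tab <- gl_table(config, gl, z_max = zspan, r_max = rmax)
  sref <- gl_reference_sum(tab, config)
  bg <- if (is.null(background)) stats::median(v) else background
  start0 <- c(
    photons = max(sum(v) - bg * length(v), max(v)),
    x0 = co$x[(length(co$x) + 1) / 2],
    y0 = co$y[(length(co$y) + 1) / 2],
    z0 = co$z[(length(co$z) + 1) / 2]
  )
  if (!is.null(init)) {
    keep <- intersect(names(init), names(start0))
    start0[keep] <- init[keep]
  }
  lower <- c(photons = 1e-6,
             x0 = min(co$x) - roi$lateral_pixel_size,
             y0 = min(co$y) - roi$lateral_pixel_size,
             z0 = start0[["z0"]] - 2 * roi$axial_step)
  upper <- c(photons = Inf,
             x0 = max(co$x) + roi$lateral_pixel_size,
             y0 = max(co$y) + roi$lateral_pixel_size,
             z0 = start0[["z0"]] + 2 * roi$axial_step)
  model <- function(p) {
    rmat <- sqrt(outer((co$y - p[["y0"]])^2, (co$x - p[["x0"]])^2, `+`))
    out <- array(0, dim(v))
    for (iz in seq_along(co$z)) {
      out[iz, , ] <- gl_lookup(tab, rmat, co$z[iz] - p[["z0"]])
    }
    out * (p[["photons"]] / sref)
  }
  res_fun <- function(p) {
    p <- stats::setNames(p, names(start0))
    as.vector(model(p) - v)
  }
  best <- NULL
  for (dz0 in c(0, -1, 1) * config$axial_step) {
    start <- start0
    start[["z0"]] <- min(max(start0[["z0"]] + dz0, lower[["z0"]]), upper[["z0"]])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = res_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ptol = 1e-8, ftol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(new_fit(start0, "gibson-lanni", FALSE, NA_real_, start0,
                   "optimizer error"))
  }
  est <- stats::setNames(unlist(best$par), names(start0))
  new_fit(est, "gibson-lanni", best$info %in% 1:4,
          sqrt(mean(best$fvec^2)) / max(v), start0, as.character(best$info))
}

#' Localize all emitters in a stack
#'
#' Runs the full single-emitter pipeline: candidate detection, 9 x 9 x 9 ROI
#' extraction, and per-candidate least-squares fitting with the requested PSF
#' model. Per-candidate failures never abort the batch.
#'
#' @param stack A [image_stack()].
#' @param config An [optical_config()].
#' @param model `"gaussian"` or `"gibson-lanni"`.
#' @param gl [gibson_lanni_params()], required for the Gibson-Lanni model.
#' @param min_peak,min_separation,smooth,rel_peak Passed to
#'   [find_candidates()].
#' @param half_size ROI half width, voxels.
#' @return A tibble, one row per candidate in detection order: `x_nm`,
#'   `y_nm`, `z_nm`, `photons`, `model`, `converged`, `residual`, plus the
#'   seed indices.
#' @examples
#' cfg <- optical_config()
#' st <- gaussian_psf_stack(
#'   data.frame(x0 = 1000, y0 = 1050, z0 = 1580, photons = 5000), cfg)
#' localize_stack(st, cfg, min_peak = 1)
#' @export
localize_stack <- function(stack, config, model = c("gaussian", "gibson-lanni"),
                           gl = NULL, min_peak = 0, min_separation = 2,
                           half_size = 4, smooth = 1, rel_peak = 0) {
  model <- match.arg(model)
  if (model == "gibson-lanni" && is.null(gl)) {
    stop("the Gibson-Lanni model needs gibson_lanni_params()")
  }
  cands <- find_candidates(stack, min_peak = min_peak,
                           min_separation = min_separation,
                           smooth = smooth, rel_peak = rel_peak)
  rows <- purrr::map(seq_len(nrow(cands)), function(i) {
    cand <- cands[i, ]
    roi <- extract_roi(stack, cand, half_size = half_size)
    init <- c(x0 = cand$x_nm, y0 = cand$y_nm, z0 = cand$z_nm)
    fit <- tryCatch(
      if (model == "gaussian") fit_gaussian(roi, config, init = init)
      else fit_gibson_lanni(roi, config, gl, init = init),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    tibble::tibble(
      x_nm = fit$estimate[["x0"]], y_nm = fit$estimate[["y0"]],
      z_nm = fit$estimate[["z0"]], photons = fit$estimate[["photons"]],
      model = fit$model, converged = fit$converged,
      residual = fit$residual_norm,
      seed_ix = cand$ix, seed_iy = cand$iy, seed_iz = cand$iz,
      seed_peak = cand$peak
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
      photons = numeric(), model = character(), converged = logical(),
      residual = numeric(), seed_ix = integer(), seed_iy = integer(),
      seed_iz = integer(), seed_peak = numeric())
  }
  out
}
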