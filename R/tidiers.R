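#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a single-emitter fit
#'
#' One row per fitted parameter, broom style.
#'
#' @param x A `kf_fit` from [fit_gaussian()] or [fit_gibson_lanni()].
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.kf_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate))
}

#' @rdname tidy.kf_fit
#' @return `glance()`: a one-row tibble with `model`, `converged` and
#'   `residual_norm`.
#' @export
glance.kf_fit <- function(x, ...) {
  tibble::tibble(model = x$model, converged = x$converged,
                 residual_norm = x$residual_norm)
}

#' Tidy Monte Carlo precision results
#'
#' @param x A `kf_mc_result` from [mc_localization_experiment()].
#' @param ... Unused.
#' @return `tidy()`: long tibble with `photons`, `method`, `axis`
#'   (lateral/axial) and `rms_nm`. `glance()`: one row with the experiment
#'   settings.
#' @export
tidy.kf_mc_result <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("photons", "method", "rms_lateral", "rms_axial") |>
    tidyr::pivot_longer(c("rms_lateral", "rms_axial"),
                        names_to = "axis", values_to = "rms_nm",
                        names_prefix = "rms_")
}

#' @rdname tidy.kf_mc_result
#' @export
glance.kf_mc_result <- function(x, ...) {
  tibble::tibble(
    L = attr(x, "L"), seed = attr(x, "seed"), nb = attr(x, "nb"),
    psf_model = attr(x, "psf_model"),
    n_levels = length(unique(x$photons)),
    n_methods = length(unique(x$method)))
}

#' Tidy a resolvability scan
#'
#' @param x A `kf_resolvability` from [min_resolvable_distance()].
#' @param ... Unused.
#' @return `tidy()`: the per-distance scan tibble with `axis` and `method`
#'   attached. `glance()`: one row with the minimal resolvable distance.
#' @export
tidy.kf_resolvability <- function(x, ...) {
  dplyr::mutate(x$scan, axis = x$axis, method = x$method)
}

#' @rdname tidy.kf_resolvability
#' @export
glance.kf_resolvability <- function(x, ...) {
  tibble::tibble(axis = x$axis, method = x$method,
                 min_distance_nm = x$min_distance,
                 n_photons = x$n_photons, nb = x$nb, trials = x$trials,
                 rate_threshold = x$rate_threshold, seed = x$seed)
}

#' Plot RMS localization error against photon count
#'
#' One line per localization method, faceted by axis, on log-log axes -- the
#' standard precision-versus-photons diagnostic.
#'
#' @param object A `kf_mc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kf_mc_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$photons, y = .data$rms_nm,
                                 colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$axis), scales = "free_y") +
    ggplot2::labs(x = "detected photons N", y = "RMS localization error (nm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a resolvability scan
#'
#' Resolved rate against emitter separation, with the decision threshold and
#' the reported minimal distance marked.
#'
#' @param object A `kf_resolvability`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kf_resolvability <- function(object, ...) {
  p <- ggplot2::ggplot(object$scan,
                       ggplot2::aes(x = .data$distance, y = .data$resolved_rate)) +
    ggplot2::geom_hline(yintercept = object$rate_threshold, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("%s separation (nm)", object$axis),
      y = "resolved fraction",
      title = sprintf("%s method: minimal resolvable distance %s nm",
                      object$method,
                      if (is.finite(object$min_distance))
                        format(object$min_distance) else "not reached")) +
    ggplot2::theme_minimal()
  if (is.finite(object$min_distance)) {
    p <- p + ggplot2::geom_vline(xintercept = object$min_distance,
                                 linetype = 3, colour = "grey40")
  }
  p
}
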