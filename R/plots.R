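#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_raster
#'   geom_line geom_ribbon geom_abline scale_fill_identity coord_equal
#'   coord_fixed labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

# gamma-encoded hex colors of a linear RGB matrix (n x 3)
encode_hex <- function(rgb, gamma = 2.2) {
  v <- pmin(pmax(rgb, 0), 1)^(1 / gamma)
  grDevices::rgb(v[, 1], v[, 2], v[, 3])
}

#' Plot an environment map as a gamma-encoded preview
#'
#' @param object An `env_map`.
#' @param scale Radiance scale before encoding (default: 99th percentile
#'   to 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot env_map
#' @export
autoplot.env_map <- function(object, scale = NULL, ...) {
  p <- object$pixels
  if (is.null(scale)) {
    q <- quantile(p, 0.99)
    scale <- if (q > 0) 1 / q else 1
  }
  H <- object$height; W <- object$width
  df <- tibble::tibble(
    col = rep(seq_len(W), each = H), row = rep(seq_len(H), W),
    fill = encode_hex(cbind(as.numeric(p[, , 1]), as.numeric(p[, , 2]),
                            as.numeric(p[, , 3])) * scale))
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$fill)) +
    geom_raster() + scale_fill_identity() + coord_equal() +
    labs(x = "azimuth (px)", y = "zenith angle (px)") + theme_minimal()
}

#' Plot per-observer truth correlations
#'
#' Bar of the mean correlation with per-observer points, the standard
#' visualization for constancy accuracy.
#'
#' @param object A `correlation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correlation_report
#' @export
autoplot.correlation_report <- function(object, ...) {
  per <- object$per_observer
  ggplot(per, aes(x = "observers", y = .data$r)) +
    geom_col(data = tibble::tibble(r = object$mean_r),
             aes(y = .data$r), fill = "grey70", width = 0.6) +
    geom_point(position = ggplot2::position_jitter(width = 0.08, seed = 1)) +
    labs(y = sprintf("correlation with ground truth (%s)", object$parameter),
         x = NULL) +
    ggplot2::ylim(min(0, min(per$r, na.rm = TRUE)), 1) + theme_minimal()
}

#' Plot standardized regression weights
#'
#' @param object A `loo_regression`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot loo_regression
#' @export
autoplot.loo_regression <- function(object, ...) {
  co <- object$coefficients
  co$predictor <- factor(co$predictor, levels = co$predictor)
  ggplot(co, aes(x = .data$predictor, y = .data$weight)) +
    geom_col(fill = "seagreen") +
    labs(x = NULL, y = "standardized weight (mean over folds)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot mean settings against ground truth per environment group
#'
#' Scatter of observer-mean settings vs ground truth, one panel per
#' lighting environment, with the identity line — the standard view of
#' constancy failures across environments.
#'
#' @param settings A `settings_table` with one parameter.
#' @param env_of Tibble `image_id, environment`.
#' @return A ggplot object.
#' @export
plot_settings_vs_truth <- function(settings, env_of = NULL) {
  s <- settings
  if (!is.null(env_of)) s <- dplyr::inner_join(s, env_of, by = "image_id")
  s <- dplyr::summarise(
    dplyr::group_by(s, .data$image_id,
                    environment = if ("environment" %in% names(s))
                      .data$environment else 1),
    setting = mean(.data$setting), truth = .data$truth[1], .groups = "drop")
  ggplot(s, aes(x = .data$truth, y = .data$setting)) +
    geom_abline(linetype = "dashed", colour = "grey50") +
    geom_point() + facet_wrap(~environment) + coord_fixed() +
    labs(x = "ground truth", y = "mean observer setting") + theme_minimal()
}

#' Plot the SH power spectrum of an environment map
#'
#' Log-log per-degree power with the fitted regression line whose slope
#' characterizes the environment (about -2 for natural outdoor light).
#'
#' @param env An `env_map`.
#' @param lmax Band limit.
#' @return A ggplot object.
#' @export
plot_sh_spectrum <- function(env, lmax = min(16L, env$height - 1L)) {
  ps <- sh_power_slope(sh_project(env_luminance(env), lmax))
  df <- dplyr::filter(ps$power, .data$l >= 1, .data$power > 0)
  ggplot(df, aes(x = log10(.data$l), y = log10(.data$power))) +
    geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    labs(x = "log10 degree", y = "log10 power",
         subtitle = sprintf("slope = %.2f", ps$slope)) +
    theme_minimal()
}
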