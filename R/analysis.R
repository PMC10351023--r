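# Average sessions within observer x image x parameter (hue circularly).
average_sessions <- function(settings) {
  dplyr::summarise(
    dplyr::group_by(settings, .data$observer, .data$image_id, .data$parameter),
    setting = if (.data$parameter[1] == "hue") circular_mean(.data$setting)
      else mean(.data$setting),
    truth = .data$truth[1], .groups = "drop")
}

#' Per-observer correlation with ground truth
#'
#' Pearson correlation between each observer's settings (sessions averaged
#' first) and the ground-truth values of one adjusted parameter, plus the
#' mean and standard error across observers. For hue the circular
#' correlation ([circular_corr()]) is used. Observers with constant
#' settings have undefined correlation; they are excluded with a warning.
#'
#' @param settings A `settings_table`.
#' @param parameter Which parameter to analyze.
#' @param method `"pearson"` or `"circular"`; default picks circular for
#'   hue, Pearson otherwise.
#' @return A list of class `correlation_report`: `per_observer` tibble
#'   (`observer, r`), `mean_r`, `se_r`, `parameter`, `n_images`.
#' @export
observer_truth_corr <- function(settings, parameter,
                                method = NULL) {
  s <- dplyr::filter(settings, .data$parameter == !!parameter)
  if (!nrow(s)) stop(sprintf("no rows for parameter `%s`", parameter), call. = FALSE)
  if (is.null(method)) method <- if (parameter == "hue") "circular" else "pearson"
  s <- average_sessions(s)
  n_img <- length(unique(s$image_id))
  if (n_img < 3) stop("need at least 3 images per observer", call. = FALSE)
  per <- dplyr::summarise(
    dplyr::group_by(s, .data$observer),
    r = if (method == "circular") circular_corr(.data$setting, .data$truth)
      else if (sd(.data$setting) == 0 || sd(.data$truth) == 0) NA_real_
      else cor(.data$setting, .data$truth),
    .groups = "drop")
  if (any(is.na(per$r))) {
    warning(sprintf("%d observer(s) with undefined correlation excluded",
                    sum(is.na(per$r))))
  }
  ok <- per$r[!is.na(per$r)]
  structure(list(per_observer = per, mean_r = mean(ok),
                 se_r = if (length(ok) > 1) sd(ok) / sqrt(length(ok)) else 0,
                 parameter = parameter, n_images = n_img,
                 method = method),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %s: mean r = %.3f (SE %.3f, %d observers, %d images)\n",
              x$parameter, x$mean_r, x$se_r, nrow(x$per_observer), x$n_images))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy correlation_report
#' @export
tidy.correlation_report <- function(x, ...) x$per_observer

#' @method glance correlation_report
#' @export
glance.correlation_report <- function(x, ...) {
  tibble::tibble(parameter = x$parameter, mean_r = x$mean_r, se_r = x$se_r,
                 n_observers = nrow(x$per_observer), n_images = x$n_images)
}

#' Circular correlation between two angle sets
#'
#' Jammalamadaka-SenGupta circular correlation: the correlation of the
#' sines of deviations from the respective circular means. Invariant to an
#' arbitrary constant rotation of either variable.
#'
#' @param angles1,angles2 Angles in degrees, equal length.
#' @return Correlation in `[-1, 1]`, or `NA` if either variable has zero
#'   circular variance.
#' @export
circular_corr <- function(angles1, angles2) {
  stopifnot(length(angles1) == length(angles2))
  m1 <- circular_mean(angles1); m2 <- circular_mean(angles2)
  if (is.na(m1) || is.na(m2)) return(NA_real_)
  s1 <- sin((angles1 - m1) * pi / 180)
  s2 <- sin((angles2 - m2) * pi / 180)
  den <- sqrt(sum(s1^2) * sum(s2^2))
  if (den < 1e-12) return(NA_real_)
  sum(s1 * s2) / den
}

#' Interobserver noise ceilings
#'
#' For each observer: the upper ceiling is the correlation between that
#' observer's settings and the settings averaged across *all* observers
#' (including them); the lower ceiling correlates against the average of
#' the *other* observers only. The band between the mean bounds limits how
#' well any image-computable model can correlate with mean behavior.
#'
#' @param settings A `settings_table` (single parameter, or supply
#'   `parameter`).
#' @param parameter Optional parameter filter.
#' @return Tibble: `observer, upper, lower`.
#' @export
noise_ceiling <- function(settings, parameter = NULL) {
  s <- if (!is.null(parameter)) {
    dplyr::filter(settings, .data$parameter == !!parameter)
  } else settings
  if (length(unique(s$parameter)) > 1) {
    stop("settings contain several parameters; supply `parameter`", call. = FALSE)
  }
  is_hue <- s$parameter[1] == "hue"
  s <- average_sessions(s)
  obs <- sort(unique(s$observer))
  if (length(obs) < 3) stop("need at least 3 observers", call. = FALSE)
  wide <- tidyr::pivot_wider(s[, c("observer", "image_id", "setting")],
                             names_from = "observer", values_from = "setting")
  wide <- dplyr::arrange(wide, .data$image_id)
  M <- as.matrix(wide[, -1])
  ccor <- function(a, b) if (is_hue) circular_corr(a, b) else cor(a, b)
  avg <- function(m) if (is_hue) apply(m, 1, circular_mean) else rowMeans(m)
  upper <- vapply(seq_along(obs), function(i) ccor(M[, i], avg(M)), numeric(1))
  lower <- vapply(seq_along(obs), function(i) {
    ccor(M[, i], avg(M[, -i, drop = FALSE]))
  }, numeric(1))
  tibble::tibble(observer = obs, upper = upper, lower = lower)
}

#' Saturation consistency of chroma/lightness settings
#'
#' Correlates ground-truth saturation `C*ab / L*` with the saturation
#' computed from each observer's chroma and lightness settings (sessions
#' averaged), then averages across observers — the check for whether
#' observers matched perceived saturation rather than chroma and lightness
#' independently.
#'
#' @param settings A `settings_table` containing `lightness` and `chroma`
#'   parameters.
#' @return A `correlation_report` for the saturation variable.
#' @export
saturation_consistency <- function(settings) {
  s <- dplyr::filter(settings, .data$parameter %in% c("lightness", "chroma"))
  s <- average_sessions(s)
  wide <- tidyr::pivot_wider(s, names_from = "parameter",
                             values_from = c("setting", "truth"))
  if (any(wide$setting_lightness <= 0) || any(wide$truth_lightness <= 0)) {
    stop("saturation undefined at zero lightness", call. = FALSE)
  }
  wide$sat_setting <- wide$setting_chroma / wide$setting_lightness
  wide$sat_truth <- wide$truth_chroma / wide$truth_lightness
  per <- dplyr::summarise(
    dplyr::group_by(wide, .data$observer),
    r = if (sd(.data$sat_setting) == 0) NA_real_
      else cor(.data$sat_setting, .data$sat_truth),
    .groups = "drop")
  ok <- per$r[!is.na(per$r)]
  structure(list(per_observer = per, mean_r = mean(ok),
                 se_r = if (length(ok) > 1) sd(ok) / sqrt(length(ok)) else 0,
                 parameter = "saturation", method = "pearson",
                 n_images = length(unique(wide$image_id))),
            class = "correlation_report")
}

# t-approximation p-value for a Pearson correlation
pearson_p <- function(r, n) {
  if (is.na(r) || n < 3 || abs(r) >= 1) return(NA_real_)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

# circular-linear correlation (Mardia): sqrt of R^2 of x on (cos a, sin a)
circ_linear_corr <- function(angles, x) {
  ca <- cos(angles * pi / 180); sa <- sin(angles * pi / 180)
  rxc <- suppressWarnings(cor(x, ca)); rxs <- suppressWarnings(cor(x, sa))
  rcs <- suppressWarnings(cor(ca, sa))
  if (any(is.na(c(rxc, rxs, rcs)))) return(NA_real_)
  sqrt(max(0, (rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2)))
}

#' Gloss-setting errors against body color
#'
#' Correlates each observer-mean gloss error (setting minus truth) with the
#' ground-truth body-color parameters (hue via circular-linear correlation,
#' chroma and lightness via Pearson), reporting Bonferroni-adjusted
#' significance over the family of color parameters tested.
#'
#' @param settings A `settings_table` with a `pellacini_c` parameter and
#'   the color parameters present as truth (via `color_truth`).
#' @param color_truth Tibble `image_id, hue, lightness, chroma` of the
#'   ground-truth body colors.
#' @param alpha Family-wise significance level before correction.
#' @return Tibble: `color_parameter, r, p, p_bonferroni, significant`.
#' @export
gloss_error_vs_color <- function(settings, color_truth, alpha = 0.05) {
  s <- dplyr::filter(settings, .data$parameter == "pellacini_c")
  if (!nrow(s)) stop("no gloss settings present", call. = FALSE)
  s <- average_sessions(s)
  err <- dplyr::summarise(dplyr::group_by(s, .data$image_id),
                          error = mean(.data$setting - .data$truth),
                          .groups = "drop")
  m <- dplyr::inner_join(err, color_truth, by = "image_id")
  n <- nrow(m)
  fam <- c("hue", "lightness", "chroma")
  rows <- lapply(fam, function(p) {
    if (sd(m$error) == 0) {
      return(tibble::tibble(color_parameter = p, r = NA_real_, p = NA_real_))
    }
    if (p == "hue") {
      r <- circ_linear_corr(m$hue, m$error)
      # R^2 of error on (cos h, sin h): F test with 2 numerator df
      pv <- if (is.na(r) || n < 4) NA_real_ else {
        r2 <- r^2
        f <- (r2 / 2) / ((1 - r2) / (n - 3))
        stats::pf(f, 2, n - 3, lower.tail = FALSE)
      }
      tibble::tibble(color_parameter = p, r = r, p = pv)
    } else {
      r <- cor(m$error, m[[p]])
      tibble::tibble(color_parameter = p, r = r, p = pearson_p(r, n))
    }
  })
  out <- dplyr::bind_rows(rows)
  out$p_bonferroni <- pmin(out$p * length(fam), 1)
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni < alpha
  out
}

#' Partial correlation
#'
#' First-order partial correlation of `x` and `y` controlling for `z`:
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{zy}) /
#'   \sqrt{(1 - r_{xz}^2)(1 - r_{zy}^2)}.}
#' Equals the correlation of the residuals of `x` and `y` after regressing
#' each on `z`. Undefined (NA) when `x` or `y` is collinear with `z`.
#'
#' @param x,y,z Numeric vectors of equal length (n >= 4).
#' @return Partial correlation coefficient.
#' @export
partial_corr <- function(x, y, z) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  rxy <- cor(x, y); rxz <- cor(x, z); rzy <- cor(z, y)
  if (abs(rxz) >= 1 - 1e-12 || abs(rzy) >= 1 - 1e-12) return(NA_real_)
  (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2))
}

#' Leave-one-observer-out multiple regression
#'
#' For each fold, regresses the mean settings of all *other* observers on
#' the z-scored image metrics (response z-scored too, so coefficients are
#' standardized), then correlates the fitted model's predictions with the
#' held-out observer's settings. Reports the per-fold held-out
#' correlations and the standardized coefficients averaged over folds.
#' A rank-deficient predictor matrix falls back to the minimum-norm
#' least-squares solution with a warning.
#'
#' @param metrics Tibble: `image_id` plus one column per predictor.
#' @param settings A `settings_table` (one parameter).
#' @return A list of class `loo_regression`: `coefficients` tibble
#'   (`predictor, weight`), `folds` tibble (`observer, r_holdout`),
#'   `mean_r_holdout`.
#' @export
loo_regression <- function(metrics, settings) {
  if (length(unique(settings$parameter)) > 1) {
    stop("settings contain several parameters; filter first", call. = FALSE)
  }
  s <- average_sessions(settings)
  obs <- sort(unique(s$observer))
  if (length(obs) < 3) stop("need at least 3 observers", call. = FALSE)
  wide <- tidyr::pivot_wider(s[, c("observer", "image_id", "setting")],
                             names_from = "observer", values_from = "setting")
  wide <- dplyr::arrange(wide, .data$image_id)
  mtab <- dplyr::arrange(metrics, .data$image_id)
  if (!identical(sort(unique(mtab$image_id)), sort(wide$image_id))) {
    stop("metrics and settings must cover the same images", call. = FALSE)
  }
  X <- as.matrix(mtab[, setdiff(names(mtab), "image_id")])
  if (nrow(X) <= ncol(X)) {
    warning("fewer images than predictors + 1; coefficients are not unique")
  }
  zX <- scale(X)
  zX[, attr(zX, "scaled:scale") == 0] <- 0
  M <- as.matrix(wide[, -1])
  fit_fold <- function(y) {
    zy <- if (sd(y) > 0) (y - mean(y)) / sd(y) else y * 0
    qr_x <- qr(zX)
    if (qr_x$rank < ncol(zX)) {
      warning("rank-deficient predictor matrix; using minimum-norm solution")
      b <- pinv(zX) %*% zy
    } else {
      b <- qr.coef(qr_x, zy)
    }
    as.numeric(b)
  }
  coefs <- matrix(0, ncol(X), length(obs))
  r_hold <- numeric(length(obs))
  for (i in seq_along(obs)) {
    y_train <- rowMeans(M[, -i, drop = FALSE])
    b <- fit_fold(y_train)
    coefs[, i] <- b
    pred <- as.numeric(zX %*% b)
    r_hold[i] <- if (sd(pred) == 0 || sd(M[, i]) == 0) NA_real_
      else cor(pred, M[, i])
  }
  structure(list(
    coefficients = tibble::tibble(predictor = colnames(X),
                                  weight = rowMeans(coefs)),
    folds = tibble::tibble(observer = obs, r_holdout = r_hold),
    mean_r_holdout = mean(r_hold, na.rm = TRUE)),
    class = "loo_regression")
}

#' @export
print.loo_regression <- function(x, ...) {
  cat(sprintf("<loo_regression> %d predictors, %d folds, mean held-out r = %.3f\n",
              nrow(x$coefficients), nrow(x$folds), x$mean_r_holdout))
  invisible(x)
}

#' @method tidy loo_regression
#' @export
tidy.loo_regression <- function(x, ...) x$coefficients

#' @method glance loo_regression
#' @export
glance.loo_regression <- function(x, ...) {
  tibble::tibble(n_predictors = nrow(x$coefficients),
                 n_folds = nrow(x$folds),
                 mean_r_holdout = x$mean_r_holdout)
}

#' Per-environment regression of settings on ground truth
#'
#' Within each lighting environment, fits mean observer settings against
#' ground truth by least squares and reports the slope and Pearson
#' correlation — a higher slope means objects under that environment were
#' perceived as glossier on average.
#'
#' @param settings A `settings_table` (one parameter) whose rows carry an
#'   `environment` column (or supply `env_of`, a tibble
#'   `image_id, environment`).
#' @param env_of Optional mapping tibble.
#' @return Tibble: `environment, slope, r, n_images`; `NA` with constant
#'   truth in a group.
#' @export
per_env_slope <- function(settings, env_of = NULL) {
  s <- settings
  if (!is.null(env_of)) s <- dplyr::inner_join(s, env_of, by = "image_id")
  if (!"environment" %in% names(s)) {
    stop("settings need an `environment` column (or pass `env_of`)", call. = FALSE)
  }
  envc <- dplyr::distinct(s, .data$image_id, .data$environment)
  s <- average_sessions(s)
  s <- dplyr::inner_join(s, envc, by = "image_id")
  m <- dplyr::summarise(dplyr::group_by(s, .data$environment, .data$image_id),
                        setting = mean(.data$setting), truth = .data$truth[1],
                        .groups = "drop")
  dplyr::summarise(
    dplyr::group_by(m, .data$environment),
    slope = if (dplyr::n() < 3 || sd(.data$truth) == 0) NA_real_
      else unname(coef(lm(setting ~ truth,
                          data = data.frame(setting = .data$setting,
                                            truth = .data$truth)))[2]),
    r = if (dplyr::n() < 3 || sd(.data$truth) == 0 || sd(.data$setting) == 0)
      NA_real_ else cor(.data$setting, .data$truth),
    n_images = dplyr::n(), .groups = "drop")
}
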