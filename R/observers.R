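#' Simulated-observer model
#'
#' Describes how synthetic observers generate settings: for each adjusted
#' parameter, the setting is a clamped sum of a *shared* systematic
#' component — a weighted mix of the ground truth and image statistics,
#' identical for every observer, which is what produces high interobserver
#' agreement alongside lighting-dependent bias — plus independent
#' per-observer setting noise.
#'
#' Bias weights are named vectors per parameter; the name `"truth"` refers
#' to the ground-truth value of that parameter, any other name must be a
#' column of the image-statistics table passed to [simulate_observers()].
#' Statistic components are standardized over images and mapped onto the
#' truth scale (matching mean and spread) before mixing, so weights are
#' comparable. Hue is treated circularly (mixed on the unit circle, no
#' clamp).
#'
#' @param n_observers Number of observers.
#' @param bias Named list of named weight vectors, one per parameter.
#' @param noise_sd Named numeric vector of setting-noise SDs (parameter
#'   units).
#' @param clamp Named list of `c(lo, hi)` ranges applied after noise
#'   (adjustment-range limits; hue has none).
#' @param seed Integer seed.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(n_observers = 10,
                           bias = list(
                             hue = c(truth = 0.9, hue_circ_mean = 0.1),
                             lightness = c(truth = 0.25, L_mean = 0.75),
                             chroma = c(truth = 0.3, C_mean = 0.7),
                             pellacini_c = c(truth = 0.45, contrast_aggregate = 0.55)),
                           noise_sd = c(hue = 8, lightness = 2.5, chroma = 2.5,
                                        pellacini_c = 0.012),
                           clamp = list(lightness = c(28, 74),
                                        chroma = c(8, 26),
                                        pellacini_c = c(0, 0.149)),
                           seed = 1) {
  stopifnot(n_observers >= 1, all(noise_sd >= 0))
  structure(list(n_observers = n_observers, bias = bias,
                 noise_sd = noise_sd, clamp = clamp, seed = seed),
            class = "observer_model")
}

# circular weighted mean of angle columns (degrees), weights >= 0
circ_mix <- function(angles_mat, w) {
  rad <- angles_mat * pi / 180
  s <- as.numeric(sin(rad) %*% w)
  c_ <- as.numeric(cos(rad) %*% w)
  (atan2(s, c_) * 180 / pi) %% 360
}

#' Simulate observer settings for a stimulus set
#'
#' Generates a long-format settings table emulating asymmetric-matching
#' data: every observer's setting for a given image shares the same
#' systematic component (so observers agree with each other even where they
#' deviate from ground truth), plus independent Gaussian setting noise,
#' clamped to the adjustment ranges. Deterministic given the model seed.
#'
#' @param truth Tibble with `image_id` and one column per adjusted
#'   parameter (`hue`, `lightness`, `chroma`, `pellacini_c` — any subset).
#' @param stats Tibble with `image_id` and image-statistic columns referred
#'   to by the model's bias weights. May be `NULL` if all biases are pure
#'   truth.
#' @param model An [observer_model()].
#' @param sessions Number of sessions (settings repeated with fresh noise).
#' @return A tibble of class `settings_table`: columns
#'   `observer, image_id, session, parameter, setting, truth`.
#' @export
simulate_observers <- function(truth, stats = NULL, model = observer_model(),
                               sessions = 1) {
  stopifnot(inherits(model, "observer_model"), "image_id" %in% names(truth))
  params <- intersect(names(model$bias), names(truth))
  if (!length(params)) stop("no adjusted parameter columns found in `truth`", call. = FALSE)
  if (!is.null(stats)) {
    stopifnot("image_id" %in% names(stats))
    truth_all <- dplyr::left_join(truth, stats, by = "image_id",
                                  suffix = c("", ".stat"))
  } else truth_all <- truth
  n_img <- nrow(truth)
  set.seed(model$seed)
  out <- list()
  for (p in params) {
    w <- model$bias[[p]]
    comp <- matrix(0, n_img, length(w))
    tvals <- truth_all[[p]]
    for (k in seq_along(w)) {
      nm <- names(w)[k]
      if (nm == "truth") {
        comp[, k] <- tvals
      } else {
        if (!nm %in% names(truth_all)) {
          stop(sprintf("bias component `%s` for parameter `%s` not found in the statistics table", nm, p),
               call. = FALSE)
        }
        sv <- truth_all[[nm]]
        if (p == "hue") {
          comp[, k] <- sv %% 360       # already an angle in degrees
        } else {
          z <- if (sd(sv) > 0) (sv - mean(sv)) / sd(sv) else sv * 0
          comp[, k] <- z * sd(tvals) + mean(tvals)
        }
      }
    }
    shared <- if (p == "hue") circ_mix(comp, w / sum(w)) else
      as.numeric(comp %*% (w / sum(w)))
    for (o in seq_len(model$n_observers)) {
      for (s in seq_len(sessions)) {
        noise <- rnorm(n_img, 0, model$noise_sd[[p]])
        setting <- shared + noise
        if (p == "hue") {
          setting <- setting %% 360
        } else if (!is.null(model$clamp[[p]])) {
          cl <- model$clamp[[p]]
          setting <- pmin(pmax(setting, cl[1]), cl[2])
        }
        out[[length(out) + 1]] <- tibble::tibble(
          observer = o, image_id = truth$image_id, session = s,
          parameter = p, setting = setting, truth = tvals)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("settings_table", class(res))
  res
}

#' Read / write a settings table as CSV
#'
#' @param settings A `settings_table` tibble.
#' @param path CSV path.
#' @export
write_settings <- function(settings, path) {
  write.csv(as.data.frame(settings), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_settings
#' @export
read_settings <- function(path) {
  res <- tibble::as_tibble(read.csv(path))
  need <- c("observer", "image_id", "session", "parameter", "setting", "truth")
  if (!all(need %in% names(res))) {
    stop("settings CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  class(res) <- c("settings_table", class(res))
  res
}
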