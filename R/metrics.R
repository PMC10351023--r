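HIGHLIGHT_K_SET <- c(0, 1, 3, 5, 10, 20, 40)

#' Sub-band filter cutoffs
#'
#' The eight Gaussian band-pass cutoff pairs, in cycles/image:
#' 1.5-3, 3-6, 6-12, 12-24, 24-48, 48-96, 96-192, 192-384.
#'
#' @return An 8 x 2 matrix with columns `lo, hi`.
#' @export
subband_cutoffs <- function() {
  lo <- 1.5 * 2^(0:7)
  cbind(lo = lo, hi = lo * 2)
}

#' Center frequency of a sub-band in cycles/degree
#'
#' Converts a band's center frequency (arithmetic mean of its cutoffs, in
#' cycles/image) to cycles of visual angle per degree under a display
#' geometry: image side in pixels, pixel pitch, and viewing distance. The
#' defaults are a 512-pixel stimulus on a 24-inch 1920 x 1200 monitor
#' (0.2692 mm pixel pitch) viewed at 49 cm, under which the top band
#' (192-384 cycles/image) evaluates to about 18 cycles/degree.
#'
#' @param band Band index 1..8.
#' @param image_px Stimulus side in pixels.
#' @param pixel_mm Pixel pitch in mm.
#' @param distance_mm Viewing distance in mm.
#' @return Center frequency in cycles/degree.
#' @export
subband_center_cpd <- function(band = 8, image_px = 512, pixel_mm = 0.2692,
                               distance_mm = 490) {
  co <- subband_cutoffs()
  stopifnot(band >= 1, band <= nrow(co))
  center_cpi <- mean(co[band, ])
  extent_deg <- 2 * atan(image_px * pixel_mm / 2 / distance_mm) * 180 / pi
  center_cpi / extent_deg
}

# luminance (CIE Y) of a linear RGB array, or pass-through for a matrix
image_luminance <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3)
  RGB2XYZ[2, 1] * img[, , 1] + RGB2XYZ[2, 2] * img[, , 2] +
    RGB2XYZ[2, 3] * img[, , 3]
}

#' Specular-only luminance image
#'
#' Subtracts the diffuse component from a composite image over the object
#' region, leaving the luminance of the specular reflection alone. Small
#' negative residuals from numerical noise are clamped to zero; pixels
#' outside the mask are zero.
#'
#' @param image Composite linear image (array or luminance matrix).
#' @param diffuse_component Diffuse-only linear image, same shape.
#' @param mask Logical object mask.
#' @return Non-negative luminance matrix.
#' @export
specular_only <- function(image, diffuse_component, mask) {
  yi <- image_luminance(image)
  yd <- image_luminance(diffuse_component)
  if (!all(dim(yi) == dim(yd)) || !all(dim(yi) == dim(mask))) {
    stop("image, diffuse component and mask must share dimensions", call. = FALSE)
  }
  d <- yi - yd
  if (min(d) < -1e-6 * max(abs(yi), 1e-12)) {
    stop("composite is substantially below its diffuse component; wrong pairing?",
         call. = FALSE)
  }
  d[d < 0] <- 0
  d[!mask] <- 0
  d
}

#' Threshold a specular image into a highlight map
#'
#' Selects pixels strictly brighter than `k`% of the maximum intensity over
#' the object region (so `k = 0` keeps all strictly positive pixels);
#' higher cutoffs discard dimmer inter-reflection-like regions.
#'
#' @param spec_lum Specular luminance matrix (e.g. [specular_only()]).
#' @param mask Logical object mask (non-empty).
#' @param k Percent cutoff, one of 0, 1, 3, 5, 10, 20, 40.
#' @return Logical highlight map (subset of `mask`). If the specular image
#'   is all zero the map is empty and carries attribute `empty = TRUE`.
#' @export
threshold_highlights <- function(spec_lum, mask, k) {
  if (!any(mask)) stop("empty object mask", call. = FALSE)
  if (!k %in% HIGHLIGHT_K_SET) {
    stop("`k` must be one of ", paste(HIGHLIGHT_K_SET, collapse = ", "), call. = FALSE)
  }
  m <- max(spec_lum[mask])
  hl <- mask & (spec_lum > (k / 100) * m)
  if (m <= 0) {
    hl[] <- FALSE
    attr(hl, "empty") <- TRUE
  }
  hl
}

#' Highlight coverage
#'
#' Proportion of the object area covered by the highlight map.
#'
#' @param highlight Logical highlight map (subset of mask).
#' @param mask Logical object mask (non-empty).
#' @return Fraction in `[0, 1]`.
#' @export
coverage <- function(highlight, mask) {
  if (!any(mask)) stop("empty object mask", call. = FALSE)
  if (any(highlight & !mask)) stop("highlight must be inside the mask", call. = FALSE)
  sum(highlight) / sum(mask)
}

# 3x3 Sobel gradient magnitude (replicate-padded borders, so a constant
# image scores exactly zero)
sobel_gradient <- function(img) {
  H <- nrow(img); W <- ncol(img)
  p <- matrix(0, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- img
  p[1, ] <- p[2, ]; p[H + 2, ] <- p[H + 1, ]
  p[, 1] <- p[, 2]; p[, W + 2] <- p[, W + 1]
  sub <- function(dr, dc) p[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  gx <- (sub(-1, 1) + 2 * sub(0, 1) + sub(1, 1)) -
    (sub(-1, -1) + 2 * sub(0, -1) + sub(1, -1))
  gy <- (sub(1, -1) + 2 * sub(1, 0) + sub(1, 1)) -
    (sub(-1, -1) + 2 * sub(-1, 0) + sub(-1, 1))
  sqrt(gx^2 + gy^2)
}

#' Highlight sharpness
#'
#' Emphasizes regions of rapid luminance change with a 3x3 Sobel gradient
#' magnitude map and returns its mean over the object region. Zero for a
#' constant image; linear in image intensity. The operator is pluggable via
#' `operator` for users who prefer a different sharpness map.
#'
#' @param image Luminance matrix (e.g. a thresholded highlight image).
#' @param mask Logical mask over which to average (default: whole image).
#' @param operator Function matrix -> gradient-magnitude matrix.
#' @return Scalar sharpness.
#' @export
sharpness <- function(image, mask = NULL, operator = sobel_gradient) {
  g <- operator(image)
  if (is.null(mask)) mean(g) else mean(g[mask])
}

#' Gaussian sub-band RMS contrast
#'
#' Decomposes an image into band-pass sub-bands with isotropic
#' Fourier-domain difference-of-Gaussian filters whose half-power radii sit
#' at the stated cutoff frequencies, and returns the RMS contrast
#' (population standard deviation over the object region) of each sub-band
#' image plus the aggregate (the sd of the sum of all sub-band images).
#' Pixels outside the mask are zeroed before filtering so the metric cannot
#' see the surround. Bands above the image Nyquist attenuate naturally.
#'
#' @param image Square luminance matrix.
#' @param mask Logical object mask.
#' @param bands Cutoff matrix (columns `lo, hi`), default [subband_cutoffs()].
#' @return Tibble with `band` (1..n and `NA` for the aggregate), `lo`, `hi`,
#'   `rms`.
#' @export
subband_contrast <- function(image, mask, bands = subband_cutoffs()) {
  if (nrow(image) != ncol(image)) stop("image must be square", call. = FALSE)
  if (!any(mask)) stop("empty object mask", call. = FALSE)
  n <- nrow(image)
  img <- image
  img[!mask] <- 0
  fi <- c(0:(n %/% 2), -rev(seq_len(n - n %/% 2 - 1)))
  rad <- sqrt(outer(fi^2, fi^2, "+"))
  Fimg <- stats::fft(img)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  band_imgs <- vector("list", nrow(bands))
  rms <- numeric(nrow(bands))
  for (b in seq_len(nrow(bands))) {
    G <- exp(-log(2) * (rad / bands[b, "hi"])^2) -
      exp(-log(2) * (rad / bands[b, "lo"])^2)
    bi <- Re(stats::fft(Fimg * G, inverse = TRUE)) / n^2
    band_imgs[[b]] <- bi
    rms[b] <- pop_sd(bi[mask])
  }
  agg <- pop_sd(Reduce(`+`, band_imgs)[mask])
  tibble::tibble(band = c(seq_len(nrow(bands)), NA),
                 lo = c(bands[, "lo"], NA), hi = c(bands[, "hi"], NA),
                 rms = c(rms, agg))
}

moment_row <- function(x, prefix) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  out <- tibble::tibble(
    mean = m, median = q[2], sd = s,
    skewness = if (s > 0) mean((x - m)^3) / s^3 else NA_real_,
    kurtosis = if (s > 0) mean((x - m)^4) / s^4 else NA_real_,
    q1 = q[1], q3 = q[3], min = min(x), max = max(x))
  names(out) <- paste0(prefix, "_", names(out))
  out
}

#' Circular mean of angles in degrees
#'
#' Resultant-vector direction of a set of angles.
#'
#' @param angles Angles in degrees.
#' @return Mean angle in `[0, 360)`, or `NA` if the resultant is zero.
#' @export
circular_mean <- function(angles) {
  r <- angles * pi / 180
  s <- mean(sin(r)); c_ <- mean(cos(r))
  if (sqrt(s^2 + c_^2) < 1e-12) return(NA_real_)
  out <- (atan2(s, c_) * 180 / pi) %% 360
  if (out >= 360 - 1e-9) out <- 0
  out
}

#' Object-region color statistics
#'
#' Descriptive statistics of lightness and chroma over the object region of
#' a linear RGB image (surrounding context excluded): mean, median, sd,
#' skewness, kurtosis, quartiles, min and max per dimension, plus the
#' circular mean hue (resultant-vector angle). Lab coordinates use a gray
#' working white of luminance `white_Y` (1 for images normalized by
#' [normalize_set()]).
#'
#' @param image Linear RGB array (H x W x 3).
#' @param mask Logical object mask.
#' @param white_Y Luminance of the working white.
#' @return One-row tibble: `L_*`, `C_*` statistic columns and
#'   `hue_circ_mean`.
#' @export
region_color_stats <- function(image, mask, white_Y = 1) {
  if (!any(mask)) stop("empty object mask", call. = FALSE)
  stopifnot(length(dim(image)) == 3)
  idx <- which(mask)
  rgb <- cbind(image[, , 1][idx], image[, , 2][idx], image[, , 3][idx])
  xyz <- rgb %*% t(RGB2XYZ)
  white <- as.numeric(RGB2XYZ %*% rep(white_Y, 3))
  lab <- xyz_to_lab(xyz, white = white)
  dplyr::bind_cols(moment_row(lab[, "L"], "L"), moment_row(lab[, "C"], "C"),
                   tibble::tibble(hue_circ_mean = circular_mean(lab[, "h"])))
}

#' All highlight metrics of one specular image across the cutoff grid
#'
#' Convenience sweep: for each threshold percentage `k`, computes coverage
#' and sharpness of the thresholded highlight image and the sub-band RMS
#' contrasts of the thresholded specular image (values retained above
#' threshold, zero elsewhere).
#'
#' @param spec_lum Specular luminance matrix.
#' @param mask Logical object mask.
#' @param k_set Threshold percentages (default the full grid).
#' @param bands Cutoff matrix for [subband_contrast()].
#' @return Long tibble: `k, metric, band, value` where `metric` is
#'   `coverage`, `sharpness` or `contrast` (`band` is `NA` except for
#'   contrast; the aggregate contrast has `band = 0`).
#' @export
highlight_metrics <- function(spec_lum, mask, k_set = HIGHLIGHT_K_SET,
                              bands = subband_cutoffs()) {
  rows <- list()
  for (k in k_set) {
    hl <- threshold_highlights(spec_lum, mask, k)
    thr_img <- spec_lum
    thr_img[!hl] <- 0
    sb <- subband_contrast(thr_img, mask, bands)
    rows[[length(rows) + 1]] <- dplyr::bind_rows(
      tibble::tibble(k = k, metric = "coverage", band = NA_real_,
                     value = coverage(hl, mask)),
      tibble::tibble(k = k, metric = "sharpness", band = NA_real_,
                     value = sharpness(thr_img, mask)),
      tibble::tibble(k = k, metric = "contrast",
                     band = ifelse(is.na(sb$band), 0, sb$band),
                     value = sb$rms))
  }
  dplyr::bind_rows(rows)
}

#' Optimize highlight-metric parameters against observer settings
#'
#' Exhaustive search over the threshold grid (and sub-band grid, for the
#' contrast metric) for the parameterization whose metric values correlate
#' most strongly (largest `|r|`, Pearson) with mean observer settings
#' across images. Ties break toward the smaller `k`, then the lower band.
#'
#' @param metric_tbl Long tibble with columns `image_id, k, metric, band,
#'   value` ([highlight_metrics()] rows bound over images with an
#'   `image_id` column added).
#' @param settings Tibble with `image_id` and `setting` (mean observer
#'   setting per image), or a vector aligned with the sorted unique
#'   `image_id`.
#' @param metric Which metric family to optimize (`"coverage"`,
#'   `"sharpness"`, `"contrast"`).
#' @return One-row tibble: `metric, k, band, correlation` (signed Pearson r
#'   at the optimum; `NA` with a warning if the metric is constant across
#'   images for every parameterization).
#' @export
optimize_metric_params <- function(metric_tbl, settings,
                                   metric = c("coverage", "sharpness", "contrast")) {
  metric <- match.arg(metric)
  stopifnot(all(c("image_id", "k", "metric", "band", "value") %in% names(metric_tbl)))
  if (!is.data.frame(settings)) {
    ids <- sort(unique(metric_tbl$image_id))
    stopifnot(length(settings) == length(ids))
    settings <- tibble::tibble(image_id = ids, setting = settings)
  }
  if (nrow(settings) < 3) stop("need settings for at least 3 images", call. = FALSE)
  sub <- dplyr::filter(metric_tbl, .data$metric == !!metric)
  grid <- dplyr::distinct(sub, .data$k, .data$band)
  grid <- dplyr::arrange(grid, .data$k, .data$band)
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    gi <- grid[i, ]
    vals <- dplyr::filter(sub, .data$k == gi$k,
                          (is.na(gi$band) & is.na(.data$band)) |
                            (!is.na(gi$band) & .data$band %in% gi$band))
    m <- dplyr::inner_join(vals, settings, by = "image_id")
    if (sd(m$value) == 0 || sd(m$setting) == 0) next
    r <- cor(m$value, m$setting)
    if (is.null(best) || abs(r) > abs(best$correlation) + 1e-12) {
      best <- tibble::tibble(metric = metric, k = gi$k, band = gi$band,
                             correlation = r)
    }
  }
  if (is.null(best)) {
    warning("metric is constant across images for every parameterization; correlation undefined")
    return(tibble::tibble(metric = metric, k = NA_real_, band = NA_real_,
                          correlation = NA_real_))
  }
  best
}
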