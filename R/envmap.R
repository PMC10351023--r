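# sRGB (D65) linear RGB <-> XYZ matrices, Y row is the luminance weighting.
RGB2XYZ <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                    0.2126729, 0.7151522, 0.0721750,
                    0.0193339, 0.1191920, 0.9503041),
                  3, 3, byrow = TRUE)
XYZ2RGB <- solve(RGB2XYZ)

#' Equirectangular environment map
#'
#' Wraps an `H x 2H x 3` array of linear radiance triplets (display-linear
#' RGB, arbitrary scale) as an environment map. Row 1 is the zenith, column 1
#' is azimuth 0, azimuth increases eastward; pixel centers sit at
#' `theta_j = (j - 1/2) * pi / H`, `phi_i = (i - 1/2) * 2 * pi / W`.
#'
#' @param pixels `H x 2H x 3` non-negative array, or `H x 2H` matrix
#'   (replicated to gray).
#' @return An object of class `env_map`.
#' @export
env_map <- function(pixels) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (dim(pixels)[2] != 2 * dim(pixels)[1]) {
    stop("equirectangular map must have width = 2 * height", call. = FALSE)
  }
  if (any(pixels < 0)) stop("radiance must be non-negative", call. = FALSE)
  structure(list(pixels = pixels, height = dim(pixels)[1],
                 width = dim(pixels)[2]),
            class = "env_map")
}

#' @export
print.env_map <- function(x, ...) {
  cat(sprintf("<env_map> %d x %d equirectangular, mean luminance %.4g\n",
              x$height, x$width, mean(env_luminance(x))))
  invisible(x)
}

#' Per-pixel geometry of an equirectangular grid
#'
#' @param H Grid height (width is `2H`).
#' @return List with `theta` (H), `phi` (2H), `dir` (H*2H x 3 unit vectors,
#'   row-major by row then column), and `omega` (H x 2H solid angles in sr,
#'   summing to 4*pi exactly).
#' @export
env_geometry <- function(H) {
  W <- 2L * H
  theta <- (seq_len(H) - 0.5) * pi / H
  phi <- (seq_len(W) - 0.5) * 2 * pi / W
  # exact per-row solid angle: dphi * (cos(theta-) - cos(theta+))
  edges <- seq(0, pi, length.out = H + 1)
  band <- (cos(edges[-(H + 1)]) - cos(edges[-1])) * (2 * pi / W)
  omega <- matrix(band, H, W)
  st <- sin(theta)
  dir <- cbind(x = as.numeric(outer(st, cos(phi))),
               y = as.numeric(outer(st, sin(phi))),
               z = rep(cos(theta), W))
  list(theta = theta, phi = phi, dir = dir, omega = omega)
}

#' Linear luminance image of an environment map
#'
#' CIE Y of the linear RGB pixels (sRGB primaries).
#'
#' @param env An `env_map`.
#' @return `H x 2H` matrix.
#' @export
env_luminance <- function(env) {
  p <- env$pixels
  RGB2XYZ[2, 1] * p[, , 1] + RGB2XYZ[2, 2] * p[, , 2] + RGB2XYZ[2, 3] * p[, , 3]
}

#' Pixel-population luminance statistics of a lighting environment
#'
#' Moments of linear luminance over the raw pixel population (unweighted by
#' solid angle, matching per-pixel histogram summaries); optionally weighted
#' by solid angle. Skewness and kurtosis are the standardized central
#' moments (kurtosis not excess). For a constant map the scale-free moments
#' are undefined and returned as `NA`.
#'
#' @param env An `env_map`.
#' @param weight `"none"` (default) or `"solid_angle"`.
#' @return A one-row tibble: `mean, sd, skewness, kurtosis`.
#' @export
luminance_stats <- function(env, weight = c("none", "solid_angle")) {
  weight <- match.arg(weight)
  y <- as.numeric(env_luminance(env))
  w <- if (weight == "none") rep(1, length(y)) else
    as.numeric(env_geometry(env$height)$omega)
  w <- w / sum(w)
  m <- sum(w * y)
  v <- sum(w * (y - m)^2)
  s <- sqrt(v)
  if (s == 0) {
    return(tibble::tibble(mean = m, sd = 0, skewness = NA_real_,
                          kurtosis = NA_real_))
  }
  tibble::tibble(
    mean = m, sd = s,
    skewness = sum(w * (y - m)^3) / s^3,
    kurtosis = sum(w * (y - m)^4) / s^4)
}

#' Diffuseness of a lighting environment
#'
#' Directional-uniformity index in `[0, 1]`: 1 for a fully uniform radiance
#' field, approaching 0 as the radiance concentrates toward a single
#' direction. Computed as one minus the ratio of the magnitude of the light
#' vector (solid-angle-weighted mean direction of radiance) to the total
#' scalar flux,
#' \deqn{D = 1 - \left| \int L(\omega)\,\hat n\, d\omega \right| /
#'           \int L(\omega)\, d\omega .}
#' Invariant to global radiance scaling.
#'
#' @param env An `env_map`.
#' @return Scalar in `[0, 1]`.
#' @export
diffuseness <- function(env) {
  g <- env_geometry(env$height)
  y <- as.numeric(env_luminance(env))
  w <- as.numeric(g$omega)
  flux <- sum(w * y)
  if (flux <= 0) stop("diffuseness undefined for an all-black map", call. = FALSE)
  vec <- colSums(w * y * g$dir)
  max(0, min(1, 1 - sqrt(sum(vec^2)) / flux))
}

# Working Lab convention for HDR radiance: the map's median luminance is
# anchored to L* = 50 with equal-energy-white chromaticity. Returns the
# white point (scalar Yn replicated over X, Y, Z).
env_white <- function(env) {
  ymed <- median(env_luminance(env))
  if (ymed <= 0) ymed <- mean(env_luminance(env))
  yn <- ymed / lab_finv((50 + 16) / 116)
  c(yn, yn, yn)
}

# Per-pixel Lab of an env map under the working white. Returns n x 5
# (L, a, b, C, h) plus the white as an attribute.
env_lab <- function(env, white = env_white(env)) {
  p <- env$pixels
  n <- env$height * env$width
  rgb <- cbind(as.numeric(p[, , 1]), as.numeric(p[, , 2]), as.numeric(p[, , 3]))
  xyz <- rgb %*% t(RGB2XYZ)
  out <- xyz_to_lab(xyz, white = white)
  attr(out, "white") <- white
  out
}

# Inverse: n x 3 Lab -> env_map pixels, negative RGB clamped only if clamp.
lab_to_env <- function(lab, H, white, clamp = TRUE) {
  xyz <- lab_to_xyz(lab[, 1:3, drop = FALSE], white = white)
  rgb <- xyz %*% t(XYZ2RGB)
  if (clamp) rgb[rgb < 0] <- 0
  env_map(array(rgb, c(H, 2L * H, 3L)))
}

#' Random sample of pixel chromaticities
#'
#' Draws a uniform random subset of pixels (without replacement) and returns
#' their a*b* chromaticities under the map's working white (median luminance
#' anchored to L* = 50, equal-energy-white chromaticity).
#'
#' @param env An `env_map`.
#' @param fraction Fraction of pixels in `(0, 1]` (default 0.10).
#' @param seed Integer seed; the subset is deterministic given it.
#' @return Tibble with columns `a, b, L` (one row per sampled pixel).
#' @export
sample_chromaticities <- function(env, fraction = 0.10, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  lab <- env_lab(env)
  n <- nrow(lab)
  m <- max(1L, round(fraction * n))
  set.seed(seed)
  idx <- if (m == n) seq_len(n) else sample.int(n, m)
  tibble::tibble(a = lab[idx, "a"], b = lab[idx, "b"], L = lab[idx, "L"])
}

#' Environment-map summary statistics
#'
#' One-row tibble combining the luminance moments, diffuseness, and the
#' spherical-harmonic power slope — the per-map diagnostic row used when
#' choosing and characterizing lighting environments.
#'
#' @param env An `env_map`.
#' @param lmax Band limit for the power-spectrum analysis.
#' @return Tibble: `mean, sd, skewness, kurtosis, diffuseness, sh_slope`.
#' @export
env_stats <- function(env, lmax = min(16L, env$height - 1L)) {
  mom <- luminance_stats(env)
  coef <- sh_project(env_luminance(env), lmax)
  dplyr::mutate(mom,
                diffuseness = diffuseness(env),
                sh_slope = sh_power_slope(coef)$slope)
}

#' Rotate an environment map about the vertical axis
#'
#' Shifts columns by a whole number of pixels (the azimuth step is snapped
#' to the pixel grid, so rotation is exact and lossless).
#'
#' @param env An `env_map`.
#' @param degrees Rotation eastward in degrees.
#' @return An `env_map`.
#' @export
rotate_env_azimuth <- function(env, degrees) {
  W <- env$width
  shift <- round(degrees / 360 * W) %% W
  if (shift == 0) return(env)
  idx <- ((seq_len(W) - 1 - shift) %% W) + 1
  env_map(env$pixels[, idx, , drop = FALSE])
}

#' Synthesize a lighting environment
#'
#' Generates an HDR-like equirectangular environment emulating the gross
#' statistics of natural light probes: a log-luminance field synthesized
#' from spherical harmonics with a power-law spectrum (heavy-tailed linear
#' histogram), an optional bright directional source (von-Mises-Fisher cap)
#' controlling diffuseness, and smooth low-frequency chromatic variation
#' whose a*b* gamut is elongated along a configurable axis (the blue-yellow
#' daylight axis by default, angle 90 degrees).
#'
#' @param H Map height in pixels (width `2H`).
#' @param seed Integer seed.
#' @param slope Power-law exponent of the log-luminance SH spectrum
#'   (about -2 for natural environments).
#' @param lmax Band limit of the synthesized structure.
#' @param log_sd Standard deviation of log luminance (contrast).
#' @param cap_strength Peak radiance of the directional source relative to
#'   the ambient mean (0 disables the source).
#' @param cap_kappa Concentration of the directional source.
#' @param cap_azimuth Azimuth of the source, degrees.
#' @param cap_elevation Elevation of the source above the horizon, degrees.
#' @param chroma_sd Standard deviations `c(minor, major)` of the a*b*
#'   distribution along the minor/major chromatic axes.
#' @param chroma_axis Orientation of the major chromatic axis in the a*b*
#'   plane, degrees (90 = blue-yellow).
#' @return An `env_map`.
#' @export
synth_envmap <- function(H = 64, seed = 1, slope = -2, lmax = 16,
                         log_sd = 0.8, cap_strength = 20, cap_kappa = 40,
                         cap_azimuth = 90, cap_elevation = 35,
                         chroma_sd = c(4, 12), chroma_axis = 90) {
  set.seed(seed)
  g <- env_geometry(H)
  # log-luminance with planted power-law SH spectrum
  lmax <- min(lmax, H - 1L)
  coef <- sh_random_coef(lmax, function(l) ifelse(l == 0, 0, l^slope),
                         seed = seed)
  logl <- sh_reconstruct(coef, H)
  if (sd(logl) > 0) logl <- logl / sd(logl) * log_sd
  y <- exp(logl)
  # directional source
  if (cap_strength > 0) {
    d0 <- c(cos(cap_elevation * pi / 180) * cos(cap_azimuth * pi / 180),
            cos(cap_elevation * pi / 180) * sin(cap_azimuth * pi / 180),
            sin(cap_elevation * pi / 180))
    cosang <- matrix(g$dir %*% d0, H, 2 * H)
    y <- y + cap_strength * mean(y) * exp(cap_kappa * (cosang - 1))
  }
  # smooth chromatic fields in the working-white Lab frame
  ca <- sh_reconstruct(sh_random_coef(4, function(l) ifelse(l == 0, 0, 1),
                                      seed = seed + 1000L), H)
  cb <- sh_reconstruct(sh_random_coef(4, function(l) ifelse(l == 0, 0, 1),
                                      seed = seed + 2000L), H)
  ca <- if (sd(ca) > 0) ca / sd(ca) * chroma_sd[1] else ca
  cb <- if (sd(cb) > 0) cb / sd(cb) * chroma_sd[2] else cb
  th <- chroma_axis * pi / 180
  a <- ca * cos(th + pi / 2) + cb * cos(th)
  b <- ca * sin(th + pi / 2) + cb * sin(th)
  yn <- median(y) / lab_finv((50 + 16) / 116)
  white <- c(yn, yn, yn)
  L <- 116 * lab_f(as.numeric(y) / yn) - 16
  lab <- cbind(L, as.numeric(a), as.numeric(b))
  env <- lab_to_env(lab, H, white, clamp = TRUE)
  env
}
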