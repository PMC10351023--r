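#' @importFrom rlang .data
#' @importFrom stats cor sd median quantile rnorm runif optim coef lm setNames
#' @importFrom utils head read.csv write.csv
NULL

# Wavelength grid shared by every spectral quantity in the package:
# 31 channels, 400..700 nm in 10-nm steps (the standard 31-channel sampling
# of matte-chip spectral databases).
SPECTRAL_WL <- seq(400, 700, by = 10)

#' Wavelength grid for spectral curves
#'
#' All spectral quantities in the package (reflectances, illuminants) live on
#' a fixed 31-sample grid from 400 to 700 nm in 10-nm steps.
#'
#' @return Integer vector of 31 wavelengths in nm.
#' @export
spectral_wavelengths <- function() SPECTRAL_WL

# CIE 1931 2-degree standard observer color matching functions sampled at the
# package grid. Values are the standard 10-nm tabulation.
CIE_CMF <- matrix(c(
  # xbar,   ybar,   zbar
  0.0143, 0.0004, 0.0679,
  0.0435, 0.0012, 0.2074,
  0.1344, 0.0040, 0.6456,
  0.2839, 0.0116, 1.3856,
  0.3483, 0.0230, 1.7471,
  0.3362, 0.0380, 1.7721,
  0.2908, 0.0600, 1.6692,
  0.1954, 0.0910, 1.2876,
  0.0956, 0.1390, 0.8130,
  0.0320, 0.2080, 0.4652,
  0.0049, 0.3230, 0.2720,
  0.0093, 0.5030, 0.1582,
  0.0633, 0.7100, 0.0782,
  0.1655, 0.8620, 0.0422,
  0.2904, 0.9540, 0.0203,
  0.4334, 0.9950, 0.0087,
  0.5945, 0.9950, 0.0039,
  0.7621, 0.9520, 0.0021,
  0.9163, 0.8700, 0.0017,
  1.0263, 0.7570, 0.0011,
  1.0622, 0.6310, 0.0008,
  1.0026, 0.5030, 0.0003,
  0.8544, 0.3810, 0.0002,
  0.6424, 0.2650, 0.0000,
  0.4479, 0.1750, 0.0000,
  0.2835, 0.1070, 0.0000,
  0.1649, 0.0610, 0.0000,
  0.0874, 0.0320, 0.0000,
  0.0468, 0.0170, 0.0000,
  0.0227, 0.0082, 0.0000,
  0.0114, 0.0041, 0.0000
), ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("xbar", "ybar", "zbar")))

#' Equal-energy white illuminant
#'
#' Flat spectral power distribution on the package wavelength grid. Under this
#' illuminant a perfect reflector maps to X = Y = Z = 100, the white-point
#' anchor used throughout.
#'
#' @return Numeric vector of 31 ones.
#' @export
illuminant_eew <- function() rep(1, length(SPECTRAL_WL))

check_spectrum <- function(x, arg = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != length(SPECTRAL_WL)) {
    stop(sprintf("`%s` must be a numeric spectral curve with %d samples (400-720 nm, 10-nm step), got length %d",
                 arg, length(SPECTRAL_WL), length(x)), call. = FALSE)
  }
  invisible(x)
}

#' Integrate a reflectance spectrum to CIE XYZ
#'
#' Computes tristimulus values of `reflectance` viewed under `illuminant`
#' using the CIE 1931 2-degree observer. Each channel is normalized so that
#' a perfect reflector maps to exactly X = Y = Z = 100 — i.e. the illuminant
#' is the working white with tristimulus (100, 100, 100), the anchor used
#' for all Lab colorimetry here. The map is linear in the reflectance.
#'
#' @param reflectance Numeric vector of 31 reflectance samples.
#' @param illuminant Numeric vector of 31 relative-power samples
#'   (default equal-energy white).
#' @return Named numeric vector `c(X, Y, Z)`.
#' @export
spectrum_to_xyz <- function(reflectance, illuminant = illuminant_eew()) {
  check_spectrum(reflectance)
  check_spectrum(illuminant)
  k <- 100 / colSums(illuminant * CIE_CMF)
  xyz <- k * colSums(reflectance * illuminant * CIE_CMF)
  setNames(as.numeric(xyz), c("X", "Y", "Z"))
}

# 3 x 31 matrix mapping a reflectance (under a fixed illuminant) to XYZ,
# same per-channel white anchoring as spectrum_to_xyz.
xyz_operator <- function(illuminant = illuminant_eew()) {
  check_spectrum(illuminant)
  k <- 100 / colSums(illuminant * CIE_CMF)
  k * t(illuminant * CIE_CMF)  # 3 x 31, rows X, Y, Z
}

lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

lab_finv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

#' CIELAB from XYZ
#'
#' Standard CIELAB conversion. The default white point is the equal-energy
#' white anchor X = Y = Z = 100 used for all reflectance colorimetry here.
#'
#' @param xyz Numeric length-3 `c(X, Y, Z)` or an n x 3 matrix.
#' @param white White point, length-3, strictly positive.
#' @return Named vector `c(L, a, b, C, h)` (chroma and hue angle in degrees,
#'   hue in `[0, 360)`), or an n x 5 matrix for matrix input.
#' @export
xyz_to_lab <- function(xyz, white = c(100, 100, 100)) {
  stopifnot(all(white > 0))
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, ncol = 3)
  fx <- lab_f(m[, 1] / white[1])
  fy <- lab_f(m[, 2] / white[2])
  fz <- lab_f(m[, 3] / white[3])
  L <- 116 * fy - 16
  a <- 500 * (fx - fy)
  b <- 200 * (fy - fz)
  C <- sqrt(a^2 + b^2)
  h <- (atan2(b, a) * 180 / pi) %% 360
  out <- cbind(L = L, a = a, b = b, C = C, h = h)
  if (is.matrix(xyz)) out else out[1, ]
}

#' XYZ from CIELAB
#'
#' Inverse of [xyz_to_lab()]; round-trips to better than 1e-9.
#'
#' @param lab Numeric `c(L, a, b)` or an n x 3 matrix.
#' @param white White point, length-3, strictly positive.
#' @return Named vector `c(X, Y, Z)` or an n x 3 matrix.
#' @export
lab_to_xyz <- function(lab, white = c(100, 100, 100)) {
  stopifnot(all(white > 0))
  m <- if (is.matrix(lab)) lab else matrix(lab, ncol = 3)
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  out <- cbind(X = white[1] * lab_finv(fx),
               Y = white[2] * lab_finv(fy),
               Z = white[3] * lab_finv(fz))
  if (is.matrix(lab)) out else out[1, ]
}

#' Lab coordinates of a hue/lightness/chroma triple
#'
#' @param hue Hue angle in degrees.
#' @param lightness CIELAB L*.
#' @param chroma CIELAB C*ab.
#' @return Numeric `c(L, a, b)`.
#' @export
lch_to_lab <- function(hue, lightness, chroma) {
  c(L = lightness,
    a = chroma * cos(hue * pi / 180),
    b = chroma * sin(hue * pi / 180))
}

#' CIE76 color difference
#'
#' @param lab1,lab2 Length-3 `c(L, a, b)` vectors or n x 3 matrices.
#' @return Euclidean distance(s) in Lab.
#' @export
delta_e <- function(lab1, lab2) {
  m1 <- if (is.matrix(lab1)) lab1[, 1:3, drop = FALSE] else matrix(lab1[1:3], ncol = 3)
  m2 <- if (is.matrix(lab2)) lab2[, 1:3, drop = FALSE] else matrix(lab2[1:3], ncol = 3)
  d <- sqrt(rowSums((m1 - m2)^2))
  if (is.matrix(lab1) || is.matrix(lab2)) d else d[1]
}
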