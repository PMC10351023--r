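#' Pellacini contrast-gloss scale for the Ward model
#'
#' Converts Ward specularity \eqn{\rho_s} to Pellacini's perceptually linear
#' contrast-gloss parameter \eqn{c} at a given conversion lightness, using
#' the cube-root contrast form
#' \deqn{c = (\rho_s + \rho_d/2)^{1/3} - (\rho_d/2)^{1/3}}
#' with the diffuse term derived from lightness as
#' \eqn{\rho_d = (L^*/100)^3}. With this mapping, \eqn{\rho_s = 0.0999}
#' corresponds to \eqn{c \approx 0.149} at \eqn{L^* = 50} and
#' \eqn{c \approx 0.223} at \eqn{L^* = 33.9}, matching the stimulus ranges
#' used for gloss adjustment.
#'
#' `c` is strictly increasing in `ward_ps` and, for `ward_ps > 0`, strictly
#' decreasing in lightness; `ward_from_pellacini()` is the closed-form
#' inverse and round-trips to better than 1e-9.
#'
#' @param ward_ps Ward specularity \eqn{\rho_s} in `[0, 1)`. Vectorized.
#' @param lightness Conversion lightness L* in `(0, 100]`. Vectorized.
#' @return `pellacini_c()`: the contrast-gloss value(s) `c >= 0`.
#' @export
pellacini_c <- function(ward_ps, lightness) {
  if (any(ward_ps < 0) || any(ward_ps >= 1)) {
    stop("`ward_ps` must lie in [0, 1)", call. = FALSE)
  }
  if (any(lightness <= 0) || any(lightness > 100)) {
    stop("`lightness` must lie in (0, 100]", call. = FALSE)
  }
  rd2 <- (lightness / 100)^3 / 2
  (ward_ps + rd2)^(1 / 3) - rd2^(1 / 3)
}

#' @rdname pellacini_c
#' @param c Pellacini contrast-gloss value(s), `c >= 0`.
#' @return `ward_from_pellacini()`: the Ward specularity \eqn{\rho_s}.
#' @export
ward_from_pellacini <- function(c, lightness) {
  if (any(c < 0)) stop("`c` must be non-negative", call. = FALSE)
  if (any(lightness <= 0) || any(lightness > 100)) {
    stop("`lightness` must lie in (0, 100]", call. = FALSE)
  }
  rd2 <- (lightness / 100)^3 / 2
  (c + rd2^(1 / 3))^3 - rd2
}

#' Material specification
#'
#' Bundles the surface parameters that define one stimulus: body color as
#' hue / L* / C*ab, gloss both as Pellacini's c and as the consistent Ward
#' specularity at the stated conversion lightness, and the fixed Ward
#' roughness.
#'
#' @param hue Hue angle, degrees (stored modulo 360).
#' @param lightness CIELAB L* of the diffuse reflectance under equal-energy
#'   white.
#' @param chroma CIELAB C*ab.
#' @param pellacini_c Contrast-gloss value; converted to Ward specularity at
#'   `conversion_lightness`.
#' @param conversion_lightness Lightness used for the gloss-scale conversion
#'   (50 in the single-object design, 33.9 in the factorial design).
#' @param roughness Ward roughness alpha (fixed at 0.05 for all stimuli).
#' @return A tibble row of class `material_spec` with columns
#'   `hue, lightness, chroma, pellacini_c, ward_ps, roughness`.
#' @export
material_spec <- function(hue, lightness, chroma, pellacini_c,
                          conversion_lightness = 50, roughness = 0.05) {
  stopifnot(roughness > 0)
  ps <- ward_from_pellacini(pellacini_c, conversion_lightness)
  if (any(ps > 0.0999 + 1e-9)) {
    stop("Pellacini c maps to Ward specularity above 0.0999, outside the stimulus range",
         call. = FALSE)
  }
  out <- tibble::tibble(
    hue = hue %% 360, lightness = lightness, chroma = chroma,
    pellacini_c = pellacini_c, ward_ps = ps,
    conversion_lightness = conversion_lightness, roughness = roughness)
  class(out) <- c("material_spec", class(out))
  out
}
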