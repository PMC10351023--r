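# Largest chroma scale factor t in [0, 1] keeping each Lab pixel inside the
# non-negative-RGB chromatic gamut, found by vectorized bisection (hue and
# L* fixed). lab: n x 3 for the pixels needing reduction.
chroma_gamut_scale <- function(lab, white, n_iter = 40) {
  in_gamut <- function(t) {
    l2 <- cbind(lab[, 1], lab[, 2] * t, lab[, 3] * t)
    rgb <- lab_to_xyz(l2, white = white) %*% t(XYZ2RGB)
    rowSums(rgb < -1e-12) == 0
  }
  lo <- rep(0, nrow(lab))
  hi <- rep(1, nrow(lab))
  ok1 <- in_gamut(rep(1, nrow(lab)))
  lo[ok1] <- 1
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    ok <- in_gamut(mid)
    lo[ok] <- mid[ok]
    hi[!ok] <- mid[!ok]
  }
  lo
}

#' Rotate the chromatic gamut of a lighting environment
#'
#' Rotates the a*b* chromatic distribution of the map by `angle` degrees
#' (default +90, turning a blue-yellow daylight axis into a red-green one)
#' while leaving every pixel's L* exactly unchanged. Pixels whose rotated
#' chromaticity falls outside the display gamut (non-negative linear RGB
#' with sRGB primaries) have their chroma reduced by bisection — hue and L*
#' fixed — until they are inside; the fraction of such pixels is reported in
#' the `"clipped_fraction"` attribute.
#'
#' Lab coordinates use the map's working white: median luminance anchored
#' to L* = 50 with equal-energy-white chromaticity.
#'
#' @param env An `env_map`.
#' @param angle Rotation in degrees (default +90).
#' @return An `env_map` with attribute `clipped_fraction`.
#' @export
rotate_gamut <- function(env, angle = 90) {
  white <- env_white(env)
  lab <- env_lab(env, white = white)
  th <- angle * pi / 180
  a2 <- lab[, "a"] * cos(th) - lab[, "b"] * sin(th)
  b2 <- lab[, "a"] * sin(th) + lab[, "b"] * cos(th)
  lab2 <- cbind(lab[, "L"], a2, b2)
  rgb <- lab_to_xyz(lab2, white = white) %*% t(XYZ2RGB)
  bad <- rowSums(rgb < -1e-12) > 0
  if (any(bad)) {
    t_ok <- chroma_gamut_scale(lab2[bad, , drop = FALSE], white)
    lab2[bad, 2] <- lab2[bad, 2] * t_ok
    lab2[bad, 3] <- lab2[bad, 3] * t_ok
  }
  out <- lab_to_env(lab2, env$height, white, clamp = TRUE)
  attr(out, "clipped_fraction") <- mean(bad)
  out
}

# Rank-based histogram matching: returns `values` remapped so its empirical
# distribution equals that of `reference` (exact for equal lengths).
match_histogram <- function(values, reference) {
  sort(reference)[rank(values, ties.method = "first")]
}

# Rank-based color transfer: each pixel of `env` receives the full RGB
# triplet of the equally-luminance-ranked pixel of `ref`. The output's
# joint color distribution (hence every luminance and chromaticity
# marginal) is exactly the reference's multiset of pixel colors, while the
# spatial arrangement follows `env`'s luminance ranks.
match_colors_by_rank <- function(env, ref) {
  y <- rank(as.numeric(env_luminance(env)), ties.method = "first")
  o <- order(as.numeric(env_luminance(ref)))
  p <- env$pixels
  for (ch in 1:3) {
    src <- as.numeric(ref$pixels[, , ch])[o]
    p[, , ch] <- matrix(src[y], env$height, env$width)
  }
  env_map(p)
}

#' Phase-scramble a lighting environment
#'
#' Distorts the directional structure of the map by rotating each
#' spherical-harmonic degree-`l` coefficient subspace by a random proper
#' rotation (identical rotation across the three color channels, so no
#' chromatic fringing is introduced). Per-degree SH power is preserved
#' exactly by construction. Because scrambling still changes the pixel
#' color distribution, the scrambled map is then histogram-matched to the
#' original by rank-based color transfer: each pixel receives the full RGB
#' color of the equally-luminance-ranked original pixel, so the joint
#' color distribution — and with it every luminance and chromaticity
#' marginal — is preserved exactly while the spatial arrangement follows
#' the scramble.
#'
#' @param env An `env_map`.
#' @param lmax Band limit of the scramble (default `H - 1`).
#' @param seed Integer seed; output is deterministic given it.
#' @param rotations Optional list of per-degree rotation matrices
#'   (`rotations[[l]]` of dimension `2l+1`); identity matrices reproduce the
#'   band-limited original. Overrides `seed`.
#' @param match Apply histogram matching (default TRUE). With
#'   `match = FALSE` the raw scrambled reconstruction is returned (negative
#'   radiance clamped to zero), mainly for inspecting spectrum preservation.
#' @return An `env_map`.
#' @export
phase_scramble <- function(env, lmax = env$height - 1L, seed = 1,
                           rotations = NULL, match = TRUE) {
  H <- env$height
  if (is.null(rotations)) {
    set.seed(seed)
    rotations <- lapply(seq_len(lmax), sh_random_rotation)
  }
  stopifnot(length(rotations) >= lmax)
  chans <- lapply(1:3, function(ch) {
    coef <- sh_project(env$pixels[, , ch], lmax)
    coef <- sh_apply_rotations(coef, rotations)
    sh_reconstruct(coef, H)
  })
  p <- array(0, c(H, 2L * H, 3L))
  for (ch in 1:3) p[, , ch] <- pmax(chans[[ch]], 0)
  out <- env_map(p)
  if (!match) return(out)
  match_colors_by_rank(out, env)
}

#' Build the manipulated lighting-environment set
#'
#' Applies both illumination manipulations to each base environment,
#' yielding, for `n` base maps, a set of `3n` environments: the originals,
#' the +90-degree gamut-rotated versions, and the phase-scrambled versions.
#'
#' @param envs List of `env_map` objects (the natural base set).
#' @param seed Integer seed for the scrambles (one derived seed per map).
#' @param lmax Band limit for scrambling (default per-map `H - 1`).
#' @return A tibble with columns `env_id`, `condition`
#'   (`natural` / `gamut_rotated` / `phase_scrambled`) and a list-column
#'   `env`.
#' @export
build_env_set <- function(envs, seed = 1, lmax = NULL) {
  stopifnot(length(envs) >= 1)
  ids <- seq_along(envs)
  rows <- list()
  for (i in ids) {
    e <- envs[[i]]
    lm_i <- if (is.null(lmax)) e$height - 1L else lmax
    rows[[length(rows) + 1]] <- tibble::tibble(
      env_id = i, condition = "natural", env = list(e))
    rows[[length(rows) + 1]] <- tibble::tibble(
      env_id = i, condition = "gamut_rotated", env = list(rotate_gamut(e)))
    rows[[length(rows) + 1]] <- tibble::tibble(
      env_id = i, condition = "phase_scrambled",
      env = list(phase_scramble(e, lmax = lm_i, seed = seed + i)))
  }
  dplyr::bind_rows(rows)
}
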