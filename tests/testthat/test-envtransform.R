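test_that("gamut rotation preserves L*, rotates a*b*, never raises chroma", {
  e <- synth_envmap(32, seed = 14)
  white <- glosscon:::env_white(e)
  lab0 <- glosscon:::env_lab(e, white)
  er <- rotate_gamut(e, angle = 90)
  labr <- glosscon:::env_lab(er, white)
  expect_equal(labr[, "L"], lab0[, "L"], tolerance = 1e-9)
  expect_true(all(labr[, "C"] <= lab0[, "C"] + 1e-6))
  # neutral pixels unchanged; in-gamut pixels rotated exactly
  neutral <- abs(lab0[, "C"]) < 1e-9
  if (any(neutral)) {
    expect_equal(labr[neutral, "a"], lab0[neutral, "a"], tolerance = 1e-9)
  }
  clipped <- attr(er, "clipped_fraction")
  expect_true(clipped >= 0 && clipped <= 1)
})

test_that("rotation definition: (a,b) = (10,0) maps to (0,10) at +90", {
  # build a map whose every pixel has the same in-gamut Lab color
  H <- 8
  yn <- 1 / glosscon:::lab_finv(66 / 116)   # white so median L* = 50
  lab <- matrix(rep(c(50, 10, 0), each = H * 2 * H), ncol = 3)
  e <- glosscon:::lab_to_env(lab, H, c(yn, yn, yn), clamp = FALSE)
  er <- rotate_gamut(e, 90)
  labr <- glosscon:::env_lab(er, glosscon:::env_white(e))
  expect_equal(unname(labr[1, "a"]), 0, tolerance = 1e-6)
  expect_equal(unname(labr[1, "b"]), 10, tolerance = 1e-6)
  # two +90 rotations equal one +180 on this clipping-free map
  e180 <- rotate_gamut(e, 180)
  e9090 <- rotate_gamut(rotate_gamut(e, 90), 90)
  expect_equal(e9090$pixels, e180$pixels, tolerance = 1e-6)
})

test_that("out-of-gamut pixels are pulled inside along chroma only", {
  H <- 8
  yn <- 1 / glosscon:::lab_finv(66 / 116)
  # saturated red: far outside the non-negative-RGB gamut after rotation
  lab <- matrix(rep(c(50, 70, 30), each = H * 2 * H), ncol = 3)
  e <- glosscon:::lab_to_env(lab, H, c(yn, yn, yn), clamp = TRUE)
  er <- rotate_gamut(e, 90)
  expect_gt(attr(er, "clipped_fraction"), 0)
  white <- glosscon:::env_white(e)
  lab0 <- glosscon:::env_lab(e, white)
  labr <- glosscon:::env_lab(er, white)
  expect_equal(labr[, "L"], lab0[, "L"], tolerance = 1e-6)
  expect_lt(max(labr[, "C"]), max(lab0[, "C"]))
  # hue equals the rotated hue
  expect_equal(unname(labr[1, "h"]), unname((lab0[1, "h"] + 90) %% 360),
               tolerance = 0.1)
  # all pixels inside the gamut
  expect_true(all(er$pixels >= 0))
})

test_that("phase scrambling preserves per-degree power and matches histograms", {
  e <- synth_envmap(64, seed = 20)
  lmax <- 40
  # spectrum preservation before histogram matching, per channel
  set.seed(33)
  rots <- lapply(seq_len(lmax), glosscon:::sh_random_rotation)
  for (ch in c(1, 3)) {
    co <- sh_project(e$pixels[, , ch], lmax)
    co2 <- glosscon:::sh_apply_rotations(co, rots)
    p1 <- sh_power_slope(co)$power$power
    p2 <- sh_power_slope(co2)$power$power
    expect_lt(max(abs(p1 - p2) / pmax(p1, 1e-300)), 1e-6)
  }
  es <- phase_scramble(e, lmax = lmax, seed = 33)
  # luminance histogram matched
  y0 <- as.numeric(env_luminance(e)); y1 <- as.numeric(env_luminance(es))
  ks <- suppressWarnings(stats::ks.test(y0, y1)$statistic)
  expect_lte(unname(ks), 0.01)
  expect_gte(min(y1), min(y0) - 1e-9)
  expect_lte(max(y1), max(y0) + 1e-9)
  # chroma marginal matched
  white <- glosscon:::env_white(e)
  c0 <- glosscon:::env_lab(e, white)[, "C"]
  c1 <- glosscon:::env_lab(es, white)[, "C"]
  ks2 <- suppressWarnings(stats::ks.test(c0, c1)$statistic)
  expect_lte(unname(ks2), 0.02)
  # determinism
  es2 <- phase_scramble(e, lmax = lmax, seed = 33)
  expect_identical(es$pixels, es2$pixels)
  # the directional structure really is scrambled
  expect_gt(mean(abs(env_luminance(es) - env_luminance(e))), 0)
})

test_that("identity rotations reproduce the band-limited original", {
  e <- synth_envmap(32, seed = 9, lmax = 12)
  lmax <- 20
  ident <- lapply(seq_len(lmax), function(l) diag(2 * l + 1))
  es <- phase_scramble(e, lmax = lmax, rotations = ident, match = FALSE)
  band <- sh_reconstruct(sh_project(e$pixels[, , 2], lmax), 32)
  expect_equal(es$pixels[, , 2], pmax(band, 0), tolerance = 1e-9)
})

test_that("the manipulated environment set has three conditions per base map", {
  envs <- lapply(1:2, function(i) synth_envmap(16, seed = i))
  es <- build_env_set(envs, seed = 4)
  expect_equal(nrow(es), 6)
  expect_setequal(es$condition, c("natural", "gamut_rotated", "phase_scrambled"))
  expect_true(all(vapply(es$env, inherits, logical(1), "env_map")))
})
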