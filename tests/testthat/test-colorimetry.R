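test_that("spectral integration is anchored at equal-energy white and linear", {
  expect_equal(unname(spectrum_to_xyz(rep(1, 31))), c(100, 100, 100))
  expect_equal(unname(spectrum_to_xyz(rep(0, 31))), c(0, 0, 0))
  expect_equal(unname(spectrum_to_xyz(rep(0.5, 31))), c(50, 50, 50))
  # linearity on random non-negative curves
  set.seed(4)
  for (i in 1:10) {
    r1 <- runif(31); r2 <- runif(31)
    a <- runif(1, 0, 2); b <- runif(1, 0, 2)
    expect_equal(spectrum_to_xyz(a * r1 + b * r2),
                 a * spectrum_to_xyz(r1) + b * spectrum_to_xyz(r2),
                 tolerance = 1e-12)
  }
  expect_error(spectrum_to_xyz(rep(1, 30)), "31 samples")
})

test_that("Lab conversion hits its anchors and round-trips", {
  lab <- xyz_to_lab(c(100, 100, 100))
  expect_equal(unname(lab[c("L", "a", "b")]), c(100, 0, 0))
  # closed-form inversion of L* = 50
  y50 <- ((50 + 16) / 116)^3 * 100
  lab2 <- xyz_to_lab(c(y50, y50, y50))
  expect_equal(unname(lab2["L"]), 50, tolerance = 1e-9)
  expect_equal(unname(lab2[c("a", "b")]), c(0, 0))
  set.seed(8)
  xyz <- matrix(runif(60, 0.5, 120), ncol = 3)
  expect_equal(lab_to_xyz(xyz_to_lab(xyz)[, 1:3]), xyz,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("NMF basis extraction recovers planted bases and is deterministic", {
  set.seed(3)
  planted <- matrix(runif(31 * 6, 0, 1), 31, 6)
  weights <- matrix(runif(6 * 200, 0, 1), 6, 200)
  chips <- planted %*% weights
  bs <- fit_basis(chips, 6, seed = 5, n_iter = 3000, n_restart = 4)
  recon_w <- apply(chips, 2, function(v) {
    coef(lm(v ~ bs$components - 1))
  })
  rmse <- sqrt(mean((chips - bs$components %*% recon_w)^2))
  expect_lt(rmse, 1e-3)
  expect_true(all(bs$components >= 0))
  # single component, identical chips
  one <- matrix(rep(runif(31, 0.2, 0.6), 10), 31, 10)
  b1 <- fit_basis(one, 1, seed = 2, n_iter = 300, n_restart = 2)
  expect_lt(sd(one[, 1] / b1$components[, 1]), 1e-6)
  # determinism
  b2 <- fit_basis(chips, 6, seed = 5, n_iter = 3000, n_restart = 4)
  expect_identical(bs$components, b2$components)
  expect_error(fit_basis(chips[, 1:4], 6), "at least as many chips")
})

test_that("reflectance solver matches targets within tolerance and flags infeasible", {
  bs <- FIX_BASIS
  # self-consistency: target = Lab of a known in-gamut basis combination
  set.seed(12)
  for (i in 1:5) {
    w <- runif(6, 0, 0.15)
    curve <- pmin(bs$components %*% w, 0.9)
    lab <- xyz_to_lab(spectrum_to_xyz(as.numeric(curve)))
    sol <- solve_reflectance(bs, lab["h"], lab["L"], lab["C"])
    expect_true(sol$feasible)
    expect_lte(sol$delta_e, 0.5)
  }
  # neutral gray target: near-flat curve with Y ~ 18.42
  gray <- solve_reflectance(bs, hue = 0, lightness = 50, chroma = 0)
  expect_true(gray$feasible)
  y50 <- ((50 + 16) / 116)^3 * 100
  expect_equal(unname(spectrum_to_xyz(gray$reflectance)["Y"]), y50,
               tolerance = 0.05)
  expect_lt(diff(range(gray$reflectance)) / mean(gray$reflectance), 0.6)
  # far outside the physical gamut
  wild <- solve_reflectance(bs, hue = 0, lightness = 50, chroma = 500)
  expect_false(wild$feasible)
  expect_gt(wild$delta_e, 0.5)
})

# independent oracle: dense grid over the tristimulus-preserving null space;
# any feasible grid point gives dE = 0, otherwise the clipped curve's dE.
brute_force_de <- function(basis, hue, lightness, chroma, half_width = 0.6,
                           n_per_axis = 13) {
  B <- basis$components
  M <- glosscon:::xyz_operator() %*% B
  target <- lab_to_xyz(lch_to_lab(hue, lightness, chroma))
  w0 <- glosscon:::pinv(M) %*% matrix(target, 3)
  N <- glosscon:::null_basis(M)
  grid1 <- seq(-half_width, half_width, length.out = n_per_axis)
  best <- Inf
  tl <- lch_to_lab(hue, lightness, chroma)
  for (z1 in grid1) for (z2 in grid1) for (z3 in grid1) {
    w <- w0 + N %*% c(z1, z2, z3)
    r <- B %*% w
    rc <- pmin(pmax(r, 0), 0.9)
    de <- delta_e(xyz_to_lab(as.numeric(glosscon:::xyz_operator() %*% rc))[1:3], tl)
    if (de < best) best <- de
  }
  best
}

test_that("solver is equivalent to a brute-force null-space minimizer", {
  bs <- FIX_BASIS
  set.seed(31)
  for (i in 1:20) {
    h <- runif(1, 0, 360); L <- runif(1, 30, 70); C <- runif(1, 8, 24)
    sol <- solve_reflectance(bs, h, L, C)
    bf <- brute_force_de(bs, h, L, C)
    expect_lt(abs(sol$delta_e - bf), 0.1)
  }
})

test_that("color grid has the full factorial cardinality and respects bounds", {
  bs <- FIX_BASIS
  g <- generate_color_grid(bs, hues = seq(0, 300, 60),
                           lightnesses = c(30, 50, 70), chromas = c(10, 20))
  expect_equal(nrow(g), 6 * 3 * 2)
  cv <- attr(g, "curves")
  expect_true(all(cv[, g$feasible] >= 0 & cv[, g$feasible] <= 0.9))
  # default axis lengths
  expect_length(seq(0, 356, by = 4), 90)
  expect_length(seq(28, 74, by = 2), 24)
  expect_length(seq(8, 26, by = 2), 10)
  # single-entry grid
  g1 <- generate_color_grid(bs, hues = 100, lightnesses = 50, chromas = 10)
  expect_equal(nrow(g1), 1)
  # hue 356 + step 4 wraps to 0 without duplication
  g2 <- generate_color_grid(bs, hues = c(0, 360), lightnesses = 50, chromas = 10)
  expect_equal(nrow(g2), 1)
  # achieved color matches the target
  lab <- xyz_to_lab(spectrum_to_xyz(grid_reflectance(g1, 1)[, 1]))
  expect_lt(abs(lab["C"] - 10), 0.5)
})

test_that("color grid exports round-trip through CSV", {
  bs <- FIX_BASIS
  g <- generate_color_grid(bs, hues = c(0, 90), lightnesses = 50, chromas = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_color_grid(g, path)
  back <- read.csv(path)
  expect_named(back, c("hue", "lightness", "chroma", paste0("w", 1:6),
                       "deltaE", "feasible"))
  expect_equal(back$w1, g$w1, tolerance = 1e-12)
})
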