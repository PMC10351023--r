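toy_settings <- function(M, truth, parameter = "pellacini_c") {
  # M: images x observers matrix of settings
  rows <- lapply(seq_len(ncol(M)), function(o) {
    tibble::tibble(observer = o, image_id = seq_len(nrow(M)), session = 1,
                   parameter = parameter, setting = M[, o], truth = truth)
  })
  dplyr::bind_rows(rows)
}

test_that("observer-truth correlations match direct computation", {
  truth <- c(1, 3, 2, 5, 4, 6)
  M <- cbind(truth, -truth + 10, truth + rnorm(6, 0, 0.1))
  st <- toy_settings(M, truth)
  rep <- suppressWarnings(observer_truth_corr(st, "pellacini_c"))
  direct <- vapply(1:3, function(o) cor(M[, o], truth), numeric(1))
  expect_equal(rep$per_observer$r, direct, tolerance = 1e-12)
  expect_equal(rep$mean_r, mean(direct))
  expect_equal(rep$se_r, sd(direct) / sqrt(3))
  expect_equal(direct[1], 1)
  expect_equal(direct[2], -1)
  # constant observer excluded with a warning
  M2 <- cbind(truth, rep(2, 6), truth)
  expect_warning(r2 <- observer_truth_corr(toy_settings(M2, truth), "pellacini_c"),
                 "undefined")
  expect_equal(nrow(r2$per_observer), 3)
  expect_equal(r2$mean_r, 1)
  # tidy/glance accessors
  expect_named(tidy(rep), c("observer", "r"))
  expect_equal(glance(rep)$n_images, 6)
})

test_that("circular correlation is rotation invariant with a null near zero", {
  set.seed(3)
  a <- runif(36, 0, 360)
  expect_equal(circular_corr(a, a), 1, tolerance = 1e-12)
  expect_equal(circular_corr(a, (a + 40) %% 360), 1, tolerance = 1e-9)
  b <- (a * 1 + rnorm(36, 0, 10)) %% 360
  r0 <- circular_corr(a, b)
  expect_equal(circular_corr((a + 123) %% 360, (b + 307) %% 360), r0,
               tolerance = 1e-9)
  nulls <- vapply(1:20, function(s) {
    set.seed(s)
    abs(circular_corr(runif(36, 0, 360), runif(36, 0, 360)))
  }, numeric(1))
  expect_lt(median(nulls), 0.4)
  expect_true(is.na(circular_corr(rep(10, 5), a[1:5])))
})

test_that("noise ceilings bound each other and match hand computation", {
  truth <- seq(0, 1, length.out = 10)
  M <- cbind(truth, truth, truth)
  nc <- noise_ceiling(toy_settings(M, truth))
  expect_equal(nc$upper, rep(1, 3), tolerance = 1e-12)
  expect_equal(nc$lower, rep(1, 3), tolerance = 1e-12)
  # hand computation on a 3-observer toy
  set.seed(4)
  M2 <- matrix(rnorm(30), 10, 3)
  nc2 <- noise_ceiling(toy_settings(M2, truth))
  expect_equal(nc2$upper[2], cor(M2[, 2], rowMeans(M2)), tolerance = 1e-12)
  expect_equal(nc2$lower[3], cor(M2[, 3], rowMeans(M2[, 1:2])), tolerance = 1e-12)
  # shared signal + independent noise: mean upper >= mean lower over seeds
  diffs <- vapply(1:20, function(s) {
    set.seed(s)
    sig <- rnorm(15)
    M3 <- sapply(1:5, function(o) sig + rnorm(15, 0, 0.7))
    n3 <- noise_ceiling(toy_settings(M3, truth = rnorm(15)))
    mean(n3$upper) - mean(n3$lower)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_error(noise_ceiling(toy_settings(M[, 1:2], truth)), "3 observers")
})

test_that("saturation consistency detects C/L-preserving strategies", {
  set.seed(7)
  n <- 24
  truth_L <- runif(n, 30, 70); truth_C <- runif(n, 8, 26)
  sat <- truth_C / truth_L
  # settings scramble C and L separately but preserve their ratio
  fac <- runif(n, 0.7, 1.3)
  rows <- lapply(1:3, function(o) dplyr::bind_rows(
    tibble::tibble(observer = o, image_id = 1:n, session = 1,
                   parameter = "lightness", setting = truth_L * fac,
                   truth = truth_L),
    tibble::tibble(observer = o, image_id = 1:n, session = 1,
                   parameter = "chroma", setting = truth_C * fac,
                   truth = truth_C)))
  st <- dplyr::bind_rows(rows)
  rep <- saturation_consistency(st)
  expect_equal(rep$mean_r, 1, tolerance = 1e-9)
  # identity settings also give r = 1
  st2 <- dplyr::mutate(st, setting = truth)
  expect_equal(saturation_consistency(st2)$mean_r, 1, tolerance = 1e-12)
})

test_that("gloss-error correlations flag planted effects and pass nulls", {
  set.seed(11)
  n <- 36
  color <- tibble::tibble(image_id = 1:n, hue = runif(n, 0, 360),
                          lightness = runif(n, 28, 74),
                          chroma = runif(n, 8, 26))
  truth <- runif(n, 0, 0.149)
  # null: errors independent of color; count significant over 20 seeds
  n_sig <- sum(vapply(1:20, function(s) {
    set.seed(s)
    M <- sapply(1:4, function(o) truth + rnorm(n, 0, 0.02))
    res <- gloss_error_vs_color(toy_settings(M, truth), color)
    sum(res$significant)
  }, numeric(1)))
  expect_lte(n_sig, 3)  # Bonferroni keeps the family-wise rate low
  # power: errors linear in lightness
  M2 <- sapply(1:4, function(o) truth + 0.004 * color$lightness +
                 rnorm(n, 0, 0.01))
  res2 <- gloss_error_vs_color(toy_settings(M2, truth), color)
  expect_true(res2$significant[res2$color_parameter == "lightness"])
  # zero errors: undefined marker
  M3 <- sapply(1:4, function(o) truth)
  res3 <- gloss_error_vs_color(toy_settings(M3, truth), color)
  expect_true(all(is.na(res3$r)))
})

test_that("partial correlation equals the residual-regression oracle", {
  set.seed(13)
  for (i in 1:100) {
    n <- 30
    z <- rnorm(n); x <- 0.5 * z + rnorm(n); y <- -0.3 * z + rnorm(n)
    pc <- partial_corr(x, y, z)
    oracle <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
    expect_equal(pc, oracle, tolerance = 1e-10)
  }
  # x = z exactly: partial correlation undefined (collinear control)
  z <- rnorm(20)
  expect_true(is.na(partial_corr(z, rnorm(20), z)))
  # independent z: partial approaches the plain correlation
  set.seed(14)
  n <- 4000
  x <- rnorm(n); y <- 0.5 * x + rnorm(n); z <- rnorm(n)
  expect_equal(partial_corr(x, y, z), cor(x, y), tolerance = 0.05)
})

test_that("leave-one-out regression recovers planted models", {
  set.seed(17)
  n <- 40
  met <- tibble::tibble(image_id = 1:n, good = rnorm(n), n1 = rnorm(n),
                        n2 = rnorm(n))
  # one predictor equals the shared settings exactly
  M <- sapply(1:5, function(o) met$good + rnorm(n, 0, 0.05))
  fit <- loo_regression(met, toy_settings(M, truth = rnorm(n)))
  expect_gt(fit$mean_r_holdout, 0.95)
  co <- tidy(fit)
  expect_equal(co$predictor[which.max(abs(co$weight))], "good")
  # identical observers + perfect linear model: held-out r = 1 per fold and
  # the fit reduces to the in-sample regression
  y <- 2 * met$good - met$n1
  Mi <- sapply(1:4, function(o) y)
  fit2 <- loo_regression(met, toy_settings(Mi, truth = rnorm(n)))
  expect_equal(fit2$folds$r_holdout, rep(1, 4), tolerance = 1e-9)
  zy <- (y - mean(y)) / sd(y)
  b_in <- qr.coef(qr(scale(as.matrix(met[, -1]))), zy)
  expect_equal(tidy(fit2)$weight, unname(b_in), tolerance = 1e-9)
  # pure-noise predictors: small held-out correlation (20-seed median)
  meds <- vapply(1:20, function(s) {
    set.seed(100 + s)
    metn <- tibble::tibble(image_id = 1:n, a = rnorm(n), b = rnorm(n),
                           c = rnorm(n))
    Mn <- sapply(1:4, function(o) rnorm(n))
    abs(loo_regression(metn, toy_settings(Mn, truth = rnorm(n)))$mean_r_holdout)
  }, numeric(1))
  expect_lt(median(meds), 0.3)
})

test_that("per-environment slopes recover planted attenuation", {
  set.seed(19)
  env_of <- tibble::tibble(image_id = 1:36, environment = rep(1:3, each = 12))
  truth <- runif(36, 0, 0.2)
  # settings identical to truth: slope 1, r 1
  M <- sapply(1:4, function(o) truth)
  st <- toy_settings(M, truth)
  st$environment <- rep(rep(1:3, each = 12), 4)
  res <- per_env_slope(st)
  expect_equal(res$slope, rep(1, 3), tolerance = 1e-9)
  expect_equal(res$r, rep(1, 3), tolerance = 1e-9)
  # planted slope 0.5 with small noise
  M2 <- sapply(1:6, function(o) 0.5 * truth + rnorm(36, 0, 0.004))
  res2 <- per_env_slope(toy_settings(M2, truth), env_of = env_of)
  expect_equal(res2$slope, rep(0.5, 3), tolerance = 0.05)
  # independent settings: r near zero on average
  rs <- vapply(1:20, function(s) {
    set.seed(s)
    M3 <- sapply(1:4, function(o) rnorm(36, 0, 0.05))
    mean(per_env_slope(toy_settings(M3, truth), env_of = env_of)$r)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.2)
})
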