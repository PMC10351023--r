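test_that("a uniform field gives the analytic Lambertian irradiance", {
  Lu <- 3
  e <- env_map(array(Lu, c(32, 64, 3)))
  rc <- render_components(bumpy_sphere(0.1, 6, seed = 2), e, resolution = 64)
  # integral of cos over the hemisphere is pi, so diffuse_unit = Lu exactly
  for (ch in 1:3) {
    expect_equal(range(rc$diffuse_unit[, , ch][rc$mask]), c(Lu, Lu),
                 tolerance = 1e-6)
    expect_equal(range(rc$specular_unit[, , ch][rc$mask]), c(Lu, Lu),
                 tolerance = 1e-6)
  }
  expect_true(all(rc$diffuse_unit[!rc$mask] == 0))
})

test_that("a black environment renders to zero components", {
  e <- env_map(array(0, c(16, 32, 3)))
  rc <- render_components(bumpy_sphere(seed = 1), e, resolution = 32)
  expect_equal(max(abs(rc$diffuse_unit)), 0)
  expect_equal(max(abs(rc$specular_unit)), 0)
})

test_that("compositing is linear in specularity and albedo", {
  e <- synth_envmap(32, seed = 8)
  rc <- render_components(bumpy_sphere(seed = 3), e, resolution = 48)
  d <- composite(rc, 0.4, 0)
  expect_equal(d, 0.4 * rc$diffuse_unit, tolerance = 1e-12)
  i1 <- composite(rc, 0.4, 0.03)
  i2 <- composite(rc, 0.4, 0.05)
  i3 <- composite(rc, 0.4, 0.08)
  expect_equal(i1 + i2 - d, i3, tolerance = 1e-9)
  # doubling albedo doubles the diffuse term only
  j <- composite(rc, 0.8, 0.05)
  expect_equal(j - i2, 0.4 * rc$diffuse_unit, tolerance = 1e-9)
  expect_true(all(composite(rc, c(0.2, 0.5, 0.3), 0.0999) >= 0))
  expect_error(composite(rc, 0.4, 0.2), "0.0999")
})

test_that("viewpoint selection finds the bright cap and respects ties", {
  e <- cap_envmap(90)
  expect_equal(select_viewpoint(e), 90)
  expect_equal(select_viewpoint(cap_envmap(210)), 210)
  # uniform map: all candidates tie, smallest azimuth wins
  expect_equal(select_viewpoint(env_map(array(1, c(32, 64, 3)))), 0)
  # rotating the environment by 30 degrees shifts the winner by 30
  expect_equal(select_viewpoint(rotate_env_azimuth(e, 30)), 120)
})

test_that("rendering is equivariant to joint env/camera rotation", {
  e <- synth_envmap(64, seed = 10)
  shp <- bumpy_sphere(0.15, 6, seed = 4)
  rc0 <- render_components(shp, e, azimuth = 0, resolution = 128)
  rc1 <- render_components(shp, rotate_env_azimuth(e, 90), azimuth = 90,
                           resolution = 128)
  rel <- function(a, b) sqrt(sum((a - b)^2) / max(sum(a^2), 1e-300))
  # shapes' bump field is attached to object space, so rotating camera and
  # environment together only changes the bump pattern seen; compare the
  # smooth-sphere case for strict equivariance
  shp0 <- bumpy_sphere(0, seed = 1)
  sc0 <- render_components(shp0, e, azimuth = 0, resolution = 128)
  sc1 <- render_components(shp0, rotate_env_azimuth(e, 90), azimuth = 90,
                           resolution = 128)
  expect_lt(rel(sc0$diffuse_unit, sc1$diffuse_unit), 0.02)
  expect_lt(rel(sc0$specular_unit, sc1$specular_unit), 0.02)
})

test_that("set normalization uses one pooled percentile factor", {
  one <- list(array(5, c(4, 4, 3)))
  ns <- normalize_set(one)
  expect_equal(ns$factor, 5)
  expect_equal(unique(as.numeric(ns$images[[1]])), 1)
  ramp <- list(matrix(seq(0, 1, length.out = 101), 1))
  expect_equal(normalize_set(ramp)$factor, 0.99)
  # ratios unchanged
  ims <- list(array(runif(48), c(4, 4, 3)), array(runif(48), c(4, 4, 3)))
  ns2 <- normalize_set(ims)
  expect_equal(ims[[1]] / ims[[2]], ns2$images[[1]] / ns2$images[[2]],
               tolerance = 1e-12)
  expect_error(normalize_set(list(array(0, c(2, 2, 3)))), "all-black")
})

test_that("stimulus sets have the factorial layout and shared scale", {
  sc <- fixture_scene_set(n_envs = 2, n_shapes = 3, H = 32, res = 48)
  expect_equal(nrow(sc), 6)
  expect_equal(sort(unique(sc$shape_id)), 1:3)
  expect_true(all(sc$ward_ps <= 0.0999 + 1e-9))
  expect_equal(pellacini_c(sc$ward_ps, 33.9), sc$pellacini_c, tolerance = 1e-9)
  # one shared normalization: pooled composite p99 equals 1
  comps <- lapply(seq_len(nrow(sc)), function(i) scene_composite(sc, i))
  expect_equal(as.numeric(quantile(unlist(comps), 0.99)), 1, tolerance = 1e-9)
})
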