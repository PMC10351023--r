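#' Procedural bumpy-sphere shape
#'
#' A unit sphere whose normals are perturbed by a sum of random sinusoidal
#' waves over the surface, emulating the spatial-frequency content of a
#' bumpy reference object (bumpiness raises the spatial contrast of the
#' specular reflection between concave and convex regions).
#'
#' @param bump_amplitude Normal-perturbation strength as a fraction of the
#'   radius (0 gives a smooth sphere).
#' @param bump_frequency Approximate cycles around the equator.
#' @param n_waves Number of random waves summed.
#' @param seed Integer seed.
#' @return An object of class `shape_model`.
#' @export
bumpy_sphere <- function(bump_amplitude = 0.15, bump_frequency = 6,
                         n_waves = 8, seed = 1) {
  stopifnot(bump_amplitude >= 0, bump_frequency > 0)
  set.seed(seed)
  u <- matrix(rnorm(3 * n_waves), n_waves, 3)
  u <- u / sqrt(rowSums(u^2))
  structure(list(
    bump_amplitude = bump_amplitude,
    bump_frequency = bump_frequency,
    wave_dir = u,
    wave_phase = runif(n_waves, 0, 2 * pi),
    wave_amp = runif(n_waves, 0.5, 1) / n_waves,
    seed = seed), class = "shape_model")
}

# Perturbed unit normals at unit sphere points P (n x 3).
shape_normals <- function(shape, P) {
  if (shape$bump_amplitude == 0) return(P)
  grad <- matrix(0, nrow(P), 3)
  f <- shape$bump_frequency
  for (k in seq_len(nrow(shape$wave_dir))) {
    uk <- shape$wave_dir[k, ]
    ph <- f * (P %*% uk) + shape$wave_phase[k]
    grad <- grad + shape$wave_amp[k] * f * as.numeric(cos(ph)) *
      matrix(uk, nrow(P), 3, byrow = TRUE)
  }
  # tangential component only, then renormalize
  grad <- grad - as.numeric(rowSums(grad * P)) * P
  n <- P + shape$bump_amplitude * grad
  n / sqrt(rowSums(n^2))
}

# Bilinear lookup of env radiance along directions D (n x 3 unit vectors).
# Returns n x 3 RGB.
env_lookup <- function(env, D) {
  H <- env$height; W <- env$width
  theta <- acos(pmin(pmax(D[, 3], -1), 1))
  phi <- atan2(D[, 2], D[, 1]) %% (2 * pi)
  r <- theta / pi * H + 0.5        # fractional row at pixel centers
  c0 <- phi / (2 * pi) * W + 0.5
  i1 <- pmin(pmax(floor(r), 1), H); i2 <- pmin(i1 + 1, H)
  fr <- pmin(pmax(r - floor(r), 0), 1); fr[r < 1 | r > H] <- 0
  jf <- floor(c0); fc <- c0 - jf
  j1 <- ((jf - 1) %% W) + 1; j2 <- (jf %% W) + 1
  out <- matrix(0, nrow(D), 3)
  for (ch in 1:3) {
    m <- env$pixels[, , ch]
    v11 <- m[cbind(i1, j1)]; v12 <- m[cbind(i1, j2)]
    v21 <- m[cbind(i2, j1)]; v22 <- m[cbind(i2, j2)]
    out[, ch] <- (1 - fr) * ((1 - fc) * v11 + fc * v12) +
      fr * ((1 - fc) * v21 + fc * v22)
  }
  out
}

# Approximate spherical Gaussian blur of an env map with angular width
# `alpha` radians: separable latitude blur (fixed sigma) and per-row
# circular longitude blur (sigma / sin(theta), capped).
blur_env_angular <- function(env, alpha) {
  if (alpha <= 0) return(env)
  H <- env$height; W <- env$width
  g <- env_geometry(H)
  gauss_kernel <- function(sigma) {
    if (sigma < 0.3) return(1)
    k <- ceiling(3 * sigma)
    w <- exp(-0.5 * ((-k:k) / sigma)^2)
    w / sum(w)
  }
  conv_circular <- function(v, kern) {
    if (length(kern) == 1) return(v)
    k <- (length(kern) - 1) / 2
    vv <- c(tail(v, k), v, head(v, k))
    as.numeric(stats::filter(vv, kern, sides = 2))[(k + 1):(k + length(v))]
  }
  conv_clamp <- function(v, kern) {
    if (length(kern) == 1) return(v)
    k <- (length(kern) - 1) / 2
    vv <- c(rep(v[1], k), v, rep(v[length(v)], k))
    as.numeric(stats::filter(vv, kern, sides = 2))[(k + 1):(k + length(v))]
  }
  p <- env$pixels
  kern_th <- gauss_kernel(alpha * H / pi)
  for (ch in 1:3) {
    m <- p[, , ch]
    m <- apply(m, 2, conv_clamp, kern = kern_th)
    sig_phi <- pmin(alpha / pmax(sin(g$theta), 1e-3) / (2 * pi / W), W / 6)
    for (r in seq_len(H)) m[r, ] <- conv_circular(m[r, ], gauss_kernel(sig_phi[r]))
    p[, , ch] <- m
  }
  env_map(pmax(p, 0))
}

# Real orthonormal SH basis (l <= 2) at directions D (n x 3): n x 9 matrix,
# column order (l,m) = (0,0),(1,-1),(1,0),(1,1),(2,-2),(2,-1),(2,0),(2,1),(2,2).
sh_basis_l2 <- function(D) {
  x <- D[, 1]; y <- D[, 2]; z <- D[, 3]
  cbind(0.2820948,
        0.4886025 * y, 0.4886025 * z, 0.4886025 * x,
        1.0925484 * x * y, 1.0925484 * y * z,
        0.3153916 * (3 * z^2 - 1),
        1.0925484 * x * z, 0.5462742 * (x^2 - y^2))
}

#' Render the diffuse and specular components of a scene
#'
#' Orthographic rendering of a (bumpy) sphere under an environment map,
#' producing the two linear components from which any colored glossy object
#' in that scene is a weighted sum: `diffuse_unit`, the Lambertian image for
#' unit albedo (per-pixel irradiance / pi from an order-2 spherical-harmonic
#' expansion of the environment), and `specular_unit`, the environment
#' looked up along the per-pixel mirror direction after an angular Gaussian
#' blur of width `roughness` radians (the narrow-lobe Ward approximation).
#' Both are in the environment's linear radiance scale.
#'
#' @param shape A `shape_model`.
#' @param env An `env_map`.
#' @param azimuth Camera azimuth in degrees (camera on the horizon, looking
#'   at the object center).
#' @param roughness Ward roughness alpha (angular blur width, default 0.05).
#' @param resolution Output image side in pixels (>= 64 recommended).
#' @return An object of class `rendered_components`: list with
#'   `diffuse_unit`, `specular_unit` (res x res x 3 arrays), `mask`
#'   (logical matrix), `azimuth`, `roughness`, `scale` (1 until
#'   [normalize_set()]).
#' @export
render_components <- function(shape, env, azimuth = 0, roughness = 0.05,
                              resolution = 128) {
  stopifnot(inherits(shape, "shape_model"), inherits(env, "env_map"),
            resolution >= 16)
  res <- resolution
  a <- azimuth * pi / 180
  view <- c(cos(a), sin(a), 0)          # direction from object to camera
  right <- c(-sin(a), cos(a), 0)
  up <- c(0, 0, 1)
  s <- seq(-1 + 1 / res, 1 - 1 / res, length.out = res)
  uu <- matrix(s, res, res, byrow = TRUE)       # screen x
  vv <- matrix(rev(s), res, res)                # screen y (row 1 = top)
  mask <- uu^2 + vv^2 <= 1
  idx <- which(mask)
  w <- sqrt(pmax(0, 1 - uu[idx]^2 - vv[idx]^2))
  P <- uu[idx] %o% right + vv[idx] %o% up + w %o% view
  N <- shape_normals(shape, P)

  # diffuse: order-2 SH irradiance per channel
  Ylm <- sh_basis_l2(N)
  Ahat <- c(pi, rep(2 * pi / 3, 3), rep(pi / 4, 5))
  diffuse <- array(0, c(res, res, 3))
  for (ch in 1:3) {
    co <- sh_project(env$pixels[, , ch], 2)
    cvec <- c(co[[1]], co[[2]], co[[3]])
    e <- Ylm %*% (Ahat * cvec) / pi
    d <- matrix(0, res, res); d[idx] <- pmax(e, 0)
    diffuse[, , ch] <- d
  }

  # specular: mirror-direction lookup in the pre-blurred environment
  benv <- blur_env_angular(env, roughness)
  ndotv <- as.numeric(N %*% view)
  R <- 2 * ndotv * N - matrix(view, length(idx), 3, byrow = TRUE)
  R <- R / sqrt(rowSums(R^2))
  spec_rgb <- env_lookup(benv, R)
  specular <- array(0, c(res, res, 3))
  for (ch in 1:3) {
    sm <- matrix(0, res, res); sm[idx] <- spec_rgb[, ch]
    specular[, , ch] <- sm
  }

  structure(list(diffuse_unit = diffuse, specular_unit = specular,
                 mask = mask, azimuth = azimuth %% 360,
                 roughness = roughness, scale = 1),
            class = "rendered_components")
}

#' @export
print.rendered_components <- function(x, ...) {
  cat(sprintf("<rendered_components> %d px, azimuth %g deg, alpha %g, scale %g\n",
              nrow(x$mask), x$azimuth, x$roughness, x$scale))
  invisible(x)
}

#' Composite a colored glossy object image
#'
#' Linear sum of the body and mirror components:
#' `image = albedo * diffuse_unit + ward_ps * specular_unit`. The result is
#' linear HDR radiance; nothing is clipped.
#'
#' @param components A `rendered_components`.
#' @param albedo Scalar or length-3 linear-RGB diffuse albedo (see
#'   [material_albedo()]).
#' @param ward_ps Ward specularity in `[0, 0.0999]`.
#' @return res x res x 3 linear image.
#' @export
composite <- function(components, albedo, ward_ps) {
  stopifnot(inherits(components, "rendered_components"))
  if (ward_ps < 0 || ward_ps > 0.0999 + 1e-12) {
    stop("`ward_ps` must lie in [0, 0.0999]", call. = FALSE)
  }
  if (length(albedo) == 1) albedo <- rep(albedo, 3)
  stopifnot(length(albedo) == 3, all(albedo >= 0))
  out <- components$diffuse_unit
  for (ch in 1:3) {
    out[, , ch] <- albedo[ch] * components$diffuse_unit[, , ch] +
      ward_ps * components$specular_unit[, , ch]
  }
  out
}

#' Linear-RGB albedo of a body color
#'
#' Converts a hue / lightness / chroma body color (Lab under the
#' equal-energy-white anchor) to the display-linear RGB albedo used by
#' [composite()]. Out-of-primaries components are clamped at zero.
#'
#' @param hue,lightness,chroma Body color.
#' @return Length-3 linear RGB in `[0, 1]` scale (Y of white = 1).
#' @export
material_albedo <- function(hue, lightness, chroma) {
  xyz <- lab_to_xyz(lch_to_lab(hue, lightness, chroma)) / 100
  pmax(as.numeric(XYZ2RGB %*% xyz), 0)
}

# Foreshortening-weighted mean luminance over an orthographic mirror-sphere
# render. The unweighted image mean is exactly viewpoint-invariant (the
# orthographic mirror ball is area-uniform over solid angle), so the mean is
# taken with the surface foreshortening cos(psi) as weight; this biases the
# measure toward light reflected near the sphere center — light arriving
# from the camera side — so the selected viewpoint is one under which the
# object is brightly and visibly lit.
mirror_probe_mean_lum <- function(env, azimuth, resolution = 64) {
  a <- azimuth * pi / 180
  vdir <- c(cos(a), sin(a), 0)
  right <- c(-sin(a), cos(a), 0)
  up <- c(0, 0, 1)
  s <- seq(-1 + 1 / resolution, 1 - 1 / resolution, length.out = resolution)
  uu <- matrix(s, resolution, resolution, byrow = TRUE)
  vv <- matrix(rev(s), resolution, resolution)
  idx <- which(uu^2 + vv^2 <= 1)
  w <- sqrt(pmax(0, 1 - uu[idx]^2 - vv[idx]^2))   # cos(psi) = n . v
  P <- uu[idx] %o% right + vv[idx] %o% up + w %o% vdir
  ndotv <- as.numeric(P %*% vdir)
  R <- 2 * ndotv * P - matrix(vdir, length(idx), 3, byrow = TRUE)
  rgb <- env_lookup(env, R / sqrt(rowSums(R^2)))
  sum(as.numeric(rgb %*% RGB2XYZ[2, ]) * w) / sum(w)
}

#' Select the camera azimuth by mirrored-sphere luminance
#'
#' Renders a mirrored sphere (smooth, pure specular, camera at three radii)
#' from candidate viewpoints and returns the azimuth with the highest mean
#' luminance over the sphere; ties break toward the smallest azimuth.
#'
#' @param env An `env_map`.
#' @param azimuths Candidate azimuths in degrees (default 0 to 330 in steps
#'   of 30).
#' @param resolution Probe-render resolution.
#' @return Azimuth in degrees.
#' @export
select_viewpoint <- function(env, azimuths = seq(0, 330, by = 30),
                             resolution = 64) {
  mean_lum <- vapply(azimuths, function(a) {
    mirror_probe_mean_lum(env, a, resolution)
  }, numeric(1))
  azimuths[which.max(mean_lum)]  # which.max takes the first (smallest) tie
}

#' Normalize a reference image collection by a shared percentile
#'
#' Computes a single scale factor — the pooled 99th-percentile pixel value
#' across all images — and divides every image by it, equating the light
#' level across the set while preserving all relative pixel ratios.
#'
#' @param images List of numeric arrays (linear images).
#' @param probs Percentile (default 0.99).
#' @return List with `images` (scaled) and `factor`.
#' @export
normalize_set <- function(images, probs = 0.99) {
  stopifnot(length(images) >= 1)
  pooled <- unlist(lapply(images, as.numeric), use.names = FALSE)
  if (all(pooled == 0)) stop("all-black image set cannot be normalized", call. = FALSE)
  f <- as.numeric(quantile(pooled, probs))
  list(images = lapply(images, function(im) im / f), factor = f)
}
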