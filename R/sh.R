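# Fully normalized associated Legendre functions P~_lm(x) for x = cos(theta),
# including sqrt((2l+1)/(4pi) (l-m)!/(l+m)!), no Condon-Shortley phase.
# Returns a list over m = 0..lmax of length(x) x (lmax - m + 1) matrices
# (columns l = m..lmax). Standard stable recurrences.
legendre_norm <- function(x, lmax) {
  st <- sqrt(pmax(0, 1 - x^2))
  out <- vector("list", lmax + 1)
  pmm <- rep(sqrt(1 / (4 * pi)), length(x))
  for (m in 0:lmax) {
    if (m > 0) pmm <- sqrt((2 * m + 1) / (2 * m)) * st * pmm
    P <- matrix(0, length(x), lmax - m + 1)
    P[, 1] <- pmm
    if (lmax > m) P[, 2] <- sqrt(2 * m + 3) * x * pmm
    if (lmax > m + 1) {
      for (l in (m + 2):lmax) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        P[, l - m + 1] <- a * (x * P[, l - m] - b * P[, l - m - 1])
      }
    }
    out[[m + 1]] <- P
  }
  out
}

# Empty coefficient container: list over l of numeric(2l+1), m = -l..l
# (negative m = sine terms, positive m = cosine terms, orthonormal real SH).
sh_zero_coef <- function(lmax) {
  structure(lapply(0:lmax, function(l) numeric(2 * l + 1)),
            class = "sh_coef", lmax = lmax)
}

#' @export
print.sh_coef <- function(x, ...) {
  cat(sprintf("<sh_coef> real spherical-harmonic coefficients, lmax = %d\n",
              attr(x, "lmax")))
  invisible(x)
}

#' Project an equirectangular field onto real spherical harmonics
#'
#' Analysis of a scalar field sampled on the package equirectangular grid
#' (see [env_geometry()]) in the real orthonormal spherical-harmonic basis.
#' Longitude is handled by exact discrete Fourier orthogonality; latitude by
#' sine-weighted least squares per azimuthal order, so the
#' projection/reconstruction round trip is exact (to machine precision) for
#' fields band-limited at `lmax`.
#'
#' @param field `H x 2H` numeric matrix (e.g. [env_luminance()] output).
#' @param lmax Band limit; must satisfy `lmax <= H - 1` (grid Nyquist).
#' @return An `sh_coef` object: list over degrees `l = 0..lmax` of
#'   coefficient vectors indexed `m = -l..l`.
#' @export
sh_project <- function(field, lmax) {
  stopifnot(is.matrix(field))
  H <- nrow(field); W <- ncol(field)
  if (W != 2 * H) stop("field must be H x 2H equirectangular", call. = FALSE)
  if (lmax < 0 || lmax > H - 1) {
    stop("`lmax` must lie in [0, H - 1] (grid Nyquist limit)", call. = FALSE)
  }
  g <- env_geometry(H)
  x <- cos(g$theta)
  P <- legendre_norm(x, lmax)
  dphi <- 2 * pi / W
  sw <- sqrt(sin(g$theta))
  coef <- sh_zero_coef(lmax)
  for (m in 0:lmax) {
    B <- P[[m + 1]]                               # H x (lmax - m + 1)
    Bw <- sw * B
    if (m == 0) {
      u <- (field %*% rep(dphi, W))[, 1] / (2 * pi)
      cvec <- qr.solve(Bw, sw * u)
      for (l in 0:lmax) coef[[l + 1]][l + 1] <- cvec[l + 1]
    } else {
      cm <- field %*% (cos(m * g$phi) * dphi)
      sm <- field %*% (sin(m * g$phi) * dphi)
      uc <- cm[, 1] / (pi * sqrt(2))
      us <- sm[, 1] / (pi * sqrt(2))
      cc <- qr.solve(Bw, sw * uc)
      cs <- qr.solve(Bw, sw * us)
      for (l in m:lmax) {
        coef[[l + 1]][l + 1 + m] <- cc[l - m + 1]
        coef[[l + 1]][l + 1 - m] <- cs[l - m + 1]
      }
    }
  }
  coef
}

#' Reconstruct an equirectangular field from SH coefficients
#'
#' @param coef An `sh_coef` object.
#' @param H Output grid height (width `2H`); must resolve the band limit.
#' @return `H x 2H` numeric matrix.
#' @export
sh_reconstruct <- function(coef, H) {
  stopifnot(inherits(coef, "sh_coef"))
  lmax <- attr(coef, "lmax")
  if (H - 1 < lmax) stop("grid too coarse for the band limit", call. = FALSE)
  g <- env_geometry(H)
  P <- legendre_norm(cos(g$theta), lmax)
  W <- 2L * H
  field <- matrix(0, H, W)
  for (m in 0:lmax) {
    cc <- vapply((max(m, 0)):lmax, function(l) coef[[l + 1]][l + 1 + m],
                 numeric(1))
    uc <- P[[m + 1]] %*% cc                      # H x 1
    if (m == 0) {
      field <- field + uc %*% t(rep(1, W))
    } else {
      cs <- vapply(m:lmax, function(l) coef[[l + 1]][l + 1 - m], numeric(1))
      us <- P[[m + 1]] %*% cs
      field <- field + sqrt(2) * (uc %*% t(cos(m * g$phi)) +
                                  us %*% t(sin(m * g$phi)))
    }
  }
  field
}

#' Per-degree SH power and its log-log slope
#'
#' Power per degree is reported as the mean squared coefficient within the
#' degree, `sum_m c_lm^2 / (2l + 1)`, so that a spatially uncorrelated
#' (white) field on the sphere has a flat spectrum. The slope is the
#' least-squares slope of `log10(power)` against `log10(l)` over degrees
#' `l >= 1` (degrees with zero power are dropped); a slope near -2 is
#' typical of natural outdoor lighting environments. `total` carries the
#' unnormalized per-degree sum.
#'
#' @param coef An `sh_coef` object.
#' @return List with `power` (tibble `l, power, total`) and `slope`.
#' @export
sh_power_slope <- function(coef) {
  stopifnot(inherits(coef, "sh_coef"))
  lmax <- attr(coef, "lmax")
  tot <- vapply(0:lmax, function(l) sum(coef[[l + 1]]^2), numeric(1))
  pw <- tot / (2 * (0:lmax) + 1)
  tab <- tibble::tibble(l = 0:lmax, power = pw, total = tot)
  use <- tab$l >= 1 & tab$power > 0
  slope <- if (sum(use) >= 2) {
    unname(coef(lm(log10(power) ~ log10(l), data = tab[use, ]))[2])
  } else NA_real_
  list(power = tab, slope = slope)
}

#' Random SH coefficients with an exact planted power spectrum
#'
#' Draws isotropic Gaussian coefficients per degree and rescales each degree
#' so that its per-mode power (`sum_m c_lm^2 / (2l + 1)`, the quantity
#' [sh_power_slope()] reports) equals `power_fun(l)` exactly.
#'
#' @param lmax Band limit.
#' @param power_fun Function of degree `l` returning the target per-mode
#'   power.
#' @param seed Integer seed.
#' @return An `sh_coef` object.
#' @export
sh_random_coef <- function(lmax, power_fun, seed = 1) {
  set.seed(seed)
  coef <- sh_zero_coef(lmax)
  for (l in 0:lmax) {
    p <- power_fun(l)
    if (p > 0) {
      v <- rnorm(2 * l + 1)
      coef[[l + 1]] <- v * sqrt(p * (2 * l + 1) / sum(v^2))
    }
  }
  coef
}

# Random proper rotation of the degree-l coefficient subspace (dimension
# 2l+1): orthogonal matrix from QR of a Gaussian matrix, determinant fixed
# to +1. Any orthogonal mixing within a degree preserves that degree's power.
sh_random_rotation <- function(l) {
  n <- 2 * l + 1
  qrd <- qr(matrix(rnorm(n * n), n, n))
  Q <- qr.Q(qrd)
  d <- sign(diag(qr.R(qrd)))
  Q <- Q %*% diag(d, n)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Apply per-degree rotations to coefficients (l = 0 untouched).
sh_apply_rotations <- function(coef, rotations) {
  lmax <- attr(coef, "lmax")
  for (l in seq_len(lmax)) {
    coef[[l + 1]] <- as.numeric(rotations[[l]] %*% coef[[l + 1]])
  }
  coef
}
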