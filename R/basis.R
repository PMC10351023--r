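#' Generate Munsell-like matte reflectance chips
#'
#' Synthetic stand-in for a measured matte chip set: smooth, non-negative
#' reflectance spectra spanning lightness and hue, built as a flat base plus
#' one or two broad Gaussian bands in wavelength (plausible for pigmented
#' matte papers). Values are kept within `[0.02, 0.88]` so that solved
#' diffuse reflectances can stay below the 0.90 physical ceiling once a
#' specular component is added.
#'
#' @param n Number of chips (default 1269, the size of the measured matte
#'   chip set the design emulates).
#' @param seed Integer seed; the chip set is deterministic given the seed.
#' @return A 31 x `n` matrix, one chip per column, on the package wavelength
#'   grid.
#' @export
synth_munsell_chips <- function(n = 1269, seed = 1) {
  stopifnot(n >= 1)
  wl <- spectral_wavelengths()
  set.seed(seed)
  chips <- matrix(0, nrow = length(wl), ncol = n)
  for (i in seq_len(n)) {
    base <- runif(1, 0.03, 0.65)
    k <- sample(0:2, 1, prob = c(0.15, 0.5, 0.35))
    r <- rep(base, length(wl))
    if (k > 0) {
      center <- runif(k, 400, 720)
      width <- runif(k, 40, 140)
      amp <- runif(k, -0.9, 1.2) * base
      for (j in seq_len(k)) {
        r <- r + amp[j] * exp(-0.5 * ((wl - center[j]) / width[j])^2)
      }
    }
    # gentle spectral tilt, as real pigments rise toward long wavelengths
    r <- r + runif(1, -0.1, 0.25) * (wl - 560) / 320
    chips[, i] <- pmin(pmax(r, 0.02), 0.88)
  }
  chips
}

#' Load a chip-spectra table
#'
#' Reads a plain-text/CSV table whose first column is wavelength in nm and
#' whose remaining columns are reflectance chips, and resamples each chip to
#' the package 31-sample grid by linear interpolation.
#'
#' @param path CSV file path.
#' @return A 31 x n_chips matrix.
#' @export
read_chips <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  if (ncol(tab) < 2) stop("chip table needs a wavelength column plus >= 1 chip", call. = FALSE)
  wl_in <- tab[[1]]
  out <- vapply(tab[-1], function(col) {
    stats::approx(wl_in, col, xout = spectral_wavelengths(), rule = 2)$y
  }, numeric(length(spectral_wavelengths())))
  if (any(out < 0)) stop("chip reflectances must be non-negative", call. = FALSE)
  out
}

# Frobenius NMF by multiplicative updates (Lee-Seung). V ~ W %*% H with
# W, H >= 0. Used for reflectance-basis extraction; restarts keep the
# lowest-error factorization so the result is deterministic given the seed.
nmf_mu <- function(V, k, n_iter = 400, n_restart = 10, seed = 1, eps = 1e-12) {
  stopifnot(all(V >= 0), k >= 1, ncol(V) >= k)
  set.seed(seed)
  best <- NULL
  best_err <- Inf
  for (r in seq_len(n_restart)) {
    W <- matrix(runif(nrow(V) * k, 0.1, 1), nrow(V), k)
    H <- matrix(runif(k * ncol(V), 0.1, 1), k, ncol(V))
    for (it in seq_len(n_iter)) {
      H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    }
    err <- sqrt(mean((V - W %*% H)^2))
    if (err < best_err) {
      best_err <- err
      best <- list(W = W, H = H, rmse = err)
    }
  }
  # fix component scale (unit max per basis) and order (by spectral centroid)
  s <- apply(best$W, 2, max)
  W <- sweep(best$W, 2, s, "/")
  H <- sweep(best$H, 1, s, "*")
  centroid <- colSums(W * spectral_wavelengths()) / colSums(W)
  o <- order(centroid)
  list(W = W[, o, drop = FALSE], H = H[o, , drop = FALSE], rmse = best_err)
}

#' Extract a non-negative reflectance basis from a chip set
#'
#' Applies non-negative matrix factorization (multiplicative updates,
#' Frobenius loss, multiple random restarts keeping the lowest error) to a
#' matte chip set to obtain `n_components` non-negative basis reflectance
#' functions. Weighted sums of these bases are the diffuse reflectances the
#' stimulus grid is built from.
#'
#' @param chips 31 x n matrix of non-negative chip reflectances (columns).
#' @param n_components Number of basis functions (default 6).
#' @param seed Integer seed; the factorization is deterministic given it.
#' @param n_iter Multiplicative-update iterations per restart.
#' @param n_restart Random restarts.
#' @return An object of class `basis_set`: list with `components`
#'   (31 x n_components non-negative matrix), `rmse` (reconstruction RMSE
#'   over the chip set), `n_chips`, `seed`.
#' @export
fit_basis <- function(chips, n_components = 6, seed = 1,
                      n_iter = 400, n_restart = 10) {
  if (!is.matrix(chips) || nrow(chips) != length(spectral_wavelengths())) {
    stop("`chips` must be a 31 x n matrix on the package wavelength grid", call. = FALSE)
  }
  if (any(chips < 0)) stop("chip reflectances must be non-negative", call. = FALSE)
  if (ncol(chips) < n_components) {
    stop("need at least as many chips as basis components", call. = FALSE)
  }
  fit <- nmf_mu(chips, n_components, n_iter = n_iter, n_restart = n_restart,
                seed = seed)
  structure(list(components = fit$W, rmse = fit$rmse,
                 n_chips = ncol(chips), seed = seed),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> %d non-negative spectral components from %d chips (reconstruction RMSE %.2e)\n",
              ncol(x$components), x$n_chips, x$rmse))
  invisible(x)
}
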