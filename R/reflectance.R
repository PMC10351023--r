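# Moore-Penrose pseudoinverse via SVD (small matrices only).
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Orthonormal null-space basis of the rows of M.
null_basis <- function(M, tol = 1e-10) {
  s <- svd(M, nu = 0, nv = ncol(M))
  rank <- sum(s$d > tol * max(s$d))
  s$v[, seq(rank + 1, ncol(M)), drop = FALSE]
}

R_MAX <- 0.90  # physical ceiling for synthesized diffuse reflectance

# Batch solver core. targets_lab: E x 3 matrix. Returns list with weights
# (n_basis x E), curves (31 x E), delta_e, max_violation.
solve_reflectance_core <- function(basis, targets_lab,
                                   n_pg_iter = 600, polish = TRUE) {
  B <- basis$components                      # 31 x k
  Txyz <- xyz_operator()                     # 3 x 31
  M <- Txyz %*% B                            # 3 x k
  Mp <- pinv(M)                              # k x 3
  N <- null_basis(M)                         # k x (k - 3)
  A <- B %*% N                               # 31 x (k - 3)

  xyz <- lab_to_xyz(targets_lab)             # E x 3
  W0 <- Mp %*% t(xyz)                        # k x E
  R0 <- B %*% W0                             # 31 x E
  E <- ncol(W0)

  # Stage 2: restore curve feasibility within the tristimulus-preserving
  # null space by projected gradient on the squared bound violations,
  # iterating only on the columns that still violate the bounds.
  Z <- matrix(0, ncol(N), E)
  step <- 1 / (2 * max(svd(A, nu = 0, nv = 0)$d)^2)
  R <- R0
  viol_of <- function(Rsub) (Rsub - R_MAX) * (Rsub > R_MAX) + Rsub * (Rsub < 0)
  active <- which(apply(abs(viol_of(R)), 2, max) > 1e-10)
  if (length(active)) {
    Za <- Z[, active, drop = FALSE]
    R0a <- R0[, active, drop = FALSE]
    Ra <- R[, active, drop = FALSE]
    for (it in seq_len(n_pg_iter)) {
      D <- viol_of(Ra)
      conv <- apply(abs(D), 2, max) < 1e-10
      if (any(conv)) {
        Z[, active[conv]] <- Za[, conv]
        R[, active[conv]] <- Ra[, conv]
        active <- active[!conv]
        if (!length(active)) break
        Za <- Za[, !conv, drop = FALSE]
        R0a <- R0a[, !conv, drop = FALSE]
        Ra <- Ra[, !conv, drop = FALSE]
        D <- D[, !conv, drop = FALSE]
      }
      Za <- Za - step * 2 * crossprod(A, D)
      Ra <- R0a + A %*% Za
    }
    if (length(active)) {
      Z[, active] <- Za
      R[, active] <- Ra
    }
  }
  W <- W0 + N %*% Z

  viol <- pmax(R - R_MAX, 0) - pmin(R, 0)
  max_viol <- apply(viol, 2, max)
  de <- numeric(E)  # tristimulus preserved exactly so far

  if (polish && any(max_viol > 1e-9)) {
    # Stage 3: entries that cannot satisfy the bounds at exact tristimulus
    # match trade color error against feasibility (penalised BFGS).
    tl <- targets_lab
    for (i in which(max_viol > 1e-9)) {
      obj <- function(w, mu) {
        r <- B %*% w
        lab <- xyz_to_lab(as.numeric(M %*% w))[1:3]
        sum((lab - tl[i, ])^2) +
          mu * sum(pmax(r - R_MAX, 0)^2 + pmin(r, 0)^2)
      }
      w <- W[, i]
      for (mu in c(1e4, 1e6, 1e8)) {
        w <- optim(w, obj, mu = mu, method = "BFGS",
                   control = list(maxit = 200))$par
      }
      W[, i] <- w
      r <- B %*% w
      R[, i] <- r
      max_viol[i] <- max(pmax(r - R_MAX, 0), pmin(r, 0) * -1)
      de[i] <- delta_e(xyz_to_lab(as.numeric(M %*% w))[1:3], tl[i, ])
    }
  }
  # report achieved Lab error for all entries (0 where XYZ matched exactly)
  lab_all <- xyz_to_lab(t(M %*% W))
  de <- delta_e(lab_all, targets_lab)
  # numerical policy: residues within the feasibility tolerance are clamped
  # onto the bounds so returned curves satisfy them exactly
  ok <- max_viol <= 1e-6
  R[, ok] <- pmin(pmax(R[, ok, drop = FALSE], 0), R_MAX)
  list(weights = W, curves = R, delta_e = de, max_violation = max_viol,
       lab = lab_all)
}

#' Solve basis weights for a target surface color
#'
#' Finds weights on the basis reflectances whose weighted sum reproduces a
#' target hue / lightness / chroma under equal-energy white, subject to the
#' physical constraint that the synthesized reflectance lie in
#' `[0, 0.90]` at every wavelength (leaving headroom for the specular
#' component). The solver first matches the target tristimulus exactly by
#' pseudoinverse, then restores curve feasibility inside the
#' tristimulus-preserving null space; targets that cannot satisfy both are
#' polished by a penalised minimizer and flagged infeasible when the
#' residual color error exceeds `tol_de`. An infeasible target is reported,
#' never silently clipped.
#'
#' @param basis A `basis_set` from [fit_basis()].
#' @param hue,lightness,chroma Target color (degrees, L*, C*ab).
#' @param tol_de Feasibility tolerance in CIE76 ΔE*ab (default 0.5).
#' @return A list with `weights`, `reflectance` (31 samples), `lab`
#'   (achieved), `delta_e`, `feasible`.
#' @export
solve_reflectance <- function(basis, hue, lightness, chroma, tol_de = 0.5) {
  stopifnot(inherits(basis, "basis_set"))
  target <- matrix(lch_to_lab(hue, lightness, chroma), ncol = 3)
  sol <- solve_reflectance_core(basis, target)
  list(weights = as.numeric(sol$weights[, 1]),
       reflectance = as.numeric(sol$curves[, 1]),
       lab = sol$lab[1, ],
       delta_e = sol$delta_e[1],
       feasible = sol$delta_e[1] <= tol_de && sol$max_violation[1] <= 1e-6)
}

#' Generate the reference color grid
#'
#' Solves a diffuse reflectance for every combination of the stimulus hue,
#' lightness and chroma values. The default grids (90 hues at 4-degree
#' steps, 24 lightness values 28-74 in steps of 2, 10 chroma values 8-26 in
#' steps of 2) give the full 21,600-entry stimulus space used for the
#' adjustable reference object.
#'
#' @param basis A `basis_set`.
#' @param hues,lightnesses,chromas Grid values. Hues are stored modulo 360
#'   and deduplicated after wrapping.
#' @param tol_de Feasibility tolerance in ΔE*ab.
#' @return A tibble of class `color_grid` with one row per grid entry:
#'   `hue, lightness, chroma, w1..wk, delta_e, feasible`. The solved
#'   reflectance curves are kept in the `"curves"` attribute
#'   (31 x n matrix), retrievable with [grid_reflectance()].
#' @export
generate_color_grid <- function(basis,
                                hues = seq(0, 356, by = 4),
                                lightnesses = seq(28, 74, by = 2),
                                chromas = seq(8, 26, by = 2),
                                tol_de = 0.5) {
  stopifnot(inherits(basis, "basis_set"))
  hues <- unique(hues %% 360)
  grid <- tidyr::expand_grid(hue = hues, lightness = lightnesses,
                             chroma = chromas)
  lab <- cbind(grid$lightness,
               grid$chroma * cos(grid$hue * pi / 180),
               grid$chroma * sin(grid$hue * pi / 180))
  sol <- solve_reflectance_core(basis, lab)
  k <- nrow(sol$weights)
  wdf <- as.data.frame(t(sol$weights))
  names(wdf) <- paste0("w", seq_len(k))
  out <- dplyr::bind_cols(grid, tibble::as_tibble(wdf))
  out$delta_e <- sol$delta_e
  out$feasible <- sol$delta_e <= tol_de & sol$max_violation <= 1e-6
  attr(out, "curves") <- sol$curves
  class(out) <- c("color_grid", class(out))
  out
}

#' Solved reflectance curve(s) of color-grid entries
#'
#' @param grid A `color_grid`.
#' @param i Row index (vectorized).
#' @return 31 x length(i) matrix of reflectance curves.
#' @export
grid_reflectance <- function(grid, i) {
  attr(grid, "curves")[, i, drop = FALSE]
}

#' Export / import a color grid as CSV
#'
#' Writes `hue,lightness,chroma,w1..wk,deltaE,feasible` (curves are
#' reconstructable from the weights and the basis).
#'
#' @param grid A `color_grid`.
#' @param path Output CSV path.
#' @export
write_color_grid <- function(grid, path) {
  df <- as.data.frame(grid)
  names(df)[names(df) == "delta_e"] <- "deltaE"
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
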