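# Shared fixtures, built once per test run. Sizes are kept small; the
# acceptance tests build their own full-scale inputs.

fixture_chips <- function(n = 300, seed = 11) synth_munsell_chips(n, seed)

# memoised small basis used across solver tests
local({
  ch <- fixture_chips()
  assign("FIX_BASIS", fit_basis(ch, 6, seed = 7, n_iter = 250, n_restart = 3),
         envir = topenv())
})

# an environment with a single bright cap and black elsewhere
cap_envmap <- function(azimuth, elevation = 35, H = 32, kappa = 40,
                       strength = 50, floor_rad = 0.02) {
  g <- env_geometry(H)
  d0 <- c(cos(elevation * pi / 180) * cos(azimuth * pi / 180),
          cos(elevation * pi / 180) * sin(azimuth * pi / 180),
          sin(elevation * pi / 180))
  y <- floor_rad + strength * exp(kappa * (matrix(g$dir %*% d0, H, 2 * H) - 1))
  env_map(array(rep(y, 3), c(H, 2 * H, 3)))
}

# small factorial scene set shared by metric/end-to-end tests
fixture_scene_set <- function(n_envs = 4, n_shapes = 3, H = 32, res = 64,
                              seed = 21) {
  envs <- lapply(seq_len(n_envs), function(i) {
    synth_envmap(H, seed = seed + i, cap_azimuth = (i * 77) %% 360,
                 cap_strength = 8 + 3 * i)
  })
  env_tbl <- tibble::tibble(env_id = seq_len(n_envs), condition = "natural",
                            env = envs)
  make_factorial_stimuli(env_tbl, n_shapes = n_shapes, seed = seed,
                         resolution = res)
}
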