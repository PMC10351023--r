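#' Build a single-object stimulus set over a lighting-environment set
#'
#' One scene per lighting environment: a randomly drawn shape and material
#' (hue on the 4-degree grid, lightness 28-74, chroma 8-26, contrast-gloss
#' uniform over the adjustable range at conversion lightness 50), rendered
#' from the viewpoint with the brightest mirrored-sphere probe. Two
#' symmetric-matching control scenes with fixed materials (hue 120 /
#' chroma 22 / lightness 40 / c 0.1305, and hue 320 / chroma 14 /
#' lightness 60 / c 0.0152) under the first environment are appended when
#' `controls = TRUE`. All composites share one 99th-percentile
#' normalization factor.
#'
#' @param env_set Tibble from [build_env_set()] (`env_id, condition, env`).
#' @param seed Integer seed for shapes and materials.
#' @param resolution Render resolution in pixels.
#' @param controls Append the two control scenes (default TRUE).
#' @param conversion_lightness Lightness for the gloss-scale conversion.
#' @return A tibble of class `scene_set`: one row per image with
#'   `image_id, env_id, condition, is_control, azimuth, hue, lightness,
#'   chroma, pellacini_c, ward_ps` and list-columns `components`
#'   (`rendered_components`) and `albedo`. The shared normalization factor
#'   is in attribute `"scale_factor"`.
#' @export
make_stimuli <- function(env_set, seed = 1, resolution = 128,
                         controls = TRUE, conversion_lightness = 50) {
  stopifnot(all(c("env_id", "condition", "env") %in% names(env_set)))
  set.seed(seed)
  n <- nrow(env_set)
  c_max <- pellacini_c(0.0999, conversion_lightness)
  mat <- tibble::tibble(
    hue = sample(seq(0, 356, by = 4), n, replace = TRUE),
    lightness = round(runif(n, 28, 74)),
    chroma = round(runif(n, 8, 26)),
    pellacini_c = runif(n, 0, c_max))
  shape_seeds <- sample.int(1e6, n, replace = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    env <- env_set$env[[i]]
    az <- select_viewpoint(env)
    shp <- bumpy_sphere(bump_amplitude = 0.15, bump_frequency = 6,
                        seed = shape_seeds[i])
    rc <- render_components(shp, env, azimuth = az, resolution = resolution)
    rows[[i]] <- tibble::tibble(
      image_id = i, env_id = env_set$env_id[i],
      condition = env_set$condition[i], is_control = FALSE,
      shape_seed = shape_seeds[i], azimuth = az,
      hue = mat$hue[i], lightness = mat$lightness[i], chroma = mat$chroma[i],
      pellacini_c = mat$pellacini_c[i],
      ward_ps = ward_from_pellacini(mat$pellacini_c[i], conversion_lightness),
      components = list(rc))
  }
  if (controls) {
    ctrl <- tibble::tibble(hue = c(120, 320), chroma = c(22, 14),
                           lightness = c(40, 60),
                           pellacini_c = c(0.1305, 0.0152))
    env <- env_set$env[[1]]
    az <- select_viewpoint(env)
    shp <- bumpy_sphere(bump_amplitude = 0.15, bump_frequency = 6, seed = 424242)
    rc <- render_components(shp, env, azimuth = az, resolution = resolution)
    for (j in 1:2) {
      rows[[n + j]] <- tibble::tibble(
        image_id = n + j, env_id = env_set$env_id[1],
        condition = env_set$condition[1], is_control = TRUE,
        shape_seed = 424242, azimuth = az,
        hue = ctrl$hue[j], lightness = ctrl$lightness[j],
        chroma = ctrl$chroma[j], pellacini_c = ctrl$pellacini_c[j],
        ward_ps = ward_from_pellacini(ctrl$pellacini_c[j], conversion_lightness),
        components = list(rc))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$albedo <- lapply(seq_len(nrow(out)), function(i) {
    material_albedo(out$hue[i], out$lightness[i], out$chroma[i])
  })
  out <- finalize_scene_set(out)
  out
}

#' Build the factorial gloss stimulus set
#'
#' Full crossing of lighting environments and shapes at a fixed greenish
#' body color (hue 188.2, lightness 33.9, chroma 11.9 — a color on the
#' red-green axis, where specular reflections of near-daylight
#' environments are most visible) with a random contrast-gloss value per
#' image drawn from the adjustable range at conversion lightness 33.9.
#'
#' @param env_set Tibble (`env_id, condition, env`), typically the 12
#'   natural environments.
#' @param n_shapes Number of bumpy-sphere shapes (default 18).
#' @param seed Integer seed.
#' @param resolution Render resolution in pixels.
#' @param body Fixed body color `c(hue, lightness, chroma)`.
#' @param conversion_lightness Lightness for the gloss-scale conversion.
#' @return A `scene_set` tibble with `n_envs x n_shapes` rows (and a
#'   `shape_id` column).
#' @export
make_factorial_stimuli <- function(env_set, n_shapes = 18, seed = 1,
                                   resolution = 128,
                                   body = c(hue = 188.2, lightness = 33.9,
                                            chroma = 11.9),
                                   conversion_lightness = 33.9) {
  set.seed(seed)
  shape_seeds <- sample.int(1e6, n_shapes)
  c_max <- pellacini_c(0.0999, conversion_lightness)
  alb <- material_albedo(body[["hue"]], body[["lightness"]], body[["chroma"]])
  rows <- list()
  img <- 0L
  for (i in seq_len(nrow(env_set))) {
    env <- env_set$env[[i]]
    az <- select_viewpoint(env)
    for (j in seq_len(n_shapes)) {
      img <- img + 1L
      shp <- bumpy_sphere(bump_amplitude = 0.15,
                          bump_frequency = 4 + (j %% 5) * 2,
                          seed = shape_seeds[j])
      rc <- render_components(shp, env, azimuth = az, resolution = resolution)
      rows[[img]] <- tibble::tibble(
        image_id = img, env_id = env_set$env_id[i],
        condition = env_set$condition[i], is_control = FALSE,
        shape_id = j, shape_seed = shape_seeds[j], azimuth = az,
        hue = body[["hue"]], lightness = body[["lightness"]],
        chroma = body[["chroma"]],
        pellacini_c = runif(1, 0, c_max),
        ward_ps = NA_real_,
        components = list(rc))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$ward_ps <- ward_from_pellacini(out$pellacini_c, conversion_lightness)
  out$albedo <- replicate(nrow(out), alb, simplify = FALSE)
  finalize_scene_set(out)
}

# shared 99th-percentile normalization across all composites of a set
finalize_scene_set <- function(scenes) {
  comps <- lapply(seq_len(nrow(scenes)), function(i) {
    composite(scenes$components[[i]], scenes$albedo[[i]], scenes$ward_ps[i])
  })
  ns <- normalize_set(comps)
  for (i in seq_len(nrow(scenes))) {
    rc <- scenes$components[[i]]
    rc$diffuse_unit <- rc$diffuse_unit / ns$factor
    rc$specular_unit <- rc$specular_unit / ns$factor
    rc$scale <- ns$factor
    scenes$components[[i]] <- rc
  }
  attr(scenes, "scale_factor") <- ns$factor
  class(scenes) <- c("scene_set", class(scenes))
  scenes
}

#' Composite image of one scene-set row
#'
#' @param scenes A `scene_set`.
#' @param i Row index.
#' @return Linear RGB array (normalized scale).
#' @export
scene_composite <- function(scenes, i) {
  composite(scenes$components[[i]], scenes$albedo[[i]], scenes$ward_ps[i])
}

#' Image-statistic table of a stimulus set
#'
#' Per image: object-region color statistics of the composite (lightness
#' and chroma moments/quantiles, circular mean hue), simple luminance
#' statistics over the object region, and the three specular-reflection
#' metrics (coverage, sharpness, sub-band RMS contrast) at a chosen
#' threshold `k` and band. The 12 columns
#' `coverage, sharpness, contrast_band, lum_{mean, median, sd, skewness,
#' kurtosis, q1, q3, min, max}` form the standard predictor set for the
#' gloss regression; `contrast_aggregate` is included alongside.
#'
#' @param scenes A `scene_set`.
#' @param k Highlight threshold percent for the specular metrics.
#' @param band Sub-band index for `contrast_band` (default 4, i.e.
#'   12-24 cycles/image).
#' @return Tibble keyed by `image_id`.
#' @export
scene_metric_table <- function(scenes, k = 5, band = 4) {
  rows <- lapply(seq_len(nrow(scenes)), function(i) {
    rc <- scenes$components[[i]]
    img <- scene_composite(scenes, i)
    diff_img <- composite(rc, scenes$albedo[[i]], 0)
    spec <- specular_only(img, diff_img, rc$mask)
    hl <- threshold_highlights(spec, rc$mask, k)
    thr <- spec; thr[!hl] <- 0
    sb <- subband_contrast(thr, rc$mask)
    lum <- image_luminance(img)[rc$mask]
    dplyr::bind_cols(
      tibble::tibble(image_id = scenes$image_id[i],
                     coverage = coverage(hl, rc$mask),
                     sharpness = sharpness(thr, rc$mask),
                     contrast_band = sb$rms[sb$band %in% band],
                     contrast_aggregate = sb$rms[is.na(sb$band)]),
      moment_row(lum, "lum"),
      region_color_stats(img, rc$mask))
  })
  dplyr::bind_rows(rows)
}

#' Highlight-metric sweep across the full parameter grid
#'
#' [highlight_metrics()] for every image of a stimulus set, long format
#' with `image_id` — the input expected by [optimize_metric_params()].
#'
#' @param scenes A `scene_set`.
#' @param k_set Threshold grid.
#' @return Long tibble `image_id, k, metric, band, value`.
#' @export
scene_highlight_sweep <- function(scenes, k_set = HIGHLIGHT_K_SET) {
  rows <- lapply(seq_len(nrow(scenes)), function(i) {
    rc <- scenes$components[[i]]
    img <- scene_composite(scenes, i)
    diff_img <- composite(rc, scenes$albedo[[i]], 0)
    spec <- specular_only(img, diff_img, rc$mask)
    hm <- highlight_metrics(spec, rc$mask, k_set)
    hm$image_id <- scenes$image_id[i]
    hm
  })
  dplyr::bind_rows(rows)
}

#' Ground-truth table of a stimulus set
#'
#' @param scenes A `scene_set`.
#' @return Tibble `image_id, hue, lightness, chroma, pellacini_c` (plus
#'   `environment` = `env_id` and `condition`).
#' @export
scene_truth <- function(scenes) {
  tibble::tibble(image_id = scenes$image_id, hue = scenes$hue,
                 lightness = scenes$lightness, chroma = scenes$chroma,
                 pellacini_c = scenes$pellacini_c,
                 environment = scenes$env_id, condition = scenes$condition)
}
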