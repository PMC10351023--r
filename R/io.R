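#' Read / write environment maps
#'
#' Environment maps are stored losslessly as 32-bit float TIFF (an
#' HDR-capable container) and, for quick inspection, as gamma-2.2 PNG
#' previews. A plain-CSV form (`row,col,R,G,B`) is provided for fully
#' text-based interchange.
#'
#' @param env An `env_map`.
#' @param path Output path.
#' @export
write_envmap <- function(env, path) {
  s <- max(env$pixels)
  if (s <= 0) s <- 1
  tiff::writeTIFF(env$pixels / s, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  # radiance scale sidecar (the TIFF body stores [0, 1] floats)
  jsonlite::write_json(list(radiance_scale = s), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_envmap
#' @export
read_envmap <- function(path) {
  px <- tiff::readTIFF(path)
  attributes(px) <- list(dim = dim(px))
  s <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    s <- jsonlite::read_json(sidecar)$radiance_scale
  }
  env_map(px * s)
}

#' @rdname write_envmap
#' @param gamma Encoding gamma for the preview.
#' @param scale Luminance scale applied before encoding (default: scale the
#'   99th percentile to 1).
#' @export
write_env_preview <- function(env, path, gamma = 2.2, scale = NULL) {
  p <- env$pixels
  if (is.null(scale)) {
    q <- quantile(p, 0.99)
    scale <- if (q > 0) 1 / q else 1
  }
  img <- pmin(pmax(p * scale, 0), 1)^(1 / gamma)
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_envmap
#' @export
write_envmap_csv <- function(env, path) {
  H <- env$height; W <- env$width
  df <- data.frame(row = rep(seq_len(H), W), col = rep(seq_len(W), each = H),
                   R = as.numeric(env$pixels[, , 1]),
                   G = as.numeric(env$pixels[, , 2]),
                   B = as.numeric(env$pixels[, , 3]))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_envmap
#' @export
read_envmap_csv <- function(path) {
  df <- read.csv(path)
  H <- max(df$row); W <- max(df$col)
  o <- order(df$col, df$row)
  env_map(array(c(df$R[o], df$G[o], df$B[o]), c(H, W, 3)))
}
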