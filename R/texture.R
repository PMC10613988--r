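# GLCM texture features: gray-level quantization, per-window co-occurrence
# matrices, the eight Haralick statistics, and plot-level aggregation.

TEXTURE_NAMES <- c("MEA", "VAR", "HOM", "CON", "DIS", "ENT", "SEM", "COR")

#' GLCM configuration
#'
#' @param window Odd moving-window size in pixels (default 3).
#' @param shift Co-occurrence shift `(d_row, d_col)`; default `c(0, 1)`,
#'   one pixel to the right.
#' @param levels Number of gray levels for linear quantization over the
#'   band's global min-max (default 32).
#' @param symmetric Accumulate each pair in both orders (default TRUE).
#' @param directions Optional list of shift vectors; when given, per-pixel
#'   features are averaged over directions (default: the single `shift`).
#' @return A `glcm_config` list.
#' @export
glcm_config <- function(window = 3, shift = c(0, 1), levels = 32,
                        symmetric = TRUE, directions = NULL) {
  stopifnot(window %% 2 == 1, window >= 1, levels >= 2,
            length(shift) == 2)
  if (window < max(abs(shift)) + 1)
    stop("window must cover the co-occurrence shift")
  if (is.null(directions)) directions <- list(as.integer(shift))
  structure(list(window = as.integer(window), shift = as.integer(shift),
                 levels = as.integer(levels), symmetric = symmetric,
                 directions = directions),
            class = "glcm_config")
}

#' Quantize a raster band to gray levels
#'
#' Linear quantization over `range` into levels `0 .. levels-1`.  A constant
#' band maps entirely to level 0.
#'
#' @param x Numeric matrix.
#' @param levels Number of gray levels.
#' @param range Quantization range; defaults to the band's min-max.
#' @return Integer matrix of levels.
#' @export
quantize_band <- function(x, levels = 32, range = base::range(x, finite = TRUE)) {
  span <- range[2] - range[1]
  if (span <= 0) return(matrix(0L, nrow(x), ncol(x)))
  q <- floor((x - range[1]) / span * levels)
  q[q >= levels] <- levels - 1L
  q[q < 0] <- 0L
  storage.mode(q) <- "integer"
  q
}

#' Co-occurrence matrix of one window
#'
#' Reference implementation used for single windows and as the documented
#' definition; the raster-scale path runs in compiled code.
#'
#' @param qwin Integer matrix of quantized levels (one window).
#' @param config A [glcm_config()].
#' @return `levels x levels` matrix of pair probabilities summing to 1.
#' @export
glcm <- function(qwin, config = glcm_config()) {
  stopifnot(is.matrix(qwin))
  if (nrow(qwin) < abs(config$shift[1]) + 1 ||
      ncol(qwin) < abs(config$shift[2]) + 1)
    stop("window smaller than the co-occurrence shift")
  L <- config$levels
  P <- matrix(0, L, L)
  dr <- config$shift[1]; dc <- config$shift[2]
  for (a in seq_len(nrow(qwin))) for (b in seq_len(ncol(qwin))) {
    a2 <- a + dr; b2 <- b + dc
    if (a2 >= 1 && a2 <= nrow(qwin) && b2 >= 1 && b2 <= ncol(qwin)) {
      i <- qwin[a, b] + 1L; j <- qwin[a2, b2] + 1L
      P[i, j] <- P[i, j] + 1
      if (config$symmetric) P[j, i] <- P[j, i] + 1
    }
  }
  s <- sum(P)
  if (s == 0) stop("no co-occurrence pairs in window")
  P / s
}

#' Haralick statistics of a normalized co-occurrence matrix
#'
#' Gray levels are indexed from 0.  `COR` is defined as 0 when either
#' marginal standard deviation vanishes.
#'
#' @param P Normalized co-occurrence matrix.
#' @return Named vector: MEA, VAR, HOM, CON, DIS, ENT, SEM, COR.
#' @export
texture_vector <- function(P) {
  L <- nrow(P)
  i <- matrix(0:(L - 1), L, L)
  j <- t(i)
  mi <- sum(i * P); mj <- sum(j * P)
  vi <- sum((i - mi)^2 * P); vj <- sum((j - mj)^2 * P)
  pos <- P > 0
  c(MEA = mi,
    VAR = vi,
    HOM = sum(P / (1 + (i - j)^2)),
    CON = sum((i - j)^2 * P),
    DIS = sum(abs(i - j) * P),
    ENT = -sum(P[pos] * log(P[pos])),
    SEM = sum(P^2),
    COR = if (vi > 1e-12 && vj > 1e-12)
      sum((i - mi) * (j - mj) * P) / sqrt(vi * vj) else 0)
}

#' Per-pixel texture feature rasters for one band
#'
#' Quantizes the band over its global range and evaluates the eight
#' statistics on the moving-window GLCM centered at every pixel (windows
#' clipped at raster edges, never padded).  With several `directions` in the
#' config, features are averaged across directions.
#'
#' @param band Numeric matrix (one raster band).
#' @param config A [glcm_config()].
#' @return Named list of eight matrices.
#' @export
texture_rasters <- function(band, config = glcm_config()) {
  q <- quantize_band(band, config$levels)
  acc <- NULL
  for (d in config$directions) {
    res <- glcm_texture_rasters_cpp(q, config$window, d[1], d[2],
                                    config$symmetric)
    if (is.null(acc)) acc <- res
    else for (k in seq_along(acc)) acc[[k]] <- acc[[k]] + res[[k]]
  }
  if (length(config$directions) > 1)
    for (k in seq_along(acc))
      acc[[k]] <- acc[[k]] / length(config$directions)
  acc
}

#' Plot-level texture features for the multispectral bands
#'
#' Computes per-pixel texture rasters for each MS band and averages them
#' over the plot's pixels; over a full run (7 stages x 5 bands x 8
#' statistics) this yields 280 texture features per sample.
#'
#' @param scene A `uav_scene`.
#' @param pixels A `plot_pixels` object for one plot.
#' @param config A [glcm_config()].
#' @param rasters Optional precomputed output of [texture_rasters()] per
#'   band (named list), to share work across plots of the same scene.
#' @return Named vector of `5 x 8` features, names `tex_<band>_<stat>`.
#' @export
plot_texture_features <- function(scene, pixels, config = glcm_config(),
                                  rasters = NULL) {
  stopifnot(inherits(pixels, "plot_pixels"))
  if (config$window > 1 &&
      pixels$n < config$window)
    stop("plot smaller than the texture window: ", pixels$sample_id)
  if (is.null(rasters))
    rasters <- lapply(stats::setNames(scene$ms$bands, scene$ms$bands),
                      function(b) texture_rasters(band_matrix(scene$ms, b),
                                                  config))
  out <- numeric(0)
  for (b in scene$ms$bands) {
    v <- vapply(TEXTURE_NAMES,
                function(f) mean(rasters[[b]][[f]][pixels$idx], na.rm = TRUE),
                numeric(1))
    names(v) <- paste0("tex_", b, "_", TEXTURE_NAMES)
    out <- c(out, v)
  }
  out
}
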