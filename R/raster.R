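# In-memory raster grid and TIFF-backed I/O.
#
# Coordinate convention (used everywhere in the package): map x increases to
# the right, map y increases upward; the grid origin is the *upper-left pixel
# corner*; rows are stored top-to-bottom (row-major display order).  The
# center of pixel (row r, col c) is therefore
#   x = origin_x + (c - 0.5) * res,   y = origin_y - (r - 0.5) * res.

#' Construct a raster grid
#'
#' A `raster_grid` is the package's in-memory raster: a `rows x cols x bands`
#' numeric array with a resolution (m/pixel), a map origin at the upper-left
#' pixel corner, and unique band labels.
#'
#' @param values Numeric matrix (`rows x cols`) or 3-d array
#'   (`rows x cols x bands`).
#' @param res Pixel size in metres (square pixels).
#' @param origin Numeric length-2, map coordinates `(x, y)` of the upper-left
#'   pixel corner.
#' @param bands Character vector of band labels, one per band.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, res, origin = c(0, 0), bands = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (!is.numeric(res) || length(res) != 1L || res <= 0)
    stop("`res` must be a single positive number")
  if (is.null(bands)) bands <- paste0("band", seq_len(dim(values)[3L]))
  if (length(bands) != dim(values)[3L]) stop("one band label per band required")
  if (anyDuplicated(bands)) stop("band labels must be unique")
  structure(
    list(values = values, res = as.numeric(res),
         origin = as.numeric(origin), bands = as.character(bands)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_grid> %d x %d pixels, %d band(s) [%s]\n",
              d[1], d[2], d[3], paste(x$bands, collapse = ", ")))
  cat(sprintf("  res %.4g m, origin (%.4g, %.4g)\n",
              x$res, x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

rg_nrow <- function(g) dim(g$values)[1L]
rg_ncol <- function(g) dim(g$values)[2L]
rg_nband <- function(g) dim(g$values)[3L]

#' Extract one band as a matrix
#' @param grid A `raster_grid`.
#' @param band Band label or index.
#' @return Numeric matrix.
#' @export
band_matrix <- function(grid, band) {
  if (is.character(band)) {
    i <- match(band, grid$bands)
    if (is.na(i)) stop("missing band label: ", band)
  } else i <- band
  grid$values[, , i]
}

#' Map coordinates of pixel centers
#' @param grid A `raster_grid`.
#' @return List with `x` (length = cols) and `y` (length = rows).
#' @export
pixel_centers <- function(grid) {
  list(x = grid$origin[1] + (seq_len(rg_ncol(grid)) - 0.5) * grid$res,
       y = grid$origin[2] - (seq_len(rg_nrow(grid)) - 0.5) * grid$res)
}

# TRUE if two grids share shape, resolution and origin bit-exactly.
same_grid <- function(a, b) {
  identical(dim(a$values)[1:2], dim(b$values)[1:2]) &&
    identical(a$res, b$res) && identical(a$origin, b$origin)
}

#' Snap values in [0, 1] to the 16-bit sample grid
#'
#' Continuous rasters are persisted as 16-bit TIFF samples (values
#' `k / 65535`).  Generating reflectance already on that grid makes
#' write/read round trips bit-identical; the grid step (1.5e-5) is far
#' below the scene's spectral noise.
#' @param x Numeric vector/array with values in `[0, 1]`.
#' @return `x` rounded to the nearest multiple of `1/65535`.
#' @export
unit16_round <- function(x) round(x * 65535) / 65535

#' Write a raster grid to a TIFF file with a JSON sidecar
#'
#' Bands are stored as separate TIFF directories (16-bit continuous samples
#' or uint8).  The sidecar `<path>.aux.json` records resolution, origin,
#' band labels and the per-file affine scale/offset used to pack values
#' into the unit interval.  Data already in `[0, 1]` are stored with the
#' identity transform, so values on the 16-bit grid (see [unit16_round()])
#' round-trip bit-identically; packed data (e.g. elevation) round-trip
#' within `scale / 65535`.
#'
#' @param grid A `raster_grid`.
#' @param path Output path (conventionally `.tif`).
#' @param type `"float"` (continuous values packed by scale/offset) or
#'   `"uint8"` (values must be integers in 0..255).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, type = c("float", "uint8")) {
  type <- match.arg(type)
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    stop("cannot write raster: directory not writable: ", dir)
  nb <- rg_nband(grid)
  if (type == "uint8") {
    offset <- 0; scale <- 255
    imgs <- lapply(seq_len(nb), function(i) grid$values[, , i] / 255)
    bits <- 8L
  } else {
    rng <- range(grid$values, finite = TRUE)
    if (rng[1] >= 0 && rng[2] <= 1) { offset <- 0; scale <- 1 }
    else { offset <- rng[1]; scale <- max(rng[2] - rng[1], 1) }
    imgs <- lapply(seq_len(nb), function(i)
      unit16_round((grid$values[, , i] - offset) / scale))
    bits <- 16L
  }
  tiff::writeTIFF(imgs, path, bits.per.sample = bits, reduce = FALSE,
                  compression = "none")
  meta <- list(res = grid$res, origin = grid$origin, bands = grid$bands,
               type = type, scale = scale, offset = offset)
  jsonlite::write_json(meta, paste0(path, ".aux.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raster written by [write_raster()]
#' @param path Path to the TIFF file (sidecar `<path>.aux.json` must exist).
#' @return A `raster_grid`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  aux <- paste0(path, ".aux.json")
  if (!file.exists(aux)) stop("sidecar metadata not found: ", aux)
  meta <- jsonlite::read_json(aux, simplifyVector = TRUE)
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  vals <- array(0, c(dim(imgs[[1]]), length(imgs)))
  for (i in seq_along(imgs)) {
    v <- imgs[[i]]
    vals[, , i] <-
      if (meta$type == "uint8") round(v * 255)
      else v * meta$scale + meta$offset
  }
  raster_grid(vals, res = meta$res, origin = meta$origin, bands = meta$bands)
}
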