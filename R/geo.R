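# Plot geometries: axis-aligned rectangles in map coordinates, carried as a
# data.frame and round-tripped through GeoJSON (Polygon features).

#' Test points against a polygon ring
#'
#' Vectorized even-odd ray casting.  Points exactly on an edge resolve
#' deterministically by the strict/non-strict comparisons below; the package
#' lays plot edges on pixel *boundaries* so pixel centers never sit on edges.
#'
#' @param px,py Point coordinates.
#' @param ring Two-column matrix of ring vertices (closed or open).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, ring) {
  ring <- as.matrix(ring)
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) { ring <- ring[-n, , drop = FALSE]; n <- n - 1L }
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin, xmin),
        y = c(ymin, ymin, ymax, ymax, ymin))
}

#' Write plot geometries to GeoJSON
#'
#' Each row of `plots` becomes a Polygon feature with properties
#' `sample_id`, `plot`, `cultivar`, `n_rate`, `replicate`, `is_subplot`.
#'
#' @param plots Plot table from [build_design()].
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_plots_geojson <- function(plots, path) {
  feats <- lapply(seq_len(nrow(plots)), function(i) {
    p <- plots[i, ]
    ring <- rect_ring(p$xmin, p$ymin, p$xmax, p$ymax)
    list(
      type = "Feature",
      properties = list(sample_id = p$sample_id, plot = p$plot,
                        cultivar = p$cultivar, n_rate = p$n_rate,
                        replicate = p$replicate, is_subplot = p$is_subplot),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(k) ring[k, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read plot geometries from GeoJSON
#' @param path Path written by [write_plots_geojson()].
#' @return Plot table (data.frame) with bounding-box columns.
#' @export
read_plots_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    pr <- f$properties
    data.frame(sample_id = pr$sample_id, plot = pr$plot,
               cultivar = pr$cultivar, n_rate = pr$n_rate,
               replicate = pr$replicate, is_subplot = pr$is_subplot,
               xmin = min(ring[, 1]), ymin = min(ring[, 2]),
               xmax = max(ring[, 1]), ymax = max(ring[, 2]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
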