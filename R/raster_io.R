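# Loading co-registered stage rasters and extracting per-plot pixel sets.

check_same_grid <- function(a, b, what) {
  if (!same_grid(a, b))
    stop("grid mismatch between layers (", what,
         "): shape, resolution and origin must match bit-exactly; ",
         "resampling is out of scope")
  invisible(TRUE)
}

#' Load all rasters of one growth stage
#'
#' Reads the multispectral stack, RGB image, DSM and the shared bare-soil
#' DEM plus plot geometries from a dataset directory, and validates that all
#' layers are co-registered and that reflectance lies in `[-0.01, 1.01]`.
#' Mismatched grids are rejected, never silently resampled.
#'
#' @param dir Dataset directory (layout of [write_dataset()]).
#' @param stage Stage label.
#' @return A `uav_scene` (without generator ground truth).
#' @export
load_stage <- function(dir, stage) {
  need <- file.path(dir, c(paste0(c("ms_", "rgb_", "dsm_"), stage, ".tif"),
                           "dem.tif", "plots.geojson"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing dataset files: ", paste(missing, collapse = ", "))
  ms <- read_raster(need[1])
  rgb <- read_raster(need[2])
  dsm <- read_raster(need[3])
  dem <- read_raster(need[4])
  plots <- read_plots_geojson(need[5])
  if (!setequal(ms$bands, MS_BANDS))
    stop("multispectral stack must carry bands ",
         paste(MS_BANDS, collapse = ", "), "; found: ",
         paste(ms$bands, collapse = ", "))
  check_same_grid(ms, rgb, "MS vs RGB")
  check_same_grid(ms, dsm, "MS vs DSM")
  check_same_grid(ms, dem, "MS vs DEM")
  for (b in ms$bands) {
    v <- band_matrix(ms, b)
    bad <- sum(v < -0.01 | v > 1.01)
    if (bad > 0)
      stop("reflectance outside [-0.01, 1.01] in band ", b, ": ",
           bad, " pixel(s)")
  }
  structure(list(stage = stage, ms = ms, rgb = rgb, dsm = dsm, dem = dem,
                 plots = plots, truth = NULL),
            class = "uav_scene")
}

#' Extract the pixels of one plot
#'
#' Membership is by the pixel-center rule: a pixel belongs to the plot iff
#' its center falls inside the polygon.  All layers of the scene are
#' co-registered, so every layer contributes the same `n` pixels.
#'
#' @param scene A `uav_scene`.
#' @param geometry One row of the plot table (`sample_id`, bounds).
#' @return A `plot_pixels` list: `sample_id`, `n`, pixel area `A` (m^2),
#'   `idx` (linear pixel indices into a band matrix), `ms` (`n x 5`
#'   reflectance matrix), `rgb` (`n x 3` digital numbers), `dsm`, `dem`
#'   (length-`n` vectors).
#' @export
extract_plot_pixels <- function(scene, geometry) {
  stopifnot(inherits(scene, "uav_scene"))
  g <- as.list(geometry)
  ctr <- pixel_centers(scene$ms)
  nr <- length(ctr$y); nc <- length(ctr$x)
  rows <- which(ctr$y > g$ymin & ctr$y < g$ymax)
  cols <- which(ctr$x > g$xmin & ctr$x < g$xmax)
  if (!length(rows) || !length(cols))
    stop("plot geometry intersects no pixel centers: sample_id ",
         g$sample_id)
  # general polygon test on the bbox candidates (rectangles pass trivially)
  cand <- expand.grid(r = rows, c = cols, KEEP.OUT.ATTRS = FALSE)
  ring <- rect_ring(g$xmin, g$ymin, g$xmax, g$ymax)
  keep <- point_in_polygon(ctr$x[cand$c], ctr$y[cand$r], ring)
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand))
    stop("plot geometry intersects no pixel centers: sample_id ",
         g$sample_id)
  idx <- cand$r + (cand$c - 1L) * nr
  ms <- sapply(seq_along(scene$ms$bands),
               function(b) scene$ms$values[, , b][idx])
  colnames(ms) <- scene$ms$bands
  rgb <- sapply(seq_along(scene$rgb$bands),
                function(b) scene$rgb$values[, , b][idx])
  colnames(rgb) <- scene$rgb$bands
  structure(list(sample_id = g$sample_id, n = nrow(cand),
                 A = scene$ms$res^2, idx = idx,
                 ms = ms, rgb = rgb,
                 dsm = scene$dsm$values[, , 1][idx],
                 dem = scene$dem$values[, , 1][idx]),
            class = "plot_pixels")
}
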