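# Agronomic trait parameters: canopy height (DSM - DEM), fractional
# vegetation cover from a supervised crop/soil classification of the
# multispectral stack, and pixel-area-weighted canopy volume.

#' Canopy height raster
#'
#' Per-pixel `CH = DSM - DEM`; negative differences (surface noise can put
#' the canopy surface below the bare-soil model) are clipped to zero.
#'
#' @param dsm,dem Co-registered single-band `raster_grid`s (m).
#' @param clip_negative Clip negative heights to 0 (default TRUE).
#' @return A single-band `raster_grid` of heights, m.
#' @export
canopy_height <- function(dsm, dem, clip_negative = TRUE) {
  check_same_grid(dsm, dem, "DSM vs DEM")
  ch <- dsm$values[, , 1] - dem$values[, , 1]
  if (clip_negative) ch[ch < 0] <- 0
  raster_grid(ch, dsm$res, dsm$origin, "CH")
}

#' Sample labeled training pixels from a scene with ground truth
#'
#' Draws a balanced sample of crop and soil pixels (band reflectances +
#' class label) from the generator's ground-truth vegetation mask.
#'
#' @param scene A `uav_scene` carrying `truth$veg_mask`.
#' @param n_per_class Pixels per class (default 500).
#' @param seed Integer seed.
#' @return data.frame with columns B, G, R, RE, NIR and factor `class`
#'   (`crop`/`soil`).
#' @export
sample_training_pixels <- function(scene, n_per_class = 500, seed = 1L) {
  if (is.null(scene$truth))
    stop("scene carries no ground-truth mask to sample labels from")
  mask <- scene$truth$veg_mask$values[, , 1]
  withr::with_seed(seed, {
    pick <- function(cls) {
      idx <- which(mask == cls)
      sample(idx, min(n_per_class, length(idx)))
    }
    icrop <- pick(1); isoil <- pick(0)
  })
  idx <- c(icrop, isoil)
  df <- as.data.frame(
    sapply(seq_along(scene$ms$bands), function(b) scene$ms$values[, , b][idx]))
  names(df) <- scene$ms$bands
  df$class <- factor(rep(c("crop", "soil"), c(length(icrop), length(isoil))),
                     levels = c("crop", "soil"))
  df
}

#' Classify crop vs soil pixels
#'
#' Default method is a support vector machine (radial kernel) on the five
#' band reflectances; `method = "threshold"` is a simple NDVI-threshold
#' classifier (threshold at the midpoint of the class-mean NDVIs of the
#' training set).  A fifth of the training pixels is held out to report
#' accuracy.
#'
#' @param ms Multispectral `raster_grid` (bands B, G, R, RE, NIR).
#' @param training data.frame of labeled pixels (band columns + `class`).
#' @param method `"svm"` or `"threshold"`.
#' @param holdout_frac Fraction of training pixels held out for the
#'   accuracy estimate.
#' @param seed Integer seed for the holdout split.
#' @return List: `mask` (single-band 0/1 `raster_grid`, 1 = crop),
#'   `accuracy` (held-out overall accuracy), `method`.
#' @export
classify_vegetation <- function(ms, training, method = c("svm", "threshold"),
                                holdout_frac = 0.2, seed = 1L) {
  method <- match.arg(method)
  if (nlevels(droplevels(training$class)) < 2)
    stop("training set must contain both crop and soil pixels")
  bands <- ms$bands
  withr::with_seed(seed, {
    ho <- sample(nrow(training), max(1, round(holdout_frac * nrow(training))))
  })
  train <- training[-ho, , drop = FALSE]
  hold <- training[ho, , drop = FALSE]
  nr <- dim(ms)[1]; nc <- dim(ms)[2]
  allpix <- as.data.frame(
    sapply(seq_along(bands), function(b) as.vector(ms$values[, , b])))
  names(allpix) <- bands
  if (method == "svm") {
    fit <- e1071::svm(class ~ ., data = train, kernel = "radial")
    acc <- mean(stats::predict(fit, hold) == hold$class)
    lab <- stats::predict(fit, allpix)
  } else {
    ndvi <- function(d) (d$NIR - d$R) / (d$NIR + d$R)
    thr <- mean(c(mean(ndvi(train)[train$class == "crop"]),
                  mean(ndvi(train)[train$class == "soil"])))
    cls <- function(d) factor(ifelse(ndvi(d) > thr, "crop", "soil"),
                              levels = c("crop", "soil"))
    acc <- mean(cls(hold) == hold$class)
    lab <- cls(allpix)
  }
  mask <- matrix(as.integer(lab == "crop"), nr, nc)
  list(mask = raster_grid(mask, ms$res, ms$origin, "crop"),
       accuracy = acc, method = method)
}

#' Fractional vegetation cover of a plot
#'
#' `FVC = 100 * c / n` where `c` is the number of crop-classified pixels in
#' the plot and `n` the total pixel count.
#'
#' @param mask Single-band 0/1 crop-mask `raster_grid`.
#' @param pixels A `plot_pixels` object (its `idx` selects the plot).
#' @return FVC in percent.
#' @export
fvc <- function(mask, pixels) {
  stopifnot(inherits(pixels, "plot_pixels"))
  if (pixels$n == 0) stop("plot has no pixels: ", pixels$sample_id)
  m <- mask$values[, , 1][pixels$idx]
  100 * sum(m == 1) / pixels$n
}

#' Canopy volume of a plot
#'
#' `VOL = sum_i A_i * CH_i` over crop-classified pixels in the plot
#' (`crop_only = FALSE` sums all in-plot pixels instead).
#'
#' @param ch Canopy-height `raster_grid` (from [canopy_height()]).
#' @param mask Crop-mask `raster_grid`.
#' @param pixels A `plot_pixels` object.
#' @param crop_only Restrict the sum to crop pixels (default TRUE).
#' @return Volume in cubic metres.
#' @export
volume <- function(ch, mask, pixels, crop_only = TRUE) {
  stopifnot(inherits(pixels, "plot_pixels"))
  h <- ch$values[, , 1][pixels$idx]
  m <- mask$values[, , 1][pixels$idx]
  if (crop_only) h <- h[m == 1]
  pixels$A * sum(h)
}

#' Per-plot agronomic trait row
#'
#' Plot CH is the mean of `DSM - DEM` over all in-plot pixels (crop-only
#' mean available via `ch_crop_only`).
#'
#' @param scene A `uav_scene`.
#' @param pixels A `plot_pixels` object.
#' @param mask Crop-mask `raster_grid` for the scene.
#' @param ch Optional precomputed canopy-height raster.
#' @param ch_crop_only Average CH over crop pixels only (default FALSE).
#' @return Named vector: CH (m), FVC (%), VOL (m^3), c, n.
#' @export
plot_trait_features <- function(scene, pixels, mask, ch = NULL,
                                ch_crop_only = FALSE) {
  if (is.null(ch)) ch <- canopy_height(scene$dsm, scene$dem)
  h <- ch$values[, , 1][pixels$idx]
  m <- mask$values[, , 1][pixels$idx]
  chbar <- if (ch_crop_only) {
    if (any(m == 1)) mean(h[m == 1]) else 0
  } else mean(h)
  c(CH = chbar,
    FVC = fvc(mask, pixels),
    VOL = volume(ch, mask, pixels),
    c = sum(m == 1), n = pixels$n)
}
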