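# Assembly of the per-sample x per-stage feature table: band reflectances,
# vegetation/color indices, GLCM textures and agronomic traits, in tidy
# (long) and wide forms.

#' Extract every feature of one scene for all plots
#'
#' @param scene A `uav_scene`.
#' @param include_texture Compute GLCM texture features (default TRUE).
#' @param classifier `"svm"` or `"threshold"` for the crop mask behind FVC
#'   and VOL.
#' @param n_train Labeled training pixels per class for the classifier.
#' @param glcm A [glcm_config()].
#' @param convention Spectral aggregation convention, see
#'   [plot_spectral_features()].
#' @param seed Integer seed (classifier training sample and holdout).
#' @return Long data.frame: `sample_id`, `stage`, `feature`, `category`,
#'   `value`.  Attribute `classifier_accuracy` carries the mask's held-out
#'   accuracy.
#' @export
scene_features <- function(scene, include_texture = TRUE,
                           classifier = c("svm", "threshold"),
                           n_train = 500, glcm = glcm_config(),
                           convention = "mean_of_index", seed = 1L) {
  classifier <- match.arg(classifier)
  train <- sample_training_pixels(scene, n_per_class = n_train, seed = seed)
  cls <- classify_vegetation(scene$ms, train, method = classifier,
                             seed = seed)
  ch <- canopy_height(scene$dsm, scene$dem)
  tex_rasters <- if (include_texture)
    lapply(stats::setNames(scene$ms$bands, scene$ms$bands),
           function(b) texture_rasters(band_matrix(scene$ms, b), glcm))
  else NULL
  rows <- vector("list", nrow(scene$plots))
  for (i in seq_len(nrow(scene$plots))) {
    px <- extract_plot_pixels(scene, scene$plots[i, ])
    spec <- plot_spectral_features(px, convention = convention)
    tr <- plot_trait_features(scene, px, cls$mask, ch = ch)
    feat <- c(spec, tr[c("CH", "FVC", "VOL")])
    if (include_texture)
      feat <- c(feat, plot_texture_features(scene, px, glcm,
                                            rasters = tex_rasters))
    cat_of <- function(nm) {
      if (nm %in% MS_BANDS) "reflectance"
      else if (startsWith(nm, "tex_")) "texture"
      else index_category(nm)
    }
    rows[[i]] <- data.frame(
      sample_id = scene$plots$sample_id[i], stage = scene$stage,
      feature = names(feat),
      category = vapply(names(feat), cat_of, character(1)),
      value = unname(feat), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "classifier_accuracy") <- cls$accuracy
  out
}

#' Build the multi-temporal feature table
#'
#' Runs [scene_features()] for every stage of a dataset and stacks the
#' results.
#'
#' @param dataset A `uav_dataset` (or a named list of `uav_scene`s).
#' @param ... Passed to [scene_features()].
#' @return Long tidy data.frame (`sample_id`, `stage`, `feature`,
#'   `category`, `value`).
#' @export
build_feature_table <- function(dataset, ...) {
  scenes <- if (inherits(dataset, "uav_dataset")) dataset$scenes else dataset
  out <- do.call(rbind, lapply(scenes, scene_features, ...))
  rownames(out) <- NULL
  out
}

#' Write / read the tidy feature CSV
#'
#' Columns: `sample_id`, `stage`, `feature_name`, `category`, `value`.
#' @param features Long feature table.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_feature_csv <- function(features, path) {
  d <- features
  names(d)[names(d) == "feature"] <- "feature_name"
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(d)[names(d) == "feature_name"] <- "feature"
  d
}

#' Widen the feature table for modeling
#'
#' Joins the long feature table with standardized yields and sample
#' metadata.  Columns are named `<feature>__<stage>`.  Rows or columns with
#' missing values are dropped with a message (no silent NA propagation).
#'
#' @param features Long feature table from [build_feature_table()].
#' @param yields data.frame with `sample_id` and `Ym` (kg/ha), e.g. from
#'   [read_harvest_csv()].
#' @param plots Plot table (for `cultivar`, `n_rate`, `plot` grouping).
#' @return A `feature_table` list: `x` (numeric matrix, samples x feature
#'   columns), `y` (yield), `meta` (data.frame), `stages`, `features`
#'   (feature/category lookup).
#' @export
widen_feature_table <- function(features, yields, plots) {
  key <- paste0(features$feature, "__", features$stage)
  ids <- sort(unique(features$sample_id))
  cols <- unique(key)
  x <- matrix(NA_real_, length(ids), length(cols),
              dimnames = list(ids, cols))
  x[cbind(match(features$sample_id, ids), match(key, cols))] <- features$value
  bad_col <- colSums(is.na(x)) > 0
  if (any(bad_col)) {
    message("dropping ", sum(bad_col), " feature column(s) with missing ",
            "values: ", paste(utils::head(cols[bad_col], 5), collapse = ", "),
            if (sum(bad_col) > 5) ", ..." else "")
    x <- x[, !bad_col, drop = FALSE]
  }
  bad_row <- rowSums(is.na(x)) > 0
  if (any(bad_row)) {
    message("dropping ", sum(bad_row), " sample row(s) with missing values")
    x <- x[!bad_row, , drop = FALSE]
  }
  m <- plots[match(rownames(x), plots$sample_id), ]
  y <- yields$Ym[match(rownames(x), yields$sample_id)]
  if (anyNA(y)) stop("yield missing for some samples")
  lookup <- unique(features[, c("feature", "category")])
  structure(list(x = x, y = y,
                 meta = data.frame(sample_id = rownames(x),
                                   plot = m$plot, cultivar = m$cultivar,
                                   n_rate = m$n_rate,
                                   replicate = m$replicate,
                                   is_subplot = m$is_subplot,
                                   stringsAsFactors = FALSE),
                 stages = unique(features$stage),
                 features = lookup),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d feature columns (%d stages)\n",
              nrow(x$x), ncol(x$x), length(x$stages)))
  invisible(x)
}

# Column names of `ft$x` for given features x stages ("all" = every stage).
feature_columns <- function(ft, features, stages = "all") {
  st <- if (identical(stages, "all")) ft$stages else stages
  cols <- as.vector(outer(features, st, function(f, s) paste0(f, "__", s)))
  missing <- setdiff(cols, colnames(ft$x))
  if (length(missing))
    stop("feature columns not in table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  cols
}
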