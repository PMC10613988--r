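# Random-forest yield models and the four evaluation protocols:
# single-feature, exhaustive feature-combination search, per-growth-stage,
# and cross-cultivar transfer.

#' Model configuration
#'
#' @param n_trees Number of trees (default 500); all other random-forest
#'   hyperparameters stay at the library defaults (`mtry = max(p/3, 1)`,
#'   `nodesize = 5` for regression in randomForest).
#' @param train_frac Training fraction (default 2/3; the remaining third is
#'   the independent test set).
#' @param grouped Keep each main plot and its subplot on the same side of
#'   the split (default TRUE, prevents plot/subplot leakage).
#' @param seed Integer seed controlling the split and the forest.
#' @return A `model_config` list.
#' @export
model_config <- function(n_trees = 500, train_frac = 2 / 3, grouped = TRUE,
                         seed = 1L) {
  stopifnot(n_trees >= 1, train_frac > 0, train_frac < 1)
  structure(list(n_trees = as.integer(n_trees), train_frac = train_frac,
                 grouped = grouped, seed = as.integer(seed)),
            class = "model_config")
}

#' Train/test split stratified by cultivar x treatment
#'
#' Samples the test third within every cultivar x nitrogen stratum so the
#' held-out set covers the design.  With `grouped = TRUE` the sampling unit
#' is the main plot (its subplot follows it).
#'
#' @param meta Sample metadata (from a `feature_table`).
#' @param config A [model_config()].
#' @return Logical vector, TRUE = test sample.
#' @export
make_split <- function(meta, config = model_config()) {
  strata <- interaction(meta$cultivar, meta$n_rate, drop = TRUE)
  test <- logical(nrow(meta))
  withr::with_seed(config$seed, {
    for (s in levels(strata)) {
      rows <- which(strata == s)
      if (config$grouped) {
        groups <- unique(meta$plot[rows])
        n_test <- max(1L, round((1 - config$train_frac) * length(groups)))
        tg <- sample(groups, n_test)
        test[rows[meta$plot[rows] %in% tg]] <- TRUE
      } else {
        n_test <- max(1L, round((1 - config$train_frac) * length(rows)))
        test[sample(rows, n_test)] <- TRUE
      }
    }
  })
  test
}

#' Fit a random forest and evaluate on the held-out third
#'
#' @param ft A `feature_table` from [widen_feature_table()].
#' @param features Character vector of feature names (e.g. `"NDVI"`,
#'   `"CH"`).
#' @param stages `"all"` (entire growth period: the per-stage columns of
#'   every stage are concatenated) or a character vector of stage labels.
#' @param config A [model_config()].
#' @param split Optional logical test-set vector (to share one split
#'   across many subsets); defaults to [make_split()].
#' @return A `uav_eval` list: `metrics` (test-set [eval_metrics()]),
#'   `train_metrics`, `features`, `stages`, `split`, `pred` (test
#'   predictions), `obs`.
#' @export
fit_predict <- function(ft, features, stages = "all",
                        config = model_config(), split = NULL) {
  stopifnot(inherits(ft, "feature_table"), length(features) >= 1)
  cols <- feature_columns(ft, features, stages)
  if (is.null(split)) split <- make_split(ft$meta, config)
  xtr <- ft$x[!split, cols, drop = FALSE]
  xte <- ft$x[split, cols, drop = FALSE]
  if (nrow(xtr) < 10) stop("fewer than 10 training rows")
  fit <- withr::with_seed(config$seed,
    randomForest::randomForest(x = xtr, y = ft$y[!split],
                               ntree = config$n_trees))
  pred_te <- stats::predict(fit, xte)
  pred_tr <- stats::predict(fit, xtr)
  structure(list(metrics = eval_metrics(ft$y[split], pred_te),
                 train_metrics = eval_metrics(ft$y[!split], pred_tr),
                 features = features, stages = stages, split = split,
                 pred = pred_te, obs = ft$y[split]),
            class = "uav_eval")
}

#' @export
print.uav_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<uav_eval> {%s} | test R2 %.3f, RMSE %.0f kg/ha, RRMSE %.2f%%\n",
              paste(x$features, collapse = ", "), m$R2, m$RMSE, m$RRMSE))
  invisible(x)
}

#' Feature-yield correlation screen
#'
#' Pearson correlation of every (feature, stage) column with yield, with a
#' t-test of the correlation at the 0.01 significance level, plus the
#' category x stage mean of `|R|`.  Zero-variance features are reported as
#' missing.
#'
#' @param ft A `feature_table`.
#' @return List: `per_feature` (feature, stage, category, R, p, signif01),
#'   `category_stage` (category, stage, mean_abs_R), `category_mean`
#'   (category, mean_abs_R over stages).
#' @export
correlation_screen <- function(ft) {
  cols <- colnames(ft$x)
  parts <- strsplit(cols, "__", fixed = TRUE)
  feats <- vapply(parts, `[`, "", 1)
  stages <- vapply(parts, `[`, "", 2)
  R <- p <- rep(NA_real_, length(cols))
  for (i in seq_along(cols)) {
    v <- ft$x[, i]
    if (stats::sd(v) > 0) {
      ct <- stats::cor.test(v, ft$y)
      R[i] <- unname(ct$estimate); p[i] <- ct$p.value
    }
  }
  cat_lu <- ft$features$category[match(feats, ft$features$feature)]
  per <- data.frame(feature = feats, stage = stages, category = cat_lu,
                    R = R, p = p, signif01 = !is.na(p) & p < 0.01,
                    stringsAsFactors = FALSE)
  agg <- stats::aggregate(abs(R) ~ category + stage, data = per, FUN = mean,
                          na.action = stats::na.omit)
  names(agg)[3] <- "mean_abs_R"
  cm <- stats::aggregate(mean_abs_R ~ category, data = agg, FUN = mean)
  list(per_feature = per, category_stage = agg, category_mean = cm)
}

#' Enumerate non-empty feature subsets
#'
#' Subsets of `k` variables are represented as bitmasks `1 .. 2^k - 1`.
#'
#' @param k Number of variables (must be <= 25).
#' @return Integer vector of bitmasks, length `2^k - 1`.
#' @export
enumerate_subsets <- function(k) {
  stopifnot(k >= 1, k <= 25)
  seq_len(2^k - 1)
}

decode_subset <- function(mask, features) {
  features[bitwAnd(mask, bitwShiftL(1L, seq_along(features) - 1L)) != 0L]
}

#' Exhaustive feature-combination search
#'
#' Evaluates every non-empty subset of a feature family with
#' [fit_predict()] under one fixed split and seed, and ranks subsets by
#' test RRMSE (ties: fewer variables, then lexicographic feature names).
#' When `2^k - 1` exceeds `max_subsets`, a random sample of subsets of that
#' size is evaluated instead (exhaustive remains the default).
#'
#' @param ft A `feature_table`.
#' @param family Character vector of the family's feature names (k <= 25
#'   unless `max_subsets` is finite).
#' @param stages `"all"` or stage labels.
#' @param config A [model_config()].
#' @param max_subsets Budget on the number of evaluated subsets.
#' @param enumerate_only If TRUE, return the enumeration (masks and subset
#'   count) without fitting any model.
#' @return A `combination_report`: `family`, `n_subsets` (full enumeration
#'   count `2^k - 1`), `results` (data.frame: subset, size, RRMSE, R2, R,
#'   RMSE), `best` (the `uav_eval` of the top subset), and `manifest`
#'   (seed, forest settings, library version).
#' @export
combination_search <- function(ft, family, stages = "all",
                               config = model_config(), max_subsets = Inf,
                               enumerate_only = FALSE) {
  k <- length(family)
  if (k > 25 && !is.finite(max_subsets))
    stop("family of ", k, " variables: 2^k - 1 subsets is above the ",
         "combinatorial guard; pass a finite max_subsets")
  if (k > 30) stop("families above 30 variables are not supported")
  if (k <= 25) {
    masks <- enumerate_subsets(k)
    n_subsets <- length(masks)
  } else {
    masks <- NULL
    n_subsets <- 2^k - 1
  }
  if (enumerate_only)
    return(structure(list(family = family, n_subsets = n_subsets,
                          results = NULL, best = NULL),
                     class = "combination_report"))
  if (n_subsets > max_subsets)
    masks <- withr::with_seed(config$seed, {
      if (is.null(masks))
        unique(floor(stats::runif(3 * max_subsets, 1, n_subsets + 1)))[
          seq_len(max_subsets)]
      else sample(masks, max_subsets)
    })
  split <- make_split(ft$meta, config)
  res <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    sub <- decode_subset(masks[i], family)
    ev <- fit_predict(ft, sub, stages, config, split = split)
    res[[i]] <- data.frame(subset = paste(sub, collapse = "+"),
                           size = length(sub),
                           RRMSE = ev$metrics$RRMSE, R2 = ev$metrics$R2,
                           R = ev$metrics$R, RMSE = ev$metrics$RMSE,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, res)
  ord <- order(res$RRMSE, res$size, res$subset)
  res <- res[ord, ]
  rownames(res) <- NULL
  best_feats <- strsplit(res$subset[1], "+", fixed = TRUE)[[1]]
  best <- fit_predict(ft, best_feats, stages, config, split = split)
  manifest <- list(seed = config$seed, ntree = config$n_trees,
                   grouped_split = config$grouped,
                   library = "randomForest",
                   version = as.character(utils::packageVersion("randomForest")),
                   defaults = "mtry = max(floor(p/3), 1), nodesize = 5")
  structure(list(family = family, n_subsets = n_subsets, results = res,
                 best = best, manifest = manifest),
            class = "combination_report")
}

#' @export
print.combination_report <- function(x, ...) {
  cat(sprintf("<combination_report> k = %d, %d subsets enumerated\n",
              length(x$family), x$n_subsets))
  if (!is.null(x$results)) {
    cat("best: ", x$results$subset[1],
        sprintf(" (RRMSE %.2f%%, R2 %.2f)\n",
                x$results$RRMSE[1], x$results$R2[1]))
  }
  invisible(x)
}

#' Per-growth-stage evaluation
#'
#' Fits and evaluates each feature set on each single stage's columns and
#' on the entire growth period (all stages concatenated).
#'
#' @param ft A `feature_table`.
#' @param feature_sets A list of character vectors (or a single character
#'   vector, treated as one single-feature set per element).
#' @param config A [model_config()].
#' @return List: `results` (data.frame: stage, subset, RRMSE, R2, RMSE; the
#'   entire period appears as stage `"ALL"`), `stage_summary` (per-stage
#'   mean/min/max RRMSE).
#' @export
stage_analysis <- function(ft, feature_sets, config = model_config()) {
  if (!is.list(feature_sets))
    feature_sets <- as.list(feature_sets)
  split <- make_split(ft$meta, config)
  runs <- expand.grid(si = seq_along(feature_sets),
                      stage = c(ft$stages, "ALL"),
                      stringsAsFactors = FALSE)
  res <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    st <- if (runs$stage[i] == "ALL") "all" else runs$stage[i]
    fs <- feature_sets[[runs$si[i]]]
    ev <- fit_predict(ft, fs, st, config, split = split)
    res[[i]] <- data.frame(stage = runs$stage[i],
                           subset = paste(fs, collapse = "+"),
                           RRMSE = ev$metrics$RRMSE, R2 = ev$metrics$R2,
                           RMSE = ev$metrics$RMSE, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, res)
  summ <- do.call(rbind, lapply(split(res, res$stage), function(d)
    data.frame(stage = d$stage[1], mean_RRMSE = mean(d$RRMSE),
               min_RRMSE = min(d$RRMSE), max_RRMSE = max(d$RRMSE),
               stringsAsFactors = FALSE)))
  rownames(res) <- rownames(summ) <- NULL
  list(results = res, stage_summary = summ)
}

#' Cross-cultivar transfer evaluation
#'
#' Trains on all samples of one cultivar and tests on all samples of the
#' other, in both directions; reported metrics are the mean of the two
#' directions (invariant to cultivar relabeling).
#'
#' @param ft A `feature_table` with at least two cultivars.
#' @param features Character vector of feature names.
#' @param stages `"all"` or stage labels.
#' @param config A [model_config()].
#' @return List: `mean` (averaged RRMSE, R2, RMSE), `directions`
#'   (data.frame with one row per train->test direction).
#' @export
cross_cultivar <- function(ft, features, stages = "all",
                           config = model_config()) {
  cvs <- unique(ft$meta$cultivar)
  if (length(cvs) < 2) stop("cross-cultivar evaluation needs >= 2 cultivars")
  cols <- feature_columns(ft, features, stages)
  dirs <- vector("list", 0)
  for (a in cvs) for (b in setdiff(cvs, a)) {
    tr <- ft$meta$cultivar == a
    te <- ft$meta$cultivar == b
    fit <- withr::with_seed(config$seed,
      randomForest::randomForest(x = ft$x[tr, cols, drop = FALSE],
                                 y = ft$y[tr], ntree = config$n_trees))
    m <- eval_metrics(ft$y[te],
                      stats::predict(fit, ft$x[te, cols, drop = FALSE]))
    dirs[[length(dirs) + 1]] <-
      data.frame(train = a, test = b, RRMSE = m$RRMSE, R2 = m$R2,
                 RMSE = m$RMSE, R = m$R, stringsAsFactors = FALSE)
  }
  dirs <- do.call(rbind, dirs)
  list(mean = list(RRMSE = mean(dirs$RRMSE), R2 = mean(dirs$R2),
                   RMSE = mean(dirs$RMSE)),
       directions = dirs)
}

#' Sensor-subset comparison
#'
#' Compares yield prediction from the multispectral sensor alone (VIs,
#' VIs+FVC), the RGB camera alone (CIs, CIs+CH) and the fused set (all
#' spectral indices plus the three agronomic traits), running a
#' combination search within each group.
#'
#' @param ft A `feature_table`.
#' @param stages `"all"` or stage labels.
#' @param config A [model_config()].
#' @param max_subsets Budget forwarded to [combination_search()].
#' @param groups Optional named list of feature groups overriding the
#'   default sensor grouping.
#' @return List: `best` (data.frame: group, sensor, k, n_subsets, best
#'   subset and metrics), `reports` (per-group `combination_report`s).
#' @export
sensor_comparison <- function(ft, stages = "all", config = model_config(),
                              max_subsets = Inf, groups = NULL) {
  fam <- feature_families()
  if (is.null(groups))
    groups <- list(
      MS_VIs = c(fam$ComVIs, fam$REVIs),
      MS_VIs_FVC = c(fam$ComVIs, fam$REVIs, "FVC"),
      RGB_CIs = fam$CIs,
      RGB_CIs_CH = c(fam$CIs, "CH"),
      MS_RGB_all = c(fam$ComVIs, fam$REVIs, fam$CIs, fam$AgTP))
  reports <- lapply(groups, function(g)
    combination_search(ft, g, stages, config, max_subsets = max_subsets))
  best <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(group = nm,
               sensor = if (startsWith(nm, "MS_RGB")) "MS+RGB"
                        else if (startsWith(nm, "MS")) "MS" else "RGB",
               k = length(r$family), n_subsets = r$n_subsets,
               best_subset = r$results$subset[1],
               RRMSE = r$results$RRMSE[1], R2 = r$results$R2[1],
               stringsAsFactors = FALSE)
  }))
  rownames(best) <- NULL
  list(best = best, reports = reports)
}
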