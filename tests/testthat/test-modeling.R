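# toy feature table with known structure for screen/split tests
toy_table <- function(n = 48) {
  withr::with_seed(99, {
    y <- rnorm(n, 7000, 800)
    x <- cbind("POS__S1" = y, "NEG__S1" = -y,
               "NOISE__S1" = rnorm(n), "FLAT__S1" = rep(1, n))
    meta <- data.frame(
      sample_id = sprintf("P%02d", 1:n),
      plot = sprintf("P%02d", rep(1:(n / 2), each = 2)),
      cultivar = rep(c("A", "B"), each = n / 2),
      n_rate = rep(c(0, 90, 180, 270), length.out = n),
      replicate = 1, is_subplot = rep(c(FALSE, TRUE), n / 2))
  })
  structure(list(x = x, y = y, meta = meta, stages = "S1",
                 features = data.frame(
                   feature = c("POS", "NEG", "NOISE", "FLAT"),
                   category = "AgTP")),
            class = "feature_table")
}

test_that("correlation screen finds perfect, inverted and degenerate features", {
  scr <- correlation_screen(toy_table())
  per <- scr$per_feature
  expect_equal(per$R[per$feature == "POS"], 1)
  expect_equal(per$R[per$feature == "NEG"], -1)
  expect_true(is.na(per$R[per$feature == "FLAT"]))
  expect_true(per$signif01[per$feature == "POS"])
  expect_false(isTRUE(per$signif01[per$feature == "NOISE"]))
})

test_that("agronomic traits out-correlate textures on synthetic data", {
  scr <- correlation_screen(fixture_feature_table())
  cm <- scr$category_mean
  expect_gt(cm$mean_abs_R[cm$category == "AgTP"],
            cm$mean_abs_R[cm$category == "texture"])
})

test_that("the stratified grouped split reserves a third and keeps subplots with their plots", {
  ft <- fixture_feature_table()
  split <- make_split(ft$meta, model_config(seed = 2))
  expect_equal(sum(split), 32)
  # a plot and its subplot always land on the same side
  for (p in unique(ft$meta$plot))
    expect_equal(length(unique(split[ft$meta$plot == p])), 1L)
  # every cultivar x treatment stratum is represented in the test set
  strat <- interaction(ft$meta$cultivar, ft$meta$n_rate)
  expect_true(all(table(strat[split]) > 0))
  expect_identical(split, make_split(ft$meta, model_config(seed = 2)))
})

test_that("model fitting is seed-reproducible and validates its inputs", {
  ft <- fixture_feature_table()
  cfg <- model_config(seed = 5)
  a <- fit_predict(ft, c("CH", "FVC"), config = cfg)
  b <- fit_predict(ft, c("CH", "FVC"), config = cfg)
  expect_identical(a$metrics, b$metrics)
  expect_error(fit_predict(ft, "NOPE"), "not in table")
  expect_equal(length(a$pred), 32)
})

test_that("subset enumeration counts follow 2^k - 1", {
  expect_equal(length(enumerate_subsets(3)), 7)
  expect_equal(length(enumerate_subsets(10)), 1023)
  ft <- toy_table()
  # a family of one reduces to the single-feature evaluation
  cfg <- model_config(seed = 3, n_trees = 50)
  cr <- combination_search(ft, "POS", config = cfg)
  expect_equal(cr$n_subsets, 1)
  single <- fit_predict(ft, "POS", config = cfg,
                        split = make_split(ft$meta, cfg))
  expect_equal(cr$results$RRMSE, single$metrics$RRMSE)
  expect_error(combination_search(ft, sprintf("V%02d", 1:26)),
               "combinatorial guard")
})

test_that("combination search ranks by test RRMSE with documented tie-breaks", {
  ft <- fixture_feature_table()
  fam <- feature_families()
  cr <- combination_search(ft, fam$AgTP, config = model_config(seed = 4))
  expect_equal(cr$n_subsets, 7)
  expect_equal(nrow(cr$results), 7)
  expect_true(!is.unsorted(cr$results$RRMSE))
  expect_equal(cr$best$metrics$RRMSE, cr$results$RRMSE[1])
  expect_equal(cr$manifest$ntree, 500)
  # budget flag samples without changing the enumeration count
  cr2 <- combination_search(ft, fam$CIs, config = model_config(seed = 4),
                            max_subsets = 10)
  expect_equal(cr2$n_subsets, 127)
  expect_equal(nrow(cr2$results), 10)
})

test_that("stage analysis spans every stage plus the entire period", {
  ft <- fixture_feature_table()
  sa <- stage_analysis(ft, list(c("CH", "NDVI")), model_config(seed = 6))
  expect_setequal(sa$results$stage, c(ft$stages, "ALL"))
  expect_equal(nrow(sa$results), 8)
  expect_true(all(is.finite(sa$results$RRMSE)))
  expect_equal(nrow(sa$stage_summary), 8)
})

test_that("pooling stages helps on average while no-signal features do not", {
  # across the 10-seed suite, the entire-period model beats the best
  # single-stage mean for the reference subset
  tabs <- fixture_small_tables()
  stages <- tabs[[1]]$stages
  mat <- t(vapply(seq_along(tabs), function(s) {
    sa <- stage_analysis(tabs[[s]], list(c("CH", "FVC", "NDVI_RE", "EVI")),
                         model_config(seed = s))
    sa$results$RRMSE[match(c(stages, "ALL"), sa$results$stage)]
  }, numeric(8)))
  expect_lt(mean(mat[, 8]), min(colMeans(mat[, 1:7])))
  # pure-noise feature performs like the mean predictor
  ft <- toy_table()
  cfg <- model_config(seed = 7, n_trees = 100)
  split <- make_split(ft$meta, cfg)
  ev <- fit_predict(ft, "NOISE", config = cfg, split = split)
  base <- eval_metrics(ft$y[split], rep(mean(ft$y[!split]), sum(split)))
  expect_lt(abs(ev$metrics$RRMSE - base$RRMSE), 0.35 * base$RRMSE)
})

test_that("cross-cultivar transfer averages both directions and needs two cultivars", {
  ft <- fixture_feature_table()
  cc <- cross_cultivar(ft, c("CH", "FVC", "NDVI_RE", "EVI"),
                       config = model_config(seed = 8))
  expect_equal(nrow(cc$directions), 2)
  expect_equal(cc$mean$RRMSE, mean(cc$directions$RRMSE))
  one <- ft
  one$meta$cultivar <- "A"
  expect_error(cross_cultivar(one, "CH"), "2 cultivars")
})

test_that("sensor groups carry the documented enumeration sizes", {
  ft <- fixture_small_tables()[[1]]
  sx <- sensor_comparison(ft, config = model_config(seed = 9),
                          max_subsets = 5)
  expect_equal(sx$best$n_subsets[match(
    c("MS_VIs", "MS_VIs_FVC", "RGB_CIs", "RGB_CIs_CH", "MS_RGB_all"),
    sx$best$group)], c(511, 1023, 127, 255, 524287))
  expect_setequal(unique(sx$best$sensor), c("MS", "RGB", "MS+RGB"))
})
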