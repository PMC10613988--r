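grid_of <- function(m, res = 0.1) raster_grid(m, res = res)

test_that("canopy height is the clipped DSM-DEM difference", {
  dem <- grid_of(matrix(50, 5, 5))
  expect_true(all(canopy_height(dem, dem)$values == 0))
  dsm <- grid_of(matrix(50.8, 5, 5))
  expect_true(all(abs(canopy_height(dsm, dem)$values - 0.8) < 1e-12))
  below <- grid_of(matrix(49.9, 5, 5))
  expect_true(all(canopy_height(below, dem)$values == 0))
  shifted <- raster_grid(matrix(50, 5, 5), res = 0.1, origin = c(0.1, 0))
  expect_error(canopy_height(dsm, shifted), "grid mismatch")
})

test_that("FVC and VOL follow their defining identities", {
  mask <- grid_of(matrix(c(rep(1, 625), rep(0, 2500 - 625)), 50, 50))
  px <- make_plot_pixels(matrix(0.5, 2500, 5,
                                dimnames = list(NULL, c("B", "G", "R", "RE", "NIR"))),
                         A = 0.01, idx = 1:2500)
  expect_equal(fvc(mask, px), 25)
  full <- grid_of(matrix(1, 50, 50))
  empty <- grid_of(matrix(0, 50, 50))
  expect_equal(fvc(full, px), 100)
  expect_equal(fvc(empty, px), 0)
  # uniform height over c crop pixels
  ch <- grid_of(matrix(0.6, 50, 50))
  expect_equal(volume(ch, mask, px), 625 * 0.01 * 0.6)
  expect_equal(volume(ch, empty, px), 0)
})

test_that("VOL matches a naive pixel loop and the mean-height identity", {
  withr::with_seed(21, {
    h <- matrix(runif(100, 0, 1), 10, 10)
    m <- matrix(rbinom(100, 1, 0.5), 10, 10)
    ch <- grid_of(h); mask <- grid_of(m)
    px <- make_plot_pixels(matrix(0.5, 100, 5,
                                  dimnames = list(NULL, c("B", "G", "R", "RE", "NIR"))),
                           A = 0.01, idx = 1:100)
    vol_loop <- 0
    for (i in 1:100) if (m[i] == 1) vol_loop <- vol_loop + 0.01 * h[i]
    expect_equal(volume(ch, mask, px), vol_loop)
    cc <- sum(m == 1)
    expect_equal(volume(ch, mask, px) / (cc * 0.01), mean(h[m == 1]))
    # monotonicity: raising one crop pixel raises VOL
    h2 <- h; h2[which(m == 1)[1]] <- h2[which(m == 1)[1]] + 0.5
    expect_gt(volume(grid_of(h2), mask, px), volume(ch, mask, px))
  })
})

test_that("the classifier separates crop from soil and rejects one-class training", {
  ds <- fixture_dataset()
  sc <- ds$scenes[["HS"]]
  train <- sample_training_pixels(sc, n_per_class = 200, seed = 1)
  cls <- classify_vegetation(sc$ms, train, seed = 1)
  expect_gte(cls$accuracy, 0.98)
  one <- train[train$class == "crop", ]
  expect_error(classify_vegetation(sc$ms, one), "both crop and soil")
  # threshold fallback also separates this scene
  thr <- classify_vegetation(sc$ms, train, method = "threshold", seed = 1)
  expect_gte(thr$accuracy, 0.9)
})

test_that("FVC recovered by classification is within 3 points of the latent cover", {
  ds <- fixture_dataset()
  for (st in c("BS", "MFS")) {
    sc <- ds$scenes[[st]]
    train <- sample_training_pixels(sc, n_per_class = 300, seed = 2)
    cls <- classify_vegetation(sc$ms, train, seed = 2)
    mains <- sc$plots[!sc$plots$is_subplot, ]
    tr <- ds$latents$traits[ds$latents$traits$stage == st, ]
    for (i in seq_len(nrow(mains))) {
      px <- extract_plot_pixels(sc, mains[i, ])
      est <- fvc(cls$mask, px)
      expect_lt(abs(est - 100 * tr$cover[tr$plot == mains$plot[i]]), 3)
    }
  }
})

test_that("plot canopy height recovers a known closed canopy within 2 cm", {
  des <- mini_design()
  lat <- simulate_latents(des, seed = 31)
  lat$traits$cover <- 1
  lat$traits$height <- 0.6
  sc <- render_scene(des, lat, "HS", seed = 31)
  ch <- canopy_height(sc$dsm, sc$dem)
  mains <- sc$plots[!sc$plots$is_subplot, ]
  for (i in seq_len(nrow(mains))) {
    px <- extract_plot_pixels(sc, mains[i, ])
    expect_lt(abs(mean(ch$values[, , 1][px$idx]) - 0.6), 0.02)
  }
})

test_that("recovered CH trajectories track the true height trajectories", {
  ds <- fixture_dataset()
  mains <- ds$plots[!ds$plots$is_subplot, ]
  rec <- sapply(ds$design$stages, function(st) {
    ch <- canopy_height(ds$scenes[[st]]$dsm, ds$scenes[[st]]$dem)
    vapply(seq_len(nrow(mains)), function(i) {
      px <- extract_plot_pixels(ds$scenes[[st]], mains[i, ])
      mean(ch$values[, , 1][px$idx])
    }, 0)
  })
  tru <- sapply(ds$design$stages, function(st) {
    tr <- ds$latents$traits[ds$latents$traits$stage == st, ]
    tr$height[match(mains$plot, tr$plot)]
  })
  rho <- vapply(seq_len(nrow(mains)),
                function(i) cor(rec[i, ], tru[i, ], method = "spearman"), 0)
  expect_gt(mean(rho), 0.95)
})
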