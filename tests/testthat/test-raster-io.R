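test_that("rasters round-trip through TIFF: reflectance bit-identical, elevation within packing tolerance", {
  dir <- withr::local_tempdir()
  ds <- local({
    des <- mini_design(stages = c("HS", "MS"))
    simulate_dataset(des, seed = 5)
  })
  f <- write_raster(ds$scenes[[1]]$ms, file.path(dir, "ms.tif"))
  back <- read_raster(f)
  expect_identical(back$values, ds$scenes[[1]]$ms$values)
  expect_identical(back$bands, ds$scenes[[1]]$ms$bands)
  f2 <- write_raster(ds$scenes[[1]]$dsm, file.path(dir, "dsm.tif"))
  expect_lt(max(abs(read_raster(f2)$values - ds$scenes[[1]]$dsm$values)), 1e-4)
})

test_that("a written dataset has the expected file inventory and loads back", {
  dir <- withr::local_tempdir()
  ds <- fixture_dataset()
  write_dataset(ds, dir)
  tifs <- list.files(dir, pattern = "\\.tif$")
  expect_equal(length(tifs), 7 * 3 + 1)
  harvest <- read.csv(file.path(dir, "harvest.csv"))
  expect_equal(nrow(harvest), 96)

  sc <- load_stage(dir, "HS")
  expect_setequal(sc$ms$bands, c("B", "G", "R", "RE", "NIR"))
  expect_identical(sc$ms$values, ds$scenes[["HS"]]$ms$values)
  expect_equal(nrow(sc$plots), 96)

  plots2 <- read_plots_geojson(file.path(dir, "plots.geojson"))
  expect_equal(plots2$sample_id, ds$plots$sample_id)
  expect_equal(plots2$xmin, ds$plots$xmin)
})

test_that("mis-registered or out-of-range layers are rejected, not resampled", {
  dir <- withr::local_tempdir()
  des <- mini_design(stages = c("HS", "MS"))
  ds <- simulate_dataset(des, seed = 6)
  write_dataset(ds, dir)
  # shift the DSM grid by one pixel
  dsm <- ds$scenes[["HS"]]$dsm
  dsm$origin <- dsm$origin + c(dsm$res, 0)
  write_raster(dsm, file.path(dir, "dsm_HS.tif"))
  expect_error(load_stage(dir, "HS"), "grid mismatch")
  write_raster(ds$scenes[["HS"]]$dsm, file.path(dir, "dsm_HS.tif"))
  # corrupt one reflectance value
  ms <- ds$scenes[["HS"]]$ms
  ms$values[1, 1, 5] <- 1.5
  write_raster(ms, file.path(dir, "ms_HS.tif"))
  expect_error(load_stage(dir, "HS"), "band NIR.*1 pixel")
})

test_that("pixel extraction follows the pixel-center rule at 2 cm resolution", {
  des <- experiment_design(cultivars = "A", n_rates = 0, replicates = 1,
                           plot_size = c(3, 13.7), ground_resolution = 0.02)
  lat <- simulate_latents(des, seed = 1)
  sc <- render_scene(des, lat, "HS", seed = 1)
  mains <- sc$plots[!sc$plots$is_subplot, ]
  subs <- sc$plots[sc$plots$is_subplot, ]
  expect_equal(extract_plot_pixels(sc, mains[1, ])$n, 150 * 685)
  expect_equal(extract_plot_pixels(sc, subs[1, ])$n, 50 * 50)
  outside <- mains[1, ]
  outside$xmin <- 100; outside$xmax <- 101
  expect_error(extract_plot_pixels(sc, outside), "no pixel centers")
})

test_that("extraction is invariant to translating raster and polygon together", {
  des <- mini_design(stages = c("HS", "MS"))
  lat <- simulate_latents(des, seed = 9)
  sc <- render_scene(des, lat, "HS", seed = 9)
  g <- sc$plots[1, ]
  px1 <- extract_plot_pixels(sc, g)
  shift <- c(12.34, -5.6)
  sc2 <- sc
  sc2$ms$origin <- sc$ms$origin + shift
  sc2$rgb$origin <- sc$rgb$origin + shift
  sc2$dsm$origin <- sc$dsm$origin + shift
  sc2$dem$origin <- sc$dem$origin + shift
  g2 <- g
  g2$xmin <- g$xmin + shift[1]; g2$xmax <- g$xmax + shift[1]
  g2$ymin <- g$ymin + shift[2]; g2$ymax <- g$ymax + shift[2]
  px2 <- extract_plot_pixels(sc2, g2)
  expect_identical(px1$idx, px2$idx)
  expect_identical(px1$ms, px2$ms)
})

test_that("per-plot pixel counts never exceed the raster and plots stay disjoint", {
  ds <- fixture_dataset()
  sc <- ds$scenes[["JS"]]
  mains <- sc$plots[!sc$plots$is_subplot, ]
  counts <- vapply(seq_len(nrow(mains)),
                   function(i) extract_plot_pixels(sc, mains[i, ])$n, 0L)
  expect_lte(sum(counts), prod(dim(sc$ms)[1:2]))
})
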