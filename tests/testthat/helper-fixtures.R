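# Shared fixtures, generated once per test run and memoized.  Problem sizes
# are the package's tested scale: 0.1 m ground resolution (the coarsest that
# divides the 3 x 13.7 m plots), the full 48-plot design for the main
# fixture, and a 3-replicate design (24 plots, 48 samples) for the 10-seed
# stochastic suite.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

test_design <- function(...) experiment_design(ground_resolution = 0.1, ...)

# small 2-plot design for renderer-level tests
mini_design <- function(stages = c("JS", "BS", "HS", "IFS", "MFS", "LFS", "MS"))
  experiment_design(cultivars = "A", n_rates = c(0, 180), replicates = 1,
                    plot_size = c(2, 3), subplot_size = c(1, 1),
                    stages = stages, ground_resolution = 0.1)

fixture_dataset <- function() memo("dataset", {
  simulate_dataset(test_design(), seed = 3)
})

fixture_yields <- function() {
  h <- fixture_dataset()$harvest
  data.frame(sample_id = h$sample_id,
             Ym = standardize_yield(h$grain_weight_kg, h$area_m2,
                                    h$moisture_pct / 100))
}

fixture_feature_table <- function() memo("feature_table", {
  ds <- fixture_dataset()
  feats <- build_feature_table(ds, include_texture = TRUE, n_train = 300,
                               seed = 3)
  widen_feature_table(feats, fixture_yields(), ds$plots)
})

fixture_long_features <- function() memo("long_features", {
  build_feature_table(fixture_dataset(), include_texture = TRUE,
                      n_train = 300, seed = 3)
})

# ten reduced-design feature tables (no textures) for stochastic properties
fixture_small_tables <- function() memo("small_tables", {
  des <- experiment_design(replicates = 3, ground_resolution = 0.1)
  lapply(1:10, function(s) {
    ds <- simulate_dataset(des, seed = s)
    feats <- build_feature_table(ds, include_texture = FALSE, n_train = 200,
                                 seed = s)
    yld <- data.frame(
      sample_id = ds$harvest$sample_id,
      Ym = standardize_yield(ds$harvest$grain_weight_kg, ds$harvest$area_m2,
                             ds$harvest$moisture_pct / 100))
    widen_feature_table(feats, yld, ds$plots)
  })
})

# hand-built plot_pixels for unit tests of the aggregation functions
make_plot_pixels <- function(ms, rgb = NULL, dsm = NULL, dem = NULL,
                             A = 0.01, idx = NULL) {
  n <- nrow(ms)
  if (is.null(rgb)) rgb <- matrix(85, n, 3,
                                  dimnames = list(NULL, c("Rdn", "Gdn", "Bdn")))
  structure(list(sample_id = "T01", n = n, A = A,
                 idx = if (is.null(idx)) seq_len(n) else idx,
                 ms = ms, rgb = rgb,
                 dsm = if (is.null(dsm)) rep(0, n) else dsm,
                 dem = if (is.null(dem)) rep(0, n) else dem),
            class = "plot_pixels")
}

ms_row <- function(B, G, R, RE, NIR)
  matrix(c(B, G, R, RE, NIR), 1, dimnames = list(NULL, c("B", "G", "R", "RE", "NIR")))

# brute-force per-window texture oracle (independent of the compiled path)
oracle_texture <- function(band, config) {
  q <- quantize_band(band, config$levels)
  h <- (config$window - 1) / 2
  out <- lapply(uavyield:::TEXTURE_NAMES,
                function(f) matrix(NA_real_, nrow(band), ncol(band)))
  names(out) <- uavyield:::TEXTURE_NAMES
  for (r in seq_len(nrow(band))) for (c in seq_len(ncol(band))) {
    rows <- max(1, r - h):min(nrow(band), r + h)
    cols <- max(1, c - h):min(ncol(band), c + h)
    P <- glcm(q[rows, cols, drop = FALSE], config)
    tv <- texture_vector(P)
    for (f in names(out)) out[[f]][r, c] <- tv[[f]]
  }
  out
}
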