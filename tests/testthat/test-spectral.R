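test_that("index bank reproduces hand-computed values", {
  ix <- index_bank(R = 0.1, G = 0.2, B = 0.05, RE = 0.4, NIR = 0.5,
                   r = 1 / 3, g = 1 / 3, b = 1 / 3)
  expect_equal(unname(ix[1, "NDVI"]), 0.4 / 0.6)
  expect_equal(unname(ix[1, "NDVI_RE"]), 0.1 / 0.9)
  expect_equal(unname(ix[1, "CI_RE"]), 0.25)
  expect_equal(unname(ix[1, "SAVI"]), 1.5 * 0.4 / 0.9)
  expect_equal(unname(ix[1, "EVI"]), 2.5 * 0.4 / (0.5 + 0.6 - 0.375 + 1))
  expect_equal(unname(ix[1, "EVI2"]), 2.5 * 0.4 / (0.5 + 0.24 + 1))
  # gray point: all color indices vanish
  expect_equal(unname(ix[1, c("ExG", "NDI", "GLI", "NDYI")]), rep(0, 4))
  expect_equal(unname(ix[1, "ExR"]), 1.4 / 3 - 1 / 3)
  expect_equal(unname(ix[1, "ExGR"]), (3 - 2.4 - 1) / 3)
  # NIR = R makes NDVI zero
  expect_equal(unname(index_bank(0.3, 0.2, 0.1, 0.25, 0.3,
                                 0.4, 0.4, 0.2)[1, "NDVI"]), 0)
})

test_that("bounded indices stay within [-1, 1] over random valid spectra", {
  withr::with_seed(42, {
    n <- 2000
    R <- runif(n); G <- runif(n); B <- runif(n)
    RE <- runif(n); NIR <- runif(n)
    dn <- matrix(runif(3 * n, 1, 255), n, 3)
    nd <- dn / rowSums(dn)
    ix <- index_bank(R, G, B, RE, NIR, nd[, 1], nd[, 2], nd[, 3])
    for (f in c("NDVI", "GNDVI", "NDVI_RE", "NDI", "GLI", "NDYI"))
      expect_true(all(abs(ix[, f]) <= 1 + 1e-12), info = f)
  })
})

test_that("EVI and EVI2 agree for vegetation spectra near the two-band design condition", {
  # EVI2 replaces the blue term via B ~ 0.48 R (its published design
  # assumption); within +/-20% of that relation the two indices agree to
  # 0.05 -- a transcription check of both formulas
  withr::with_seed(7, {
    n <- 500
    NIR <- runif(n, 0.3, 0.7); R <- runif(n, 0.02, 0.15)
    B <- 0.48 * R * runif(n, 0.8, 1.2); G <- runif(n, 0.05, 0.15)
    RE <- runif(n, 0.2, 0.4)
    ix <- index_bank(R, G, B, RE, NIR, 1 / 3, 1 / 3, 1 / 3)
    expect_lt(max(abs(ix[, "EVI"] - ix[, "EVI2"])), 0.05)
  })
})

test_that("plot aggregation is mean-of-index and order-invariant", {
  # two pixels engineered to NDVI 0.2 and 0.6
  ms <- rbind(ms_row(0.05, 0.1, 0.4, 0.45, 0.6),    # NDVI = 0.2
              ms_row(0.05, 0.1, 0.1, 0.3, 0.4))     # NDVI = 0.6
  px <- make_plot_pixels(ms)
  f <- plot_spectral_features(px)
  expect_equal(unname(f["NDVI"]), 0.4)
  px_rev <- make_plot_pixels(ms[2:1, ])
  expect_equal(plot_spectral_features(px_rev), f)
  # constant plot equals the single-pixel index
  pxc <- make_plot_pixels(ms[c(1, 1), ])
  f1 <- index_bank(0.4, 0.1, 0.05, 0.45, 0.6,
                   1 / 3, 1 / 3, 1 / 3)[1, "NDVI"]
  expect_equal(unname(plot_spectral_features(pxc)["NDVI"]), unname(f1))
})

test_that("zero denominators yield the NA sentinel and are excluded from plot means", {
  # g + r - b = 0 makes VARI undefined for the first pixel
  rgb <- rbind(c(64, 32, 96), c(120, 150, 60))
  colnames(rgb) <- c("Rdn", "Gdn", "Bdn")
  ms <- rbind(ms_row(0.1, 0.1, 0.1, 0.2, 0.4),
              ms_row(0.1, 0.1, 0.1, 0.2, 0.4))
  px <- make_plot_pixels(ms, rgb = rgb)
  f <- plot_spectral_features(px)
  nd <- rgb[2, ] / sum(rgb[2, ])
  expect_equal(unname(f["VARI"]),
               unname((nd[2] - nd[1]) / (nd[2] + nd[1] - nd[3])))
  # with every pixel degenerate the plot value is missing
  px_all <- make_plot_pixels(ms, rgb = rgb[c(1, 1), ])
  expect_true(is.na(plot_spectral_features(px_all)["VARI"]))
})

test_that("plot NDVI is higher mid-season than at maturity on rendered scenes", {
  ds <- fixture_dataset()
  mains <- ds$plots[!ds$plots$is_subplot, ][1:8, ]
  for (i in seq_len(nrow(mains))) {
    f_mid <- plot_spectral_features(
      extract_plot_pixels(ds$scenes[["IFS"]], mains[i, ]))
    f_mat <- plot_spectral_features(
      extract_plot_pixels(ds$scenes[["MS"]], mains[i, ]))
    expect_gt(f_mid["NDVI"], f_mat["NDVI"])
  }
})
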