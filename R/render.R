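# Raster renderer: turns latent traits into co-registered multispectral,
# RGB and DSM rasters over the designed field layout.
#
# Soil/vegetation assignment thresholds a spatially correlated Gaussian
# field at the per-plot cover quantile, so the realized vegetation-pixel
# fraction matches the latent cover to within 1/n while the pattern stays
# patchy enough for texture features to be informative.

#' Parameters of the scene renderer
#'
#' @param soil Named soil reflectance (B, G, R, RE, NIR); a flat, bright
#'   spectrum typical of dry loam.
#' @param veg_base,veg_chl,veg_sen Named per-band coefficients of the linear
#'   vegetation spectral model
#'   `rho_band = base + chl_coef * chl + sen_coef * senescence`:
#'   NIR rises with the chlorophyll proxy and falls with senescence, red the
#'   reverse.
#' @param corr_length Correlation length of the Gaussian pattern fields, m.
#' @param spectral_mod Relative amplitude of the smooth within-plot
#'   modulation of the chlorophyll proxy (creates realistic texture).
#' @param height_mod Relative amplitude of smooth within-plot height
#'   variation.
#' @param band_noise_sd Per-pixel reflectance noise SD.
#' @param surface_noise_sd DSM surface noise SD, m (default 1 cm).
#' @param rgb_gain Gain applied to visible reflectance before 8-bit
#'   quantization of the RGB digital numbers.
#' @param dem_base,dem_slope_x,dem_slope_y Bare-soil elevation plane:
#'   `z = base + sx * x + sy * y` (a gentle documented slope).
#' @return A `render_params` list.
#' @export
render_params <- function(soil = c(B = 0.10, G = 0.14, R = 0.18,
                                   RE = 0.21, NIR = 0.23),
                          veg_base = c(B = 0.03, G = 0.08, R = 0.06,
                                       RE = 0.15, NIR = 0.25),
                          veg_chl = c(B = 0.00, G = 0.04, R = -0.04,
                                      RE = 0.25, NIR = 0.40),
                          veg_sen = c(B = 0.05, G = 0.04, R = 0.18,
                                      RE = -0.08, NIR = -0.10),
                          corr_length = 0.10,
                          spectral_mod = 0.15,
                          height_mod = 0.10,
                          band_noise_sd = 0.008,
                          surface_noise_sd = 0.01,
                          rgb_gain = 2.2,
                          dem_base = 50, dem_slope_x = 0.002,
                          dem_slope_y = 0.004) {
  structure(as.list(environment()), class = "render_params")
}

MS_BANDS <- c("B", "G", "R", "RE", "NIR")

# Standardized Gaussian random field with approximate correlation length
# `sigma_px` pixels (white noise blurred by a separable Gaussian kernel).
gaussian_field <- function(nr, nc, sigma_px) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma_px >= 0.5) {
    half <- max(1L, ceiling(3 * sigma_px))
    k <- stats::dnorm(seq(-half, half), sd = sigma_px)
    k <- k / sum(k)
    # reflective padding keeps field variance stable at the edges
    conv1 <- function(m, kern) {
      h <- (length(kern) - 1L) / 2L
      idx <- c(rev(seq_len(h)), seq_len(nrow(m)),
               nrow(m) - seq_len(h) + 1L)
      mp <- m[idx, , drop = FALSE]
      out <- matrix(0, nrow(m), ncol(m))
      for (j in seq_along(kern))
        out <- out + kern[j] * mp[j:(j + nrow(m) - 1L), , drop = FALSE]
      out
    }
    z <- conv1(z, k)
    z <- t(conv1(t(z), k))
  }
  (z - mean(z)) / stats::sd(z)
}

# Row/col index ranges of pixels whose centers fall inside a rectangle.
rect_pixel_range <- function(grid, xmin, ymin, xmax, ymax) {
  ctr <- pixel_centers(grid)
  list(rows = which(ctr$y > ymin & ctr$y < ymax),
       cols = which(ctr$x > xmin & ctr$x < xmax))
}

#' Render one growth-stage scene
#'
#' @param design An [experiment_design()].
#' @param latents Output of [simulate_latents()] (same design and seed).
#' @param stage Stage label, one of `design$stages`.
#' @param seed Integer seed (the layout seed; per-stage randomness is
#'   derived from it and the stage index).
#' @param params A [render_params()] list.
#' @return A `uav_scene`: raster grids `ms` (5 reflectance bands),
#'   `rgb` (digital numbers 0-255), `dsm`, `dem`, the plot table `plots`,
#'   the stage label, and `truth` (ground-truth vegetation mask and
#'   realized per-plot cover).
#' @export
render_scene <- function(design, latents, stage, seed = 1L,
                         params = render_params()) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(latents, "latent_traits"))
  si <- match(stage, design$stages)
  if (is.na(si)) stop("unknown stage label: ", stage)
  plots <- build_design(design, seed = seed)
  mains <- plots[!plots$is_subplot, ]
  res <- design$ground_resolution
  ext <- field_extent(design)
  nr <- as.integer(round(ext[["height"]] / res))
  nc <- as.integer(round(ext[["width"]] / res))
  origin <- c(0, unname(ext["height"]))
  p <- params
  tr <- latents$traits[latents$traits$stage == stage, ]
  tr <- tr[match(mains$plot, tr$plot), ]

  tmpl <- raster_grid(array(0, c(nr, nc, 1)), res, origin)
  ctr <- pixel_centers(tmpl)
  dem_m <- p$dem_base + p$dem_slope_x * matrix(ctr$x, nr, nc, byrow = TRUE) +
    p$dem_slope_y * matrix(ctr$y, nr, nc)

  withr::with_seed(seed + 1000L * si, {
    fld_mask <- gaussian_field(nr, nc, p$corr_length / res)
    fld_mod <- gaussian_field(nr, nc, p$corr_length / res)
    mask <- matrix(0, nr, nc)
    chl_px <- matrix(0, nr, nc)
    sen_px <- matrix(0, nr, nc)
    hgt_px <- matrix(0, nr, nc)
    realized <- numeric(nrow(mains))
    for (i in seq_len(nrow(mains))) {
      rr <- rect_pixel_range(tmpl, mains$xmin[i], mains$ymin[i],
                             mains$xmax[i], mains$ymax[i])
      f <- fld_mask[rr$rows, rr$cols]
      veg <- if (tr$cover[i] <= 0) array(FALSE, dim(f)) else
        f <= stats::quantile(f, tr$cover[i], names = FALSE)
      mask[rr$rows, rr$cols] <- veg * 1
      realized[i] <- mean(veg)
      m <- fld_mod[rr$rows, rr$cols]
      chl_px[rr$rows, rr$cols] <-
        pmin(1, pmax(0, tr$chl[i] * (1 + p$spectral_mod * m)))
      sen_px[rr$rows, rr$cols] <- tr$senescence[i]
      hgt_px[rr$rows, rr$cols] <-
        pmax(0, tr$height[i] * (1 + p$height_mod * m)) * veg
    }
    ms <- array(0, c(nr, nc, 5))
    for (b in seq_along(MS_BANDS)) {
      bn <- MS_BANDS[b]
      veg_refl <- p$veg_base[[bn]] + p$veg_chl[[bn]] * chl_px +
        p$veg_sen[[bn]] * sen_px
      soil_refl <- p$soil[[bn]] * (1 + 0.05 * fld_mod)
      refl <- ifelse(mask == 1, veg_refl, soil_refl) +
        stats::rnorm(nr * nc, 0, p$band_noise_sd)
      ms[, , b] <- pmin(1, pmax(0, refl))
    }
    dsm_m <- dem_m + hgt_px + stats::rnorm(nr * nc, 0, p$surface_noise_sd)
    rgb <- array(0, c(nr, nc, 3))
    for (b in seq_len(3)) {
      vis <- ms[, , match(c("R", "G", "B")[b], MS_BANDS)]
      rgb[, , b] <- round(pmin(1, vis * p$rgb_gain) * 255)
    }
  })

  structure(list(
    stage = stage,
    ms = raster_grid(unit16_round(ms), res, origin, MS_BANDS),
    rgb = raster_grid(rgb, res, origin, c("Rdn", "Gdn", "Bdn")),
    dsm = raster_grid(dsm_m, res, origin, "dsm"),
    dem = raster_grid(dem_m, res, origin, "dem"),
    plots = plots,
    truth = list(veg_mask = raster_grid(mask, res, origin, "veg"),
                 realized_cover = data.frame(plot = mains$plot,
                                             cover = realized))),
    class = "uav_scene")
}

#' @export
print.uav_scene <- function(x, ...) {
  cat(sprintf("<uav_scene> stage %s: %d x %d px, %d plots (+%d subplots)\n",
              x$stage, dim(x$ms)[1], dim(x$ms)[2],
              sum(!x$plots$is_subplot), sum(x$plots$is_subplot)))
  invisible(x)
}
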