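# End-to-end synthetic dataset: scenes for all stages, harvest records,
# and the on-disk layout consumed by the loading functions.

#' Simulate harvest records
#'
#' Each sample (main plot and subplot) gets a grain weight, harvested area
#' and grain moisture such that standardizing to 13% moisture recovers the
#' latent yield.  Subplots share the parent plot's deterministic yield but
#' draw independent multiplicative noise.
#'
#' @param design An [experiment_design()].
#' @param latents Output of [simulate_latents()].
#' @param seed Integer seed (use the dataset seed).
#' @return data.frame: `sample_id`, `grain_weight_kg`, `area_m2`,
#'   `moisture_pct`, plus the latent truth `yield_true` (kg/ha at 13%
#'   moisture) for validation.
#' @export
simulate_harvest <- function(design, latents, seed = 1L) {
  plots <- build_design(design, seed = seed)
  py <- latents$plot_yield
  cv <- latents$params$yield_cv
  withr::with_seed(seed + 7L, {
    ydet <- py$yield_det[match(plots$plot, py$plot)]
    ypot <- py$yield_potential[match(plots$plot, py$plot)]
    noise <- stats::rnorm(nrow(plots), 0, cv)
    ytrue <- ifelse(plots$is_subplot, pmax(ydet * (1 + noise), 0), ypot)
    moisture <- stats::runif(nrow(plots), 11, 16)   # percent
    area <- (plots$xmax - plots$xmin) * (plots$ymax - plots$ymin)
    grain <- ytrue * area * (1 - 0.13) / (10000 * (1 - moisture / 100))
  })
  data.frame(sample_id = plots$sample_id,
             grain_weight_kg = grain, area_m2 = area,
             moisture_pct = moisture, yield_true = ytrue,
             stringsAsFactors = FALSE)
}

#' Simulate the full multi-temporal dataset
#'
#' Builds the layout, simulates latent traits, renders one scene per growth
#' stage and draws harvest records.  Byte-identical for a given seed and
#' configuration.
#'
#' @param design An [experiment_design()].
#' @param seed Integer seed for every source of randomness.
#' @param latent_params,render_params Generator parameter lists.
#' @return A `uav_dataset`: `design`, `plots`, `latents`, `scenes` (named
#'   list by stage), `harvest`.
#' @export
simulate_dataset <- function(design = experiment_design(), seed = 1L,
                             latent_params = uavyield::latent_params(),
                             render_params = uavyield::render_params()) {
  latents <- simulate_latents(design, seed = seed, params = latent_params)
  scenes <- lapply(design$stages, function(st)
    render_scene(design, latents, st, seed = seed, params = render_params))
  names(scenes) <- design$stages
  harvest <- simulate_harvest(design, latents, seed = seed)
  structure(list(design = design, plots = scenes[[1]]$plots,
                 latents = latents, scenes = scenes, harvest = harvest),
            class = "uav_dataset")
}

#' Write a dataset to a directory
#'
#' Layout: `ms_<stage>.tif`, `rgb_<stage>.tif`, `dsm_<stage>.tif` per stage,
#' one `dem.tif`, `plots.geojson`, `harvest.csv` (columns `sample_id`,
#' `grain_weight_kg`, `area_m2`, `moisture_pct`).
#'
#' @param dataset A `uav_dataset` from [simulate_dataset()].
#' @param out_dir Output directory (created if missing).
#' @return Character vector of files written, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "uav_dataset"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    stop("cannot write dataset: directory not writable: ", out_dir)
  files <- character(0)
  for (st in names(dataset$scenes)) {
    sc <- dataset$scenes[[st]]
    files <- c(files,
               write_raster(sc$ms, file.path(out_dir, paste0("ms_", st, ".tif"))),
               write_raster(sc$rgb, file.path(out_dir, paste0("rgb_", st, ".tif")),
                            type = "uint8"),
               write_raster(sc$dsm, file.path(out_dir, paste0("dsm_", st, ".tif"))))
  }
  files <- c(files,
             write_raster(dataset$scenes[[1]]$dem, file.path(out_dir, "dem.tif")))
  write_plots_geojson(dataset$plots, file.path(out_dir, "plots.geojson"))
  harvest <- dataset$harvest[, c("sample_id", "grain_weight_kg",
                                 "area_m2", "moisture_pct")]
  utils::write.csv(harvest, file.path(out_dir, "harvest.csv"),
                   row.names = FALSE)
  invisible(c(files, file.path(out_dir, c("plots.geojson", "harvest.csv"))))
}
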