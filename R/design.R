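# Field-trial design: a factorial cultivar x nitrogen-rate layout with
# replicate rows, each main plot carrying one interior 1 x 1 m subplot.

#' Describe the field experiment
#'
#' Defaults emulate a winter-wheat trial: two cultivars, four nitrogen rates
#' (kg N/ha), six replicates (48 main plots of 3 x 13.7 m, each with a
#' 1 x 1 m subplot, 96 samples in total) and seven flight dates from
#' jointing (JS) to maturity (MS).
#'
#' @param cultivars Character vector of cultivar identifiers.
#' @param n_rates Numeric nitrogen rates in kg/ha.
#' @param replicates Number of replicate blocks.
#' @param plot_size Main-plot `(width, length)` in metres.
#' @param subplot_size Subplot `(width, length)` in metres.
#' @param stages Ordered growth-stage labels, one per flight.
#' @param ground_resolution Pixel size in m/pixel.  Plot and alley
#'   dimensions must be whole multiples of it.
#' @param alley Gap between neighbouring plots and around the field margin, m.
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(cultivars = c("JYM1", "YM20"),
                              n_rates = c(0, 90, 180, 270),
                              replicates = 6,
                              plot_size = c(3, 13.7),
                              subplot_size = c(1, 1),
                              stages = c("JS", "BS", "HS", "IFS",
                                         "MFS", "LFS", "MS"),
                              ground_resolution = 0.02,
                              alley = 0.5) {
  stopifnot(length(cultivars) >= 1, length(n_rates) >= 1, replicates >= 1,
            length(plot_size) == 2, length(subplot_size) == 2,
            all(plot_size > 0), all(subplot_size > 0),
            ground_resolution > 0, alley >= 0)
  if (anyDuplicated(stages)) stop("stage labels must be unique")
  if (anyDuplicated(cultivars)) stop("cultivar labels must be unique")
  if (any(subplot_size >= plot_size))
    stop("subplot must fit strictly inside the main plot")
  divisible <- function(x) abs(x / ground_resolution -
                                 round(x / ground_resolution)) < 1e-9
  if (!all(divisible(c(plot_size, subplot_size, alley))))
    stop("plot, subplot and alley dimensions must be whole multiples of ",
         "the ground resolution (", ground_resolution, " m)")
  structure(
    list(cultivars = cultivars, n_rates = n_rates, replicates = replicates,
         plot_size = plot_size, subplot_size = subplot_size,
         stages = stages, ground_resolution = ground_resolution,
         alley = alley),
    class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment_design> %d cultivar(s) x %d N rate(s) x %d rep(s) = %d plots\n",
    length(x$cultivars), length(x$n_rates), x$replicates,
    length(x$cultivars) * length(x$n_rates) * x$replicates))
  cat(sprintf("  plot %.4g x %.4g m, subplot %.4g x %.4g m, res %.4g m, %d stages\n",
              x$plot_size[1], x$plot_size[2], x$subplot_size[1],
              x$subplot_size[2], x$ground_resolution, length(x$stages)))
  invisible(x)
}

#' Lay out plot and subplot rectangles
#'
#' Plots are arranged on a grid: one column per cultivar x nitrogen
#' treatment combination, one row per replicate, separated by alleys.
#' Treatment combinations are randomized to columns independently within
#' each replicate row (randomized complete block layout).  Each main plot
#' receives one interior subplot whose corners are aligned to the pixel
#' grid.  Main plots are `P01`, `P02`, ...; subplots `S01`, ... share the
#' parent plot id in column `plot`.
#'
#' @param design An [experiment_design()].
#' @param seed Integer seed controlling the within-block randomization.
#' @return A data.frame with one row per sample (main plots then subplots):
#'   `sample_id`, `plot`, `cultivar`, `n_rate`, `replicate`, `is_subplot`,
#'   and map-coordinate bounds `xmin`, `ymin`, `xmax`, `ymax`.
#' @export
build_design <- function(design, seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  combos <- expand.grid(cultivar = design$cultivars, n_rate = design$n_rates,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ncombo <- nrow(combos)
  w <- design$plot_size[1]; l <- design$plot_size[2]; a <- design$alley
  rows <- withr::with_seed(seed, {
    out <- vector("list", design$replicates)
    for (r in seq_len(design$replicates)) {
      ord <- sample.int(ncombo)
      y0 <- a + (design$replicates - r) * (l + a)   # block 1 at the top
      out[[r]] <- data.frame(
        cultivar = combos$cultivar[ord], n_rate = combos$n_rate[ord],
        replicate = r,
        xmin = a + (seq_len(ncombo) - 1) * (w + a), ymin = y0,
        xmax = a + (seq_len(ncombo) - 1) * (w + a) + w, ymax = y0 + l,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  n <- nrow(rows)
  plots <- data.frame(sample_id = sprintf("P%02d", seq_len(n)),
                      plot = sprintf("P%02d", seq_len(n)),
                      rows, is_subplot = FALSE, stringsAsFactors = FALSE)
  # subplot: interior window, lower-left corner offset by one alley-width
  # (snapped to the pixel grid) from the plot's lower-left corner
  res <- design$ground_resolution
  off <- round(max(a, 0.5) / res) * res
  sw <- design$subplot_size[1]; sl <- design$subplot_size[2]
  subs <- plots
  subs$sample_id <- sprintf("S%02d", seq_len(n))
  subs$is_subplot <- TRUE
  subs$xmin <- plots$xmin + off
  subs$ymin <- plots$ymin + off
  subs$xmax <- subs$xmin + sw
  subs$ymax <- subs$ymin + sl
  if (any(subs$xmax >= plots$xmax) || any(subs$ymax >= plots$ymax))
    stop("subplot does not fit inside the main plot with the chosen offset")
  out <- rbind(plots, subs)
  cols <- c("sample_id", "plot", "cultivar", "n_rate", "replicate",
            "is_subplot", "xmin", "ymin", "xmax", "ymax")
  rownames(out) <- NULL
  out[, cols]
}

#' Field extent implied by a design layout
#' @param design An [experiment_design()].
#' @return Named numeric `(width, height)` in metres.
#' @export
field_extent <- function(design) {
  ncombo <- length(design$cultivars) * length(design$n_rates)
  w <- design$plot_size[1]; l <- design$plot_size[2]; a <- design$alley
  c(width = ncombo * (w + a) + a,
    height = design$replicates * (l + a) + a)
}
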