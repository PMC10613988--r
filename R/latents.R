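# Latent crop state driving the scene renderer and the yield ground truth.
#
# Growth follows logistic curves over the ordinal stage axis t = 1..S.
# Nitrogen acts through a saturating response f(N) = N / (N + K); one
# cultivar carries a height offset and a phenology shift so cross-cultivar
# evaluation has a real difference to detect.

#' Parameters of the latent growth model
#'
#' All constants of the generative model, with defaults chosen so that the
#' simulated trial shows the qualitative structure expected of a nitrogen
#' trial: taller, denser, greener canopies at high N, mid-season NIR peak,
#' late-season senescence, and yield strongly driven by peak height, peak
#' cover and the seasonal chlorophyll integral.
#'
#' @param height_max Asymptotic canopy height at zero nitrogen, m.
#' @param height_n_gain Fractional height increase at saturating nitrogen.
#' @param n_half_sat Nitrogen half-saturation constant, kg/ha.
#' @param height_rate,height_mid Logistic rate and midpoint (stage units)
#'   of height growth.
#' @param height_settle Multiplicative settling of height at the final
#'   stage (slight lodging/dry-down).
#' @param cover_base,cover_n_gain Fractional-cover asymptote at zero N and
#'   its additive gain at saturating N (capped at `cover_cap`).
#' @param cover_rate,cover_mid Logistic rate and midpoint of cover growth.
#' @param cover_cap Maximum attainable cover.
#' @param chl_base,chl_n_gain Chlorophyll proxy (0-1) at zero/saturating N.
#' @param chl_sen_loss Fraction of the chlorophyll proxy lost at full
#'   senescence.
#' @param sen_rate,sen_mid Logistic rate and midpoint of the senescence
#'   curve (rescaled to equal 0 at the first stage).
#' @param cultivar_height_offset Multiplicative height offset of the second
#'   cultivar (+15% by default).
#' @param cultivar_stage_shift Phenology shift of the second cultivar in
#'   stage units (negative = earlier peak).
#' @param plot_sd Standard deviation of the per-plot log-normal *fertility*
#'   effect shared by the height, cover and chlorophyll asymptotes
#'   (plot-to-plot soil variability).
#' @param trait_sd Standard deviation of the additional trait-specific
#'   log-normal effect (independent across the three traits).
#' @param yield_intercept,yield_height_coef,yield_cover_coef,yield_chl_coef
#'   Coefficients (kg/ha, and kg/ha per unit trait) of the deterministic
#'   yield model `Y = b0 + b1*peakCH + b2*peakFVC + b3*mean(chl)`.
#' @param yield_cv Coefficient of variation of multiplicative Gaussian
#'   yield noise (default 8%).
#' @return A `latent_params` list.
#' @export
latent_params <- function(height_max = 0.55, height_n_gain = 0.30,
                          n_half_sat = 120,
                          height_rate = 1.2, height_mid = 2.5,
                          height_settle = 0.98,
                          cover_base = 0.55, cover_n_gain = 0.42,
                          cover_rate = 1.5, cover_mid = 1.8,
                          cover_cap = 0.98,
                          chl_base = 0.55, chl_n_gain = 0.35,
                          chl_sen_loss = 0.75,
                          sen_rate = 1.6, sen_mid = 5.2,
                          cultivar_height_offset = 1.15,
                          cultivar_stage_shift = -1,
                          plot_sd = 0.10,
                          trait_sd = 0.02,
                          yield_intercept = 300,
                          yield_height_coef = 5000,
                          yield_cover_coef = 3000,
                          yield_chl_coef = 3000,
                          yield_cv = 0.08) {
  p <- as.list(environment())
  stopifnot(p$yield_cv >= 0, p$plot_sd >= 0, p$cover_cap <= 1)
  structure(p, class = "latent_params")
}

logistic <- function(t, rate, mid) 1 / (1 + exp(-rate * (t - mid)))

#' Simulate latent traits for every plot and stage
#'
#' @param design An [experiment_design()].
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @param params A [latent_params()] list.
#' @return A `latent_traits` list: `traits` (data.frame: `plot`, `stage`,
#'   `height`, `cover`, `chl`, `senescence`), `plot_yield` (data.frame:
#'   `plot`, `yield_potential` in kg/ha at standard moisture, plus the
#'   deterministic part `yield_det`), and the `params` used.
#' @export
simulate_latents <- function(design, seed = 1L, params = latent_params()) {
  stopifnot(inherits(design, "experiment_design"))
  plots <- build_design(design, seed = seed)
  plots <- plots[!plots$is_subplot, ]
  S <- length(design$stages)
  t <- seq_len(S)
  p <- params
  nfac <- plots$n_rate / (plots$n_rate + p$n_half_sat)
  cult2 <- plots$cultivar == design$cultivars[min(2, length(design$cultivars))] &
    length(design$cultivars) > 1
  shift <- ifelse(cult2, p$cultivar_stage_shift, 0)
  hmult <- ifelse(cult2, p$cultivar_height_offset, 1)

  withr::with_seed(seed + 1L, {
    fert <- exp(stats::rnorm(nrow(plots), 0, p$plot_sd))
    re <- fert * matrix(exp(stats::rnorm(3 * nrow(plots), 0, p$trait_sd)),
                        ncol = 3)
    traits <- vector("list", nrow(plots))
    for (i in seq_len(nrow(plots))) {
      hmax <- p$height_max * (1 + p$height_n_gain * nfac[i]) * hmult[i] * re[i, 1]
      cmax <- pmin(p$cover_cap,
                   (p$cover_base + p$cover_n_gain * nfac[i]) * re[i, 2])
      gmax <- pmin(1, (p$chl_base + p$chl_n_gain * nfac[i]) * re[i, 3])
      h <- hmax * logistic(t, p$height_rate, p$height_mid + shift[i])
      h[S] <- h[S] * p$height_settle
      cov <- cmax * logistic(t, p$cover_rate, p$cover_mid + shift[i])
      sen_raw <- logistic(t, p$sen_rate, p$sen_mid + shift[i])
      sen <- (sen_raw - sen_raw[1]) / (1 - sen_raw[1])
      chl <- gmax * (1 - p$chl_sen_loss * sen)
      traits[[i]] <- data.frame(plot = plots$plot[i], stage = design$stages,
                                height = h, cover = cov, chl = chl,
                                senescence = sen, stringsAsFactors = FALSE)
    }
    traits <- do.call(rbind, traits)
    peak_h <- tapply(traits$height, traits$plot, max)[plots$plot]
    peak_c <- tapply(traits$cover, traits$plot, max)[plots$plot]
    chl_mean <- tapply(traits$chl, traits$plot, mean)[plots$plot]
    ydet <- p$yield_intercept + p$yield_height_coef * peak_h +
      p$yield_cover_coef * peak_c + p$yield_chl_coef * chl_mean
    ypot <- ydet * (1 + stats::rnorm(nrow(plots), 0, p$yield_cv))
    plot_yield <- data.frame(plot = plots$plot,
                             yield_potential = pmax(ypot, 0),
                             yield_det = ydet, stringsAsFactors = FALSE)
  })
  rownames(traits) <- rownames(plot_yield) <- NULL
  structure(list(traits = traits, plot_yield = plot_yield, params = params,
                 stages = design$stages),
            class = "latent_traits")
}
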