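# Evaluation metrics for observed (x) vs predicted (y) yield.

#' Evaluation metrics
#'
#' Pearson `R`, coefficient of determination `R2 = 1 - SSE/SST` (computed
#' on the evaluation set; the squared Pearson correlation is reported
#' alongside as `R2_pearson`), `RMSE = sqrt(mean((x - y)^2))` and
#' `RRMSE = 100 * RMSE / mean(x)` in percent.
#'
#' @param obs Observed values.
#' @param pred Predicted values.
#' @return Named list: `R`, `R2`, `R2_pearson`, `RMSE`, `RRMSE`, `n`,
#'   `obs_mean`.
#' @export
eval_metrics <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) > 1)
  rmse <- sqrt(mean((obs - pred)^2))
  sst <- sum((obs - mean(obs))^2)
  r <- if (stats::sd(pred) > 0 && stats::sd(obs) > 0)
    stats::cor(obs, pred) else NA_real_
  list(R = r,
       R2 = 1 - sum((obs - pred)^2) / sst,
       R2_pearson = if (is.na(r)) NA_real_ else r^2,
       RMSE = rmse,
       RRMSE = 100 * rmse / mean(obs),
       n = length(obs),
       obs_mean = mean(obs))
}
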