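# Harvest records and yield standardization to 13% grain moisture.

#' Standardize yield to 13% moisture
#'
#' `Ym = 10000 * (G / A) * (1 - C) / (1 - 0.13)` in kg/ha: dry matter is
#' scaled back to the standard wheat moisture content of 13%, so a sample
#' measured at exactly 13% moisture has `Ym = 10000 * G / A`.
#'
#' @param G Harvested grain weight, kg.
#' @param A Harvested area, m^2.
#' @param C Grain moisture content as a fraction in `[0, 1)`.
#' @param sample_id Optional ids used in validation messages.
#' @return Yield in kg/ha at 13% moisture.
#' @export
standardize_yield <- function(G, A, C, sample_id = NULL) {
  bad <- which(C < 0 | C >= 1 | A <= 0 | G < 0)
  if (length(bad)) {
    ids <- if (is.null(sample_id)) paste("row", bad) else sample_id[bad]
    stop("invalid harvest record(s): ", paste(ids, collapse = ", "),
         " (need 0 <= C < 1, A > 0, G >= 0)")
  }
  10000 * (G / A) * (1 - C) / (1 - 0.13)
}

#' Read a harvest CSV and standardize yields
#'
#' Expects columns `sample_id`, `grain_weight_kg`, `area_m2` and either
#' `moisture_pct` (percent) or `moisture_frac` (fraction); the header name
#' disambiguates the unit.
#'
#' @param path CSV path.
#' @return data.frame: `sample_id`, `G`, `A`, `C` (fraction), `Ym` (kg/ha).
#' @export
read_harvest_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "grain_weight_kg", "area_m2")
  if (!all(need %in% names(d)))
    stop("harvest CSV must have columns: ", paste(need, collapse = ", "))
  C <- if ("moisture_pct" %in% names(d)) d$moisture_pct / 100
  else if ("moisture_frac" %in% names(d)) d$moisture_frac
  else stop("harvest CSV must have a moisture_pct or moisture_frac column")
  data.frame(sample_id = d$sample_id, G = d$grain_weight_kg, A = d$area_m2,
             C = C,
             Ym = standardize_yield(d$grain_weight_kg, d$area_m2, C,
                                    d$sample_id),
             stringsAsFactors = FALSE)
}
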