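# Band reflectance features and the sixteen vegetation/color indices.
#
# Nine multispectral indices are computed from band reflectances (B, G, R,
# RE, NIR in [0,1]); seven color indices from normalized digital numbers
# r = R/(R+G+B) etc. of the RGB image.  Zero-denominator pixels return NA
# (the documented sentinel) and are excluded from plot means.

#' Index definitions and category membership
#'
#' Families: `ComVIs` (commonly used NIR/visible vegetation indices),
#' `REVIs` (red-edge vegetation indices), `CIs` (color indices),
#' `AgTP` (agronomic trait parameters).
#' @return Named list of character vectors.
#' @export
feature_families <- function() {
  list(ComVIs = c("NDVI", "GNDVI", "EVI", "EVI2", "MTVI2", "SAVI"),
       REVIs = c("NDVI_RE", "MSR_RE", "CI_RE"),
       CIs = c("NDI", "ExG", "ExR", "ExGR", "VARI", "GLI", "NDYI"),
       AgTP = c("CH", "FVC", "VOL"))
}

index_category <- function(feature) {
  fam <- feature_families()
  for (f in names(fam)) if (feature %in% fam[[f]]) return(f)
  NA_character_
}

#' Normalize RGB digital numbers
#'
#' `r = R/(R+G+B)` and likewise for `g`, `b`, so `r + g + b = 1`.  Pixels
#' with zero DN sum return NA.
#'
#' @param rgb Matrix with columns `Rdn`, `Gdn`, `Bdn` (or any 3 columns in
#'   R, G, B order).
#' @return Matrix with columns `r`, `g`, `b`.
#' @export
normalize_dn <- function(rgb) {
  s <- rowSums(rgb)
  s[s == 0] <- NA_real_
  out <- rgb / s
  colnames(out) <- c("r", "g", "b")
  out
}

#' Compute all sixteen vegetation/color indices
#'
#' Vectorized over pixels.  Multispectral inputs are reflectances in [0,1];
#' `r`, `g`, `b` are normalized digital numbers summing to 1.  Pixels where
#' an index's denominator vanishes get NA for that index.
#'
#' @param R,G,B,RE,NIR Band reflectances.
#' @param r,g,b Normalized digital numbers.
#' @return Numeric matrix, one row per pixel, 16 named index columns.
#' @export
index_bank <- function(R, G, B, RE, NIR, r, g, b) {
  safe <- function(num, den) ifelse(abs(den) < 1e-12, NA_real_, num / den)
  sr_re <- safe(NIR, RE)          # simple ratio NIR/RE
  out <- cbind(
    NDVI  = safe(NIR - R, NIR + R),
    GNDVI = safe(NIR - G, NIR + G),
    EVI   = 2.5 * safe(NIR - R, NIR + 6 * R - 7.5 * B + 1),
    EVI2  = 2.5 * safe(NIR - R, NIR + 2.4 * R + 1),
    MTVI2 = 1.5 * (1.2 * (NIR - G) - 2.5 * (R - G)) /
      sqrt((2 * NIR + 1)^2 - (6 * NIR - 5 * sqrt(pmax(R, 0))) - 0.5),
    SAVI  = 1.5 * safe(NIR - R, NIR - R + 0.5),
    NDVI_RE = safe(NIR - RE, NIR + RE),
    MSR_RE  = (sr_re - 1) / (sqrt(pmax(sr_re, 0)) + 1),
    CI_RE   = sr_re - 1,
    NDI  = safe(g - r, g + r),
    ExG  = 2 * g - r - b,
    ExR  = 1.4 * r - g,
    ExGR = 3 * g - 2.4 * r - b,
    VARI = safe(g - r, g + r - b),
    GLI  = safe(2 * g - b - r, 2 * g + b + r),
    NDYI = safe(g - b, g + b))
  out
}

#' Per-plot spectral feature row
#'
#' Computes the five band-reflectance means and the sixteen indices for one
#' plot.  Default convention is mean-of-index: the index is evaluated per
#' pixel and averaged over all in-plot pixels (soil and vegetation alike);
#' `convention = "index_of_mean"` instead evaluates each index once on the
#' plot-mean spectrum.  An index with more than half of its pixels NA is
#' reported NA for the plot.
#'
#' @param pixels A `plot_pixels` object.
#' @param convention `"mean_of_index"` (default) or `"index_of_mean"`.
#' @return Named numeric vector: `B`, `G`, `R`, `RE`, `NIR`, then the 16
#'   indices.
#' @export
plot_spectral_features <- function(pixels,
                                   convention = c("mean_of_index",
                                                  "index_of_mean")) {
  convention <- match.arg(convention)
  stopifnot(inherits(pixels, "plot_pixels"), pixels$n > 0)
  bands <- colMeans(pixels$ms)
  nd <- normalize_dn(pixels$rgb)
  if (convention == "mean_of_index") {
    ix <- index_bank(R = pixels$ms[, "R"], G = pixels$ms[, "G"],
                     B = pixels$ms[, "B"], RE = pixels$ms[, "RE"],
                     NIR = pixels$ms[, "NIR"],
                     r = nd[, "r"], g = nd[, "g"], b = nd[, "b"])
    nmiss <- colSums(is.na(ix))
    feat <- colMeans(ix, na.rm = TRUE)
    feat[nmiss > 0.5 * pixels$n] <- NA_real_
    feat[is.nan(feat)] <- NA_real_
  } else {
    ndm <- colMeans(nd, na.rm = TRUE)
    feat <- index_bank(R = bands[["R"]], G = bands[["G"]], B = bands[["B"]],
                       RE = bands[["RE"]], NIR = bands[["NIR"]],
                       r = ndm[["r"]], g = ndm[["g"]], b = ndm[["b"]])[1, ]
  }
  c(bands[MS_BANDS], feat)
}
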