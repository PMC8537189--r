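# Raw measurement -> mass/area conversions: filter gravimetry, TDS soluble
# mass, and the displaced-volume needle-area formula for conifers.

#' PM mass collected on one membrane filter
#'
#' Each filter is weighed several times before loading (tare, M1) and after
#' filtration and drying (loaded, M2); replicates are aggregated by
#' arithmetic mean and the PM mass is `mean(loaded) - mean(tare)`.
#'
#' Weighing noise can push the difference slightly negative.  Differences in
#' `[-qc_tolerance_mg, 0)` are clamped to zero with a warning; differences
#' below `-qc_tolerance_mg` indicate a data error rather than balance noise
#' and are excluded (returned as `NA`) with a warning.
#'
#' @param tare_mg Numeric vector of tare weighings (mg), all > 0.
#' @param loaded_mg Numeric vector of loaded weighings (mg), all > 0.
#' @param qc_tolerance_mg Magnitude of negative difference attributed to
#'   balance noise (mg).  Default 0.05, the precision class of a 0.1 mg
#'   analytical balance.
#' @return PM mass in mg (>= 0), or `NA_real_` for an excluded measurement.
#' @export
#' @examples
#' filter_pm_mass(c(120.1, 120.3, 120.2), 123.4) # 3.2 mg
filter_pm_mass <- function(tare_mg, loaded_mg, qc_tolerance_mg = 0.05) {
  stopifnot(length(tare_mg) >= 1, length(loaded_mg) >= 1,
            all(is.finite(tare_mg)), all(is.finite(loaded_mg)),
            all(tare_mg > 0), all(loaded_mg > 0),
            is.numeric(qc_tolerance_mg), qc_tolerance_mg >= 0)
  diff <- mean(loaded_mg) - mean(tare_mg)
  if (diff >= 0) return(diff)
  if (-diff <= qc_tolerance_mg) {
    rlang::warn(
      sprintf("negative mass difference %.4f mg within QC tolerance; clamped to 0", diff),
      class = "leafdepo_qc_clamp")
    return(0)
  }
  rlang::warn(
    sprintf("mass difference %.4f mg below -QC tolerance (%.3f mg); measurement excluded",
            diff, qc_tolerance_mg),
    class = "leafdepo_qc_exclude")
  NA_real_
}

#' Soluble PM mass from a TDS reading
#'
#' The eluate passing the finest (0.1 um) membrane is quantified as total
#' dissolved solids with a conductivity meter; the soluble PM mass is the
#' concentration times the eluate volume.  For the water step this is DPM,
#' for the chloroform step OPM.
#'
#' @param concentration_mg_per_l TDS concentration C (mg/L), >= 0.
#' @param volume_l Eluate volume V (L), > 0.
#' @return Mass C * V in mg.
#' @export
#' @examples
#' soluble_mass(10, 0.35) # 3.5 mg
soluble_mass <- function(concentration_mg_per_l, volume_l) {
  stopifnot(is.numeric(concentration_mg_per_l), is.numeric(volume_l),
            all(concentration_mg_per_l >= 0), all(volume_l > 0))
  concentration_mg_per_l * volume_l
}

#' Total surface area of a batch of conifer needles
#'
#' Needle area from mean length L (m), needle count n, and mean displaced
#' volume V' (m^3, water displacement):
#'
#'   A = 2 L (1 + pi/n) sqrt(n V' / (pi L))
#'
#' which models needles as slender cylinders plus end caps and yields m^2.
#'
#' @param length_m Mean needle length L (m), > 0.
#' @param n Needle count, > 0.
#' @param volume_m3 Mean displaced volume V' (m^3), > 0.
#' @return Area in m^2.
#' @export
needle_area <- function(length_m, n, volume_m3) {
  stopifnot(all(length_m > 0), all(n > 0), all(volume_m3 > 0))
  a <- 2 * length_m * (1 + pi / n) * sqrt(n * volume_m3 / (pi * length_m))
  if (any(!is.finite(a))) {
    ld_abort("needle_area produced a non-finite result", "leafdepo_numeric_error")
  }
  a
}
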