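# Controlled vocabularies shared across the pipeline.

#' Wash steps of the sequential elution protocol
#'
#' Leaves are first washed with deionised water and brushed (releasing the
#' surface PM pool, SPM), then washed with chloroform (dissolving cuticular
#' wax and releasing the in-wax pool, WPM).
#'
#' @return Character vector `c("water", "chloroform")`.
#' @export
wash_steps <- function() c("water", "chloroform")

#' Size fractions resolved by the filtration cascade
#'
#' Each eluate is pumped successively through membranes of pore size 10,
#' 2.5 and 0.1 um; material passing the final membrane is quantified as
#' total dissolved solids and reported as the soluble fraction.
#'
#' @return Character vector of the four fraction labels, soluble first.
#' @export
pm_fractions <- function() c("soluble", "PM0.1-2.5", "PM2.5-10", "PM>10")

# Pore size (um) -> insoluble size-fraction label.  The cascade order is
# fixed 10 -> 2.5 -> 0.1, so each membrane intercepts the band between its
# own pore and the previous one.
pore_fraction_map <- function() {
  c(`10` = "PM>10", `2.5` = "PM2.5-10", `0.1` = "PM0.1-2.5")
}

#' Display label of a fraction within a wash step
#'
#' The soluble fraction is reported as DPM (water-soluble) or OPM
#' (chloroform-soluble) depending on the wash step; insoluble size
#' fractions keep their labels, and the step totals are SPM / WPM.
#'
#' @param wash_step `"water"` or `"chloroform"`.
#' @param fraction One of [pm_fractions()], or `"total"`.
#' @return Character label.
#' @export
fraction_label <- function(wash_step, fraction) {
  stopifnot(all(wash_step %in% wash_steps()))
  wash_step <- rep_len(wash_step, length(fraction))
  out <- fraction
  sol <- fraction == "soluble"
  tot <- fraction == "total"
  out[sol] <- ifelse(wash_step[sol] == "water", "DPM", "OPM")
  out[tot] <- ifelse(wash_step[tot] == "water", "SPM", "WPM")
  out
}

# internal: stop with a classed error so stages can be identified upstream
ld_abort <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "leafdepo_error"), ...)
}
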