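# Bundled reference dataset: published field measurements for 20 evergreen
# species from a temperate urban campus (7-day winter exposure).  The
# tables ship the printed values at one-decimal precision and serve as
# fixtures for closure, ranking and surface-energy checks.

ref_path <- function(name) {
  system.file("extdata", name, package = "leafdepo", mustWork = TRUE)
}

#' Reference retention-efficiency table (20 species)
#'
#' Retention efficiency of the rain-removable (SPM) pool and its four
#' sub-fractions at the leaf, plant and green-land scales, as published at
#' one-decimal precision.  Units: mg/(m^2 d) for `leaf` and `land`, mg/d
#' for `plant`.
#'
#' Note the species-code quirk inherited from the source tables: the
#' bamboo appears as `PhSu` here but as `PhVi` in
#' [reference_species()]; [check_species_codes()] surfaces this.
#'
#' @return Long tibble `species_id`, `scale`, `fraction`, `value`.
#' @export
reference_efficiency <- function() {
  readr::read_csv(ref_path("reference_efficiency.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Reference wettability and surface-free-energy table (20 species)
#'
#' Mean and SD of water and diiodomethane contact angles on adaxial leaf
#' surfaces, with the published Owens-Wendt surface free energy components
#' (mJ/m^2) at one-decimal precision.
#'
#' @return Tibble, one row per species.
#' @export
reference_contact_angles <- function() {
  readr::read_csv(ref_path("reference_contact_angles.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Reference species register (20 species)
#'
#' Family, life form, leaf shape/texture, and the published capacity
#' cluster label (1 = smallest deposited PM, 3 = largest).
#'
#' @return Tibble, one row per species.
#' @export
reference_species <- function() {
  readr::read_csv(ref_path("reference_species.csv"),
                  show_col_types = FALSE, progress = FALSE)
}
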