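# Retention efficiency at three scales.  Only the water-removable pool
# (SPM and its sub-fractions) counts: in-wax PM is immobilised and is not
# renewed by rainfall, so no deposition efficiency is defined for it.

#' Retention efficiency per unit leaf area
#'
#' AE_leaf = M_j / t: the deposition density of fraction j (mg/m^2)
#' accumulated over the exposure period, divided by the exposure time in
#' days.
#'
#' @param densities Tibble with columns `fraction` and `density_mg_m2`,
#'   SPM-side (water step) fractions only.  A `wash_step` column, if
#'   present, must be all `"water"`.
#' @param exposure_days Exposure time t in days, > 0 (default 7).
#' @return The input with an `ae_leaf` column in mg/(m^2 d).
#' @export
ae_leaf <- function(densities, exposure_days = 7) {
  stopifnot(all(c("fraction", "density_mg_m2") %in% names(densities)),
            is.numeric(exposure_days), all(exposure_days > 0))
  if ("wash_step" %in% names(densities) &&
      any(as.character(densities$wash_step) != "water")) {
    ld_abort("retention efficiency is defined for the rain-removable (water/SPM) pool only",
             "leafdepo_validation_error")
  }
  dplyr::mutate(densities, ae_leaf = .data$density_mg_m2 / exposure_days)
}

#' Total leaf area of an individual plant
#'
#' LA = LAI x D^2 x pi / 4: the leaf area index times the vertically
#' projected crown area of a crown of diameter D (m, geometric mean of two
#' perpendicular tape measures).
#'
#' @param lai Leaf area index (m^2 leaf per m^2 ground), > 0.
#' @param crown_diameter_m Crown diameter D (m), > 0.
#' @return Total leaf area in m^2.
#' @export
total_leaf_area <- function(lai, crown_diameter_m) {
  stopifnot(all(lai > 0), all(crown_diameter_m > 0))
  lai * crown_diameter_m^2 * pi / 4
}

#' Retention efficiency of an individual plant
#'
#' AE_plant = AE_leaf x LA (mg/d).
#'
#' @param ae Tibble with an `ae_leaf` column (from [ae_leaf()]).
#' @param la Total leaf area LA (m^2), > 0.
#' @return The input with an `ae_plant` column.
#' @export
ae_plant <- function(ae, la) {
  stopifnot("ae_leaf" %in% names(ae), is.numeric(la), all(la > 0))
  dplyr::mutate(ae, ae_plant = .data$ae_leaf * la)
}

#' Retention efficiency per unit green ground area
#'
#' AE_land = AE_leaf x LAI (mg/(m^2 d)); the LAI converts leaf-scale
#' efficiency into efficiency of the planted ground it shades.
#'
#' @param ae Tibble with an `ae_leaf` column.
#' @param lai Leaf area index, > 0.
#' @return The input with an `ae_land` column.
#' @export
ae_land <- function(ae, lai) {
  stopifnot("ae_leaf" %in% names(ae), is.numeric(lai), all(lai > 0))
  dplyr::mutate(ae, ae_land = .data$ae_leaf * lai)
}

#' Full efficiency table for a study
#'
#' Combines species-level SPM-side densities with morphometrics into the
#' three-scale efficiency table (leaf, plant, land) for the four
#' sub-fractions plus their SPM sum.
#'
#' @param spp_densities Output of [species_densities()].
#' @param morphometrics Tibble `species_id`, `lai`, `crown_diameter_m`.
#' @return Long tibble `species_id`, `fraction` (DPM, PM0.1-2.5, PM2.5-10,
#'   PM>10, SPM), `scale` (leaf/plant/land), `value`.  Units: mg/(m^2 d)
#'   for leaf and land, mg/d for plant.
#' @export
efficiency_table <- function(spp_densities, morphometrics) {
  water <- spp_densities |>
    dplyr::filter(.data$wash_step == "water") |>
    dplyr::mutate(fraction = fraction_label("water", as.character(.data$fraction)))
  miss <- setdiff(water$species_id, morphometrics$species_id)
  if (length(miss) > 0) {
    ld_abort(paste0("no morphometrics for species: ", paste(miss, collapse = ", ")),
             "leafdepo_referential_error")
  }
  per_fraction <- water |>
    dplyr::group_by(.data$species_id) |>
    dplyr::group_modify(function(df, key) {
      t <- unique(df$exposure_days)
      if (length(t) != 1) {
        ld_abort("exposure_days differs across fractions within a species",
                 "leafdepo_validation_error")
      }
      ae_leaf(df, exposure_days = t)
    }) |>
    dplyr::ungroup()
  spm <- per_fraction |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(fraction = "SPM", ae_leaf = sum(.data$ae_leaf), .groups = "drop")
  out <- dplyr::bind_rows(
    per_fraction |> dplyr::select("species_id", "fraction", "ae_leaf"),
    spm
  ) |>
    dplyr::left_join(
      morphometrics |> dplyr::select("species_id", "lai", "crown_diameter_m"),
      by = "species_id"
    ) |>
    dplyr::mutate(la = total_leaf_area(.data$lai, .data$crown_diameter_m))
  out <- ae_plant(out, out$la)
  out <- ae_land(out, out$lai)
  out |>
    dplyr::select("species_id", "fraction", leaf = "ae_leaf",
                  plant = "ae_plant", land = "ae_land") |>
    tidyr::pivot_longer(c("leaf", "plant", "land"),
                        names_to = "scale", values_to = "value") |>
    dplyr::mutate(
      fraction = factor(.data$fraction,
                        levels = c("DPM", "PM0.1-2.5", "PM2.5-10", "PM>10", "SPM")),
      scale = factor(.data$scale, levels = c("leaf", "plant", "land"))
    ) |>
    dplyr::arrange(.data$species_id, .data$scale, .data$fraction)
}

#' Rank species by retention efficiency
#'
#' @param efficiency Long efficiency table (see [efficiency_table()]).
#' @param scale `"leaf"`, `"plant"` or `"land"`.
#' @param fraction Fraction label, default `"SPM"`.
#' @return List: `ranking` (tibble, descending value, ties broken
#'   alphabetically by `species_id`), `max_species`, `max_value`,
#'   `min_species`, `min_value`.
#' @export
rank_species <- function(efficiency, scale = "land", fraction = "SPM") {
  sel <- efficiency |>
    dplyr::filter(.data$scale == !!scale, .data$fraction == !!fraction)
  if (nrow(sel) == 0) {
    ld_abort("no efficiency records at the requested scale and fraction",
             "leafdepo_validation_error")
  }
  ranking <- sel |>
    dplyr::arrange(dplyr::desc(.data$value), .data$species_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  list(
    ranking = ranking,
    max_species = ranking$species_id[1],
    max_value = ranking$value[1],
    min_species = ranking$species_id[nrow(ranking)],
    min_value = ranking$value[nrow(ranking)]
  )
}
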