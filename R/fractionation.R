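# Assembly of the 8-cell PM inventory (wash step x fraction) per batch and
# the derived proportions and per-leaf-area densities.

#' Assemble the per-batch PM inventory from gravimetry and TDS tables
#'
#' For each batch and wash step the filtration cascade yields three filter
#' masses (pores 10, 2.5, 0.1 um) and one soluble mass from the TDS of the
#' final filtrate, giving an 8-cell inventory per batch:
#' water (SPM) and chloroform (WPM) each split into soluble, 0.1-2.5,
#' 2.5-10 and >10 um.
#'
#' @param weighings Tibble with `batch_id`, `wash_step`, `pore_um`,
#'   `replicate`, `tare_mg`, `loaded_mg` (one row per replicate weighing).
#' @param tds Tibble with `batch_id`, `wash_step`,
#'   `concentration_mg_per_l`, `volume_l`.
#' @param batches Tibble with `batch_id`, `species_id`, `leaf_area_m2`,
#'   `exposure_days`.
#' @param qc_tolerance_mg Passed to [filter_pm_mass()].
#' @return Tibble (class `leafdepo_inventory`) with one row per batch x
#'   wash step x fraction: `batch_id`, `species_id`, `wash_step`,
#'   `fraction`, `mass_mg`, `leaf_area_m2`, `exposure_days`.  Cells whose
#'   weighing failed QC carry `NA` mass.
#' @export
assemble_inventory <- function(weighings, tds, batches, qc_tolerance_mg = 0.05) {
  pores <- pore_fraction_map()
  if (!all(weighings$pore_um %in% as.numeric(names(pores)))) {
    ld_abort("pore_um must be one of 10, 2.5, 0.1", "leafdepo_validation_error")
  }
  if (!all(weighings$wash_step %in% wash_steps()) ||
      !all(tds$wash_step %in% wash_steps())) {
    ld_abort("wash_step must be 'water' or 'chloroform'", "leafdepo_validation_error")
  }

  filt <- weighings |>
    dplyr::group_by(.data$batch_id, .data$wash_step, .data$pore_um) |>
    dplyr::summarise(
      mass_mg = filter_pm_mass(.data$tare_mg, .data$loaded_mg,
                               qc_tolerance_mg = qc_tolerance_mg),
      .groups = "drop"
    ) |>
    dplyr::mutate(fraction = unname(pores[as.character(.data$pore_um)])) |>
    dplyr::select("batch_id", "wash_step", "fraction", "mass_mg")

  dup <- tds |> dplyr::count(.data$batch_id, .data$wash_step) |> dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    ld_abort(paste0("duplicate TDS reading for batch/step: ",
                    paste(dup$batch_id, dup$wash_step, sep = "/", collapse = ", ")),
             "leafdepo_validation_error")
  }
  sol <- tds |>
    dplyr::mutate(
      fraction = "soluble",
      mass_mg = soluble_mass(.data$concentration_mg_per_l, .data$volume_l)
    ) |>
    dplyr::select("batch_id", "wash_step", "fraction", "mass_mg")

  cells <- dplyr::bind_rows(filt, sol)
  expected <- tidyr::expand_grid(
    batch_id = batches$batch_id,
    wash_step = wash_steps(),
    fraction = pm_fractions()
  )
  missing <- dplyr::anti_join(expected, cells,
                              by = c("batch_id", "wash_step", "fraction"))
  if (nrow(missing) > 0) {
    ld_abort(paste0("missing inventory cell(s): ",
                    paste(missing$batch_id, missing$wash_step, missing$fraction,
                          sep = "/", collapse = ", ")),
             "leafdepo_validation_error")
  }
  extra <- dplyr::anti_join(cells, expected,
                            by = c("batch_id", "wash_step", "fraction"))
  if (nrow(extra) > 0) {
    ld_abort(paste0("measurement rows for unknown batch_id: ",
                    paste(unique(extra$batch_id), collapse = ", ")),
             "leafdepo_referential_error")
  }

  inv <- expected |>
    dplyr::left_join(cells, by = c("batch_id", "wash_step", "fraction")) |>
    dplyr::left_join(
      batches |> dplyr::select("batch_id", "species_id", "leaf_area_m2",
                               "exposure_days"),
      by = "batch_id"
    ) |>
    dplyr::mutate(
      wash_step = factor(.data$wash_step, levels = wash_steps()),
      fraction = factor(.data$fraction, levels = pm_fractions())
    ) |>
    dplyr::arrange(.data$batch_id, .data$wash_step, .data$fraction)
  class(inv) <- c("leafdepo_inventory", class(inv))
  inv
}

#' Wash-step totals of an inventory
#'
#' SPM (water step) and WPM (chloroform step) totals per batch, derived as
#' the sum of the soluble and three insoluble cells; totals are never
#' stored independently.
#'
#' @param inventory Output of [assemble_inventory()].
#' @return Tibble `batch_id`, `species_id`, `wash_step`, `total_mg`.
#' @export
inventory_totals <- function(inventory) {
  inventory |>
    dplyr::group_by(.data$batch_id, .data$species_id, .data$wash_step) |>
    dplyr::summarise(total_mg = sum(.data$mass_mg), .groups = "drop")
}

#' Mass proportions of the eight inventory cells
#'
#' Each cell mass as a percentage of the batch's total PM (both wash steps
#' combined): P_ij = M_ij / sum(M_ij) x 100.
#'
#' @param inventory Output of [assemble_inventory()].
#' @return The inventory with a `proportion_pct` column; proportions sum to
#'   100 within each batch.
#' @export
mass_proportions <- function(inventory) {
  out <- inventory |>
    dplyr::group_by(.data$batch_id) |>
    dplyr::mutate(total = sum(.data$mass_mg)) |>
    dplyr::ungroup()
  if (any(!is.na(out$total) & out$total <= 0)) {
    ld_abort("total PM mass is zero; proportions are undefined",
             "leafdepo_numeric_error")
  }
  out |>
    dplyr::mutate(proportion_pct = .data$mass_mg / .data$total * 100) |>
    dplyr::select(-"total")
}

#' Deposition density per unit leaf area
#'
#' Divides each inventory cell mass by the batch leaf area.
#'
#' @param inventory Output of [assemble_inventory()].
#' @return The inventory with a `density_mg_m2` column.
#' @export
density_per_leaf_area <- function(inventory) {
  if (any(inventory$leaf_area_m2 <= 0)) {
    ld_abort("leaf_area_m2 must be > 0", "leafdepo_validation_error")
  }
  inventory |>
    dplyr::mutate(density_mg_m2 = .data$mass_mg / .data$leaf_area_m2)
}

#' Species-level mean deposition densities
#'
#' Unweighted mean over the batches of a species (typically three), per
#' wash step and fraction.  Batches whose cell failed weighing QC (`NA`)
#' are dropped from that cell's mean.
#'
#' @param batch_densities Output of [density_per_leaf_area()].
#' @return Tibble `species_id`, `wash_step`, `fraction`, `density_mg_m2`,
#'   `n_batches`, `exposure_days` (mean over contributing batches).
#' @export
species_densities <- function(batch_densities) {
  batch_densities |>
    dplyr::group_by(.data$species_id, .data$wash_step, .data$fraction) |>
    dplyr::summarise(
      n_batches = sum(!is.na(.data$density_mg_m2)),
      exposure_days = mean(.data$exposure_days[!is.na(.data$density_mg_m2)]),
      density_mg_m2 = mean(.data$density_mg_m2, na.rm = TRUE),
      .groups = "drop"
    )
}
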