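# Reading and validation of the study CSV bundle, and report writing.
# All tables are comma-separated UTF-8 with a header row, long format (one
# row per physical measurement); units are fixed by the schema (mg, m,
# m^2, L, mg/L, degrees, days) with no auto-detection.

study_schemas <- function() {
  list(
    species = c("species_id", "binomial", "life_form", "leaf_habit"),
    morphometrics = c("species_id", "lai", "crown_diameter_m", "n_individuals"),
    batches = c("batch_id", "species_id", "leaf_area_m2", "n_leaves",
                "exposure_days"),
    weighings = c("batch_id", "wash_step", "pore_um", "replicate", "tare_mg",
                  "loaded_mg"),
    tds = c("batch_id", "wash_step", "concentration_mg_per_l", "volume_l"),
    contact_angles = c("species_id", "liquid", "replicate", "angle_deg")
  )
}

life_forms <- function() c("tree", "shrub", "herb", "tree-dwelling")

read_study_table <- function(dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  if (!file.exists(path)) {
    ld_abort(paste0("missing study table: ", path), "leafdepo_schema_error")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  want <- study_schemas()[[name]]
  miss <- setdiff(want, names(tab))
  if (length(miss) > 0) {
    ld_abort(paste0("table '", name, "' is missing column(s): ",
                    paste(miss, collapse = ", ")),
             "leafdepo_schema_error")
  }
  tab[want]
}

#' Read and validate a study directory
#'
#' Loads the six study tables (`species.csv`, `morphometrics.csv`,
#' `batches.csv`, `weighings.csv`, `tds.csv`, `contact_angles.csv`) and
#' validates schemas, value ranges and referential integrity: every
#' measurement row must join to a known batch, and every batch to a known
#' species.
#'
#' @param dir Directory containing the CSV tables.
#' @return A validated study bundle: named list of tibbles, class
#'   `leafdepo_study`.
#' @export
read_study <- function(dir) {
  if (!dir.exists(dir)) {
    ld_abort(paste0("study directory does not exist: ", dir),
             "leafdepo_schema_error")
  }
  bundle <- lapply(stats::setNames(nm = names(study_schemas())),
                   function(nm) read_study_table(dir, nm))
  validate_study(bundle)
}

#' Validate an in-memory study bundle
#'
#' @param bundle Named list of the six study tibbles.
#' @return The bundle, classed `leafdepo_study`, or an error.
#' @export
validate_study <- function(bundle) {
  need <- names(study_schemas())
  miss <- setdiff(need, names(bundle))
  if (length(miss) > 0) {
    ld_abort(paste0("bundle is missing table(s): ", paste(miss, collapse = ", ")),
             "leafdepo_schema_error")
  }
  sp <- bundle$species
  if (anyDuplicated(sp$species_id)) {
    ld_abort("species_id must be unique in species table", "leafdepo_validation_error")
  }
  if (!all(sp$life_form %in% life_forms())) {
    ld_abort(paste0("life_form must be one of: ", paste(life_forms(), collapse = ", ")),
             "leafdepo_validation_error")
  }
  mm <- bundle$morphometrics
  if (any(mm$lai <= 0) || any(mm$crown_diameter_m <= 0)) {
    ld_abort("lai and crown_diameter_m must be > 0", "leafdepo_validation_error")
  }
  bt <- bundle$batches
  if (any(bt$leaf_area_m2 <= 0)) {
    ld_abort("leaf_area_m2 must be > 0", "leafdepo_validation_error")
  }
  if (any(bt$exposure_days <= 0)) {
    ld_abort("exposure_days must be > 0", "leafdepo_validation_error")
  }
  if (any(bundle$weighings$tare_mg <= 0) || any(bundle$weighings$loaded_mg <= 0)) {
    ld_abort("weighing masses must be > 0", "leafdepo_validation_error")
  }
  if (any(bundle$tds$concentration_mg_per_l < 0) || any(bundle$tds$volume_l <= 0)) {
    ld_abort("TDS concentration must be >= 0 and volume > 0",
             "leafdepo_validation_error")
  }
  if (any(bundle$contact_angles$angle_deg <= 0 |
          bundle$contact_angles$angle_deg >= 180)) {
    ld_abort("contact angles must lie in (0, 180)", "leafdepo_validation_error")
  }

  check_ref <- function(child, col, parent_vals, what) {
    orphan <- setdiff(unique(child[[col]]), parent_vals)
    if (length(orphan) > 0) {
      ld_abort(paste0(what, " references unknown ", col, ": ",
                      paste(orphan, collapse = ", ")),
               "leafdepo_referential_error")
    }
  }
  check_ref(bt, "species_id", sp$species_id, "batches")
  check_ref(mm, "species_id", sp$species_id, "morphometrics")
  check_ref(bundle$weighings, "batch_id", bt$batch_id, "weighings")
  check_ref(bundle$tds, "batch_id", bt$batch_id, "tds")
  check_ref(bundle$contact_angles, "species_id", sp$species_id, "contact_angles")

  class(bundle) <- c("leafdepo_study", class(bundle))
  bundle
}

#' Write a study bundle to a directory
#'
#' Inverse of [read_study()]; emits the six CSV tables.
#'
#' @param bundle A `leafdepo_study` bundle (or compatible named list).
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(study_schemas())) {
    readr::write_csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                     progress = FALSE)
  }
  invisible(dir)
}

#' Cross-check species codes between tables
#'
#' Warns about species codes that appear in a results or measurement table
#' but not in the species register (or vice versa).  Published species
#' tables occasionally disagree on abbreviations (for instance a bamboo
#' coded `PhSu` in one table and `PhVi` in another); the pipeline treats
#' codes as opaque keys and surfaces such mismatches rather than guessing.
#'
#' @param codes Character vector of species codes used in a table.
#' @param register Character vector of registered species codes.
#' @return Tibble of mismatches (`code`, `where`), invisibly; warns if any.
#' @export
check_species_codes <- function(codes, register) {
  only_codes <- setdiff(unique(codes), register)
  only_reg <- setdiff(register, unique(codes))
  out <- dplyr::bind_rows(
    tibble::tibble(code = only_codes, where = "table only"),
    tibble::tibble(code = only_reg, where = "register only")
  )
  if (nrow(out) > 0) {
    rlang::warn(paste0(
      "species code mismatch between table and register: ",
      paste(out$code, " (", out$where, ")", sep = "", collapse = ", ")),
      class = "leafdepo_code_mismatch")
  }
  invisible(out)
}

round1 <- function(x) ifelse(is.na(x), NA_real_, round(x, 1))

#' Write the human-readable and machine-readable result reports
#'
#' Emits, per results component, a human report rounded to one decimal and
#' a full-precision machine-readable companion (`*_full.csv`).  Column and
#' row order are deterministic, so identical results give byte-identical
#' files.
#'
#' @param results Named list with tibbles `efficiency` (long, per species x
#'   fraction x scale), `proportions`, `densities`, `sfe`, and optionally
#'   `clusters`, `anova`, `correlations`.
#' @param out_dir Output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(results, out_dir) {
  stopifnot(is.list(results))
  if (is.null(results$efficiency) || nrow(results$efficiency) == 0) {
    ld_abort("results are empty; nothing to report", "leafdepo_validation_error")
  }
  eff <- results$efficiency
  if (!is.null(results$sfe)) {
    missing_sp <- setdiff(unique(eff$species_id), unique(results$sfe$species_id))
    if (length(missing_sp) > 0) {
      ld_abort(paste0("results incomplete; species missing from SFE table: ",
                      paste(sort(missing_sp), collapse = ", ")),
               "leafdepo_validation_error")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(tab, name) {
    tab <- dplyr::arrange(tab, dplyr::across(dplyr::any_of(
      c("species_id", "batch_id", "scale", "wash_step", "fraction", "pair"))))
    full <- file.path(out_dir, paste0(name, "_full.csv"))
    readr::write_csv(tab, full, progress = FALSE)
    human <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(
      dplyr::mutate(tab, dplyr::across(dplyr::where(is.double), round1)),
      human, progress = FALSE)
    written <<- c(written, full, human)
  }
  emit(eff, "efficiency")
  for (nm in c("proportions", "densities", "sfe", "clusters", "anova",
               "correlations")) {
    if (!is.null(results[[nm]])) emit(results[[nm]], nm)
  }
  invisible(written)
}
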