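# End-to-end orchestration: read -> quantify -> statistics -> report.

#' Run configuration
#'
#' @param qc_tolerance_mg Negative-weighing QC tolerance (mg), see
#'   [filter_pm_mass()].
#' @param alpha Significance level for ANOVA/Tukey, in (0, 1).
#' @param k Number of capacity clusters, >= 2.
#' @param seed Seed for the k-means restarts.
#' @param n_restarts K-means random starts.
#' @param liquids Probe-liquid constants override; default [probe_liquids()].
#' @param report_digits Decimals in the human-readable report.
#' @return Validated config list, class `leafdepo_run_config`.
#' @export
run_config <- function(qc_tolerance_mg = 0.05, alpha = 0.05, k = 3,
                       seed = 20181218, n_restarts = 50,
                       liquids = probe_liquids(), report_digits = 1) {
  stopifnot(qc_tolerance_mg >= 0, alpha > 0, alpha < 1, k >= 2,
            n_restarts >= 1, report_digits >= 0)
  check_liquids(liquids)
  cfg <- list(qc_tolerance_mg = qc_tolerance_mg, alpha = alpha, k = k,
              seed = seed, n_restarts = n_restarts, liquids = liquids,
              report_digits = report_digits)
  class(cfg) <- c("leafdepo_run_config", "list")
  cfg
}

with_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    rlang::abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
                 class = c("leafdepo_stage_error", "leafdepo_error"),
                 parent = e)
  })
}

#' Quantify a study bundle
#'
#' Runs gravimetry, inventory assembly, proportions, densities, surface
#' free energy and the three-scale efficiency table.
#'
#' @param bundle A validated `leafdepo_study` (see [read_study()]).
#' @param config A [run_config()].
#' @return List: `inventory`, `proportions`, `batch_densities`,
#'   `densities` (species level), `sfe`, `efficiency`.
#' @export
quantify_study <- function(bundle, config = run_config()) {
  inv <- with_stage("gravimetry", assemble_inventory(
    bundle$weighings, bundle$tds, bundle$batches,
    qc_tolerance_mg = config$qc_tolerance_mg))
  prop <- with_stage("fractionation", mass_proportions(inv))
  bdens <- with_stage("fractionation", density_per_leaf_area(inv))
  sdens <- with_stage("fractionation", species_densities(bdens))
  sfe <- with_stage("surface_energy",
                    surface_energy_table(bundle$contact_angles,
                                         liquids = config$liquids))
  eff <- with_stage("efficiency",
                    efficiency_table(sdens, bundle$morphometrics))
  list(inventory = inv, proportions = prop, batch_densities = bdens,
       densities = sdens, sfe = sfe, efficiency = eff)
}

#' Species-comparison statistics for a quantified study
#'
#' Per-species ANOVA of batch SPM densities, correlations of total PM
#' density with water contact angle and surface free energy, and k-means
#' capacity clustering on the standardized 8-cell density profile plus
#' total.
#'
#' @param quant Output of [quantify_study()].
#' @param config A [run_config()].
#' @return List: `anova`, `tukey`, `correlations`, `clusters`.
#' @export
analyze_study <- function(quant, config = run_config()) {
  with_stage("stats", {
    spm_batches <- quant$batch_densities |>
      dplyr::group_by(.data$batch_id, .data$species_id) |>
      dplyr::summarise(total = sum(.data$density_mg_m2), .groups = "drop")
    an <- one_way_anova(spm_batches$total, spm_batches$species_id)
    tk <- tukey_hsd(spm_batches$total, spm_batches$species_id,
                    alpha = config$alpha)

    totals <- quant$densities |>
      dplyr::group_by(.data$species_id) |>
      dplyr::summarise(total = sum(.data$density_mg_m2), .groups = "drop")
    ca_water <- quant$sfe |>
      dplyr::select("species_id", ca = "mean_deg_water")
    traits <- totals |>
      dplyr::left_join(ca_water, by = "species_id") |>
      dplyr::left_join(quant$sfe |> dplyr::select("species_id", "gamma_total",
                                                  "gamma_polar", "gamma_dispersive"),
                       by = "species_id")
    correlations <- dplyr::bind_rows(
      dplyr::mutate(correlate(traits$ca, traits$total), x = "contact_angle_water"),
      dplyr::mutate(correlate(traits$gamma_total, traits$total), x = "gamma_total"),
      dplyr::mutate(correlate(traits$gamma_polar, traits$total), x = "gamma_polar"),
      dplyr::mutate(correlate(traits$gamma_dispersive, traits$total),
                    x = "gamma_dispersive")
    ) |> dplyr::relocate("x")

    features <- quant$densities |>
      dplyr::mutate(cell = paste(.data$wash_step, .data$fraction, sep = "_")) |>
      tidyr::pivot_wider(id_cols = "species_id", names_from = "cell",
                         values_from = "density_mg_m2") |>
      dplyr::left_join(totals, by = "species_id")
    cl <- kmeans_capacity_clusters(features, k = config$k, seed = config$seed,
                                   n_restarts = config$n_restarts)
    list(anova = an, tukey = tk, correlations = correlations, clusters = cl)
  })
}

#' Run the full pipeline on a study directory
#'
#' Reads and validates the bundle, quantifies it, runs the statistics, and
#' writes the report tables plus a run manifest (`manifest.yml`: seed,
#' config, package version, input checksums).  Identical inputs and config
#' give byte-identical machine-readable outputs.
#'
#' @param input_dir Directory with the study CSVs.
#' @param out_dir Report directory (created if absent).
#' @param config A [run_config()].
#' @return The full results list, invisibly.
#' @export
run_pipeline <- function(input_dir, out_dir, config = run_config()) {
  bundle <- with_stage("io", read_study(input_dir))
  quant <- quantify_study(bundle, config)
  stats <- analyze_study(quant, config)
  results <- list(
    efficiency = quant$efficiency,
    proportions = quant$proportions,
    densities = quant$densities,
    sfe = quant$sfe,
    clusters = stats$clusters$assignments,
    anova = stats$anova,
    correlations = stats$correlations
  )
  with_stage("report", {
    write_report(results, out_dir)
    manifest <- list(
      package = "leafdepo",
      version = as.character(utils::packageVersion("leafdepo")),
      seed = config$seed,
      config = list(qc_tolerance_mg = config$qc_tolerance_mg,
                    alpha = config$alpha, k = config$k,
                    n_restarts = config$n_restarts,
                    report_digits = config$report_digits),
      inputs = as.list(tools::md5sum(sort(list.files(input_dir,
                                                     pattern = "\\.csv$",
                                                     full.names = TRUE)))),
      counts = list(species = nrow(bundle$species),
                    batches = nrow(bundle$batches),
                    weighings = nrow(bundle$weighings),
                    tds = nrow(bundle$tds),
                    contact_angles = nrow(bundle$contact_angles))
    )
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  })
  invisible(c(quant, stats))
}
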