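# Fixtures are built in code: a minimal hand-made study bundle with exact
# masses, and small simulator configs for end-to-end tests.

# One species, one batch, every inventory cell exactly `cell_mass_mg`.
make_tiny_bundle <- function(cell_mass_mg = 1, leaf_area_m2 = 0.05,
                             species_id = "AaBb", validate = TRUE) {
  weighings <- tidyr::expand_grid(
    batch_id = "b1",
    wash_step = c("water", "chloroform"),
    pore_um = c(10, 2.5, 0.1),
    replicate = 1:3
  )
  weighings$tare_mg <- 150
  weighings$loaded_mg <- 150 + cell_mass_mg
  bundle <- list(
    species = tibble::tibble(species_id = species_id,
                             binomial = "Testus plantus",
                             life_form = "tree", leaf_habit = "evergreen"),
    morphometrics = tibble::tibble(species_id = species_id, lai = 3,
                                   crown_diameter_m = 2, n_individuals = 3),
    batches = tibble::tibble(batch_id = "b1", species_id = species_id,
                             leaf_area_m2 = leaf_area_m2, n_leaves = 10,
                             exposure_days = 7),
    weighings = weighings,
    tds = tibble::tibble(batch_id = "b1",
                         wash_step = c("water", "chloroform"),
                         concentration_mg_per_l = cell_mass_mg / c(0.35, 0.15),
                         volume_l = c(0.35, 0.15)),
    contact_angles = tidyr::expand_grid(
      species_id = species_id,
      liquid = c("water", "diiodomethane"),
      replicate = 1:3
    ) |> dplyr::mutate(angle_deg = ifelse(liquid == "water", 75, 55) + replicate)
  )
  if (validate) validate_study(bundle) else bundle
}

withr_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

small_config <- function(...) {
  generator_config(n_species = 4, n_batches = 2, n_ca_replicates = 5,
                   seed = 101, ...)
}
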