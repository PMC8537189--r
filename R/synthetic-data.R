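# Forward simulator of a complete study: ground-truth deposition densities
# and surface energies -> raw weighings, TDS readings, contact angles and
# morphometrics, so every pipeline stage can be tested against known truth.

#' Configuration for the study simulator
#'
#' Defaults emulate the study conditions of a 20-species, 3-batch,
#' 7-day-exposure field campaign: the SPM and DPM shares of total PM are
#' drawn uniformly from the reported field ranges (44.9-66.9% and
#' 12.9-22.1% of total PM), weighing noise matches a 0.1 mg-class
#' analytical balance, and contact-angle scatter matches typical
#' leaf-surface replicate standard deviations.
#'
#' @param n_species Number of species to simulate.
#' @param n_batches Leaf batches per species (default 3).
#' @param leaf_area_range Batch leaf-area range (m^2).
#' @param exposure_days Exposure time t (days, default 7).
#' @param spm_share_range Uniform range for the SPM share of total PM.
#' @param dpm_share_range Uniform range for the DPM share of total PM.
#' @param opm_share_range Uniform range for the OPM share of total PM.
#' @param spm_size_alpha,wpm_size_alpha Dirichlet concentration for the
#'   split of the insoluble pool into (0.1-2.5, 2.5-10, >10 um); defaults
#'   put most insoluble mass in the >10 um class, as observed in the field.
#' @param tier_base_mg_m2 Mean total PM density (mg/m^2, accumulated over
#'   the exposure) of the low-capacity tier.
#' @param tier_sd_mg_m2 Between-species SD of total PM density within a tier.
#' @param tier_separation_sd Tier-mean spacing in units of `tier_sd_mg_m2`
#'   (default 5, i.e. well-separated capacity tiers).
#' @param sfe_effect Increase in each surface-energy component (mJ/m^2) per
#'   1 SD of total PM capacity; positive, so retention and surface energy
#'   are positively linked as observed on real leaves.
#' @param sfe_noise SD of the species-level surface-energy scatter (mJ/m^2).
#' @param weighing_sd_mg SD of Gaussian noise per replicate weighing (mg).
#' @param ca_sd_deg SD of Gaussian noise per contact-angle droplet (deg).
#' @param tds_rel_sd Relative SD of TDS concentration noise (default 0:
#'   conductivity-meter error is secondary to weighing error).
#' @param n_weigh_replicates Replicate weighings per filter per side.
#' @param n_ca_replicates Contact-angle droplets per species and liquid.
#' @param eluate_volume_l Named eluate volumes (L) per wash step.
#' @param seed Default seed for [generate_truth()] and
#'   [simulate_measurements()].
#' @return Validated config list, class `leafdepo_generator_config`.
#' @export
generator_config <- function(n_species = 20,
                             n_batches = 3,
                             leaf_area_range = c(0.05, 0.30),
                             exposure_days = 7,
                             spm_share_range = c(0.449, 0.669),
                             dpm_share_range = c(0.129, 0.221),
                             opm_share_range = c(0.012, 0.088),
                             spm_size_alpha = c(3, 7, 50),
                             wpm_size_alpha = c(3, 7, 30),
                             tier_base_mg_m2 = 500,
                             tier_sd_mg_m2 = 100,
                             tier_separation_sd = 5,
                             sfe_effect = 2.5,
                             sfe_noise = 1.5,
                             weighing_sd_mg = 0.05,
                             ca_sd_deg = 5,
                             tds_rel_sd = 0,
                             n_weigh_replicates = 3,
                             n_ca_replicates = 15,
                             eluate_volume_l = c(water = 0.35, chloroform = 0.15),
                             seed = 20181218) {
  cfg <- as.list(environment())
  ok_range <- function(r) length(r) == 2 && r[1] > 0 && r[2] < 1 && r[1] <= r[2]
  if (!ok_range(spm_share_range) || !ok_range(dpm_share_range) ||
      !ok_range(opm_share_range)) {
    ld_abort("share ranges must lie within (0, 1) with min <= max",
             "leafdepo_config_error")
  }
  if (max(dpm_share_range) >= min(spm_share_range)) {
    ld_abort("dpm_share_range must lie entirely below spm_share_range (DPM is part of SPM)",
             "leafdepo_config_error")
  }
  if (max(opm_share_range) >= 1 - max(spm_share_range)) {
    ld_abort("opm_share_range must fit inside the WPM share (1 - SPM share)",
             "leafdepo_config_error")
  }
  if (weighing_sd_mg < 0 || ca_sd_deg < 0 || tds_rel_sd < 0) {
    ld_abort("noise SDs must be >= 0", "leafdepo_config_error")
  }
  stopifnot(n_species >= 1, n_batches >= 1, exposure_days > 0,
            all(leaf_area_range > 0), tier_sd_mg_m2 > 0,
            n_weigh_replicates >= 1, n_ca_replicates >= 2,
            all(eluate_volume_l > 0),
            all(c("water", "chloroform") %in% names(eluate_volume_l)))
  class(cfg) <- c("leafdepo_generator_config", "list")
  cfg
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Draw the ground truth behind a synthetic study
#'
#' Species are split evenly across three capacity tiers (low / mid / high
#' total PM density, tier means spaced `tier_separation_sd` within-tier SDs
#' apart).  Each species gets a total PM density, solubility shares, size
#' splits, surface-energy components positively linked to capacity, and
#' morphometrics.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return List of class `leafdepo_truth`: `species` (per-species tibble
#'   with tier, total density, shares, gamma_polar/dispersive, lai,
#'   crown_diameter_m) and `densities` (long tibble per species x wash
#'   step x fraction, mg/m^2).
#' @export
generate_truth <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "leafdepo_generator_config"))
  set.seed(seed)
  n <- cfg$n_species
  ids <- sprintf("S%02d", seq_len(n))
  tiers <- sample(rep(c("low", "mid", "high"), length.out = n))
  tier_mu <- cfg$tier_base_mg_m2 +
    cfg$tier_separation_sd * cfg$tier_sd_mg_m2 *
    (match(tiers, c("low", "mid", "high")) - 1)
  total <- pmax(stats::rnorm(n, tier_mu, cfg$tier_sd_mg_m2), cfg$tier_sd_mg_m2 / 10)

  spm_share <- stats::runif(n, cfg$spm_share_range[1], cfg$spm_share_range[2])
  dpm_share <- stats::runif(n, cfg$dpm_share_range[1], cfg$dpm_share_range[2])
  opm_share <- stats::runif(n, cfg$opm_share_range[1], cfg$opm_share_range[2])

  z <- as.numeric(scale(total))
  if (any(!is.finite(z))) z <- rep(0, n)  # single species or zero spread
  gamma_polar <- pmin(pmax(10 + cfg$sfe_effect * z +
                             stats::rnorm(n, 0, cfg$sfe_noise), 0.5), 35)
  gamma_dispersive <- pmin(pmax(24 + cfg$sfe_effect * z +
                                  stats::rnorm(n, 0, cfg$sfe_noise), 5), 35)

  species <- tibble::tibble(
    species_id = ids,
    tier = tiers,
    total_density_mg_m2 = total,
    spm_share = spm_share,
    dpm_share = dpm_share,
    opm_share = opm_share,
    gamma_polar = gamma_polar,
    gamma_dispersive = gamma_dispersive,
    lai = stats::runif(n, 1.5, 5.5),
    crown_diameter_m = stats::runif(n, 1, 6),
    n_individuals = sample(2:4, n, replace = TRUE)
  )

  densities <- purrr::map_dfr(seq_len(n), function(i) {
    spm_sizes <- rdirichlet1(cfg$spm_size_alpha) * (spm_share[i] - dpm_share[i])
    wpm_sizes <- rdirichlet1(cfg$wpm_size_alpha) *
      (1 - spm_share[i] - opm_share[i])
    tibble::tibble(
      species_id = ids[i],
      wash_step = rep(wash_steps(), each = 4),
      fraction = rep(pm_fractions(), 2),
      density_mg_m2 = total[i] * c(dpm_share[i], spm_sizes,
                                   opm_share[i], wpm_sizes)
    )
  })

  out <- list(species = species, densities = densities)
  class(out) <- c("leafdepo_truth", "list")
  out
}

resample_truncated <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- x <= lower | x >= upper
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x <= lower | x >= upper
  }
  x
}

#' Simulate the raw measurement record of a study
#'
#' Inverts the measurement protocol: per batch and wash step, cell masses
#' are the true densities times the batch leaf area; insoluble masses
#' become tare/loaded replicate weighings with Gaussian balance noise;
#' soluble masses become TDS concentrations given the eluate volume; true
#' surface energies become replicate contact angles via the forward
#' Owens-Wendt model plus angular noise truncated to (0, 180).
#'
#' @param truth Output of [generate_truth()].
#' @param cfg The [generator_config()] used to generate it.
#' @param seed Integer seed; defaults to `cfg$seed + 1`.
#' @return A validated `leafdepo_study` bundle (see [read_study()]).
#' @export
simulate_measurements <- function(truth, cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(truth, "leafdepo_truth"),
            inherits(cfg, "leafdepo_generator_config"))
  set.seed(seed)
  sp <- truth$species
  n <- nrow(sp)

  species <- tibble::tibble(
    species_id = sp$species_id,
    binomial = paste("Synthetica", tolower(sp$species_id)),
    life_form = sample(life_forms(), n, replace = TRUE),
    leaf_habit = "evergreen"
  )
  morphometrics <- tibble::tibble(
    species_id = sp$species_id,
    lai = sp$lai,
    crown_diameter_m = sp$crown_diameter_m,
    n_individuals = sp$n_individuals
  )
  batches <- tidyr::expand_grid(species_id = sp$species_id,
                                b = seq_len(cfg$n_batches)) |>
    dplyr::mutate(
      batch_id = sprintf("%s_b%d", .data$species_id, .data$b),
      leaf_area_m2 = stats::runif(dplyr::n(), cfg$leaf_area_range[1],
                                  cfg$leaf_area_range[2]),
      n_leaves = sample(8:40, dplyr::n(), replace = TRUE),
      exposure_days = cfg$exposure_days
    ) |>
    dplyr::select("batch_id", "species_id", "leaf_area_m2", "n_leaves",
                  "exposure_days")

  cells <- batches |>
    dplyr::left_join(truth$densities, by = "species_id",
                     relationship = "many-to-many") |>
    dplyr::mutate(mass_mg = .data$density_mg_m2 * .data$leaf_area_m2)

  insol <- cells |>
    dplyr::filter(.data$fraction != "soluble") |>
    dplyr::mutate(pore_um = as.numeric(names(pore_fraction_map()))[
      match(.data$fraction, unname(pore_fraction_map()))])
  nw <- cfg$n_weigh_replicates
  weighings <- insol[rep(seq_len(nrow(insol)), each = nw), ] |>
    dplyr::mutate(
      replicate = rep(seq_len(nw), times = nrow(insol)),
      tare_base = rep(stats::runif(nrow(insol), 120, 180), each = nw),
      tare_mg = .data$tare_base + stats::rnorm(dplyr::n(), 0, cfg$weighing_sd_mg),
      loaded_mg = .data$tare_base + .data$mass_mg +
        stats::rnorm(dplyr::n(), 0, cfg$weighing_sd_mg)
    ) |>
    dplyr::select("batch_id", "wash_step", "pore_um", "replicate",
                  "tare_mg", "loaded_mg")

  tds <- cells |>
    dplyr::filter(.data$fraction == "soluble") |>
    dplyr::mutate(
      volume_l = unname(cfg$eluate_volume_l[.data$wash_step]),
      concentration_mg_per_l = pmax(
        .data$mass_mg / .data$volume_l *
          (1 + stats::rnorm(dplyr::n(), 0, cfg$tds_rel_sd)), 0)
    ) |>
    dplyr::select("batch_id", "wash_step", "concentration_mg_per_l", "volume_l")

  liq <- probe_liquids()
  contact_angles <- purrr::map_dfr(seq_len(n), function(i) {
    purrr::map_dfr(seq_len(nrow(liq)), function(j) {
      theta <- tryCatch(
        forward_contact_angles(sp$gamma_polar[i], sp$gamma_dispersive[i],
                               liq[j, ]),
        leafdepo_nonphysical_error = function(e) {
          rlang::warn(paste0("non-physical contact angle for ", sp$species_id[i],
                             "; surface energy shrunk toward a physical value"),
                      class = "leafdepo_resample")
          gp <- sp$gamma_polar[i]; gd <- sp$gamma_dispersive[i]
          repeat {
            gp <- gp * 0.9; gd <- gd * 0.9
            th <- tryCatch(forward_contact_angles(gp, gd, liq[j, ]),
                           leafdepo_nonphysical_error = function(e) NULL)
            if (!is.null(th)) return(th)
          }
        })
      tibble::tibble(
        species_id = sp$species_id[i],
        liquid = liq$liquid[j],
        replicate = seq_len(cfg$n_ca_replicates),
        angle_deg = resample_truncated(cfg$n_ca_replicates, theta,
                                       cfg$ca_sd_deg, 0, 180)
      )
    })
  })

  validate_study(list(
    species = species,
    morphometrics = morphometrics,
    batches = batches,
    weighings = weighings,
    tds = tds,
    contact_angles = contact_angles
  ))
}

#' Generate truth and simulate its measurement record in one call
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return List with `truth` and `bundle`.
#' @export
simulate_study <- function(cfg = generator_config(), seed = cfg$seed) {
  truth <- generate_truth(cfg, seed = seed)
  bundle <- simulate_measurements(truth, cfg, seed = seed + 1L)
  list(truth = truth, bundle = bundle)
}
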