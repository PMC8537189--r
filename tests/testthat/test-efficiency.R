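ref_eff_wide <- function() {
  reference_efficiency() |>
    tidyr::pivot_wider(names_from = "fraction", values_from = "value")
}

test_that("leaf-scale efficiency divides density by exposure time", {
  d <- tibble::tibble(fraction = c("soluble", "PM>10"),
                      density_mg_m2 = c(0, 1188.6), wash_step = "water")
  ae <- ae_leaf(d, exposure_days = 7)
  expect_equal(ae$ae_leaf, c(0, 169.8))
  expect_equal(ae_leaf(d, exposure_days = 14)$ae_leaf, ae$ae_leaf / 2)
  # efficiency is defined for the rain-removable pool only
  d$wash_step <- "chloroform"
  expect_error(ae_leaf(d), class = "leafdepo_validation_error")
})

test_that("total leaf area is LAI times projected crown area", {
  expect_equal(total_leaf_area(1, 2 / sqrt(pi)), 1)
  expect_equal(total_leaf_area(4, 3), 4 * 9 * pi / 4)
  expect_equal(round(total_leaf_area(4, 3), 3), 28.274)
})

test_that("plant and land scales are shared multiples of the leaf scale", {
  ae <- tibble::tibble(fraction = c("DPM", "SPM"), ae_leaf = c(0, 73.9))
  expect_equal(ae_plant(ae, 195.52)$ae_plant, c(0, 14449), tolerance = 0.005)
  ae2 <- tibble::tibble(fraction = "SPM", ae_leaf = 134.3)
  expect_equal(ae_land(ae2, 4.159)$ae_land, 558.6, tolerance = 0.005)
  expect_equal(ae_land(ae2, 1)$ae_land, ae2$ae_leaf)
  # ae_land / ae_plant = 1 / crown area for every fraction
  lai <- 3.2; d <- 2.5
  la <- total_leaf_area(lai, d)
  ae3 <- tibble::tibble(fraction = c("DPM", "PM>10", "SPM"),
                        ae_leaf = c(12.2, 80.7, 92.9))
  full <- ae_land(ae_plant(ae3, la), lai)
  expect_equal(full$ae_land / full$ae_plant, rep(1 / (pi * d^2 / 4), 3),
               tolerance = 1e-12)
})

test_that("reference rows close: sub-fractions sum to SPM at all scales", {
  w <- ref_eff_wide()
  gap <- w$DPM + w$`PM0.1-2.5` + w$`PM2.5-10` + w$`PM>10` - w$SPM
  expect_lt(max(abs(gap)), 0.15)
})

test_that("species ranking returns published extrema", {
  eff <- reference_efficiency()
  leaf_spm <- rank_species(eff, "leaf", "SPM")
  expect_equal(leaf_spm$max_species, "PlOr")
  expect_equal(leaf_spm$max_value, 169.8)
  expect_equal(leaf_spm$min_species, "TrRe")
  expect_equal(leaf_spm$min_value, 22.7)
  leaf_dpm <- rank_species(eff, "leaf", "DPM")
  expect_equal(leaf_dpm$max_species, "TrFo")
  expect_equal(leaf_dpm$max_value, 36.1)
  land_spm <- rank_species(eff, "land", "SPM")
  expect_equal(land_spm$max_species, "ViOd")
  expect_equal(land_spm$max_value, 558.6)
  expect_equal(land_spm$min_value, 64.1)
  # single record is both max and min; ties break alphabetically
  one <- rank_species(eff[eff$species_id == "LiLu", ], "leaf", "SPM")
  expect_equal(one$max_species, one$min_species)
  tie <- tibble::tibble(species_id = c("Bb", "Aa"), scale = "leaf",
                        fraction = "SPM", value = c(5, 5))
  expect_equal(rank_species(tie, "leaf", "SPM")$ranking$species_id, c("Aa", "Bb"))
  expect_error(rank_species(eff, "leaf", "OPM"), class = "leafdepo_validation_error")
})

test_that("land/leaf ratio is constant across fractions up to printed rounding", {
  eff <- reference_efficiency()
  w <- eff |>
    dplyr::filter(scale %in% c("leaf", "land")) |>
    tidyr::pivot_wider(names_from = "scale", values_from = "value")
  spm <- w |> dplyr::filter(fraction == "SPM") |>
    dplyr::transmute(species_id, leaf_s = leaf, land_s = land)
  x <- w |> dplyr::filter(fraction != "SPM") |> dplyr::left_join(spm, by = "species_id")
  # one-decimal printing makes each value exact to +/- 0.05; a cell is
  # consistent if its ratio interval overlaps the species' SPM-implied
  # LAI interval, or agrees within 1.5% outright
  lo <- (x$land - 0.05) / (x$leaf + 0.05); hi <- (x$land + 0.05) / (x$leaf - 0.05)
  lo_s <- (x$land_s - 0.05) / (x$leaf_s + 0.05)
  hi_s <- (x$land_s + 0.05) / (x$leaf_s - 0.05)
  overlap <- lo <= hi_s & lo_s <= hi
  reldev <- abs((x$land / x$leaf) / (x$land_s / x$leaf_s) - 1)
  expect_true(all(overlap | reldev <= 0.015))
  # implied LAIs are plausible canopy values
  implied_lai <- spm$land_s / spm$leaf_s
  expect_true(all(implied_lai > 1 & implied_lai < 5))
})

test_that("efficiency table built from densities satisfies closure and scaling", {
  cfg <- small_config(weighing_sd_mg = 0, ca_sd_deg = 0)
  ss <- simulate_study(cfg)
  q <- quantify_study(ss$bundle)
  eff <- q$efficiency
  w <- eff |> tidyr::pivot_wider(names_from = "fraction", values_from = "value")
  expect_equal(w$DPM + w$`PM0.1-2.5` + w$`PM2.5-10` + w$`PM>10`, w$SPM,
               tolerance = 1e-9)
  # land/leaf ratio equals the species LAI for every fraction
  rat <- eff |>
    dplyr::filter(scale != "plant") |>
    tidyr::pivot_wider(names_from = "scale", values_from = "value") |>
    dplyr::left_join(ss$bundle$morphometrics, by = "species_id")
  expect_equal(rat$land / rat$leaf, rat$lai, tolerance = 1e-9)
})
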