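test_that("two-liquid solve reproduces published surface energies", {
  # hydrophilic broadleaf: gamma_p 9.1, gamma_d 25.4, gamma 34.5 mJ/m^2
  lilu <- owens_wendt_solve(76.3, 55.9)
  expect_equal(lilu$gamma_polar, 9.1, tolerance = 0.15 / 9.1)
  expect_equal(lilu$gamma_dispersive, 25.4, tolerance = 0.15 / 25.4)
  expect_equal(lilu$gamma_total, 34.5, tolerance = 0.15 / 34.5)
  # conifer with the highest surface energy of the set
  plor <- owens_wendt_solve(66.3, 46.3)
  expect_equal(plor$gamma_polar, 13.2, tolerance = 0.15 / 13.2)
  expect_equal(plor$gamma_dispersive, 28.9, tolerance = 0.15 / 28.9)
  expect_equal(plor$gamma_total, 42.1, tolerance = 0.15 / 42.1)
  expect_false(lilu$clamped_polar || lilu$clamped_dispersive)
})

test_that("solve matches the full published 20-species table", {
  ref <- reference_contact_angles()
  for (i in seq_len(nrow(ref))) {
    got <- owens_wendt_solve(ref$theta_water_mean[i],
                             ref$theta_diiodomethane_mean[i])
    if (ref$species_id[i] == "TrRe") {
      # degenerate hydrophobic surface: unconstrained polar root is
      # slightly negative and is clamped to zero
      expect_true(got$clamped_polar)
      expect_equal(got$gamma_polar, 0)
      next
    }
    expect_lt(abs(got$gamma_polar - ref$gamma_polar[i]), 0.15)
    expect_lt(abs(got$gamma_dispersive - ref$gamma_dispersive[i]), 0.15)
    expect_lt(abs(got$gamma_total - ref$gamma_total[i]), 0.15)
  }
})

test_that("forward model handles like-on-like and zero-energy limits", {
  water <- probe_liquids()[1, ]
  # surface identical to water: complete wetting, theta = 0
  expect_equal(forward_contact_angles(51.0, 21.8, water), 0, tolerance = 1e-6)
  # zero-energy surface: cos theta = -1, theta = 180
  expect_equal(forward_contact_angles(0, 0, water), 180)
  # inverse of the published solve
  expect_equal(forward_contact_angles(9.069, 25.363, water), 76.3,
               tolerance = 0.1)
  # non-physical combination errors
  expect_error(forward_contact_angles(60, 60, water),
               class = "leafdepo_nonphysical_error")
})

test_that("solve inverts the forward model on the physical domain", {
  liq <- probe_liquids()
  set.seed(11)
  n_ok <- 0
  while (n_ok < 200) {
    gp <- runif(1, 0.5, 50); gd <- runif(1, 5, 50)
    th <- tryCatch(
      c(forward_contact_angles(gp, gd, liq[1, ]),
        forward_contact_angles(gp, gd, liq[2, ])),
      leafdepo_nonphysical_error = function(e) NULL)
    if (is.null(th) || any(th <= 0) || any(th >= 180)) next
    back <- owens_wendt_solve(th[1], th[2])
    expect_equal(back$gamma_polar, gp, tolerance = 1e-8)
    expect_equal(back$gamma_dispersive, gd, tolerance = 1e-8)
    n_ok <- n_ok + 1
  }
})

test_that("increasing water angle decreases the polar component", {
  gp <- vapply(seq(50, 110, by = 5),
               function(tw) owens_wendt_solve(tw, 55)$gamma_polar, numeric(1))
  expect_true(all(diff(gp) < 0))
})

test_that("solver input validation and singularity are caught", {
  expect_error(owens_wendt_solve(0, 55), class = "leafdepo_validation_error")
  expect_error(owens_wendt_solve(70, 180), class = "leafdepo_validation_error")
  prop_liq <- tibble::tibble(
    liquid = c("water", "diiodomethane"),
    gamma_total = c(60, 30), gamma_polar = c(40, 20),
    gamma_dispersive = c(20, 10))
  expect_error(owens_wendt_solve(70, 55, liquids = prop_liq),
               class = "leafdepo_numeric_error")
})

test_that("wettability summaries give mean, sample sd and class", {
  ca <- tibble::tibble(species_id = "X", liquid = "water", replicate = 1:3,
                       angle_deg = c(80, 80, 80))
  s <- summarize_wettability(ca)
  expect_equal(s$mean_deg, 80)
  expect_equal(s$sd_deg, 0)
  ca$angle_deg <- c(70, 80, 90)
  s2 <- summarize_wettability(ca)
  expect_equal(s2$mean_deg, 80)
  expect_equal(s2$sd_deg, 10)
  expect_equal(s2$wettability, "wettable")
  # the most hydrophobic leaf of the reference set is highly non-wettable
  expect_equal(wettability_class(131.2), "highly non-wettable")
  expect_equal(wettability_class(100), "non-wettable")
  expect_error(summarize_wettability(ca[1, ]), class = "leafdepo_validation_error")
})
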