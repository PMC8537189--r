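# Owens-Wendt surface free energy: the two-liquid solve, its forward model
# (surface energy -> contact angle), and wettability summaries.

#' Probe-liquid surface-tension registry
#'
#' Total, polar and dispersive surface-tension components (mJ/m^2) of the
#' two probe liquids used for leaf surface free energy: distilled water
#' (72.8 = 51.0 + 21.8) and diiodomethane (50.8 = 2.3 + 48.5).  Override by
#' passing a tibble of the same shape to [owens_wendt_solve()].
#'
#' @return Tibble with columns `liquid`, `gamma_total`, `gamma_polar`,
#'   `gamma_dispersive`.
#' @export
probe_liquids <- function() {
  tibble::tibble(
    liquid           = c("water", "diiodomethane"),
    gamma_total      = c(72.8, 50.8),
    gamma_polar      = c(51.0, 2.3),
    gamma_dispersive = c(21.8, 48.5)
  )
}

check_liquids <- function(liquids) {
  stopifnot(is.data.frame(liquids),
            all(c("liquid", "gamma_total", "gamma_polar", "gamma_dispersive")
                %in% names(liquids)))
  if (any(abs(liquids$gamma_polar + liquids$gamma_dispersive -
              liquids$gamma_total) > 1e-9)) {
    ld_abort("liquid components must sum to gamma_total", "leafdepo_validation_error")
  }
  if (any(liquids$gamma_polar < 0) || any(liquids$gamma_dispersive < 0)) {
    ld_abort("liquid surface-tension components must be nonnegative",
             "leafdepo_validation_error")
  }
  liquids
}

#' Solve the Owens-Wendt two-liquid system for leaf surface free energy
#'
#' For each probe liquid the Owens-Wendt relation
#' \deqn{\gamma_l (1 + \cos\theta) = 2(\sqrt{\gamma_l^p \gamma_s^p} +
#'   \sqrt{\gamma_l^d \gamma_s^d})}
#' is linear in \eqn{(a, b) = (\sqrt{\gamma_s^p}, \sqrt{\gamma_s^d})}.  Two
#' liquids with distinct polar/dispersive character give a 2x2 system; the
#' roots are squared to recover the components.  A negative root (possible
#' for strongly hydrophobic, near-zero-polarity surfaces) is clamped to 0
#' and flagged.
#'
#' @param theta_water_deg Mean water contact angle (degrees, in (0, 180)).
#' @param theta_diiodomethane_deg Mean diiodomethane contact angle (degrees).
#' @param liquids Probe-liquid constants; defaults to [probe_liquids()].
#' @return Tibble with one row: `gamma_polar`, `gamma_dispersive`,
#'   `gamma_total` (mJ/m^2) and logical `clamped_polar`, `clamped_dispersive`.
#' @export
#' @examples
#' owens_wendt_solve(76.3, 55.9) # gamma ~ 34.4 mJ/m^2
owens_wendt_solve <- function(theta_water_deg, theta_diiodomethane_deg,
                              liquids = probe_liquids()) {
  liquids <- check_liquids(liquids)
  stopifnot(length(theta_water_deg) == 1, length(theta_diiodomethane_deg) == 1)
  theta <- c(theta_water_deg, theta_diiodomethane_deg)
  if (any(!is.finite(theta)) || any(theta <= 0) || any(theta >= 180)) {
    ld_abort("contact angles must lie strictly between 0 and 180 degrees",
             "leafdepo_validation_error")
  }
  liquids <- liquids[match(c("water", "diiodomethane"), liquids$liquid), ]
  if (anyNA(liquids$liquid)) {
    ld_abort("liquid registry must contain 'water' and 'diiodomethane'",
             "leafdepo_validation_error")
  }
  A <- cbind(sqrt(liquids$gamma_polar), sqrt(liquids$gamma_dispersive))
  if (abs(det(A)) < 1e-8) {
    ld_abort("probe liquids have proportional polar/dispersive vectors; system is singular",
             "leafdepo_numeric_error")
  }
  rhs <- liquids$gamma_total * (1 + cos(theta * pi / 180)) / 2
  roots <- solve(A, rhs)
  clamped <- roots < 0
  roots[clamped] <- 0
  tibble::tibble(
    gamma_polar       = roots[1]^2,
    gamma_dispersive  = roots[2]^2,
    gamma_total       = roots[1]^2 + roots[2]^2,
    clamped_polar     = clamped[1],
    clamped_dispersive = clamped[2]
  )
}

#' Predicted contact angle of a liquid on a surface of known energy
#'
#' Inverts the Owens-Wendt relation:
#' \eqn{\cos\theta = 2(\sqrt{\gamma_l^p\gamma_s^p} +
#' \sqrt{\gamma_l^d\gamma_s^d})/\gamma_l - 1}.  Errors when the implied
#' cosine falls outside `[-1, 1]` (complete wetting or non-wetting, where no
#' finite sessile-drop angle exists).
#'
#' @param gamma_polar,gamma_dispersive Surface components (mJ/m^2), >= 0.
#' @param liquid One row of a probe-liquid tibble (see [probe_liquids()]).
#' @return Contact angle in degrees.
#' @export
forward_contact_angles <- function(gamma_polar, gamma_dispersive, liquid) {
  stopifnot(all(gamma_polar >= 0), all(gamma_dispersive >= 0),
            is.data.frame(liquid), nrow(liquid) == 1)
  cos_theta <- 2 * (sqrt(liquid$gamma_polar * gamma_polar) +
                    sqrt(liquid$gamma_dispersive * gamma_dispersive)) /
    liquid$gamma_total - 1
  bad <- cos_theta < -1 - 1e-12 | cos_theta > 1 + 1e-12
  if (any(bad)) {
    ld_abort(
      "surface/liquid combination is non-physical (complete wetting or non-wetting)",
      "leafdepo_nonphysical_error")
  }
  acos(pmin(1, pmax(-1, cos_theta))) * 180 / pi
}

#' Wettability class of a mean contact angle
#'
#' Surfaces are wettable below 90 degrees, non-wettable between 90 and 130,
#' and highly non-wettable above 130.
#'
#' @param theta_deg Mean contact angle (degrees).
#' @return Character class label.
#' @export
wettability_class <- function(theta_deg) {
  dplyr::case_when(
    theta_deg < 90  ~ "wettable",
    theta_deg <= 130 ~ "non-wettable",
    TRUE            ~ "highly non-wettable"
  )
}

#' Summarise replicate contact angles per species and liquid
#'
#' @param contact_angles Tibble with columns `species_id`, `liquid`,
#'   `replicate`, `angle_deg` (one row per droplet).
#' @return Tibble per species x liquid: `n`, `mean_deg`, `sd_deg`,
#'   `wettability` (classed on the mean angle).
#' @export
summarize_wettability <- function(contact_angles) {
  stopifnot(all(c("species_id", "liquid", "angle_deg") %in% names(contact_angles)))
  if (any(contact_angles$angle_deg <= 0 | contact_angles$angle_deg >= 180)) {
    ld_abort("replicate contact angles must lie in (0, 180)", "leafdepo_validation_error")
  }
  out <- contact_angles |>
    dplyr::group_by(.data$species_id, .data$liquid) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_deg = mean(.data$angle_deg),
      sd_deg = stats::sd(.data$angle_deg),
      .groups = "drop"
    ) |>
    dplyr::mutate(wettability = wettability_class(.data$mean_deg))
  if (any(out$n < 2)) {
    ld_abort("at least 2 contact-angle replicates are required per species and liquid",
             "leafdepo_validation_error")
  }
  out
}

#' Surface free energy table for all species in a study
#'
#' Solves the Owens-Wendt system from the per-species mean contact angles
#' of the two probe liquids.
#'
#' @param contact_angles Long replicate table (see [summarize_wettability()]).
#' @param liquids Probe-liquid constants.
#' @return Tibble per species: mean/sd angles per liquid (wide), solved
#'   `gamma_polar`, `gamma_dispersive`, `gamma_total`, and clamp flags.
#' @export
surface_energy_table <- function(contact_angles, liquids = probe_liquids()) {
  summ <- summarize_wettability(contact_angles)
  wide <- summ |>
    tidyr::pivot_wider(
      id_cols = "species_id",
      names_from = "liquid",
      values_from = c("mean_deg", "sd_deg")
    )
  need <- c("mean_deg_water", "mean_deg_diiodomethane")
  if (!all(need %in% names(wide))) {
    ld_abort("contact angles for both water and diiodomethane are required",
             "leafdepo_validation_error")
  }
  sfe <- purrr::map2_dfr(
    wide$mean_deg_water, wide$mean_deg_diiodomethane,
    function(tw, td) owens_wendt_solve(tw, td, liquids = liquids)
  )
  dplyr::bind_cols(wide, sfe) |>
    dplyr::arrange(.data$species_id)
}
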