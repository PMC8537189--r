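---
title: "Quantifying leaf-retained particulate matter: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying leaf-retained particulate matter: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafdepo)
```

## The measurement model

`leafdepo` implements the mass accounting behind a sequential leaf-washing
campaign. Leaves exposed for `t` days (default 7) are washed in two steps:
deionised water plus brushing releases the *surface* pool (SPM), the pool
rain can renew; chloroform then dissolves the cuticular wax and releases the
*in-wax* pool (WPM), which is considered immobilised. Each eluate passes a
filtration cascade of 10, 2.5 and 0.1 µm membranes, in that order, so each
membrane intercepts the size band between its own pore and the previous one.

Two measurement primitives convert raw readings to masses:

* **Filter gravimetry.** Each membrane is weighed several times before
  (`M1`) and after (`M2`) loading; the PM mass is `mean(M2) − mean(M1)`.
  Replicates are aggregated by arithmetic mean — the protocol weighs three
  times to suppress balance noise but does not name an aggregate, and the
  mean is the estimator that makes the noise model below exact.
* **TDS solubles.** Whatever passes the 0.1 µm membrane is quantified as
  total dissolved solids: mass = `C · V` with `C` in mg/L from a
  conductivity meter and `V` the eluate volume in litres. In the water step
  this is DPM; in the chloroform step, OPM.

Two caveats are inherited from the protocol rather than introduced here.
First, the *soluble* fraction is operationally "what passes 0.1 µm", although
the TDS convention is nominally defined at 2 µm; the package implements the
operational definition. Second, OPM is computed exactly like DPM even though
conductivity measurements in chloroform are physically questionable; the
package reproduces the prescribed computation and leaves the interpretation
to the analyst.

### Negative weighing differences

A loaded filter can weigh less than its tare purely through balance noise.
Differences in `[-qc_tolerance_mg, 0)` are clamped to zero with a classed
warning; anything below `-qc_tolerance_mg` is treated as a data error and
excluded (`NA`, dropped from the species mean with its batch count reported).
The default tolerance of 0.05 mg corresponds to the precision class of a
0.1 mg analytical balance. The clamp introduces a small positive bias only
when true cell masses are comparable to the noise — at realistic loads
(≥0.3 mg per cell) the exclusion and clamp paths are essentially never taken,
which the Monte-Carlo recovery test confirms.

### Needle area

Printed forms of the conifer needle-area relation are frequently mangled by
typesetting; `needle_area()` uses the displaced-volume formula

$$A = 2L\left(1 + \frac{\pi}{n}\right)\sqrt{\frac{nV'}{\pi L}}$$

with `L` the mean needle length (m), `n` the needle count and `V'` the mean
water-displacement volume (m³). This is the standard slender-cylinder-plus-
end-caps model: it is dimensionally consistent (m²), strictly increasing in
`L` and `V'`, and reduces to `2L√(nV'/(πL))` as `n → ∞`, all of which the
test suite checks numerically.

## Surface free energy

The Owens–Wendt relation for a probe liquid of known components,
$\gamma_l(1+\cos\theta) = 2(\sqrt{\gamma_l^p\gamma_s^p} +
\sqrt{\gamma_l^d\gamma_s^d})$, is linear in
$(a, b) = (\sqrt{\gamma_s^p}, \sqrt{\gamma_s^d})$. With two liquids of
distinct polar/dispersive character — distilled water (72.8 = 51.0 + 21.8
mJ/m²) and diiodomethane (50.8 = 2.3 + 48.5 mJ/m²), shipped as an
overridable registry — the system is a well-conditioned 2×2 solve.

Numerical choices:

* Angles are degrees at every interface and radians only inside the solver;
  the conversion uses R's `pi` at full precision.
* The solve runs on the per-species *mean* angles, matching how such tables
  are reported; per-replicate solving is possible by calling the solver
  replicate-wise but is not the default.
* A negative root — which occurs for strongly hydrophobic, near-zero-polarity
  surfaces (dense wax crystals, water CA above ~130°) — is clamped to zero
  and flagged (`clamped_polar` / `clamped_dispersive`) rather than solved
  under a nonnegativity constraint. Clamping is the simplest defensible rule,
  and the only case it affects in the bundled reference set is the one
  degenerate clover surface, for which the printed polar component (0.1
  mJ/m²) is itself not reproducible from the printed mean angles.
* The forward model `forward_contact_angles()` errors when the implied
  cosine leaves `[-1, 1]` (complete wetting or non-wetting): no finite
  sessile-drop angle exists there, so returning a number would be wrong.

The solver and forward model are exact inverses on the physical domain; the
suite round-trips 10³ random surfaces at 1e-8 tolerance.

## Efficiency scaling

Only the rain-removable pool enters efficiency (the in-wax pool saturates and
is not renewed): per fraction `j`,

* `AE_leaf = M_j / t` in mg m⁻² d⁻¹,
* `AE_plant = AE_leaf × LA`, `LA = LAI · D²π/4`, in mg d⁻¹,
* `AE_land = AE_leaf × LAI` in mg m⁻² d⁻¹.

`t` is a batch attribute, not a global constant, so designs with unequal
exposures remain representable. Species-level densities are the *unweighted*
mean over a species' batches: batches differ in leaf count by leaf-size
class, so normalising to area first and then averaging is the defensible
reading. Closure — SPM equals the sum of its four sub-fractions — holds at
every scale by construction and is asserted on both the bundled reference
table and every simulated run. Reports round to one decimal for humans;
machine-readable companions keep full precision.

When checking published tables for internal consistency, the package's tests
treat printed one-decimal values as intervals (±0.05): the land/leaf ratio of
every fraction is compared with the species' SPM-implied LAI by interval
overlap, because at small printed magnitudes (e.g. 1.0 mg m⁻² d⁻¹) rounding
alone moves the ratio by more than the 1.5% band that larger cells satisfy
outright.

## Species statistics

ANOVA, Tukey HSD, correlation and k-means go through `stats::aov`,
`stats::TukeyHSD`, `stats::cor.test` and `stats::kmeans` — these are
standard, well-tested routines and re-implementing them would add risk, not
value. The replicate unit for ANOVA is the batch (three per species), which
inherits the pseudo-replication of the field design; the package does not
pretend otherwise. The Tukey implementation is cross-checked in the suite
against a direct studentized-range computation.

Capacity clustering uses the eight inventory-cell densities plus the total,
standardized to zero mean and unit variance — without standardization the
>10 µm fraction dominates every distance. Lloyd's algorithm runs with 50
random restarts from a fixed seed (default 20181218, the campaign's sampling
date) and labels are renumbered so cluster 1 has the lowest mean total PM.
The seed is saved/restored around the clustering call so callers' RNG
streams are untouched. Tie-breaks in species rankings are alphabetical by
species code, making reports deterministic.

## The synthetic-study generator

`generator_config()` defaults describe the study conditions the package is
built around: 20 species in three balanced capacity tiers, 3 batches per
species, 7-day exposure, batch leaf areas U(0.05, 0.30) m². Ground truth per
species is a total PM density (tier means 500/1000/1500 mg/m², within-tier
SD 100 — tier separation of 5 SD, i.e. cleanly separated capacity classes),
an SPM share U(0.449, 0.669) and DPM share U(0.129, 0.221) of total (the
reported field ranges), an OPM share U(0.012, 0.088), and Dirichlet size
splits concentrated on the >10 µm class as observed on real leaves. Surface
energies are drawn with a positive link to capacity (+2.5 mJ/m² per capacity
SD on both components, clamped to a physically valid region), so the
wettability/SFE correlations the statistics module estimates have a known
sign and magnitude in truth.

Measurement noise: i.i.d. Gaussian per replicate weighing (SD 0.05 mg, the
balance class), Gaussian contact-angle scatter (SD 5°, truncated to (0, 180)
by resampling, matching typical replicate SDs on leaves), and exact TDS by
default — conductivity error is secondary to weighing error and can be
switched on via `tds_rel_sd`. With all noise at zero the pipeline recovers
truth to machine precision, which the suite asserts.

What the generator does *not* emulate: spatial or temporal deposition
dynamics (rain resuspension, within-crown gradients), correlated balance
drift, operator effects, or leaf-to-leaf heterogeneity within a batch.
Passing recovery tests therefore demonstrates that the *accounting and
estimation* are unbiased under the stated noise model — not that a field
campaign is free of systematic error.

## Problem sizes used by the test suite

The suite runs a 20-species default-noise study 200 times for the bias check
(observed per-cell bias well under 2%), 10³ random surfaces for the
solver round-trip, 10⁴ species for the share-distribution check, and one
default-seed clustering recovery (19/20 tier agreement). These sizes give
Monte-Carlo errors comfortably below the asserted bounds while keeping the
full suite around a minute.

## Known limitations

* Broadleaf batch areas are inputs (from scans); the package does not parse
  images, and area convention (projected vs total) is "as measured" — it is
  the caller's responsibility to be consistent, since the protocol itself
  does not fix one.
* Efficiency assumes deposition accumulates linearly over the exposure
  window; saturation or rain events within the window are not modelled.
* The two-liquid Owens–Wendt method is the only SFE theory provided; acid–
  base or Zisman analyses are out of scope.
* Species codes are opaque keys. Published registers occasionally disagree
  on abbreviations between tables (the bundled reference set contains one
  such case, a bamboo coded `PhSu` in the efficiency table and `PhVi` in the
  register); `check_species_codes()` warns instead of guessing.
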