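# leafdepo

Urban vegetation removes airborne particulate matter (PM), but species differ
enormously in how much they retain and how easily rain renews the deposit.
`leafdepo` quantifies leaf-retained PM from a sequential elution/filtration
protocol and compares species at three scales, for researchers in urban
forestry and plant ecophysiology who run gravimetric leaf-washing campaigns.

## What it computes

**Mass accounting.** Leaves washed first with water (plus brushing) release the
surface pool (SPM — rain-removable); a subsequent chloroform wash dissolves the
cuticular wax and releases the in-wax pool (WPM — immobilised). Each eluate is
pumped through 10, 2.5 and 0.1 µm membranes; every filter's PM load is
`mean(M2) − mean(M1)` from replicate weighings, and the final filtrate's
dissolved load (DPM in water, OPM in chloroform) is the total-dissolved-solids
concentration times eluate volume, `C · V`. That yields an 8-cell inventory per
leaf batch — {SPM, WPM} × {soluble, 0.1–2.5, 2.5–10, >10 µm} — plus mass
proportions and per-leaf-area densities. Conifer needle area comes from the
displaced-volume formula `A = 2L(1 + π/n)·√(nV′/(πL))`.

**Surface energy.** Leaf surface free energy is solved from water and
diiodomethane contact angles by the Owens–Wendt two-liquid method,

γ_l (1 + cos θ) = 2(√(γ_l^p γ_s^p) + √(γ_l^d γ_s^d)),

a 2×2 linear system in (√γ_s^p, √γ_s^d). Wettability and surface energy are
the mechanistic correlates of retention capacity.

**Efficiency at three scales.** For the rain-removable pool only:
AE_leaf = M_j / t (mg m⁻² d⁻¹), AE_plant = AE_leaf × LA with
LA = LAI · D²π/4 (mg d⁻¹), and AE_land = AE_leaf × LAI (mg m⁻² d⁻¹) — the
last being the index that best supports planting decisions per unit of green
ground.

**Statistics.** One-way ANOVA with Tukey HSD across species, correlation of
retention with contact angle and surface-energy components, and k-means
clustering of species into low/intermediate/high capacity tiers.

**Simulator.** A forward generator draws ground-truth densities, shares and
surface energies, then emits the full raw measurement record (replicate
weighings with balance noise, TDS readings, contact-angle droplets), so the
entire pipeline is testable against known truth.

A published 20-species reference dataset (efficiency table, wettability/SFE
table, species register) is bundled under `inst/extdata/` and exposed via
`reference_efficiency()`, `reference_contact_angles()`, `reference_species()`.

## Worked example

```r
library(leafdepo)

# Surface free energy of a glossy broadleaf (water CA 76.3°, CH2I2 CA 55.9°)
owens_wendt_solve(76.3, 55.9)
#>   gamma_polar gamma_dispersive gamma_total clamped_polar clamped_dispersive
#> 1        9.07             25.4        34.4 FALSE         FALSE

# Which species removes most PM per square metre of planted ground?
r <- rank_species(reference_efficiency(), scale = "land", fraction = "SPM")
#> best: ViOd (558.6), worst: TrRe (64.1)   # mg m^-2 d^-1

# Simulate a small study and quantify it end to end
ss <- simulate_study(generator_config(n_species = 5, seed = 42))
q  <- quantify_study(ss$bundle)
head(q$efficiency, 5)
#>   species_id fraction  scale  value
#> 1 S01        DPM       leaf  15.3
#> 2 S01        PM0.1-2.5 leaf   0.884
#> 3 S01        PM2.5-10  leaf   5.30
#> 4 S01        PM>10     leaf  25.8
#> 5 S01        SPM       leaf  47.2
```

The surface-energy row reads: a polar component of 9.07 and dispersive
component of 25.4 mJ/m² (total 34.4) — a moderately wettable leaf whose
retention is dominated by dispersive adsorption. The efficiency rows are
mg m⁻² d⁻¹ at the leaf scale; the SPM row is the sum of its four
sub-fractions (closure holds at every scale by construction).

Run the whole pipeline on a study directory with
`run_pipeline(input_dir, out_dir)`: it validates the six input CSVs, writes
one-decimal human reports plus full-precision `*_full.csv` companions, and a
`manifest.yml` recording seed, config and input checksums.

## Layout

- `R/` — gravimetry, fractionation, surface energy, efficiency, statistics,
  simulator, I/O, pipeline orchestration
- `inst/extdata/` — reference CSV tables (plain text)
- `tests/testthat/` — unit, property and end-to-end acceptance tests
- `vignettes/leaf-pm-retention.Rmd` — methods and design notes
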