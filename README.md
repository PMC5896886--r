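# tractorpull

Analysis of cantilever-probe ("tractor pull") measurements of the tensile
convergence forces generated by amphibian marginal-zone explants, and of
uniaxial tensile stress-relaxation tests of embryonic tissue.

During *Xenopus* gastrulation the involuting marginal zone (IMZ) converges
circumferentially and closes the blastopore. In a tractor pull, an explant of
this tissue is gripped between a fixed anchor strip and a mobile sled; as the
tissue converges it deflects a calibrated optical-fibre probe, and the
deflection time series is the raw measurement. This package is for
biomechanics/morphogenesis researchers who need to turn such recordings into
forces, viscoelastic constants and per-cell force estimates — and to validate
every step against simulated data with known ground truth.

## What it computes

* **Force traces** — probe deflection to force via `F = D · M · K_P`
  (deflection px × magnification µm/px × spring constant µN/µm), linear
  drift correction from pre/post unstressed probe positions, optional
  explicit friction compensation, hourly means ± SEM
  (`deflection_to_force`, `correct_drift`, `subtract_friction`,
  `hourly_summary`).
* **Stress relaxation** — structural stiffness `SS(t) = (F/A)/ε`
  (1 µN/mm² = 1 Pa) fitted with the standard linear solid
  `SS(t) = S_inf + S_sp · e^(−t/τ)`, viscosity `η = τ · S_inf`, residual
  stiffness at 180 s, bulk spring stiffness `F(180)/ε(180)`, plasticity and
  recoil metrics (`fit_sls`, `residual_stiffness_180`, `spring_stiffness`,
  `plastic_fraction`, `recoil_metrics`).
* **Morphometrics** — convergence rates (µm/min and %/hr), signed regional
  strain rates, shear relative to the attachment strips (edge minus sled
  convergence), and sagittal-sectional-area regressions per explant type
  (`convergence_rate`, `regional_strain_rate`, `shear_rate`, `ssa_predict`,
  `fit_ssa_model`).
* **Force per cell** — per-cell force `F · a_cell / SSA_eff` (nN) and
  tensional stress `F / SSA_eff` (Pa) from effective deep-mesoderm sectional
  areas (`force_per_cell`, `tensional_stress`, `build_cell_force_table`).
* **Simulation** — an active motor–spring–dashpot series chain pulling on a
  probe spring (quasi-static, linear force–velocity motors, plastic yield,
  timed recruitment of convergent-extension modules), SLS relaxation traces,
  and marker tracks with prescribed regional strain rates; all seeded and
  returning exact ground truth (`simulate_tractor_pull`,
  `simulate_relaxation`, `simulate_marker_tracks`, `pull_config_preset`).

## Worked example

Simulate a standard pull (two-phase force profile), drift-correct it and
summarise hourly; then fit a simulated relaxation test and rebuild the
per-cell force table from the bundled reference measurements:

```r
library(tractorpull)

sim <- simulate_tractor_pull(pull_config_preset("standard", seed = 42))
hs  <- hourly_summary(correct_drift(sim$trace))
head(hs, 3)
#>   hour   mean_uN     sem_uN  n
#> 1    0 0.2734945 0.05338876 10
#> 2    1 0.6926255 0.03460970 10
#> 3    2 1.0286960 0.03286342 10
```

Force rises through gastrulation, plateaus near 2 µN during neurulation, and
climbs to ~4 µN after the convergent-extension modules reach the attachment
strips (`hs$mean_uN[19]` is 4.03 µN at hour 18).

```r
p   <- sls_parameters(S_inf = 14, S_sp = 25, tau = 45)
rel <- simulate_relaxation(p, strain = 0.12, area_mm2 = 0.41,
                           noise_sd_rel = 0.02, seed = 42)
fit_sls(rel)
#> SLS fit (nls, n = 198, ramp excluded < 3 s): converged, RMS residual 0.379 Pa
#> SLS parameters: S_inf = 14.02 Pa, S_sp = 25.37 Pa, tau = 44.13 s, eta = 618.5 Pa*s
```

The fit recovers the generating parameters (residual stiffness 14 Pa ~ a
late-gastrula explant) to ~1% under 2% measurement noise.

```r
build_cell_force_table(giant_pull_force_ssa())[, c(1, 2, 5, 10, 11)]
#>   time_hr force_uN effective_ssa_mm2 force_per_cell_nN_2sf stress_pa_2sf
#> 1     1.0     0.25              0.12                   1.3           2.1
#> 2     2.1     0.31              0.11                   1.8           2.8
#> 3     2.9     0.49              0.13                   2.4           3.8
#> 4     4.3     0.94              0.27                   2.2           3.5
#> 5     6.5     1.60              0.41                   2.4           3.9
#> 6    11.8     2.60              0.68                   2.4           3.8
```

Force per cell stabilises near 2.3 nN from mid-gastrulation on, and
tensional stress near 4 Pa: maximal force tracks the growing effective
cross-section, not stronger cells.

## Command line

A wrapper script is installed at
`system.file("cli", "tractorpull", package = "tractorpull")`:

```sh
tractorpull simulate-pull --preset standard --seed 7 --out trace.csv --truth truth.json
tractorpull summarize-pull --trace trace.csv --out summary.csv [--friction-offset 0.2]
tractorpull fit-relaxation --trace rel.csv --out params.json
tractorpull morpho --tracks tracks.csv --windows windows.json --out rates.csv
tractorpull cell-force --rows rows.csv --out table.csv --cell-area 625
tractorpull run --config pipeline.json --out-dir out/
```

Every run writes a JSON manifest (command, config/input digests, seed,
version). Stochastic commands require an explicit `--seed`.

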