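---
title: "Measuring and modelling convergence forces in embryonic explants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling convergence forces in embryonic explants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractorpull)
```

## The measurement problem

During amphibian gastrulation the ring of presumptive mesoderm around the
blastopore (the involuting marginal zone, IMZ) converges circumferentially and
squeezes the blastopore shut. Two cellular machines drive this convergence:
convergent thickening (CT), an isotropic, surface-tension-like contraction of
the pre-involution IMZ, and convergent extension (CE), the anisotropic
narrowing-and-lengthening produced by mediolateral cell intercalation, which
is recruited progressively as cells involute. The tension these machines
generate can be measured directly in a "tractor pull": a sandwich explant of
the marginal zone is gripped between a fixed anchor strip and a mobile sled,
and as the tissue converges it pulls a cleat on the sled against a calibrated
optical-fibre probe. `tractorpull` implements the complete analysis chain for
such experiments, plus a generative simulator for every input, so that each
analysis stage can be validated against known ground truth without any
external data.

## Force traces

Probe deflection `D(t)` (pixels) converts to force by `F = D * M * K_P`, with
`M` the magnification (um/px) and `K_P` the probe spring constant (uN/um)
(`deflection_to_force()`). Probe drift is estimated from the unstressed probe
position recorded before and after the assay, interpolated linearly over the
test and subtracted (`correct_drift()`). Two choices deserve comment:

* **Negative corrected forces are retained**, flagged, and never clipped. The
  probe cannot push, so small negatives are drift/noise artefacts; clipping
  them would bias hourly means upward.
* **Friction compensation is off by default.** Sled friction reduces observed
  force by a roughly constant ~0.2 uN; `subtract_friction()` adds an explicit,
  recorded offset to strictly positive samples only (no force is fabricated
  at rest). Because the loss is only an approximate systematic underestimate,
  it is an opt-in correction, and the CLI logs when it is applied.

Hourly summaries use half-open `[h, h+1)` bins from gastrulation onset (G0)
and report mean with SEM = SD/sqrt(n); a single-sample bin has no defined SEM
and reports `NA`. Sampling cadence is not enforced (pulls were typically
recorded every 6 min).

A unit note: the probes used for the original measurements are quoted with
spring constants of 27 and 12 uN/um, which imply sub-micron deflections at
uN-scale forces. The package treats calibration constants as opaque numbers;
nothing downstream depends on their absolute plausibility.

## Stress relaxation and the standard linear solid

A step strain (stage moved 300 um, ~10-12% strain, applied over a second or
two) is followed for five minutes while the stress decays. Structural
stiffness — stress over strain for the composite explant, *not* an elastic
modulus — is modelled as a standard linear solid,

`SS(t) = S_inf + S_sp * exp(-t / tau)`,

with residual stiffness `S_inf`, decaying component `S_sp`, relaxation time
`tau`, and derived viscosity `eta = tau * S_inf` (computed, never re-entered,
so the identity holds exactly). Numerical choices:

* **Ramp idealisation.** The model assumes an instantaneous step; samples
  earlier than `ramp_end_s` (default 3 s, the upper end of the real ramp
  duration) are excluded from fitting.
* **Fitting.** Bounded (`S_inf, S_sp >= 0`, `tau > 0`) nonlinear least
  squares via `nls(algorithm = "port")`, initialised from the data (tail for
  `S_inf`, head-minus-tail for `S_sp`, half-decay crossing for `tau`, with a
  span/3 fallback), then refined by variable projection: for fixed `tau` the
  model is linear in `(S_inf, S_sp)`, so the profiled RSS is optimised over
  `tau` alone and the linear part solved exactly. An independent L-BFGS-B
  route (`method = "optim"`) serves as the second analytical technique and as
  a cross-check; non-convergence is flagged on the result, never silently
  replaced by defaults.
* **Degenerate input.** A series with no measurable decay returns
  `S_inf = mean`, `S_sp = 0` and an unidentifiable `tau` (`NA`, flagged),
  rather than an arbitrary time constant.
* **Strain.** A realized marker-based strain series, when recorded,
  supersedes the nominal imposed strain; stiffness at 180 s (`E_180`, the
  practical proxy for `S_inf`) interpolates linearly between bracketing
  samples.
* Structural stiffness units work out as 1 uN/mm2 = 1 Pa, so no conversion
  constants appear in the code.

Plasticity after release is summarised by `plastic_fraction()` (residual over
applied strain; at the published operating point, 12% applied strain with a
25% plastic fraction leaves the explant 3% longer) and rapid elastic recoil
by `recoil_metrics()` (fractional recoil in %, recoil rate converted to %/hr
even though measured over 5 s, to match how convergence rates are reported).

## Morphometrics

Rates are ordinary least-squares slopes over a stated time window rather than
endpoint differences (endpoint differencing remains available as a
cross-check). The %/hr normalisation uses the width at the *start* of the
window; for an exponentially converging width this makes the measured rate
slightly smaller in magnitude than the instantaneous rate (a width following
`3000*exp(-0.10 t)` um sampled over one hour reads ~9.5 %/hr), which is a
property of the definition, not an error. Regional strain rates are signed
(negative = convergence) while convergence rates are sign-flipped positive;
both conventions appear in published tables and are preserved as distinct
quantities. Shear with respect to the attachment strips is edge convergence
minus sled convergence, an exact identity asserted property-style in the
tests.

Sagittal sectional area (SSA) is assigned to a test time by regression:
a line `0.085 t + 0.24` mm2 for standard giant and dorsal-180 explants, a
quadratic `-0.0042 t^2 + 0.085 t + 0.25` mm2 for ventral-180 explants held
at its 10-hr value of 0.68 mm2 thereafter (the cap expresses that ventral
thickening plateaus), and a constant 0.16 mm2 for animal caps
(`ssa_reference_models()`). `fit_ssa_model()` refits any of these forms;
a fitted quadratic is capped at its stationary point unless a cap time is
supplied.

## Force per cell

With a mean deep-mesoderm cell sectional area of 625 um2, the effective
(deep-mesoderm-only) SSA converts force to per-cell force:
`F * cell_area / SSA`, reported in nN, and to tensional stress `F / SSA` in
Pa. The source table prints the cell area as "625 nm^2", which is
dimensionally inconsistent with nN-scale per-cell forces; 625 um2 (a 25 um
cell) reproduces every printed value and is adopted, with the discrepancy
surfaced here and in the function documentation.

### Reproducing the published derived tables

Full-precision values are kept alongside 2-significant-figure columns
(`signif(x, 2)`, round-half-even). Recomputing the published derived columns
from the published *rounded* inputs reproduces the stress column exactly
(6/6 values) but the per-cell column only to within one unit in the last
digit for three rows (computed 1.76, 2.36 and 2.44 nN round to 1.8, 2.4 and
2.4 where the table prints 1.7, 2.3 and 2.5). No rounding convention maps
the printed inputs onto all printed outputs simultaneously; the original
values were evidently derived from unrounded means. The acceptance tests
therefore assert exact agreement where it is arithmetically attainable and
one-ulp agreement elsewhere.

## The chain simulator: a stated world

The simulator formalises the motor-and-spring cartoon of the tissue as a
quasi-static series chain of active Kelvin elements pulling on a linear probe
spring. The governing equations are the package's design (the conceptual
model it formalises carries no equations):

* Each element has rest length `R_i`, spring constant `k_i`, a motor with
  linear force-velocity `dR_i/dt = -v0 (1 - T/F_stall)` (clamped at stall),
  and a plastic dashpot `dR_i/dt = +(T - T_yield)/eta_d` above yield.
* Quasi-static force balance is closed-form at every step:
  `T = (L0 - sum R_i) / (sum 1/k_i + 1/K_P)`, clamped at `T >= 0`; with a
  static-friction dead band `F_s`, the sled holds until the imbalance between
  chain tension and probe force exceeds `F_s`, then settles on the band edge.
* Recruitment: an element can be replaced by a stronger CE parameter set at
  a stated time (rest length continuous), modelling intercalation spreading
  laterally to the attachment strips.
* Integration is explicit Euler, `dt = 0.1` min by default; a step-halving
  test bounds the terminal-force discretisation error below 0.5%.
* Noise (Gaussian, in uN), linear probe drift (px/min) and friction act on
  the *emitted* deflection series only, so the returned ground truth is
  exact. All generators take a mandatory seed and are bit-reproducible.

This model reproduces, with minimal parameters, the qualitative mechanics it
was built to express: a series chain's tension asymptotes at the largest
active stall; a flanking element whose yield sits below the central stall
pins tension near that yield (the plateau) until the weak link is replaced by
recruitment, after which force rises again; removing the weak flanks (a
dorsal-explant-like configuration) removes the plateau; a CT-only chain
plateaus at the CT stall ceiling and never shows a second rise.

The shipped presets (`pull_config_preset()`) are *calibrations*, not
measurements: element constants were chosen so the standard configuration
hits the landmark magnitudes of real pulls (force above 1 uN by G+6 hr, first
plateau ~2 uN from ~G+7.5 to G+10.5 hr, final 4-5 uN; CT-only ceiling ~2 uN).
Spring constants (~0.25 uN/um per element) are of the order implied by
measured bulk spring stiffnesses; motor velocities were set by the observed
multi-hour rise times through the chain-plus-probe compliance. What a green
simulator test establishes is that the analysis pipeline recovers the stated
world's ground truth — not that embryonic tissue obeys this chain model; in
particular the simulator is 1-D, has no cell-level structure, and its
force-velocity and yield laws are the simplest consistent choices, with the
CT motor law deliberately identical to CE's (how CT's force generation scales
with thickening is unknown; the element kind and constants are configurable).

Marker-track simulation prescribes piecewise-uniform exponential strain per
region (regions must tile the axis); relaxation-trace simulation is the SLS
forward model with multiplicative Gaussian noise. Both record their ground
truth, enabling the round-trip tests (prescribed regional rates of -7.2 and
+1.1 %/hr are recovered within 2%; noise-free SLS parameters within 1e-6
relative; at 2% noise and n = 200, Monte-Carlo RMSE is ~1% per parameter,
comfortably inside the 5% acceptance band, with S_inf bias below 1%).

## Files, configs, determinism

Traces are RFC-4180 CSV with `#`-prefixed metadata headers and unit-suffixed
column names; there is no standard format for force traces in this domain,
so a self-describing text format was preferred over anything binary. Configs
and manifests are JSON (no YAML parser is assumed). Every pipeline/CLI run
writes exactly one manifest (command, config and input digests, seed,
package version, timestamp); timestamps live only in the manifest so result
files from identical inputs are byte-identical. Seeds are mandatory for all
stochastic commands — there is no wall-clock seeding anywhere.

## Known limitations

* Inference of per-tissue elastic moduli from composite structural stiffness
  is out of scope, as is any multi-exponential / generalized Maxwell model.
* Drift correction implements the linear interpolation between unstressed
  reference positions only; richer drift/friction characterisation of the
  instrument is not modelled.
* The second published analytical technique for SLS estimation is not
  specified in the available description; the pluggable `method` argument
  holds that slot with an independent optimiser.
* Region definitions for morphometrics (e.g. "edges of the widest part of
  the IMZ") are user-supplied labels; the package does no image analysis.
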