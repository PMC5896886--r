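#' Force per cell within the effective sagittal sectional area
#'
#' The mean mediolateral tensile force borne by each cell in the deep
#' mesoderm: the measured force divided by the number of cells in the
#' effective sagittal section, i.e. `force * cell_area / effective_SSA`.
#' With force in uN, cell sectional area in um2 and SSA in mm2 the result is
#' returned in nN.
#'
#' Note on units: the mean cell sectional area for Xenopus deep mesodermal
#' cells is 625 um2 (a 25 um x 25 um cell section). A nm2-scale value would
#' be dimensionally inconsistent with nN-scale per-cell forces.
#'
#' @param force_uN Tensile force, uN (> 0).
#' @param effective_ssa_mm2 Effective (deep-mesoderm-only) sagittal sectional
#'   area, mm2 (> 0).
#' @param cell_area_um2 Mean cell sectional area, um2 (> 0; default 625).
#' @return Force per cell in nN (full precision; round with `signif(x, 2)`
#'   for table-style reporting).
#' @examples
#' force_per_cell(0.49, 0.13)  # about 2.36 nN
#' @export
force_per_cell <- function(force_uN, effective_ssa_mm2, cell_area_um2 = 625) {
  stopifnot(is.numeric(force_uN), is.numeric(effective_ssa_mm2),
            is.numeric(cell_area_um2))
  if (any(force_uN <= 0) || any(effective_ssa_mm2 <= 0) || any(cell_area_um2 <= 0))
    stop("force, effective SSA and cell area must all be positive")
  # cells per section = (SSA mm2 -> um2) / cell_area; uN -> nN is *1000
  force_uN * 1000 / (effective_ssa_mm2 * 1e6 / cell_area_um2)
}

#' Tensional stress within the effective SSA
#'
#' Force divided by effective sagittal sectional area; with force in uN and
#' area in mm2, 1 uN/mm2 = 1 Pa. Homogeneous of degree zero: scaling force
#' and area together leaves the stress unchanged.
#'
#' @inheritParams force_per_cell
#' @return Stress in Pa (full precision).
#' @examples
#' tensional_stress(1.6, 0.41)  # about 3.9 Pa
#' @export
tensional_stress <- function(force_uN, effective_ssa_mm2) {
  stopifnot(is.numeric(force_uN), is.numeric(effective_ssa_mm2))
  if (any(force_uN <= 0) || any(effective_ssa_mm2 <= 0))
    stop("force and effective SSA must be positive")
  force_uN / effective_ssa_mm2
}

#' Build a force-per-cell / tensional-stress table
#'
#' From rows of (time after G0, mean force, effective SSA) and a mean cell
#' sectional area, derives the per-cell force (nN) and tensional stress (Pa),
#' keeping full precision alongside 2-significant-figure columns for
#' table-style reporting.
#'
#' @param rows Data frame with columns `time_hr`, `force_uN`,
#'   `effective_ssa_mm2` (extra columns such as `n` or `sem` are carried
#'   through). An empty data frame yields an empty table.
#' @param cell_area_um2 Mean cell sectional area, um2 (default 625).
#' @return Data frame with added columns `force_per_cell_nN`, `stress_pa`
#'   (full precision) and `force_per_cell_nN_2sf`, `stress_pa_2sf`.
#' @export
build_cell_force_table <- function(rows, cell_area_um2 = 625) {
  stopifnot(is.data.frame(rows))
  need <- c("time_hr", "force_uN", "effective_ssa_mm2")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- rows
  if (nrow(rows) == 0L) {
    out$force_per_cell_nN <- numeric(0)
    out$stress_pa <- numeric(0)
    out$force_per_cell_nN_2sf <- numeric(0)
    out$stress_pa_2sf <- numeric(0)
    return(out)
  }
  out$force_per_cell_nN <- force_per_cell(rows$force_uN, rows$effective_ssa_mm2,
                                          cell_area_um2)
  out$stress_pa <- tensional_stress(rows$force_uN, rows$effective_ssa_mm2)
  out$force_per_cell_nN_2sf <- signif(out$force_per_cell_nN, 2)
  out$stress_pa_2sf <- signif(out$stress_pa, 2)
  out
}

#' Reference force / effective-SSA measurements for giant explants
#'
#' Bundled summary measurements from circumblastoporal tractor-pull assays of
#' Xenopus giant sandwich explants: mean tensile force and effective
#' (deep-mesoderm-only) sagittal sectional area at six developmental times,
#' with sample sizes and standard errors. These are the inputs from which
#' per-cell forces and tensional stresses are derived via
#' [build_cell_force_table()].
#'
#' @return Data frame with columns `time_hr`, `force_uN`, `force_n`,
#'   `force_sem`, `effective_ssa_mm2`, `ssa_n`, `ssa_sem`.
#' @export
giant_pull_force_ssa <- function() {
  data.frame(
    time_hr = c(1, 2.1, 2.9, 4.3, 6.5, 11.8),
    force_uN = c(0.25, 0.31, 0.49, 0.94, 1.6, 2.6),
    force_n = c(3L, 3L, 4L, 4L, 5L, 6L),
    force_sem = c(0.08, 0.09, 0.16, 0.04, 0.11, 0.19),
    effective_ssa_mm2 = c(0.12, 0.11, 0.13, 0.27, 0.41, 0.68),
    ssa_n = c(1L, 4L, 4L, 3L, 3L, 3L),
    ssa_sem = c(NA, 0.014, 0.018, 0.024, 0.020, 0.051)
  )
}

#' Reference convergence, strain and shear rates for tractor-pull assays
#'
#' Bundled morphometric rates from tractor-pull and control assays:
#' average convergence (positive = converging), regional strain rates of the
#' dorsal and lateroventral (LV) tissue (negative = converging), and shear
#' relative to the attachment strips, per assay phase. These tabulated rates
#' are inputs to internal-consistency checks (e.g. shear equals edge
#' convergence minus sled convergence).
#'
#' @return Data frame with columns `condition`, `window_hr_start`,
#'   `window_hr_end`, `convergence_um_min`, `convergence_pct_hr`,
#'   `dorsal_strain_pct_hr`, `lv_strain_pct_hr`, `shear_pct_hr`.
#' @export
giant_pull_convergence_rates <- function() {
  data.frame(
    condition = c("intact_embryo", "giant_unencumbered",
                  "standard_pull_probe3", "standard_pull_probe3",
                  "standard_pull_probe3", "standard_pull_probe4",
                  "standard_pull_probe4", "standard_pull_probe4"),
    window_hr_start = c(2, 0, 2, 7.5, 10.5, 2.5, 7.5, 10.5),
    window_hr_end = c(7, 7, 7.5, 10.5, 15.5, 7.5, 10.5, 16.5),
    convergence_um_min = c(10, 5, NA, NA, NA, NA, NA, NA),
    convergence_pct_hr = c(17.5, 10, 4.1, 2.5, 3.7, 4.5, 1.7, 3.0),
    dorsal_strain_pct_hr = c(NA, NA, -7.2, -7.0, -5.5, NA, NA, NA),
    lv_strain_pct_hr = c(NA, NA, 1.1, 1.7, -0.5, NA, NA, NA),
    shear_pct_hr = c(NA, NA, 3.7, 2.5, 3.2, 3.1, 1.7, 2.1)
  )
}
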