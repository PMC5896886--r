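#' Active chain element (motor - spring - dashpot module)
#'
#' One module of the series chain used to simulate an explant in the tractor
#' pull. Each element is a Kelvin-type unit: an active contractile motor in
#' parallel with a linear spring, in series with the rest of the chain, plus
#' a plastic dashpot that flows when tension exceeds the element's yield
#' tension. The motor follows a linear force-velocity law: it shortens the
#' element's rest length at `v0 * max(0, 1 - T / stall_force)`.
#'
#' Two motor phenotypes are distinguished. Convergent-thickening (CT)
#' modules act from the start; convergent-extension (CE) modules are
#' recruited over time as cells transition into mediolateral intercalation.
#' An element with a finite `recruitment_time` switches behaviour at that
#' time: if `recruit` (another `chain_element` giving the post-recruitment
#' mechanics) is supplied, its parameters take over with the rest length
#' carried continuously; otherwise a CE element is simply inactive (motor
#' off, no yield flow) before its recruitment time.
#'
#' @param kind `"CT"`, `"CE"` or `"passive"` (passive = no motor).
#' @param stall_force Motor stall tension, uN (>= 0; 0 for passive).
#' @param free_shortening_velocity Unloaded shortening velocity `v0`, um/min.
#' @param spring_constant Element spring constant, uN/um (> 0, finite).
#' @param dashpot_viscosity Plastic dashpot viscosity, uN min/um; flow rate
#'   above yield is `(T - yield) / dashpot_viscosity`.
#' @param yield_tension Tension above which the element flows plastically,
#'   uN. `Inf` = never yields; a value at or above `stall_force` is allowed.
#' @param rest_length Initial unloaded rest length, um (> 0).
#' @param recruitment_time Minutes after G0 at which the element switches
#'   behaviour (default `Inf` = never).
#' @param recruit Optional `chain_element` whose mechanical parameters
#'   replace this element's at `recruitment_time` (models CT tissue being
#'   replaced by CE as intercalation reaches it).
#' @return An object of class `chain_element`.
#' @export
chain_element <- function(kind = c("CT", "CE", "passive"),
                          stall_force = 0,
                          free_shortening_velocity = 0,
                          spring_constant = 0.25,
                          dashpot_viscosity = Inf,
                          yield_tension = Inf,
                          rest_length = 600,
                          recruitment_time = Inf,
                          recruit = NULL) {
  kind <- match.arg(kind)
  num1 <- function(x, nm, lo = 0, allow_inf = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (!allow_inf && !is.finite(x)) || x < lo)
      stop("`", nm, "` must be a single number >= ", lo)
    as.numeric(x)
  }
  stall_force <- num1(stall_force, "stall_force", allow_inf = FALSE)
  free_shortening_velocity <- num1(free_shortening_velocity,
                                   "free_shortening_velocity", allow_inf = FALSE)
  spring_constant <- num1(spring_constant, "spring_constant", allow_inf = FALSE)
  if (spring_constant <= 0) stop("`spring_constant` must be > 0")
  dashpot_viscosity <- num1(dashpot_viscosity, "dashpot_viscosity")
  if (dashpot_viscosity <= 0) stop("`dashpot_viscosity` must be > 0")
  yield_tension <- num1(yield_tension, "yield_tension")
  rest_length <- num1(rest_length, "rest_length", allow_inf = FALSE)
  if (rest_length <= 0) stop("`rest_length` must be > 0")
  recruitment_time <- num1(recruitment_time, "recruitment_time")
  if (!is.null(recruit) && !inherits(recruit, "chain_element"))
    stop("`recruit` must be a chain_element or NULL")
  structure(
    list(kind = kind, stall_force = stall_force,
         free_shortening_velocity = free_shortening_velocity,
         spring_constant = spring_constant,
         dashpot_viscosity = dashpot_viscosity,
         yield_tension = yield_tension, rest_length = rest_length,
         recruitment_time = recruitment_time, recruit = recruit),
    class = "chain_element")
}

#' Tractor-pull simulation configuration
#'
#' Specifies the full simulated experiment: the ordered chain of
#' [chain_element()]s (anchor end to sled end), the probe spring, the
#' measurement-layer imperfections (Gaussian force noise, linear probe drift,
#' static sled friction) and the integration grid. Noise and drift corrupt
#' only the *emitted* deflection series; the returned ground truth is exact.
#'
#' @param elements List of [chain_element()]s (at least one).
#' @param probe_spring_constant Probe spring constant, uN/um (> 0).
#' @param magnification Image scale for the emitted deflection, um/px.
#' @param static_friction Sled static-friction dead band, uN (>= 0): the sled
#'   does not move while the imbalance between chain tension and probe force
#'   is within this band.
#' @param drift_rate Probe drift, px/min, added to the emitted deflection.
#' @param noise_sd Measurement noise SD, uN, applied to the emitted series.
#' @param dt Euler time step, min (default 0.1).
#' @param duration Simulated duration, min.
#' @param sample_every Emission cadence, min (default 6, the usual recording
#'   interval for pulls).
#' @param seed Integer RNG seed; mandatory (reproducibility contract).
#' @return An object of class `pull_sim_config`.
#' @export
pull_sim_config <- function(elements, probe_spring_constant,
                            magnification = 0.25,
                            static_friction = 0, drift_rate = 0,
                            noise_sd = 0, dt = 0.1, duration = 1080,
                            sample_every = 6, seed) {
  if (!is.list(elements) || length(elements) < 1L ||
      !all(vapply(elements, inherits, logical(1), "chain_element")))
    stop("`elements` must be a non-empty list of chain_element objects")
  stopifnot(is.numeric(probe_spring_constant), probe_spring_constant > 0,
            is.numeric(magnification), magnification > 0,
            is.numeric(static_friction), static_friction >= 0,
            is.numeric(drift_rate), is.numeric(noise_sd), noise_sd >= 0,
            is.numeric(dt), dt > 0, is.numeric(duration), duration > 0,
            is.numeric(sample_every), sample_every > 0)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` is mandatory for simulation configs (no wall-clock seeding)")
  structure(
    list(elements = elements,
         probe_spring_constant = as.numeric(probe_spring_constant),
         magnification = as.numeric(magnification),
         static_friction = as.numeric(static_friction),
         drift_rate = as.numeric(drift_rate), noise_sd = as.numeric(noise_sd),
         dt = as.numeric(dt), duration = as.numeric(duration),
         sample_every = as.numeric(sample_every), seed = as.integer(seed)),
    class = "pull_sim_config")
}

# Effective mechanical parameters of an element at simulation time t.
element_params_at <- function(el, t) {
  if (t >= el$recruitment_time) {
    if (!is.null(el$recruit)) {
      r <- el$recruit
      return(list(stall = r$stall_force, v0 = r$free_shortening_velocity,
                  k = r$spring_constant, visc = r$dashpot_viscosity,
                  yield = r$yield_tension, active = r$stall_force > 0))
    }
    return(list(stall = el$stall_force, v0 = el$free_shortening_velocity,
                k = el$spring_constant, visc = el$dashpot_viscosity,
                yield = el$yield_tension, active = el$stall_force > 0))
  }
  if (el$kind == "CE" && is.finite(el$recruitment_time)) {
    # not yet recruited: motor off, no plastic flow
    return(list(stall = 0, v0 = 0, k = el$spring_constant, visc = Inf,
                yield = Inf, active = FALSE))
  }
  list(stall = el$stall_force, v0 = el$free_shortening_velocity,
       k = el$spring_constant, visc = el$dashpot_viscosity,
       yield = el$yield_tension, active = el$stall_force > 0)
}

#' Simulate a tractor pull from an active motor-spring-dashpot chain
#'
#' Quasi-static (inertia-free) simulation of an explant as a series chain of
#' active Kelvin elements pulling the sled cleat against a linear probe
#' spring. At every instant a single chain tension `T` balances the probe
#' force: with rest lengths `R_i`, element spring constants `k_i`, probe
#' constant `K_P` and total initial span `L0`, the loaded lengths satisfy
#' `sum(R_i + T/k_i) = L0 - d` and `T = K_P d`, giving the closed-form
#' `T = (L0 - sum R_i) / (sum 1/k_i + 1/K_P)`, clamped at `T >= 0` (the
#' probe cannot pull the sled). With a static-friction dead band `F_s`, the
#' sled (hence `d`) only moves once the imbalance `|T(d) - K_P d|` exceeds
#' `F_s`, and then settles where the imbalance equals `F_s`.
#'
#' Rest lengths evolve by explicit Euler: motors shorten them at
#' `v0 max(0, 1 - T/stall)` and plastic flow lengthens them at
#' `(T - yield)/viscosity` when `T > yield`. Measurement noise and linear
#' probe drift are applied to the emitted deflection series only; the ground
#' truth is exact.
#'
#' @param config A [pull_sim_config()].
#' @return An object of class `pull_simulation`: list with
#'   * `trace`: a [force_trace()] of the emitted (noisy, drifting) deflection
#'     with the correct unstressed reference positions, ready for
#'     [correct_drift()];
#'   * `truth`: data frame `time_min`, `tension_uN` (exact chain tension),
#'     `probe_force_uN`, `deflection_um`, `max_active_stall_uN`,
#'     `total_active_stall_uN`;
#'   * `rest_lengths`, `loaded_lengths`: matrices (time x element), um;
#'   * `config`.
#' @export
simulate_tractor_pull <- function(config) {
  stopifnot(inherits(config, "pull_sim_config"))
  els <- config$elements
  n <- length(els)
  KP <- config$probe_spring_constant
  Fs <- config$static_friction
  dt <- config$dt
  set.seed(config$seed)

  R <- vapply(els, function(e) e$rest_length, numeric(1))
  # initial span: chain unloaded, probe just touching (T = 0, d = 0)
  L0 <- sum(R)
  d <- 0

  times <- seq(0, config$duration, by = dt)
  emit_at <- seq(0, config$duration, by = config$sample_every)
  n_emit <- length(emit_at)
  truth <- data.frame(time_min = emit_at, tension_uN = NA_real_,
                      probe_force_uN = NA_real_, deflection_um = NA_real_,
                      max_active_stall_uN = NA_real_,
                      total_active_stall_uN = NA_real_)
  rest_m <- matrix(NA_real_, n_emit, n)
  load_m <- matrix(NA_real_, n_emit, n)
  emit_i <- 1L

  for (ti in seq_along(times)) {
    t <- times[ti]
    pars <- lapply(els, element_params_at, t = t)
    Cchain <- sum(vapply(pars, function(p) 1 / p$k, numeric(1)))
    slack <- L0 - sum(R)
    if (!is.finite(slack))
      stop("force-balance solve failed at step ", ti, " (t = ", t, " min): ",
           "non-finite chain state")
    # sled position update with friction dead band
    tension_at <- function(dd) max((slack - dd) / Cchain, 0)
    imbalance <- tension_at(d) - KP * d
    if (imbalance > Fs) {
      d <- (slack - Cchain * Fs) / (1 + Cchain * KP)
      d <- max(d, 0)
      # recompute so the imbalance sits on the +Fs edge
    } else if (imbalance < -Fs) {
      d <- max((slack + Cchain * Fs) / (1 + Cchain * KP), 0)
    }
    Tn <- tension_at(d)

    if (emit_i <= n_emit && abs(t - emit_at[emit_i]) < dt / 2) {
      act <- vapply(pars, function(p) if (p$active) p$stall else NA_real_, numeric(1))
      truth$tension_uN[emit_i] <- Tn
      truth$probe_force_uN[emit_i] <- KP * d
      truth$deflection_um[emit_i] <- d
      truth$max_active_stall_uN[emit_i] <- if (all(is.na(act))) 0 else max(act, na.rm = TRUE)
      truth$total_active_stall_uN[emit_i] <- sum(act, na.rm = TRUE)
      rest_m[emit_i, ] <- R
      load_m[emit_i, ] <- R + Tn / vapply(pars, function(p) p$k, numeric(1))
      emit_i <- emit_i + 1L
    }

    # Euler update of rest lengths
    dR <- vapply(pars, function(p) {
      v <- 0
      if (p$stall > 0 && p$v0 > 0) v <- v - p$v0 * max(0, 1 - Tn / p$stall)
      if (is.finite(p$yield) && Tn > p$yield && is.finite(p$visc))
        v <- v + (Tn - p$yield) / p$visc
      v
    }, numeric(1))
    R <- pmax(R + dR * dt, 0)
  }

  M <- config$magnification
  drift_px <- config$drift_rate * truth$time_min
  noise_px <- stats::rnorm(n_emit, 0, config$noise_sd / (KP * M))
  deflection_px <- truth$deflection_um / M + drift_px + noise_px
  cal <- probe_calibration(KP, M, probe_id = "simulated")
  trace <- force_trace(truth$time_min, deflection_px, cal,
                       pre_unstressed_px = 0,
                       post_unstressed_px = config$drift_rate * config$duration)
  structure(list(trace = trace, truth = truth, rest_lengths = rest_m,
                 loaded_lengths = load_m, config = config),
            class = "pull_simulation")
}

#' @export
print.pull_simulation <- function(x, ...) {
  cat(sprintf("Tractor-pull simulation: %d elements, %g min, dt %g min, seed %d\n",
              length(x$config$elements), x$config$duration, x$config$dt,
              x$config$seed))
  cat(sprintf("  terminal tension %.3g uN (max %.3g uN)\n",
              x$truth$tension_uN[nrow(x$truth)], max(x$truth$tension_uN)))
  invisible(x)
}

#' Preset tractor-pull configurations
#'
#' Labeled calibrations of the chain simulator reproducing the landmark
#' magnitudes of circumblastoporal pulls. These presets are calibrations of
#' the simulator, not measurements:
#' * `"standard"`: five modules; CT modules flanking three CE modules that
#'   are recruited in sequence with growing stall forces. The flanking CT
#'   modules yield at ~2 uN, pinning tension near 2 uN (the plateau) until
#'   they are themselves recruited to CE at G+10.5 hr, after which tension
#'   rises toward 4-5 uN.
#' * `"ventralized"`: CT-only chain (no CE recruitment); tension asymptotes
#'   at the ~2 uN CT stall ceiling and shows no second rise.
#' * `"D180"`: CE modules directly attached to the strips (no weak CT
#'   flanks); a continuous rise with no plateau.
#'
#' @param type Preset name.
#' @param seed RNG seed for the config (default 1).
#' @param noise_sd,drift_rate,static_friction Measurement-layer settings
#'   (defaults: 0.05 uN noise, 0.02 px/min drift, no friction).
#' @param dt,duration Integration step and duration, min.
#' @return A [pull_sim_config()].
#' @export
pull_config_preset <- function(type = c("standard", "ventralized", "D180"),
                               seed = 1, noise_sd = 0.05, drift_rate = 0.02,
                               static_friction = 0, dt = 0.1, duration = 1080) {
  type <- match.arg(type)
  ct <- function(yield = 2.5, visc = 5, recruitment_time = Inf, recruit = NULL)
    chain_element("CT", stall_force = 2.0, free_shortening_velocity = 0.08,
                  spring_constant = 0.25, dashpot_viscosity = visc,
                  yield_tension = yield, rest_length = 600,
                  recruitment_time = recruitment_time, recruit = recruit)
  ce <- function(stall)
    chain_element("CE", stall_force = stall, free_shortening_velocity = 0.15,
                  spring_constant = 0.35, dashpot_viscosity = 50,
                  yield_tension = 20, rest_length = 600)
  elements <- switch(type,
    standard = list(
      ct(yield = 2.0, visc = 1, recruitment_time = 630, recruit = ce(4.5)),
      ct(recruitment_time = 300, recruit = ce(3.0)),
      ct(recruitment_time = 420, recruit = ce(4.0)),
      ct(recruitment_time = 540, recruit = ce(4.5)),
      ct(yield = 2.0, visc = 1, recruitment_time = 630, recruit = ce(4.5))
    ),
    ventralized = list(ct(), ct(), ct(), ct(), ct()),
    D180 = list(
      ct(yield = 20, recruitment_time = 150, recruit = ce(3.0)),
      ct(yield = 20, recruitment_time = 300, recruit = ce(4.0)),
      ct(yield = 20, recruitment_time = 450, recruit = ce(4.5))
    )
  )
  pull_sim_config(elements, probe_spring_constant = 0.05,
                  magnification = 0.25, static_friction = static_friction,
                  drift_rate = drift_rate, noise_sd = noise_sd, dt = dt,
                  duration = duration, seed = seed)
}

#' Simulate a step-strain stress-relaxation trace
#'
#' Forward model of the uniaxial relaxation test: with SLS parameters
#' `params`, imposed strain and cross-sectional area, the noise-free force is
#' `F(t) = SS(t) * area * strain` (uN, with area in mm2 and SS in Pa), and
#' multiplicative Gaussian measurement noise `(1 + eps_t)`,
#' `eps_t ~ N(0, noise_sd_rel)`, is applied per sample. Reproducible under
#' `seed`.
#'
#' @param params An [sls_parameters()].
#' @param strain Imposed strain (fraction, > 0; default 0.12).
#' @param area_mm2 Cross-sectional area, mm2 (default 0.5).
#' @param noise_sd_rel Relative noise SD (default 0.02).
#' @param n_samples Number of samples (>= 2; default 200).
#' @param duration_s Trace duration, s (default 300; relaxation is followed
#'   for five minutes).
#' @param seed Integer RNG seed (mandatory).
#' @param explant_type,stage_hr Labels stored on the trace.
#' @return A [relaxation_trace()].
#' @export
simulate_relaxation <- function(params, strain = 0.12, area_mm2 = 0.5,
                                noise_sd_rel = 0.02, n_samples = 200,
                                duration_s = 300, seed,
                                explant_type = "simulated", stage_hr = NA_real_) {
  stopifnot(inherits(params, "sls_parameters"))
  if (!is.numeric(n_samples) || n_samples < 2L) stop("`n_samples` must be >= 2")
  if (!is.numeric(strain) || strain <= 0) stop("`strain` must be > 0")
  if (!is.numeric(area_mm2) || area_mm2 <= 0) stop("`area_mm2` must be > 0")
  if (!is.numeric(noise_sd_rel) || noise_sd_rel < 0)
    stop("`noise_sd_rel` must be >= 0")
  if (missing(seed)) stop("`seed` is mandatory")
  set.seed(seed)
  t <- seq(0, duration_s, length.out = n_samples)
  f <- sls_stress(t, params) * area_mm2 * strain
  if (noise_sd_rel > 0) f <- f * (1 + stats::rnorm(n_samples, 0, noise_sd_rel))
  relaxation_trace(t, f, imposed_strain = strain, area_mm2 = area_mm2,
                   explant_type = explant_type, stage_hr = stage_hr)
}

#' Simulate marker tracks with prescribed regional strain rates
#'
#' Generates boundary-marker tracks for contiguous tissue regions tiling the
#' mediolateral axis, each deforming by piecewise-uniform exponential strain:
#' region `r` of initial width `w_r` has width `w_r * exp(rate_r/100 * t_hr)`
#' at time `t` (negative rates converge). The anchor-side end is fixed;
#' positions accumulate region widths from there. Optional Gaussian
#' positional jitter emulates tracking error on the emitted positions only;
#' ground-truth rates are recorded as an attribute.
#'
#' @param rates Named numeric vector of strain rates, %/hr, one per region in
#'   anchor-to-sled order (names are the region labels).
#' @param boundaries_um Region boundary positions at t = 0, um; strictly
#'   increasing, length `length(rates) + 1` (regions must tile the axis
#'   without overlap).
#' @param duration_min Track duration, min (default 60).
#' @param dt_min Sampling interval, min (default 2.5).
#' @param jitter_sd_um Positional jitter SD, um (default 0).
#' @param seed Integer RNG seed (mandatory).
#' @return A [marker_tracks()] with two tracks per region (its left and
#'   right boundary, labeled with the region) and attribute `truth_rates`.
#' @export
simulate_marker_tracks <- function(rates, boundaries_um, duration_min = 60,
                                   dt_min = 2.5, jitter_sd_um = 0, seed) {
  stopifnot(is.numeric(rates), length(rates) >= 1L, !is.null(names(rates)),
            is.numeric(boundaries_um))
  if (length(boundaries_um) != length(rates) + 1L)
    stop("`boundaries_um` must have length(rates) + 1 entries")
  if (any(diff(boundaries_um) <= 0))
    stop("regions overlap or are empty: `boundaries_um` must be strictly increasing")
  if (!is.numeric(jitter_sd_um) || jitter_sd_um < 0)
    stop("`jitter_sd_um` must be >= 0")
  if (missing(seed)) stop("`seed` is mandatory")
  set.seed(seed)
  t <- seq(0, duration_min, by = dt_min)
  w0 <- diff(boundaries_um)
  # widths over time: n_time x n_region
  widths <- outer(t / 60, rates / 100, function(th, r) exp(r * th))
  widths <- sweep(widths, 2L, w0, `*`)
  pos <- cbind(boundaries_um[1L], boundaries_um[1L] + t(apply(widths, 1L, cumsum)))
  if (length(rates) == 1L) pos <- cbind(boundaries_um[1L], boundaries_um[1L] + widths)
  out <- do.call(rbind, lapply(seq_along(rates), function(r) {
    rbind(
      data.frame(track_id = paste0(names(rates)[r], ".left"), time_min = t,
                 position_um = pos[, r], region = names(rates)[r]),
      data.frame(track_id = paste0(names(rates)[r], ".right"), time_min = t,
                 position_um = pos[, r + 1L], region = names(rates)[r])
    )
  }))
  if (jitter_sd_um > 0)
    out$position_um <- out$position_um +
      stats::rnorm(nrow(out), 0, jitter_sd_um)
  mt <- marker_tracks(out)
  attr(mt, "truth_rates") <- rates
  mt
}
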