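#' Standard-linear-solid (SLS) parameters
#'
#' The SLS model of tissue stress relaxation under a step strain:
#' `SS(t) = S_inf + S_sp * exp(-t / tau)`, with `SS` the structural stiffness
#' (stress / strain, Pa), `S_inf` the residual stiffness at infinite time,
#' `S_sp` the decaying (instantaneous-minus-residual) stiffness component and
#' `tau` the relaxation (e-folding) time in seconds. The apparent viscosity is
#' derived as `eta = tau * S_inf` (Pa s) and is always computed, never
#' user-supplied.
#'
#' @param S_inf Residual stiffness, Pa (>= 0).
#' @param S_sp Decaying stiffness component, Pa (>= 0).
#' @param tau Relaxation time, s (> 0). `NA` is allowed only for the
#'   degenerate no-decay case (`S_sp = 0`), where tau is unidentifiable.
#' @return An object of class `sls_parameters` with fields `S_inf`, `S_sp`,
#'   `tau`, `eta`.
#' @examples
#' sls_parameters(S_inf = 10, S_sp = 20, tau = 60)
#' @export
sls_parameters <- function(S_inf, S_sp, tau) {
  tau <- as.numeric(tau)  # accept logical NA for the degenerate case
  stopifnot(is.numeric(S_inf), is.numeric(S_sp), is.numeric(tau),
            length(S_inf) == 1L, length(S_sp) == 1L, length(tau) == 1L)
  if (!is.finite(S_inf) || S_inf < 0) stop("`S_inf` must be >= 0")
  if (!is.finite(S_sp) || S_sp < 0) stop("`S_sp` must be >= 0")
  if (is.na(tau)) {
    if (S_sp > 0) stop("`tau` may be NA only when S_sp = 0 (no decay)")
  } else if (!is.finite(tau) || tau <= 0) {
    stop("`tau` must be > 0")
  }
  structure(
    list(S_inf = as.numeric(S_inf), S_sp = as.numeric(S_sp),
         tau = as.numeric(tau), eta = as.numeric(tau) * as.numeric(S_inf)),
    class = "sls_parameters"
  )
}

#' @export
print.sls_parameters <- function(x, ...) {
  cat(sprintf("SLS parameters: S_inf = %.4g Pa, S_sp = %.4g Pa, tau = %.4g s, eta = %.4g Pa*s\n",
              x$S_inf, x$S_sp, x$tau, x$eta))
  invisible(x)
}

#' Evaluate the SLS stress-relaxation curve
#'
#' `SS(t) = S_inf + S_sp * exp(-t / tau)`. Strictly decreasing in `t` when
#' `S_sp > 0`, constant at `S_inf` when `S_sp = 0`.
#'
#' @param t Time(s) since strain application, s (>= 0).
#' @param params An [sls_parameters()].
#' @return Structural stiffness in Pa.
#' @export
sls_stress <- function(t, params) {
  stopifnot(inherits(params, "sls_parameters"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be finite and >= 0")
  if (params$S_sp == 0) return(rep(params$S_inf, length(t)))
  params$S_inf + params$S_sp * exp(-t / params$tau)
}

#' Step-strain stress-relaxation trace
#'
#' Record of a uniaxial tensile stress-relaxation test: the explant is
#' stretched along its mediolateral axis by a nominally fixed strain (stage
#' moved 300 um, typically 10-12% strain) over a second or two, then the probe
#' force is followed as stress relaxes. Times are seconds since strain
#' application.
#'
#' @param time_s Strictly increasing sample times (s), starting at or after 0.
#' @param force_uN Probe force at each sample, uN.
#' @param imposed_strain Nominal imposed engineering strain (fraction, > 0).
#' @param area_mm2 Tissue cross-sectional (sagittal sectional) area, mm2 (> 0).
#' @param strain Optional per-sample *realized* strain series (from marker
#'   positions over the attachment strips). When present it supersedes
#'   `imposed_strain` in stiffness computations.
#' @param explant_type Label: `"giant"`, `"D180"`, `"V180"`, `"AC"` or other.
#' @param stage_hr Developmental time of the test, hours after G0 (optional).
#' @return An object of class `relaxation_trace`.
#' @export
relaxation_trace <- function(time_s, force_uN, imposed_strain, area_mm2,
                             strain = NULL, explant_type = NA_character_,
                             stage_hr = NA_real_) {
  stopifnot(is.numeric(time_s), is.numeric(force_uN))
  if (length(time_s) != length(force_uN))
    stop("`time_s` and `force_uN` must have the same length")
  if (any(!is.finite(time_s)) || any(time_s < 0))
    stop("`time_s` must be finite and start at or after 0")
  if (any(diff(time_s) <= 0)) stop("`time_s` must be strictly increasing")
  if (!is.numeric(imposed_strain) || length(imposed_strain) != 1L ||
      !is.finite(imposed_strain) || imposed_strain <= 0)
    stop("`imposed_strain` must be a single positive fraction")
  if (!is.numeric(area_mm2) || length(area_mm2) != 1L ||
      !is.finite(area_mm2) || area_mm2 <= 0)
    stop("`area_mm2` must be a single positive number")
  if (!is.null(strain)) {
    if (length(strain) != length(time_s) || any(!is.finite(strain)) || any(strain <= 0))
      stop("`strain`, when given, must be positive and match the sample length")
  }
  structure(
    list(time_s = as.numeric(time_s), force_uN = as.numeric(force_uN),
         imposed_strain = as.numeric(imposed_strain),
         area_mm2 = as.numeric(area_mm2),
         strain = if (is.null(strain)) NULL else as.numeric(strain),
         explant_type = as.character(explant_type),
         stage_hr = as.numeric(stage_hr)),
    class = "relaxation_trace"
  )
}

#' @export
print.relaxation_trace <- function(x, ...) {
  cat(sprintf("Stress-relaxation trace (%s): %d samples over %.0f s, strain %.3g, area %.3g mm2\n",
              x$explant_type, length(x$time_s), max(x$time_s),
              x$imposed_strain, x$area_mm2))
  invisible(x)
}

#' @export
as.data.frame.relaxation_trace <- function(x, ...) {
  d <- data.frame(time_s = x$time_s, force_uN = x$force_uN)
  if (!is.null(x$strain)) d$strain <- x$strain
  d
}

#' Structural stiffness over time from a relaxation trace
#'
#' Structural stiffness is stress over strain for the composite explant:
#' `SS(t) = (F(t) / area) / strain(t)`, with force in uN and area in mm2 so
#' that 1 uN/mm2 = 1 Pa. The realized strain series, when recorded, supersedes
#' the nominal imposed strain.
#'
#' @param trace A [relaxation_trace()].
#' @return A data frame with columns `time_s`, `stiffness_pa`.
#' @export
structural_stiffness_series <- function(trace) {
  stopifnot(inherits(trace, "relaxation_trace"))
  strain <- if (!is.null(trace$strain)) trace$strain else trace$imposed_strain
  data.frame(time_s = trace$time_s,
             stiffness_pa = (trace$force_uN / trace$area_mm2) / strain)
}

#' Residual structural stiffness at 180 s
#'
#' The practical proxy for `S_inf`: structural stiffness evaluated from the
#' force and realized strain 180 s after strain application, linearly
#' interpolated between the bracketing samples when no sample falls exactly
#' at 180 s.
#'
#' @param trace A [relaxation_trace()] spanning at least 180 s.
#' @param at_s Evaluation time, s (default 180).
#' @return Stiffness in Pa.
#' @export
residual_stiffness_180 <- function(trace, at_s = 180) {
  stopifnot(inherits(trace, "relaxation_trace"))
  if (max(trace$time_s) < at_s || min(trace$time_s) > at_s)
    stop(sprintf("trace does not span %g s (range %g-%g s)",
                 at_s, min(trace$time_s), max(trace$time_s)))
  ss <- structural_stiffness_series(trace)
  stats::approx(ss$time_s, ss$stiffness_pa, xout = at_s)$y
}

#' Bulk spring stiffness (force / strain)
#'
#' The cross-section-weighted force-bearing capacity of an explant: the force
#' at 180 s divided by the strain at 180 s. Units are uN, since strain is a
#' dimensionless fraction.
#'
#' @param force_at_180_uN Force at 180 s, uN.
#' @param strain_at_180 Realized strain at 180 s (fraction, > 0).
#' @return Spring stiffness in uN.
#' @export
spring_stiffness <- function(force_at_180_uN, strain_at_180) {
  stopifnot(is.numeric(force_at_180_uN), is.numeric(strain_at_180))
  if (any(!is.finite(strain_at_180)) || any(strain_at_180 <= 0))
    stop("`strain_at_180` must be > 0")
  force_at_180_uN / strain_at_180
}

# Heuristic initialization for the SLS fit: residual from the tail,
# amplitude from the head, tau from the half-decay crossing (fallback span/3).
sls_init <- function(time_s, stiffness_pa) {
  s_inf0 <- max(stiffness_pa[length(stiffness_pa)], 0)
  s_sp0 <- max(stiffness_pa[1L] - s_inf0, 1e-8)
  half <- s_inf0 + s_sp0 / 2
  below <- which(stiffness_pa <= half)
  span <- max(time_s) - min(time_s)
  tau0 <- if (length(below) && time_s[below[1L]] > min(time_s)) {
    (time_s[below[1L]] - min(time_s)) / log(2)
  } else {
    span / 3
  }
  list(S_inf = s_inf0, S_sp = s_sp0, tau = max(tau0, 1e-6))
}

#' Fit the SLS model to a stress-relaxation series
#'
#' Bounded nonlinear least squares of `SS(t) = S_inf + S_sp * exp(-t / tau)`
#' against a structural-stiffness series, with `S_inf, S_sp >= 0` and
#' `tau > 0`. Two analytical routes are provided: `"nls"` (default;
#' `stats::nls` with the bounded `"port"` trust-region algorithm) and
#' `"optim"` (L-BFGS-B minimisation of the residual sum of squares), so the
#' fit can be cross-checked by an independent optimiser. If the primary route
#' fails to converge, the result is returned flagged (`converged = FALSE`)
#' with the fallback estimates, never silently defaulted.
#'
#' Because the model assumes an instantaneous step strain while the real ramp
#' takes one to a few seconds, samples at `t < ramp_end_s` (default 3 s) are
#' excluded from the fit.
#'
#' A series with no measurable decay (constant within numerical noise) is
#' degenerate: `S_inf` is the mean, `S_sp = 0`, and `tau` is unidentifiable
#' (returned as `NA`, `tau_identifiable = FALSE`).
#'
#' @param x A [relaxation_trace()] or a data frame with columns `time_s`,
#'   `stiffness_pa`.
#' @param init Optional [sls_parameters()] used as the starting point;
#'   defaults to a data-driven heuristic.
#' @param ramp_end_s Samples earlier than this are excluded (default 3 s).
#' @param method `"nls"` (bounded trust-region, default) or `"optim"`
#'   (L-BFGS-B), the second analytical route.
#' @return An object of class `sls_fit`: list with `parameters`
#'   ([sls_parameters()]), `converged`, `tau_identifiable`, `rms_residual_pa`,
#'   `method`, `n_used`, `ramp_end_s`.
#' @examples
#' p <- sls_parameters(10, 20, 60)
#' tr <- simulate_relaxation(p, strain = 0.12, area_mm2 = 0.5,
#'                           noise_sd_rel = 0, n_samples = 100,
#'                           duration_s = 300, seed = 1)
#' fit_sls(tr)$parameters
#' @export
fit_sls <- function(x, init = NULL, ramp_end_s = 3, method = c("nls", "optim")) {
  method <- match.arg(method)
  if (inherits(x, "relaxation_trace")) x <- structural_stiffness_series(x)
  stopifnot(is.data.frame(x), all(c("time_s", "stiffness_pa") %in% names(x)))
  keep <- x$time_s >= ramp_end_s
  t <- x$time_s[keep]
  ss <- x$stiffness_pa[keep]
  if (length(t) < 4L)
    stop("need at least 4 samples after the ramp-exclusion window to fit the SLS model")

  # degenerate, no-decay series
  amp <- diff(range(ss))
  if (amp <= max(1e-10, 1e-9 * max(abs(ss)))) {
    pars <- sls_parameters(S_inf = mean(ss), S_sp = 0, tau = NA_real_)
    return(structure(list(parameters = pars, converged = TRUE,
                          tau_identifiable = FALSE,
                          rms_residual_pa = sqrt(mean((ss - mean(ss))^2)),
                          method = "degenerate", n_used = length(t),
                          ramp_end_s = ramp_end_s),
                     class = "sls_fit"))
  }

  start <- if (is.null(init)) sls_init(t, ss) else
    list(S_inf = init$S_inf, S_sp = max(init$S_sp, 1e-8), tau = init$tau)
  lower <- c(S_inf = 0, S_sp = 0, tau = 1e-6)

  est <- NULL
  converged <- FALSE
  used_method <- method
  if (method == "nls") {
    fit <- tryCatch(
      stats::nls(ss ~ S_inf + S_sp * exp(-t / tau),
                 data = data.frame(t = t, ss = ss),
                 start = start, algorithm = "port", lower = lower,
                 control = stats::nls.control(maxiter = 500, warnOnly = FALSE,
                                              tol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      est <- as.list(stats::coef(fit))
      converged <- fit$convInfo$isConv
    }
  }
  rss <- function(p) {
    r <- ss - (p[1L] + p[2L] * exp(-t / p[3L]))
    sum(r * r)
  }
  if (is.null(est) || method == "optim") {
    op <- stats::optim(unlist(start), rss, method = "L-BFGS-B",
                       lower = lower,
                       control = list(factr = 10, maxit = 2000,
                                      parscale = pmax(abs(unlist(start)), 1e-3)))
    est <- as.list(op$par)
    names(est) <- c("S_inf", "S_sp", "tau")
    converged <- op$convergence == 0
    used_method <- if (method == "optim") "optim" else "optim-fallback"
  }

  # Variable-projection refinement: for fixed tau the model is linear in
  # (S_inf, S_sp), so profile the RSS over tau alone and solve the linear
  # part exactly. Tightens the optimiser's last digits at negligible cost.
  prof <- function(tau) {
    X <- cbind(1, exp(-t / tau))
    cf <- tryCatch(stats::lm.fit(X, ss)$coefficients, error = function(e) NULL)
    if (is.null(cf) || anyNA(cf) || any(cf < 0)) return(NULL)
    list(coef = cf, rss = sum((ss - X %*% cf)^2))
  }
  if (is.finite(est$tau) && est$tau > 0) {
    opt <- tryCatch(
      stats::optimize(function(lt) {
        p <- prof(exp(lt))
        if (is.null(p)) .Machine$double.xmax / 2 else p$rss
      }, interval = log(est$tau) + c(-0.7, 0.7), tol = 1e-12),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$objective)) {
      tau_ref <- exp(opt$minimum)
      p <- prof(tau_ref)
      if (!is.null(p) && p$rss <= rss(c(est$S_inf, est$S_sp, est$tau))) {
        est <- list(S_inf = unname(p$coef[1L]), S_sp = unname(p$coef[2L]),
                    tau = tau_ref)
      }
    }
  }

  pars <- sls_parameters(max(est$S_inf, 0), max(est$S_sp, 0), est$tau)
  resid <- ss - sls_stress(t, pars)
  out <- structure(
    list(parameters = pars, converged = converged, tau_identifiable = TRUE,
         rms_residual_pa = sqrt(mean(resid^2)),
         method = used_method, n_used = length(t), ramp_end_s = ramp_end_s),
    class = "sls_fit")
  if (!converged)
    warning("SLS fit did not converge; parameters returned flagged (converged = FALSE)")
  out
}

#' @export
print.sls_fit <- function(x, ...) {
  cat(sprintf("SLS fit (%s, n = %d, ramp excluded < %g s): %sconverged, RMS residual %.3g Pa\n",
              x$method, x$n_used, x$ramp_end_s,
              if (x$converged) "" else "NOT ", x$rms_residual_pa))
  print(x$parameters)
  invisible(x)
}

#' Plastic deformation after release from tension
#'
#' After release, explants recoil but remain somewhat longer than before the
#' test: part of the applied strain is lost to permanent (plastic)
#' deformation. With widths measured before stretch (`initial`), at peak
#' stretch (`peak`) and after recovery (`recovered`):
#' applied strain = (peak - initial)/initial, residual elongation =
#' (recovered - initial)/initial, plastic fraction = residual/applied.
#'
#' @param initial_width,peak_strained_width,recovered_width Widths in any
#'   common length unit; must satisfy `initial <= recovered <= peak` (a
#'   tension test).
#' @return List with `applied_strain`, `residual_strain`, `plastic_fraction`.
#' @examples
#' plastic_fraction(1000, 1120, 1030)  # 12% applied, 3% residual, 25% plastic
#' @export
plastic_fraction <- function(initial_width, peak_strained_width, recovered_width) {
  stopifnot(is.numeric(initial_width), is.numeric(peak_strained_width),
            is.numeric(recovered_width))
  if (any(initial_width <= 0)) stop("`initial_width` must be positive")
  if (any(peak_strained_width < recovered_width) ||
      any(recovered_width < initial_width))
    stop("width ordering violated: need initial <= recovered <= peak ",
         "(got initial ", initial_width, ", recovered ", recovered_width,
         ", peak ", peak_strained_width, ")")
  if (any(peak_strained_width == initial_width))
    stop("no strain was applied (peak equals initial width)")
  applied <- (peak_strained_width - initial_width) / initial_width
  residual <- (recovered_width - initial_width) / initial_width
  list(applied_strain = applied, residual_strain = residual,
       plastic_fraction = residual / applied)
}

#' Recoil measurement from a tension-release step
#'
#' When the anchor is moved toward the probe, a known tension is released and
#' the explant recoils elastically. The immediate (first `recoil_window_s`
#' seconds, conventionally 5 s) recoil is summarised by the fraction of the
#' released tension recovered and by the recoil distance as a fraction of the
#' mediolateral explant width.
#'
#' @param tension_released_uN Tension released by anchor movement, uN (> 0).
#' @param immediate_recoil_uN Tension recovered within the window, uN; must
#'   lie in `[0, tension_released_uN]`.
#' @param recoil_distance_frac Immediate recoil distance as a fraction of
#'   explant width (e.g. 0.0093 for 0.93%).
#' @param recoil_window_s Window length, s (> 0; default 5).
#' @return An object of class `recoil_measurement`.
#' @export
recoil_measurement <- function(tension_released_uN, immediate_recoil_uN,
                               recoil_distance_frac, recoil_window_s = 5) {
  stopifnot(is.numeric(tension_released_uN), is.numeric(immediate_recoil_uN),
            is.numeric(recoil_distance_frac), is.numeric(recoil_window_s))
  if (tension_released_uN <= 0) stop("`tension_released_uN` must be > 0")
  if (immediate_recoil_uN < 0 || immediate_recoil_uN > tension_released_uN)
    stop("`immediate_recoil_uN` must lie in [0, tension_released_uN]")
  if (recoil_window_s <= 0) stop("`recoil_window_s` must be > 0")
  if (recoil_distance_frac < 0) stop("`recoil_distance_frac` must be >= 0")
  structure(
    list(tension_released_uN = tension_released_uN,
         immediate_recoil_uN = immediate_recoil_uN,
         recoil_distance_frac = recoil_distance_frac,
         recoil_window_s = recoil_window_s),
    class = "recoil_measurement")
}

#' Fractional recoil and recoil rate
#'
#' Fractional recoil (%) is the immediate elastic recoil tension divided by
#' the tension released by the anchor movement. The recoil rate converts the
#' immediate recoil distance (percent of mediolateral explant width, over the
#' first few seconds) to %/hr, the unit in which convergence rates are
#' reported (e.g. 0.93% of width in 5 s is about 670 %/hr).
#'
#' @param m A [recoil_measurement()].
#' @return List with `fractional_recoil_pct` and `recoil_rate_pct_hr`.
#' @export
recoil_metrics <- function(m) {
  stopifnot(inherits(m, "recoil_measurement"))
  list(
    fractional_recoil_pct = 100 * m$immediate_recoil_uN / m$tension_released_uN,
    recoil_rate_pct_hr = 100 * m$recoil_distance_frac / m$recoil_window_s * 3600
  )
}
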