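#' Probe calibration metadata
#'
#' A calibrated optical-fibre cantilever probe is described by its spring
#' constant (force per unit tip displacement) and the magnification of the
#' imaging system used to record its deflection. Force is recovered from a
#' recorded deflection as `deflection_px * magnification * spring_constant`.
#'
#' @param spring_constant Probe spring constant, uN per um of tip displacement.
#'   Must be a single positive finite number.
#' @param magnification Image scale, um per pixel. Must be positive and finite.
#' @param probe_id Optional label (e.g. `"probe3"`).
#' @return An object of class `probe_calibration`.
#' @examples
#' probe_calibration(27, 0.25, "probe3")
#' @export
probe_calibration <- function(spring_constant, magnification, probe_id = NA_character_) {
  stopifnot(is.numeric(spring_constant), length(spring_constant) == 1L,
            is.numeric(magnification), length(magnification) == 1L)
  if (!is.finite(spring_constant) || spring_constant <= 0)
    stop("`spring_constant` must be a positive finite number (uN/um)")
  if (!is.finite(magnification) || magnification <= 0)
    stop("`magnification` must be a positive finite number (um/px)")
  structure(
    list(spring_constant = as.numeric(spring_constant),
         magnification = as.numeric(magnification),
         probe_id = as.character(probe_id)),
    class = "probe_calibration"
  )
}

#' @export
print.probe_calibration <- function(x, ...) {
  cat(sprintf("Probe calibration%s: K_P = %g uN/um, M = %g um/px\n",
              if (is.na(x$probe_id)) "" else paste0(" [", x$probe_id, "]"),
              x$spring_constant, x$magnification))
  invisible(x)
}

#' Convert probe deflection to force
#'
#' Applies the probe calibration: `F = D * M * K_P`, where `D` is deflection in
#' pixels, `M` the magnification in um/px and `K_P` the probe spring constant
#' in uN/um. Linear in deflection; sign is preserved (a negative deflection
#' yields a negative force, which downstream code flags rather than clips).
#'
#' @param deflection_px Numeric vector of deflections, pixels. Must be finite.
#' @param calibration A [probe_calibration()].
#' @return Force(s) in uN.
#' @examples
#' deflection_to_force(100, probe_calibration(0.02, 0.5))  # 1 uN
#' @export
deflection_to_force <- function(deflection_px, calibration) {
  stopifnot(inherits(calibration, "probe_calibration"))
  if (!is.numeric(deflection_px) || any(!is.finite(deflection_px)))
    stop("`deflection_px` must be finite numeric")
  deflection_px * calibration$magnification * calibration$spring_constant
}

#' Tractor-pull force trace
#'
#' A time series of probe deflections recorded while an explant pulls the sled
#' cleat against a calibrated probe, together with the probe calibration and
#' the unstressed probe positions observed before and after the assay (used
#' for linear drift correction). Time is measured in minutes from the onset of
#' gastrulation (G0). The derived force series (uN) is computed from the
#' deflection via [deflection_to_force()].
#'
#' @param time_min Strictly increasing sample times, minutes after G0.
#' @param deflection_px Recorded probe deflection at each sample, pixels.
#' @param calibration A [probe_calibration()].
#' @param pre_unstressed_px,post_unstressed_px Unstressed probe position
#'   (pixels) observed before/after the assay; `NA` if not recorded, in which
#'   case [correct_drift()] refuses to correct and marks the trace
#'   `"uncorrected"`.
#' @return An object of class `force_trace`: a list with elements `time_min`,
#'   `deflection_px`, `force_uN`, `calibration`, `pre_unstressed_px`,
#'   `post_unstressed_px`, `status` (one of `"raw"`, `"drift_corrected"`,
#'   `"uncorrected"`), and `friction_offset_uN` (0 until
#'   [subtract_friction()] is applied).
#' @export
force_trace <- function(time_min, deflection_px, calibration,
                        pre_unstressed_px = NA_real_,
                        post_unstressed_px = NA_real_) {
  stopifnot(is.numeric(time_min), is.numeric(deflection_px),
            inherits(calibration, "probe_calibration"))
  if (length(time_min) != length(deflection_px))
    stop("`time_min` and `deflection_px` must have the same length")
  if (length(time_min) < 1L) stop("a force trace needs at least one sample")
  if (any(!is.finite(time_min)) || any(!is.finite(deflection_px)))
    stop("times and deflections must be finite")
  if (any(diff(time_min) <= 0))
    stop("`time_min` must be strictly increasing (offending index ",
         which(diff(time_min) <= 0)[1L] + 1L, ")")
  structure(
    list(time_min = as.numeric(time_min),
         deflection_px = as.numeric(deflection_px),
         force_uN = deflection_to_force(as.numeric(deflection_px), calibration),
         calibration = calibration,
         pre_unstressed_px = as.numeric(pre_unstressed_px),
         post_unstressed_px = as.numeric(post_unstressed_px),
         status = "raw",
         friction_offset_uN = 0),
    class = "force_trace"
  )
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("Tractor-pull force trace: %d samples, %.1f-%.1f min after G0\n",
              length(x$time_min), min(x$time_min), max(x$time_min)))
  cat(sprintf("  status: %s; friction offset: %g uN; force range %.3g to %.3g uN\n",
              x$status, x$friction_offset_uN, min(x$force_uN), max(x$force_uN)))
  print(x$calibration)
  invisible(x)
}

#' @export
as.data.frame.force_trace <- function(x, ...) {
  data.frame(time_min = x$time_min,
             deflection_px = x$deflection_px,
             force_uN = x$force_uN)
}

#' Correct probe drift by linear interpolation of the unstressed positions
#'
#' Probe drift over the assay is estimated from the unstressed probe position
#' recorded before and after the measurement, interpolated linearly in time
#' over the trace and subtracted from the recorded deflection. The corrected
#' deflection at the first sample equals raw minus `pre_unstressed_px`, at the
#' last sample raw minus `post_unstressed_px`.
#'
#' Corrected deflections (hence forces) can be slightly negative; the probe
#' cannot push, so these are measurement/drift artefacts. They are retained,
#' not clipped (clipping would bias hourly means), and counted in the returned
#' trace's `n_negative` field.
#'
#' If either reference position is missing the trace is returned with status
#' `"uncorrected"` and a warning, never silently passed through as corrected.
#'
#' @param trace A [force_trace()].
#' @return A `force_trace` with corrected deflection and force, status
#'   `"drift_corrected"` (or `"uncorrected"` if references are missing).
#' @export
correct_drift <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  pre <- trace$pre_unstressed_px
  post <- trace$post_unstressed_px
  if (is.na(pre) || is.na(post)) {
    warning("unstressed reference position(s) missing; trace left uncorrected")
    trace$status <- "uncorrected"
    return(trace)
  }
  t <- trace$time_min
  span <- max(t) - min(t)
  frac <- if (span > 0) (t - min(t)) / span else rep(0, length(t))
  drift <- pre + frac * (post - pre)
  out <- trace
  out$deflection_px <- trace$deflection_px - drift
  out$force_uN <- deflection_to_force(out$deflection_px, trace$calibration)
  # references are consumed: a corrected trace is re-zeroed
  out$pre_unstressed_px <- 0
  out$post_unstressed_px <- 0
  out$status <- "drift_corrected"
  out$n_negative <- sum(out$force_uN < 0)
  out
}

#' Compensate static sled friction with an explicit additive offset
#'
#' Sled-substrate friction reduces the observed force by a roughly constant
#' amount while the explant is under tension; this optional correction *adds*
#' the offset back to every strictly positive force sample. It is off by
#' default throughout the package because the friction loss is only an
#' approximate, systematic underestimate. No force is fabricated at rest:
#' samples at exactly 0 uN (and negative, drift-artefact samples) are left
#' unchanged. The applied offset is recorded in `friction_offset_uN`.
#'
#' @param trace A [force_trace()].
#' @param friction_offset_uN Non-negative offset in uN (0 = identity).
#' @return A `force_trace` with compensated forces.
#' @export
subtract_friction <- function(trace, friction_offset_uN) {
  stopifnot(inherits(trace, "force_trace"))
  if (!is.numeric(friction_offset_uN) || length(friction_offset_uN) != 1L ||
      !is.finite(friction_offset_uN) || friction_offset_uN < 0)
    stop("`friction_offset_uN` must be a single non-negative number")
  out <- trace
  pos <- out$force_uN > 0
  out$force_uN[pos] <- out$force_uN[pos] + friction_offset_uN
  # keep deflection consistent with the compensated force
  out$deflection_px <- out$force_uN /
    (trace$calibration$magnification * trace$calibration$spring_constant)
  out$friction_offset_uN <- trace$friction_offset_uN + friction_offset_uN
  out
}

#' Hourly summary of a drift-corrected force trace
#'
#' Bins samples into half-open whole-hour windows `[h, h+1)` after G0 and
#' reports the mean force and the standard error of the hourly mean
#' (sample SD / sqrt(n)) per bin. Bins with a single sample report `NA` SEM
#' (undefined); empty bins are omitted.
#'
#' @param trace A drift-corrected [force_trace()] (apply [correct_drift()]
#'   first; a raw or uncorrected trace is an error).
#' @return A data frame of class `hourly_summary` with columns `hour`
#'   (integer bin index), `mean_uN`, `sem_uN`, `n`.
#' @export
hourly_summary <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  if (!identical(trace$status, "drift_corrected"))
    stop("hourly_summary requires a drift-corrected trace; run correct_drift() first")
  hour <- floor(trace$time_min / 60)
  agg <- split(trace$force_uN, hour)
  out <- data.frame(
    hour = as.integer(names(agg)),
    mean_uN = vapply(agg, mean, numeric(1)),
    sem_uN = vapply(agg, function(v) {
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1)),
    n = vapply(agg, length, integer(1)),
    row.names = NULL
  )
  out <- out[order(out$hour), , drop = FALSE]
  class(out) <- c("hourly_summary", "data.frame")
  out
}
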