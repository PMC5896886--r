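#' Marker tracks along the mediolateral axis
#'
#' Labeled positions of tracked markers/edges over time, used to compute
#' convergence, regional strain and shear rates. Positions are in um along
#' the mediolateral axis, increasing from the anchor toward the sled; time is
#' minutes after G0. Each region (e.g. `"dorsal"`, `"LV"`, `"sled"`,
#' `"IMZ-edge"`) is bounded by the two tracks carrying its label.
#'
#' @param tracks Data frame with columns `track_id`, `time_min`,
#'   `position_um`, `region`.
#' @return An object of class `marker_tracks` (a validated data frame).
#' @export
marker_tracks <- function(tracks) {
  stopifnot(is.data.frame(tracks))
  need <- c("track_id", "time_min", "position_um", "region")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) stop("missing track columns: ", paste(miss, collapse = ", "))
  tracks <- tracks[order(tracks$track_id, tracks$time_min), need, drop = FALSE]
  for (id in unique(tracks$track_id)) {
    tt <- tracks$time_min[tracks$track_id == id]
    if (any(diff(tt) <= 0))
      stop("track '", id, "' has non-increasing times")
  }
  class(tracks) <- c("marker_tracks", "data.frame")
  tracks
}

# OLS slope and value-at-window-start of a (time, y) series restricted to
# [window[1], window[2]]. Endpoint differencing available for cross-checks.
window_slope <- function(time_min, y, window, method = c("regression", "endpoint")) {
  method <- match.arg(method)
  if (window[2] <= window[1]) stop("window must be an increasing (start, end) pair")
  keep <- time_min >= window[1] & time_min <= window[2]
  if (sum(keep) < 2L)
    stop(sprintf("window [%g, %g] min contains fewer than 2 samples", window[1], window[2]))
  t <- time_min[keep]
  v <- y[keep]
  slope <- if (method == "regression") {
    tc <- t - mean(t)
    sum(tc * v) / sum(tc * tc)
  } else {
    (v[length(v)] - v[1L]) / (t[length(t)] - t[1L])
  }
  # reference value at window start: interpolated observation
  y0 <- stats::approx(time_min, y, xout = window[1], rule = 2)$y
  list(slope_per_min = slope, y_at_start = y0)
}

#' Convergence rate of a width series
#'
#' The rate at which a tissue width (e.g. the mediolateral span of the widest
#' part of the IMZ, or the sled-to-anchor distance) decreases over a time
#' window. The rate is the ordinary least-squares slope of width versus time
#' over the window, sign-flipped so that convergence is positive, reported
#' both in um/min and normalized as %/hr of the width at the window start.
#'
#' @param width_series Data frame with columns `time_min`, `width_um`.
#' @param window Length-2 numeric `(start, end)` in minutes after G0.
#' @param method `"regression"` (OLS slope, default; robust to sampling
#'   jitter) or `"endpoint"` (first/last differencing, for cross-checks).
#' @return An object of class `convergence_rate`: list with `um_per_min`,
#'   `pct_per_hr` (both positive for convergence), `width_at_start_um`,
#'   `window`, `method`.
#' @export
convergence_rate <- function(width_series, window, method = c("regression", "endpoint")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(width_series),
            all(c("time_min", "width_um") %in% names(width_series)))
  ws <- window_slope(width_series$time_min, width_series$width_um, window, method)
  um_per_min <- -ws$slope_per_min
  structure(
    list(um_per_min = um_per_min,
         pct_per_hr = 100 * um_per_min / ws$y_at_start * 60,
         width_at_start_um = ws$y_at_start,
         window = as.numeric(window), method = method),
    class = "convergence_rate")
}

#' @export
print.convergence_rate <- function(x, ...) {
  cat(sprintf("Convergence over [%g, %g] min: %.3g um/min = %.3g %%/hr (width at start %.4g um)\n",
              x$window[1], x$window[2], x$um_per_min, x$pct_per_hr,
              x$width_at_start_um))
  invisible(x)
}

#' Regional strain rate from bounding marker tracks
#'
#' The signed strain rate of the tissue segment bounded by the two tracks
#' labeled with `region`: OLS slope of the segment length over the window,
#' normalized by the length at the window start, in %/hr. Negative values
#' indicate convergence (the segment shrinks), matching the reporting
#' convention for regional strains; it is the exact negative of the
#' [convergence_rate()] of the same segment.
#'
#' @param tracks A [marker_tracks()].
#' @param region Region label; exactly two tracks must carry it.
#' @param window Length-2 numeric `(start, end)`, minutes after G0.
#' @param method Passed to the slope computation, see [convergence_rate()].
#' @return Signed strain rate, %/hr, with the window as attribute `window`.
#' @export
regional_strain_rate <- function(tracks, region, window,
                                 method = c("regression", "endpoint")) {
  method <- match.arg(method)
  stopifnot(inherits(tracks, "marker_tracks"))
  sub <- tracks[tracks$region == region, , drop = FALSE]
  ids <- unique(sub$track_id)
  if (length(ids) != 2L)
    stop("region '", region, "' must be bounded by exactly 2 tracks (found ",
         length(ids), ")")
  a <- sub[sub$track_id == ids[1L], ]
  b <- sub[sub$track_id == ids[2L], ]
  common <- intersect(a$time_min, b$time_min)
  if (length(common) < 2L)
    stop("bounding tracks of region '", region, "' share fewer than 2 time points")
  common <- sort(common)
  len <- abs(b$position_um[match(common, b$time_min)] -
             a$position_um[match(common, a$time_min)])
  ws <- window_slope(common, len, window, method)
  rate <- 100 * ws$slope_per_min / ws$y_at_start * 60
  attr(rate, "window") <- as.numeric(window)
  rate
}

#' Shear rate relative to the attachment strips
#'
#' Explant convergence is accommodated partly by movement of the sled toward
#' the anchor and partly by slippage (shear) of the tissue relative to the
#' attachment strips: shear rate = convergence rate of the edges of the
#' widest part of the IMZ minus the convergence rate of the sled toward the
#' anchor, both in %/hr over the same window.
#'
#' @param edge_convergence,sled_convergence Either [convergence_rate()]
#'   objects (their windows must agree) or plain %/hr numbers.
#' @return Shear rate, %/hr.
#' @export
shear_rate <- function(edge_convergence, sled_convergence) {
  get_rate <- function(x) {
    if (inherits(x, "convergence_rate")) x$pct_per_hr else as.numeric(x)
  }
  w1 <- if (inherits(edge_convergence, "convergence_rate")) edge_convergence$window
  w2 <- if (inherits(sled_convergence, "convergence_rate")) sled_convergence$window
  if (!is.null(w1) && !is.null(w2) && !isTRUE(all.equal(w1, w2)))
    stop("edge and sled convergence were computed over different windows")
  get_rate(edge_convergence) - get_rate(sled_convergence)
}

#' Sagittal-sectional-area (SSA) model
#'
#' Polynomial regression of explant sagittal sectional area (mm2) on hours
#' after G0, used to assign a stage-specific cross-sectional area to
#' stress-relaxation tests. Three forms are used: a line for standard giant
#' and dorsal-180 explants, a quadratic capped at (or before) its stationary
#' point for ventral-180 explants (whose thickening plateaus), and a constant
#' for animal-cap explants.
#'
#' @param explant_type One of `"giant_or_D180"`, `"V180"`, `"AC"` (or another
#'   label for fitted models).
#' @param coefficients Polynomial coefficients in increasing order
#'   (intercept, linear, quadratic, ...), mm2 per hr^k.
#' @param cap_hr Optional cap time: predictions for `t >= cap_hr` are held at
#'   the value at `cap_hr`.
#' @return An object of class `ssa_model`.
#' @export
ssa_model <- function(explant_type, coefficients, cap_hr = NULL) {
  stopifnot(is.character(explant_type), is.numeric(coefficients),
            length(coefficients) >= 1L)
  if (!is.null(cap_hr)) stopifnot(is.numeric(cap_hr), length(cap_hr) == 1L, cap_hr > 0)
  structure(list(explant_type = explant_type,
                 coefficients = as.numeric(coefficients),
                 cap_hr = cap_hr),
            class = "ssa_model")
}

#' @export
print.ssa_model <- function(x, ...) {
  terms <- paste0(signif(x$coefficients, 4), c("", " t", if (length(x$coefficients) > 2)
    paste0(" t^", seq(2, length(x$coefficients) - 1))))
  cat(sprintf("SSA model [%s]: SSA(t) = %s mm2%s\n", x$explant_type,
              paste(terms, collapse = " + "),
              if (is.null(x$cap_hr)) "" else sprintf(" (capped at %g hr)", x$cap_hr)))
  invisible(x)
}

#' Reference SSA models for the standard explant types
#'
#' The regression models used to assign stage-specific SSA in
#' stress-relaxation analysis: standard giant / dorsal-180 explants follow
#' the line `0.085 t + 0.24` mm2 (t in hours after G0); ventral-180 explants
#' follow the quadratic `-0.0042 t^2 + 0.085 t + 0.25` mm2, held at its 10-hr
#' value (0.68 mm2) thereafter; animal-cap sandwiches are a constant
#' 0.16 mm2.
#'
#' @return Named list of three [ssa_model()] objects: `giant_or_D180`,
#'   `V180`, `AC`.
#' @export
ssa_reference_models <- function() {
  list(
    giant_or_D180 = ssa_model("giant_or_D180", c(0.24, 0.085)),
    V180 = ssa_model("V180", c(0.25, 0.085, -0.0042), cap_hr = 10),
    AC = ssa_model("AC", 0.16)
  )
}

#' Predict SSA at a developmental time
#'
#' Evaluates the polynomial of an [ssa_model()] at `hours_after_G0`, applying
#' the model's cap rule (predictions constant at and beyond `cap_hr`).
#'
#' @param model An [ssa_model()], or a character label understood by
#'   [ssa_reference_models()].
#' @param hours_after_G0 Non-negative time(s), hours after G0.
#' @return Predicted SSA in mm2.
#' @examples
#' ssa_predict("giant_or_D180", 4)   # 0.58 mm2
#' ssa_predict("V180", c(10, 14))    # both 0.68 mm2
#' @export
ssa_predict <- function(model, hours_after_G0) {
  if (is.character(model)) {
    ref <- ssa_reference_models()
    if (!model %in% names(ref)) stop("unknown explant type '", model, "'")
    model <- ref[[model]]
  }
  stopifnot(inherits(model, "ssa_model"), is.numeric(hours_after_G0))
  if (any(hours_after_G0 < 0)) stop("`hours_after_G0` must be >= 0")
  t <- hours_after_G0
  if (!is.null(model$cap_hr)) t <- pmin(t, model$cap_hr)
  k <- seq_along(model$coefficients) - 1
  vapply(t, function(ti) sum(model$coefficients * ti^k), numeric(1))
}

#' Fit an SSA regression model
#'
#' Least-squares fit of SSA observations against hours after G0, in one of
#' three forms: `"linear"`, `"quadratic_capped"` (the fitted quadratic is
#' capped at its stationary point, or at `cap_hr` when supplied), or
#' `"constant"` (the mean).
#'
#' @param hours,ssa_mm2 Observation vectors (same length).
#' @param form Model form.
#' @param explant_type Label stored in the returned model.
#' @param cap_hr Optional explicit cap for `"quadratic_capped"`.
#' @return An [ssa_model()].
#' @export
fit_ssa_model <- function(hours, ssa_mm2,
                          form = c("linear", "quadratic_capped", "constant"),
                          explant_type = "fitted", cap_hr = NULL) {
  form <- match.arg(form)
  stopifnot(is.numeric(hours), is.numeric(ssa_mm2), length(hours) == length(ssa_mm2))
  npar <- switch(form, constant = 1L, linear = 2L, quadratic_capped = 3L)
  if (length(hours) < npar + 1L)
    stop("need at least ", npar + 1L, " observations for form '", form, "'")
  if (form != "constant" && length(unique(hours)) < npar)
    stop("degenerate design: observation times do not span the model form")
  co <- switch(form,
    constant = mean(ssa_mm2),
    linear = unname(stats::coef(stats::lm(ssa_mm2 ~ hours))),
    quadratic_capped = unname(stats::coef(stats::lm(ssa_mm2 ~ hours + I(hours^2))))
  )
  if (form == "quadratic_capped" && is.null(cap_hr)) {
    a <- co[3L]
    cap_hr <- if (is.finite(a) && a < 0) -co[2L] / (2 * a) else NULL
  }
  ssa_model(explant_type, co, cap_hr = if (form == "quadratic_capped") cap_hr)
}
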