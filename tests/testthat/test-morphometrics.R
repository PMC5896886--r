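test_that("convergence_rate computes the sign-flipped OLS slope and %/hr", {
  ws <- data.frame(time_min = seq(0, 60, by = 6),
                   width_um = seq(3000, 2400, length.out = 11))
  r <- convergence_rate(ws, c(0, 60))
  expect_equal(r$um_per_min, 10)
  expect_equal(r$pct_per_hr, 20)

  ws$width_um <- 2800
  r <- convergence_rate(ws, c(0, 60))
  expect_equal(r$um_per_min, 0)
  expect_equal(r$pct_per_hr, 0)

  # sampled exponential: width 3000 exp(-0.10 t_hr) over the first hour;
  # the OLS-slope definition gives about 9.5 %/hr (not the instantaneous 10)
  ws <- data.frame(time_min = seq(0, 60, by = 6))
  ws$width_um <- 3000 * exp(-0.10 * ws$time_min / 60)
  r <- convergence_rate(ws, c(0, 60))
  expect_equal(r$pct_per_hr, 9.5, tolerance = 0.01)

  expect_error(convergence_rate(ws, c(100, 200)), "fewer than 2")
  # endpoint differencing available as a cross-check
  re <- convergence_rate(ws, c(0, 60), method = "endpoint")
  expect_equal(re$pct_per_hr, 100 * (1 - exp(-0.1)), tolerance = 1e-10)
})

test_that("regional strain rate has Table-1 sign convention and round-trips", {
  mt <- simulate_marker_tracks(c(dorsal = -7.2, LV = 1.1),
                               boundaries_um = c(0, 1200, 2400),
                               duration_min = 60, dt_min = 2.5,
                               jitter_sd_um = 0, seed = 1)
  rd <- regional_strain_rate(mt, "dorsal", c(0, 15))
  rl <- regional_strain_rate(mt, "LV", c(0, 15))
  expect_equal(as.numeric(rd), -7.2, tolerance = 7.2 * 0.02)
  expect_equal(as.numeric(rl), +1.1, tolerance = 1.1 * 0.02)
  expect_error(regional_strain_rate(mt, "notochord", c(0, 15)), "exactly 2")

  # static segment
  mt0 <- simulate_marker_tracks(c(dorsal = 0), c(0, 1000), seed = 1)
  expect_equal(as.numeric(regional_strain_rate(mt0, "dorsal", c(0, 30))), 0)
})

test_that("strain rates are invariant under uniform translation", {
  mt <- simulate_marker_tracks(c(dorsal = -7.2, LV = 1.1),
                               boundaries_um = c(0, 1200, 2400), seed = 3)
  shifted <- as.data.frame(mt)
  shifted$position_um <- shifted$position_um + 5000
  mts <- marker_tracks(shifted)
  expect_equal(as.numeric(regional_strain_rate(mts, "dorsal", c(0, 30))),
               as.numeric(regional_strain_rate(mt, "dorsal", c(0, 30))))
})

test_that("convergence %/hr of a segment is minus its regional strain rate", {
  mt <- simulate_marker_tracks(c(dorsal = -7.2), c(0, 1200),
                               duration_min = 30, dt_min = 2.5, seed = 5)
  d <- as.data.frame(mt)
  left <- d[d$track_id == "dorsal.left", ]
  right <- d[d$track_id == "dorsal.right", ]
  ws <- data.frame(time_min = left$time_min,
                   width_um = abs(right$position_um - left$position_um))
  cr <- convergence_rate(ws, c(0, 30))
  sr <- regional_strain_rate(mt, "dorsal", c(0, 30))
  expect_equal(cr$pct_per_hr, -as.numeric(sr))
})

test_that("shear rate is edge minus sled convergence", {
  expect_equal(shear_rate(4.1, 0.4), 3.7)
  expect_equal(shear_rate(2.5, 0), 2.5)
  expect_equal(shear_rate(3.3, 3.3), 0)
  # identity on random inputs: shear + sled = edge
  set.seed(13)
  e <- runif(20, 0, 10); s <- runif(20, 0, 5)
  expect_equal(shear_rate(e, s) + s, e)
  # window mismatch between rate objects is an error
  ws <- data.frame(time_min = 0:60, width_um = 3000 - (0:60) * 5)
  a <- convergence_rate(ws, c(0, 30))
  b <- convergence_rate(ws, c(0, 60))
  expect_error(shear_rate(a, b), "different windows")
  expect_equal(shear_rate(a, a), 0)
})

test_that("reference SSA models evaluate as published", {
  expect_equal(ssa_predict("giant_or_D180", 0), 0.24)
  expect_equal(ssa_predict("giant_or_D180", 4), 0.58)
  expect_equal(ssa_predict("V180", 10), 0.68)
  expect_equal(ssa_predict("V180", 14), 0.68)   # capped at its 10-hr value
  expect_equal(ssa_predict("AC", c(0, 5, 20)), rep(0.16, 3))
  expect_error(ssa_predict("mystery", 1), "unknown explant type")
  expect_error(ssa_predict("AC", -1), ">= 0")
  # V180 non-decreasing on [0, 10] then constant
  v <- ssa_predict("V180", seq(0, 10, by = 0.25))
  expect_true(all(diff(v) >= 0))
  expect_true(all(ssa_predict("V180", c(10, 12, 20)) == v[length(v)]))
})

test_that("fit_ssa_model recovers exact and noisy coefficients", {
  h <- c(0, 2, 4, 6, 8, 10)
  m <- fit_ssa_model(h, 0.085 * h + 0.24, form = "linear")
  expect_equal(m$coefficients, c(0.24, 0.085), tolerance = 1e-12)

  # collinear points: zero residual
  m3 <- fit_ssa_model(c(1, 2, 3), c(1, 2, 3) * 0.1 + 0.2, form = "linear")
  expect_equal(ssa_predict(m3, c(1, 2, 3)), c(0.3, 0.4, 0.5))

  # noisy synthetic points from the V180 quadratic (fixed seed): within 10%
  truth <- c(0.25, 0.085, -0.0042)
  set.seed(21)
  h <- rep(seq(0, 10, by = 1), 3)
  y <- truth[1] + truth[2] * h + truth[3] * h^2 + rnorm(length(h), 0, 0.01)
  mq <- fit_ssa_model(h, y, form = "quadratic_capped")
  expect_equal(mq$coefficients, truth, tolerance = 0.10)
  # capped at the stationary point, near 10 hr for these coefficients
  expect_equal(mq$cap_hr, -truth[2] / (2 * truth[3]), tolerance = 0.2)
  expect_equal(ssa_predict(mq, 30), ssa_predict(mq, mq$cap_hr))

  expect_equal(fit_ssa_model(c(1, 2, 5), c(1, 2, 3) / 10,
                             form = "constant")$coefficients, 0.2)
  expect_error(fit_ssa_model(c(1, 1, 1), c(1, 2, 3), form = "linear"),
               "degenerate")
  expect_error(fit_ssa_model(1, 0.1, form = "linear"), "at least")
})
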