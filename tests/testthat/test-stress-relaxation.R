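test_that("sls_stress evaluates S_inf + S_sp exp(-t/tau)", {
  p <- sls_parameters(10, 20, 60)
  expect_equal(sls_stress(0, p), 30)                      # exponential at 0
  expect_equal(sls_stress(1000 * 60, p), 10)              # asymptote
  expect_equal(sls_stress(60, p), 10 + 20 / exp(1))       # about 17.358
  expect_error(sls_stress(-1, p), ">= 0")
})

test_that("sls_stress is strictly decreasing when S_sp > 0, constant when 0", {
  t <- seq(0, 600, by = 5)
  expect_true(all(diff(sls_stress(t, sls_parameters(10, 20, 60))) < 0))
  expect_true(all(diff(sls_stress(t, sls_parameters(10, 0, NA))) == 0))
})

test_that("eta = tau * S_inf holds exactly for constructed parameters", {
  set.seed(7)
  for (i in 1:25) {
    S_inf <- runif(1, 0, 50); tau <- runif(1, 1, 300)
    p <- sls_parameters(S_inf, runif(1, 0, 100), tau)
    expect_identical(p$eta, tau * S_inf)
  }
  expect_error(sls_parameters(-1, 5, 10), "S_inf")
  expect_error(sls_parameters(1, 5, 0), "tau")
  expect_error(sls_parameters(1, 5, NA), "NA")
})

test_that("structural stiffness is (F/area)/strain with uN/mm2 = Pa", {
  tr <- relaxation_trace(c(0, 1), c(1, 1), imposed_strain = 0.1, area_mm2 = 1)
  expect_equal(structural_stiffness_series(tr)$stiffness_pa, c(10, 10))
  tr <- relaxation_trace(c(0, 1), c(0.84, 0), imposed_strain = 0.12, area_mm2 = 0.5)
  expect_equal(structural_stiffness_series(tr)$stiffness_pa, c(14, 0))
  expect_error(relaxation_trace(c(0, 1), c(1, 1), 0, 1), "positive")
  expect_error(relaxation_trace(c(0, 1), c(1, 1), 0.1, 0), "positive")
  # realized strain series supersedes the nominal imposed strain
  tr <- relaxation_trace(c(0, 1), c(1, 1), imposed_strain = 0.1, area_mm2 = 1,
                         strain = c(0.1, 0.2))
  expect_equal(structural_stiffness_series(tr)$stiffness_pa, c(10, 5))
})

test_that("fit_sls recovers noise-free parameters to 1e-6 by both routes", {
  truth <- sls_parameters(10, 20, 60)
  tr <- sls_trace(truth)
  for (m in c("nls", "optim")) {
    fit <- fit_sls(tr, method = m)
    expect_true(fit$converged)
    expect_equal(fit$parameters$S_inf, 10, tolerance = 1e-6)
    expect_equal(fit$parameters$S_sp, 20, tolerance = 1e-6)
    expect_equal(fit$parameters$tau, 60, tolerance = 1e-6)
    expect_equal(fit$parameters$eta, fit$parameters$tau * fit$parameters$S_inf)
  }
})

test_that("fit_sls flags the degenerate no-decay series", {
  tr <- data.frame(time_s = seq(0, 300, by = 10), stiffness_pa = 10)
  fit <- fit_sls(tr)
  expect_equal(fit$parameters$S_inf, 10)
  expect_equal(fit$parameters$S_sp, 0)
  expect_false(fit$tau_identifiable)
  expect_true(is.na(fit$parameters$tau))
})

test_that("fit_sls recovers parameters within 5% under 2% noise (fixed seed)", {
  truth <- sls_parameters(14, 25, 45)
  tr <- sls_trace(truth, n = 200, noise = 0.02, seed = 99)
  fit <- fit_sls(tr)
  expect_lt(abs(fit$parameters$S_inf / 14 - 1), 0.05)
  expect_lt(abs(fit$parameters$S_sp / 25 - 1), 0.05)
  expect_lt(abs(fit$parameters$tau / 45 - 1), 0.05)
})

test_that("fit_sls enforces its preconditions", {
  expect_error(fit_sls(data.frame(time_s = c(5, 10, 15),
                                  stiffness_pa = c(3, 2, 1))), "at least 4")
})

test_that("residual_stiffness_180 interpolates stiffness at 180 s", {
  # arithmetic oracle: F(180) = 1.2 uN, area 0.6 mm2, strain 0.12
  tr <- relaxation_trace(c(0, 120, 240), c(2, 1.2 * 2 - 1.2, 1.2),
                         imposed_strain = 0.12, area_mm2 = 0.6)
  # force at 180 s interpolates (1.2, 1.2) -> 1.2
  expect_equal(residual_stiffness_180(tr), (1.2 / 0.6) / 0.12)  # 16.667 Pa

  # constant force: equals the stiffness series at any t
  tr <- relaxation_trace(seq(0, 300, by = 30), rep(0.84, 11),
                         imposed_strain = 0.12, area_mm2 = 0.5)
  expect_equal(residual_stiffness_180(tr), 14)

  # synthetic SLS trace -> closed form at 180 s within interpolation tolerance
  p <- sls_parameters(12, 30, 50)
  tr <- sls_trace(p, n = 601, duration = 300)
  expect_equal(residual_stiffness_180(tr), sls_stress(180, p), tolerance = 1e-5)

  expect_error(residual_stiffness_180(
    relaxation_trace(c(0, 100), c(1, 1), 0.1, 1)), "span")
})

test_that("spring stiffness is force over strain and round-trips", {
  expect_equal(spring_stiffness(1.0, 0.10), 10)
  expect_equal(spring_stiffness(0, 0.1), 0)
  expect_equal(spring_stiffness(0.84, 0.12), 7.0)
  expect_error(spring_stiffness(1, 0), "> 0")
  set.seed(11)
  f <- runif(20, 0, 5); s <- runif(20, 0.05, 0.3)
  expect_equal(spring_stiffness(f, s) * s, f)
})

test_that("plastic_fraction decomposes applied strain into plastic and elastic", {
  r <- plastic_fraction(1000, 1120, 1030)
  expect_equal(r$applied_strain, 0.12)
  expect_equal(r$residual_strain, 0.03)
  expect_equal(r$plastic_fraction, 0.25)
  expect_equal(plastic_fraction(100, 112, 100)$plastic_fraction, 0)  # full recovery
  expect_equal(plastic_fraction(100, 112, 112)$plastic_fraction, 1)  # fully plastic
  expect_error(plastic_fraction(100, 112, 99), "ordering")
  expect_error(plastic_fraction(100, 112, 113), "ordering")
})

test_that("recoil metrics reproduce the fractional-recoil and rate conventions", {
  m <- recoil_measurement(1.0, 0.41, 0.0093, 5)
  r <- recoil_metrics(m)
  expect_equal(r$fractional_recoil_pct, 41)
  expect_equal(r$recoil_rate_pct_hr, 0.93 / 5 * 3600)  # about 670 %/hr
  expect_equal(
    recoil_metrics(recoil_measurement(0.8, 0.8, 0, 5))$fractional_recoil_pct,
    100)  # fully elastic
  expect_error(recoil_measurement(0, 0, 0.01), "> 0")
  expect_error(recoil_measurement(1, 1.2, 0.01), "lie in")
})
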