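quiet_cfg <- function(elements, ...) {
  pull_sim_config(elements, probe_spring_constant = 0.05,
                  static_friction = 0, drift_rate = 0, noise_sd = 0,
                  dt = 0.1, seed = 1, ...)
}

test_that("an all-passive chain produces zero force", {
  els <- replicate(3, chain_element("passive"), simplify = FALSE)
  sim <- simulate_tractor_pull(quiet_cfg(els, duration = 120))
  expect_equal(sim$truth$tension_uN, rep(0, nrow(sim$truth)))
  expect_equal(sim$trace$force_uN, rep(0, length(sim$trace$force_uN)))
})

test_that("a single CT element asymptotes at its stall force", {
  el <- chain_element("CT", stall_force = 2, free_shortening_velocity = 0.5,
                      spring_constant = 0.25)
  sim <- simulate_tractor_pull(quiet_cfg(list(el), duration = 1200))
  tn <- sim$truth$tension_uN
  expect_true(all(diff(tn) >= -1e-12))                    # monotone rise
  expect_lt(max(tn), 2 + 1e-9)                            # never exceeds stall
  expect_equal(tn[length(tn)], 2, tolerance = 1e-3)       # asymptote
})

test_that("ground-truth tension equals the probe spring force (no friction)", {
  sim <- simulate_tractor_pull(pull_config_preset("standard", seed = 4,
                                                  noise_sd = 0, drift_rate = 0))
  expect_equal(sim$truth$tension_uN, sim$truth$probe_force_uN, tolerance = 1e-10)
  expect_equal(sim$truth$probe_force_uN,
               sim$config$probe_spring_constant * sim$truth$deflection_um)
})

test_that("noise-free tension never exceeds the active total stall", {
  for (ty in c("standard", "ventralized", "D180")) {
    sim <- simulate_tractor_pull(pull_config_preset(ty, seed = 5,
                                                    noise_sd = 0, drift_rate = 0))
    expect_true(all(sim$truth$tension_uN <=
                      sim$truth$total_active_stall_uN + 1e-9), label = ty)
  }
})

test_that("static friction holds the sled until the dead band is exceeded", {
  el <- chain_element("CT", stall_force = 2, free_shortening_velocity = 0.5,
                      spring_constant = 0.25)
  cfg <- pull_sim_config(list(el), probe_spring_constant = 0.05,
                         static_friction = 0.5, noise_sd = 0, drift_rate = 0,
                         dt = 0.1, duration = 600, seed = 1)
  sim <- simulate_tractor_pull(cfg)
  # probe force lags chain tension by (up to) the friction band
  gap <- sim$truth$tension_uN - sim$truth$probe_force_uN
  expect_true(all(gap <= 0.5 + 1e-9))
  expect_true(all(gap >= -1e-9))
  # sled does not move at all until tension builds past the band
  expect_equal(sim$truth$deflection_um[1], 0)
})

test_that("simulators are bit-reproducible under a seed", {
  a <- simulate_tractor_pull(pull_config_preset("standard", seed = 7))
  b <- simulate_tractor_pull(pull_config_preset("standard", seed = 7))
  expect_identical(a$trace$deflection_px, b$trace$deflection_px)
  expect_identical(a$truth, b$truth)

  p <- sls_parameters(14, 25, 45)
  expect_identical(as.data.frame(simulate_relaxation(p, seed = 3)),
                   as.data.frame(simulate_relaxation(p, seed = 3)))

  m1 <- simulate_marker_tracks(c(d = -5), c(0, 1000), jitter_sd_um = 4, seed = 9)
  m2 <- simulate_marker_tracks(c(d = -5), c(0, 1000), jitter_sd_um = 4, seed = 9)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
})

test_that("simulate_relaxation matches its forward model", {
  p <- sls_parameters(14, 25, 45)
  tr <- simulate_relaxation(p, strain = 0.12, area_mm2 = 0.5,
                            noise_sd_rel = 0, n_samples = 50,
                            duration_s = 300, seed = 1)
  expect_equal(tr$force_uN, sls_stress(tr$time_s, p) * 0.5 * 0.12)
  # degenerate SLS: flat trace at S_inf * area * strain
  flat <- simulate_relaxation(sls_parameters(10, 0, NA), strain = 0.1,
                              area_mm2 = 1, noise_sd_rel = 0,
                              n_samples = 10, seed = 1)
  expect_equal(flat$force_uN, rep(1, 10))
})

test_that("simulate_marker_tracks validates tiling and holds static tracks still", {
  mt <- simulate_marker_tracks(c(a = 0, b = 0), c(0, 500, 1000),
                               jitter_sd_um = 0, seed = 1)
  d <- as.data.frame(mt)
  for (id in unique(d$track_id))
    expect_equal(var(d$position_um[d$track_id == id]), 0)
  expect_error(simulate_marker_tracks(c(a = 1, b = 2), c(0, 500, 400), seed = 1),
               "overlap")
  expect_error(simulate_marker_tracks(c(a = 1), c(0, 500, 600), seed = 1),
               "length")
})

test_that("chain_element validates its mechanical constants", {
  expect_error(chain_element("CT", stall_force = -1), "stall_force")
  expect_error(chain_element("CT", spring_constant = 0), "> 0")
  expect_error(chain_element("CT", rest_length = 0), "> 0")
  expect_error(pull_sim_config(list(), probe_spring_constant = 1, seed = 1),
               "non-empty")
  expect_error(pull_sim_config(list(chain_element("CT")),
                               probe_spring_constant = 1),
               "seed")
})
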