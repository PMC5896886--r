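# Shared fixture builders (all data generated in code; no stored fixtures).

probe3 <- function() probe_calibration(27, 0.25, "probe3")

# simple force trace: constant raw deflection, optional references
flat_trace <- function(deflection_px = 10, n = 10, dt_min = 6,
                       pre = NA_real_, post = NA_real_,
                       calibration = probe_calibration(0.02, 0.5, "toy")) {
  force_trace(seq(0, by = dt_min, length.out = n),
              rep(deflection_px, n), calibration,
              pre_unstressed_px = pre, post_unstressed_px = post)
}

# noise-free SLS relaxation trace with a sample grid dense around 180 s
sls_trace <- function(params, strain = 0.12, area = 0.5, n = 101,
                      duration = 300, seed = 1, noise = 0) {
  simulate_relaxation(params, strain = strain, area_mm2 = area,
                      noise_sd_rel = noise, n_samples = n,
                      duration_s = duration, seed = seed)
}
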