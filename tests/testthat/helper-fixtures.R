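# shared fixtures, built once per test run

# noiseless ground-truth arterial input on the dense grid
fix_aif <- synth_aif(noise_sd = 0, seed = 1)

# well-separated two-compartment truth used for recovery tests: a slow
# capillary bed and a fast, strongly flowing arteriolar compartment with
# shorter delay and dispersion
fix_comps_2c <- list(
  compartment_params(8.3e-4, 12, delay_s = 2, dispersion_s = 1,
                     label = "capillary"),
  compartment_params(3.3e-3, 2, delay_s = 1, dispersion_s = 0.3,
                     label = "arteriolar"))
fix_truth_2c <- c(flow_cap = 8.3e-4, mtt_cap = 12, flow_art = 3.3e-3,
                  mtt_art = 2, delay_cap = 2, delay_art = 1,
                  dispersion_cap = 1, dispersion_art = 0.3)

fix_comps_1c <- compartment_params(1.667e-3, 8, delay_s = 2, dispersion_s = 1)
fix_truth_1c <- c(flow_f = 1.667e-3, mtt_t = 8, delay_s = 2, dispersion_s = 1)

# O(n^2) direct-sum oracle for the trapezoidal causal convolution
conv_direct <- function(x, k, dt) {
  n <- length(x)
  m <- min(length(k), n)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(min(i, m))) acc <- acc + k[j] * x[i - j + 1L]
    kf <- if (i <= m) k[i] else 0
    y[i] <- dt * (acc - 0.5 * k[1L] * x[i] - 0.5 * kf * x[1L])
  }
  y
}

# small noiseless study shared by pipeline tests
fix_mini_study <- function(seed = 3, noise = FALSE) {
  synth_study(n_subjects = 2L, n_measurements = 3L, n_segments = 4L,
              aif_jitter_sdlog = if (noise) 0.15 else 0,
              tissue_noise_sd = if (noise) 0.04 else 0,
              aif_noise_sd = if (noise) 0.25 else 0,
              seed = seed)
}
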