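test_that("AIF extraction averages the masked voxels per frame", {
  nt <- 10
  v <- seq_len(nt) / 2
  frames <- array(0, c(2, 2, 1, nt))
  frames[1, 1, 1, ] <- v
  frames[2, 1, 1, ] <- 3 * v
  frames[1, 2, 1, ] <- v
  dyn <- dynamic_series(frames, 1.5, "delta_r1")
  mask <- array(FALSE, c(2, 2, 1))

  mask[1, 1, 1] <- TRUE; mask[1, 2, 1] <- TRUE  # identical voxels
  a1 <- extract_aif(dyn, mask)
  expect_equal(a1$curve$value, v)
  expect_equal(a1$n_voxels, 2L)

  mask2 <- array(FALSE, c(2, 2, 1)); mask2[1:2, 1, 1] <- TRUE  # v and 3v
  expect_equal(extract_aif(dyn, mask2)$curve$value, 2 * v)

  expect_error(extract_aif(dyn, array(FALSE, c(2, 2, 1))), "empty")
})

test_that("arrival detection finds an unambiguous step and rejects flat noise", {
  step <- time_curve(c(rep(0, 9), rep(10, 11)), 1.5)
  expect_identical(detect_arrival(step, baseline_frames = 5), 10L)
  set.seed(1)
  flat <- time_curve(rnorm(60, sd = 0.25), 1.5)
  expect_error(detect_arrival(flat, baseline_frames = 5),
               class = "dceflow_no_bolus")
})

test_that("arrival detection is accurate on noisy bolus curves", {
  # frame-sampled AIF, arrival at 15 s with 1.5 s frames: true index 11
  hits <- vapply(1:200, function(i) {
    a <- synth_aif(arrival_s = 15, step_s = 1.5, noise_sd = 0.25, seed = i)
    idx <- tryCatch(detect_arrival(a$curve, baseline_frames = 5, k_sigma = 3),
                    error = function(e) NA_integer_)
    !is.na(idx) && abs(idx - 11L) <= 1L
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("transport kernel has unit mass, exponential shape, and a resolution guard", {
  dt <- 0.1
  for (beta in c(0.3, 1, 2)) {
    k <- transport_kernel(beta, dt)
    mass <- dt * (sum(k) - 0.5 * k[1] - 0.5 * k[length(k)])
    expect_equal(mass, 1, tolerance = 1e-12)
    # shape: constant log-slope equal to -beta * dt
    expect_equal(k[2] / k[1], exp(-beta * dt), tolerance = 1e-12)
  }
  expect_warning(transport_kernel(4, 0.5), "under-resolved")
  expect_error(transport_kernel(-1, 0.1), "beta")
})

test_that("unit-step response of the transport kernel matches the closed form", {
  dt <- 0.1
  tt <- seq(0, 30, by = dt)
  u <- rep(1, length(tt))
  y <- conv_causal(u, transport_kernel(1, dt), dt)
  sel <- tt >= 1
  expect_lt(max(abs(y[sel] - (1 - exp(-tt[sel]))) / (1 - exp(-tt[sel]))), 0.01)
})

test_that("AIF correction: identity, pure shift, and oracle equivalence", {
  dt <- 0.1
  tt <- seq(0, 60, by = dt)
  curve <- time_curve(exp(-(tt - 20)^2 / 18), dt)

  # identity transport
  out0 <- correct_aif(curve, transport_params(0, 0), step_s = dt)
  expect_lt(max(abs(out0$value - curve$value)), 1e-6)

  # pure delay of an impulse: 2 s shift
  imp <- time_curve(c(numeric(100), 1, numeric(100)), dt)
  sh <- correct_aif(imp, transport_params(2, 0), step_s = dt)
  expect_equal(which.max(sh$value), 121L)

  # dispersion of a boxcar equals the direct-sum oracle
  box <- time_curve(as.numeric(tt >= 5 & tt <= 20), dt)
  k <- transport_kernel(0.5, dt)
  out <- correct_aif(box, transport_params(0, 2), step_s = dt)
  expect_lt(max(abs(out$value - conv_direct(box$value, k, dt))), 1e-10)
})

test_that("transport preserves mass and lowers the peak; delay and dispersion commute", {
  dt <- 0.1
  tt <- seq(0, 120, by = dt)
  curve <- time_curve(exp(-(tt - 20)^2 / 18), dt)
  out <- correct_aif(curve, transport_params(1.5, 2), step_s = dt)
  expect_equal(sum(out$value) * dt, sum(curve$value) * dt, tolerance = 5e-3)
  expect_lt(max(out$value), max(curve$value))

  disp_then_delay <- dceflow:::shift_later(
    conv_causal(curve$value, transport_kernel(0.5, dt), dt), 1.7, dt)
  delay_then_disp <- conv_causal(
    dceflow:::shift_later(curve$value, 1.7, dt), transport_kernel(0.5, dt), dt)
  expect_lt(max(abs(disp_then_delay - delay_then_disp)), 1e-10)
})

test_that("excessive delay triggers a truncated-support warning", {
  curve <- time_curve(exp(-(seq(0, 30, 0.1) - 10)^2 / 8), 0.1)
  expect_warning(correct_aif(curve, transport_params(40, 0)), "support")
})

test_that("plateau statistic averages the steady-state window", {
  # constant plateau of 5 after an arrival step
  v <- c(numeric(10), rep(5, 80))
  a <- aif_estimate(time_curve(v, 1.5), arrival_index = 11L)
  expect_equal(plateau_stat(a), 5)

  # curve ending 30 s after arrival cannot host the 60-80 s window
  short <- aif_estimate(time_curve(c(numeric(10), rep(5, 20)), 1.5),
                        arrival_index = 11L)
  expect_error(plateau_stat(short), class = "dceflow_short_curve")
})

test_that("plateau statistic of noisy synthetic AIFs obeys the CLT bound", {
  a0 <- synth_aif(noise_sd = 0, step_s = 1.5)
  w0 <- plateau_stat(a0)
  n_frames <- floor(20 / 1.5) + 1
  bound <- 3 * 0.25 / sqrt(n_frames)
  hits <- vapply(1:50, function(i) {
    a <- synth_aif(noise_sd = 0.25, step_s = 1.5, seed = i)
    a$arrival_index <- a0$arrival_index
    abs(plateau_stat(a) - w0) <= bound
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
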