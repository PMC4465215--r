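mk_meas <- function(id, w, perf, vol = rep(1000, length(perf)),
                    cap = 0.7 * perf, art = 0.3 * perf, ref = NULL) {
  seg <- data.frame(segment_id = seq_along(perf), name = paste0("s", seq_along(perf)),
                    volume_cm3 = vol, perfusion_ml_min_100cm3 = perf,
                    flow_cap_ml_min_100cm3 = cap, flow_art_ml_min_100cm3 = art)
  list(measurement_id = id, plateau_w = w, segments = seg,
       total_flow_ml_min = total_flow(seg), reference_flow_ml_min = ref)
}

test_that("total flow integrates perfusion x volume / 100", {
  expect_equal(total_flow(data.frame(perfusion_ml_min_100cm3 = 10,
                                     volume_cm3 = 1000)), 100)
  # a uniform 4.7 mL/(min 100cm^3) over 5510.6 cm^3 gives the 259 mL/min
  # offset flow of a whole hind leg
  expect_equal(total_flow(data.frame(perfusion_ml_min_100cm3 = 4.7,
                                     volume_cm3 = 5510.6)), 259, tolerance = 1e-3)
  set.seed(8)
  seg <- data.frame(perfusion_ml_min_100cm3 = runif(8, 2, 44),
                    volume_cm3 = runif(8, 300, 1200))
  brute <- 0
  for (i in 1:8) brute <- brute + seg$perfusion_ml_min_100cm3[i] * seg$volume_cm3[i] / 100
  expect_lt(abs(total_flow(seg) - brute), 1e-9)
  # permutation invariance
  expect_equal(total_flow(seg[sample(8), ]), total_flow(seg))
  seg$perfusion_ml_min_100cm3[3] <- NA
  expect_error(total_flow(seg), class = "dceflow_incomplete_segments")
})

test_that("plateau normalization rescales flows by w_n / W", {
  m <- list(mk_meas("a", 4, 10), mk_meas("b", 6, 10))
  out <- normalize_flows(m)
  expect_equal(vapply(out, `[[`, 0, "norm_factor"), c(0.8, 1.2))
  expect_equal(vapply(out, `[[`, 0, "total_flow_ml_min"), c(80, 120))
  expect_equal(vapply(out, `[[`, 0, "total_flow_uncorrected_ml_min"), c(100, 100))
  # the mean of the correction factors is exactly 1
  expect_identical(mean(vapply(out, `[[`, 0, "norm_factor")), 1)

  eq <- normalize_flows(list(mk_meas("a", 5, 10), mk_meas("b", 5, 20)))
  expect_equal(vapply(eq, `[[`, 0, "norm_factor"), c(1, 1))

  single <- normalize_flows(list(mk_meas("a", 7.3, 10)))
  expect_identical(single[[1]]$norm_factor, 1)

  expect_error(normalize_flows(list(mk_meas("a", -1, 10))), "positive")
})

test_that("validation regression reproduces exact lines and a reference implementation", {
  x <- c(150, 300, 450, 600, 750)
  r <- regress_validation(x, x)
  expect_equal(r$slope, 1); expect_equal(r$intercept, 0)
  expect_equal(r$pearson_r, 1); expect_equal(r$p_value, 0)

  r2 <- regress_validation(2 * x + 3, x)
  expect_equal(r2$slope, 2); expect_equal(r2$intercept, 3)
  expect_equal(r2$pearson_r, 1)

  set.seed(31)
  ref <- runif(20, 142, 941)
  est <- 1.2 * ref + 259 + rnorm(20, sd = 138)
  r3 <- regress_validation(est, ref)
  lm_fit <- lm(est ~ ref)
  ct <- cor.test(est, ref)
  expect_equal(r3$slope, unname(coef(lm_fit)[2]), tolerance = 1e-10)
  expect_equal(r3$intercept, unname(coef(lm_fit)[1]), tolerance = 1e-10)
  expect_equal(r3$pearson_r, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(r3$p_value, ct$p.value, tolerance = 1e-10)
  expect_equal(r3$residual_sd, summary(lm_fit)$sigma, tolerance = 1e-10)

  expect_error(regress_validation(rep(1, 5), 1:5),
               class = "dceflow_degenerate_correlation")
  expect_error(regress_validation(1:2, 1:2), "3 paired")
})

test_that("compartment attribution splits and sums consistently", {
  m <- list(mk_meas("a", 5, c(10, 20)), mk_meas("b", 5, c(5, 5)))
  att <- compartment_attribution(m)
  tot <- vapply(m, `[[`, 0, "total_flow_ml_min")
  expect_equal(att$capillary_flow_ml_min + att$arteriolar_flow_ml_min, tot)
  # pure one-compartment study: everything is capillary
  m1 <- list(mk_meas("a", 5, c(10, 20), cap = c(10, 20), art = c(0, 0)))
  att1 <- compartment_attribution(m1)
  expect_identical(att1$arteriolar_flow_ml_min, 0)
  expect_equal(att1$capillary_flow_ml_min, m1[[1]]$total_flow_ml_min)
})

test_that("arteriolar attribution tracks the generator's flow-increase channel", {
  # forced 2C fits on a study whose flow increase is arteriolar
  st <- synth_study(n_subjects = 2, n_measurements = 4, n_segments = 3,
                    flow_range_ml_min = c(500, 941),
                    aif_jitter_sdlog = 0, tissue_noise_sd = 0,
                    aif_noise_sd = 0, seed = 14)
  results <- lapply(st$measurements, function(m) {
    segs <- m$segments
    rows <- lapply(seq_len(nrow(segs)), function(s) {
      fit <- suppressWarnings(fit_2c(m$tissue[[s]], m$aif))
      rep <- perfusion_report(fit)
      data.frame(volume_cm3 = segs$volume_cm3[s],
                 flow_cap_ml_min_100cm3 = rep$perfusion_ml_min_100cm3[1],
                 flow_art_ml_min_100cm3 = rep$perfusion_ml_min_100cm3[2])
    })
    list(measurement_id = m$measurement_id,
         segments = do.call(rbind, rows),
         reference = m$reference_flow_ml_min,
         truth_art = sum(st$truth_table[st$truth_table$measurement_id ==
                                          m$measurement_id, "perf_art_ml_min_100cm3"] *
                           segs$volume_cm3) / 100)
  })
  att <- compartment_attribution(results)
  truth_art <- vapply(results, `[[`, 0, "truth_art")
  ref <- vapply(results, `[[`, 0, "reference")
  slope_est <- regress_validation(att$arteriolar_flow_ml_min, ref)$slope
  slope_tru <- regress_validation(truth_art, ref)$slope
  expect_lt(abs(slope_est - slope_tru) / abs(slope_tru), 0.10)
})
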