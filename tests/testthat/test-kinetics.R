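test_that("exponential residue function behaves analytically", {
  expect_identical(residue(0, 7), 1)
  expect_equal(residue(7, 7), exp(-1))
  tt <- seq(0, 60, by = 0.5)
  expect_true(all(diff(residue(tt, 9)) < 0))
  expect_error(residue(-1, 5), "t_s")
  expect_error(residue(1, 0), "mtt_t")
})

test_that("forward model matches the constant-input closed form to <0.1%", {
  dt <- 0.1
  aif <- time_curve(rep(1, 601), dt)
  cp <- compartment_params(1.667e-3, 8)
  tis <- forward_tissue(aif, cp)
  tt <- tc_time(tis)
  exact <- 1.667e-3 * 8 * (1 - exp(-tt / 8))
  sel <- tt >= 1
  expect_lt(max(abs(tis$value[sel] - exact[sel]) / exact[sel]), 1e-3)
})

test_that("forward model is superposable and vanishes at zero flow", {
  two <- forward_tissue(fix_aif, fix_comps_2c)
  one_a <- forward_tissue(fix_aif, fix_comps_2c[[1]])
  one_b <- forward_tissue(fix_aif, fix_comps_2c[[2]])
  expect_lt(max(abs(two$value - one_a$value - one_b$value)), 1e-12)
  null <- forward_tissue(fix_aif, compartment_params(0, 8))
  expect_true(all(null$value == 0))
})

test_that("forward model conserves tracer mass (area = vb x AIF area)", {
  # finite-support bolus (no recirculation plateau), long window
  aif <- synth_aif(noise_sd = 0, plateau_fraction = 0, duration_s = 400,
                   require_plateau_window = FALSE)
  comps <- list(compartment_params(1e-3, 10, 2, 1),
                compartment_params(3e-3, 2, 1, 0.3))
  tis <- forward_tissue(aif, comps)
  vb <- sum(vapply(comps, function(cp) cp$vb, 0))
  expect_equal(sum(tis$value) / sum(aif$curve$value), vb, tolerance = 0.01)
})

test_that("one-compartment fit recovers noiseless parameters to <1%", {
  tis <- synth_tissue(fix_aif, fix_comps_1c, noise_sd = 0)
  fit <- fit_1c(tis, fix_aif)
  expect_lt(max(abs(coef(fit) - fix_truth_1c) / fix_truth_1c), 0.01)
  expect_equal(fit$n_params, 4L)
  expect_true(fit$converged)
})

test_that("two-compartment fit recovers noiseless parameters to <5%", {
  tis <- synth_tissue(fix_aif, fix_comps_2c, noise_sd = 0)
  fit <- fit_2c(tis, fix_aif)
  expect_lt(max(abs(coef(fit) - fix_truth_2c) / fix_truth_2c), 0.05)
  expect_equal(fit$n_params, 8L)
  # central volume theorem: fitted vb within 5% of the generator vb
  vb_fit <- vapply(fit$compartments, function(cp) cp$vb, 0)
  vb_tru <- vapply(fix_comps_2c, function(cp) cp$vb, 0)
  expect_lt(max(abs(vb_fit - vb_tru) / vb_tru), 0.05)
})

test_that("a null tissue curve yields essentially zero flow", {
  tis <- time_curve(numeric(100), 1.5)
  fit <- fit_1c(tis, fix_aif)
  expect_lt(coef(fit)[["flow_f"]], 1e-6)
})

test_that("fits are deterministic: same inputs and seed, identical output", {
  tis <- synth_tissue(fix_aif, fix_comps_2c, noise_sd = 0.04, seed = 4)
  f1 <- dce_fit(tis, fix_aif, seed = 7L)
  f2 <- dce_fit(tis, fix_aif, seed = 7L)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$rss, f2$rss)
  expect_identical(f1$model_order, f2$model_order)
})

test_that("the two-compartment rss never exceeds the one-compartment rss", {
  for (i in 1:5) {
    tis <- synth_tissue(fix_aif, fix_comps_1c, noise_sd = 0.04, seed = 100 + i)
    f1 <- fit_1c(tis, fix_aif)
    f2 <- fit_2c(tis, fix_aif)
    expect_lte(f2$rss, f1$rss)
  }
})

test_that("F-test arithmetic and selection logic are exact", {
  mk <- function(rss, np) structure(list(rss = rss, n_obs = 40L, n_params = np),
                                    class = "dce_fit")
  sel <- f_test_select(mk(2, 4L), mk(1, 8L), alpha = 0.05)
  expect_equal(sel$f_stat, 8)  # ((2-1)/4) / (1/32)
  expect_equal(sel$p_value, pf(8, 4, 32, lower.tail = FALSE))
  expect_identical(sel$chosen_order, 2L)

  same <- f_test_select(mk(1.5, 4L), mk(1.5, 8L))
  expect_equal(same$f_stat, 0)
  expect_identical(same$chosen_order, 1L)

  worse <- f_test_select(mk(1, 4L), mk(1.2, 8L))
  expect_equal(worse$f_stat, 0)
  expect_identical(worse$chosen_order, 1L)

  expect_error(f_test_select(structure(list(rss = 1, n_obs = 8L, n_params = 4L),
                                       class = "dce_fit"),
                             structure(list(rss = 0.5, n_obs = 8L, n_params = 8L),
                                       class = "dce_fit")),
               "insufficient")
})

test_that("perfusion report converts units and sums compartments", {
  tis <- synth_tissue(fix_aif, fix_comps_2c, noise_sd = 0)
  fit <- fit_2c(tis, fix_aif)
  rep <- perfusion_report(fit)
  expect_equal(rep$perfusion_ml_min_100cm3, rep$flow_per_s * 6000)
  expect_equal(attr(rep, "total_perfusion"), sum(rep$perfusion_ml_min_100cm3))
  one <- perfusion_report(fit_1c(synth_tissue(fix_aif,
                                              compartment_params(1.667e-3, 8, 2, 1),
                                              noise_sd = 0), fix_aif))
  expect_equal(one$perfusion_ml_min_100cm3, 1.667e-3 * 6000, tolerance = 1e-4)
})

test_that("model selection picks the richer model only when the data demand it", {
  # strong, well-separated arteriolar bolus: 2C should win
  strong <- list(compartment_params(8.3e-4, 14, 3, 1.5, label = "capillary"),
                 compartment_params(6.67e-3, 2.5, 0.8, 0.2, label = "arteriolar"))
  tis2 <- synth_tissue(fix_aif, strong, noise_sd = 0.04, seed = 21)
  fit2 <- dce_fit(tis2, fix_aif)
  expect_identical(fit2$model_order, 2L)
  expect_s3_class(fit2$selection, "dce_ftest")
  # 1C truth: the extra parameters should usually not be justified
  tis1 <- synth_tissue(fix_aif, fix_comps_1c, noise_sd = 0.04, seed = 22)
  fit1 <- dce_fit(tis1, fix_aif)
  expect_identical(fit1$selection$chosen_order, fit1$model_order)
})

test_that("fit methods expose the standard modelling interface", {
  tis <- synth_tissue(fix_aif, fix_comps_1c, noise_sd = 0.04, seed = 5)
  fit <- dce_fit(tis, fix_aif)
  expect_named(coef(fit))
  expect_length(residuals(fit), fit$n_obs)
  expect_equal(fitted(fit) + residuals(fit), fit$data)
  pr <- predict(fit, times = c(0, 10, 20))
  expect_length(pr, 3L)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(fit$n_obs, 3L))
  expect_identical(simulate(fit, nsim = 3, seed = 1), sims)
  s <- summary(fit)
  expect_s3_class(s, "summary.dce_fit")
  expect_output(print(s), "perfusion")
  expect_output(print(fit), "compartment")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
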