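test_that("synthetic AIF hits the requested first-pass width and is causal", {
  a <- synth_aif(peak_amplitude = 60, arrival_s = 15, fwhm_s = 10,
                 plateau_fraction = 0, noise_sd = 0,
                 require_plateau_window = FALSE, duration_s = 80)
  v <- a$curve$value
  tt <- tc_time(a$curve)
  half <- max(v) / 2
  above <- range(tt[v >= half])
  expect_equal(diff(above), 10, tolerance = 0.02 * 10)
  expect_true(all(v[tt <= 15] == 0))
  # determinism
  a1 <- synth_aif(seed = 5); a2 <- synth_aif(seed = 5)
  expect_identical(a1$curve$value, a2$curve$value)
  expect_error(synth_aif(duration_s = 60), "duration")
})

test_that("synthetic tissue curves sample the forward model and scale with flow", {
  cp <- compartment_params(1.5e-3, 9, 2, 0.8)
  tis <- synth_tissue(fix_aif, cp, noise_sd = 0)
  dense <- forward_tissue(fix_aif, cp)
  td <- tc_time(dense)
  expected <- approx(td, dense$value, xout = tc_time(tis), rule = 2)$y
  expect_equal(tis$value, expected, tolerance = 1e-12)
  # doubling the flow doubles the noiseless curve
  tis2 <- synth_tissue(fix_aif, compartment_params(3e-3, 9, 2, 0.8), noise_sd = 0)
  expect_equal(tis2$value, 2 * tis$value, tolerance = 1e-12)
})

test_that("default muscle curves reach the expected contrast-to-noise ratio", {
  cnrs <- vapply(1:50, function(i) {
    tis <- synth_tissue(fix_aif, noise_sd = 0.04, seed = i)
    tt <- tc_time(tis)
    mean(tis$value[tt > 18]) / sd(tis$value[tt > 4.5 & tt < 15])
  }, 0)
  expect_gt(mean(cnrs), 9 * 0.7)
  expect_lt(mean(cnrs), 9 * 1.3)
})

test_that("synthetic studies are internally consistent and reproducible", {
  st <- synth_study(n_subjects = 3, n_measurements = 6, seed = 2)
  expect_length(st$measurements, 6L)
  for (m in st$measurements) {
    # construction identity: segment flows integrate to the drawn target
    expect_lt(abs(total_flow(data.frame(
      perfusion_ml_min_100cm3 = m$truth$perfusion,
      volume_cm3 = m$segments$volume_cm3)) - m$reference_flow_ml_min), 1e-9)
    expect_gte(m$reference_flow_ml_min, 142)
    expect_lte(m$reference_flow_ml_min, 941)
  }
  # every generated parameter lies inside the fitting bounds
  b <- dce_bounds()
  tt <- st$truth_table
  expect_true(all(tt$mtt_cap_s >= b$mtt_t[1] & tt$mtt_cap_s <= b$mtt_t[2]))
  expect_true(all(tt$mtt_art_s >= b$mtt_t[1] & tt$mtt_art_s <= b$mtt_t[2]))
  expect_true(all(tt$delay_cap_s <= b$delay_s[2] & tt$delay_art_s >= b$delay_s[1]))
  expect_true(all(tt$disp_cap_s >= b$dispersion_s[1] &
                    tt$disp_cap_s <= b$dispersion_s[2]))
  expect_true(all(tt$perfusion_ml_min_100cm3 / 6000 <= b$flow_f[2]))
  # ordering constraint honored by the generator
  expect_true(all(tt$delay_art_s <= tt$delay_cap_s))
  expect_true(all(tt$disp_art_s <= tt$disp_cap_s))

  st2 <- synth_study(n_subjects = 3, n_measurements = 6, seed = 2)
  expect_identical(st$measurements[[4]]$tissue[[3]]$value,
                   st2$measurements[[4]]$tissue[[3]]$value)
  expect_identical(st$measurements[[2]]$aif$curve$value,
                   st2$measurements[[2]]$aif$curve$value)

  expect_error(synth_study(segment_volumes_cm3 = c(100, 200)), "per segment")
})

test_that("disabling the plateau jitter equalizes the plateau statistics", {
  st <- synth_study(n_subjects = 2, n_measurements = 4,
                    aif_jitter_sdlog = 0, aif_noise_sd = 0.25, seed = 6)
  w <- vapply(st$measurements, function(m) {
    a <- m$aif
    a$arrival_index <- detect_arrival(a$curve, baseline_frames = 50)
    plateau_stat(a)
  }, 0)
  expect_lt(sd(w) / mean(w), 0.02)
})

test_that("the 4D phantom reproduces its own geometry, maps and curves", {
  st <- fix_mini_study(seed = 5)
  ph <- synth_phantom_4d(st$measurements[[1]], grid_dim = c(10, 10, 4))
  vox_cm3 <- prod(c(2.9, 2.9, 4.5)) / 1000
  counts <- tabulate(ph$labels[ph$labels > 0], nbins = 4)
  expect_equal(ph$measurement$segments$volume_cm3, counts * vox_cm3)

  maps <- fit_vfa(ph$vfa)
  expect_true(all(maps$valid_mask))
  expect_lt(max(abs(maps$r10 - ph$r10) / ph$r10), 0.01)

  dr1 <- dynamic_delta_r1(ph$dynamic, maps, alpha_deg = 30, tr_s = 0.00269,
                          baseline_frames = 5)
  aif <- extract_aif(dr1, ph$aorta_mask)
  aif_true_frames <- approx(tc_time(st$measurements[[1]]$aif_true$curve),
                            st$measurements[[1]]$aif_true$curve$value,
                            xout = tc_time(aif$curve), rule = 2)$y
  expect_lt(max(abs(aif$curve$value - aif_true_frames)), 1e-6)
})

test_that("phantoms and relaxometry maps round-trip through NIfTI files", {
  st <- fix_mini_study(seed = 5)
  ph <- synth_phantom_4d(st$measurements[[1]], grid_dim = c(8, 8, 3))
  dir <- tempfile("phantom")
  write_phantom_nifti(ph, dir)
  maps <- fit_vfa(ph$vfa)
  mdir <- tempfile("maps")
  write_relaxometry_nifti(maps, mdir)
  r10_back <- RNifti::readNifti(file.path(mdir, "r10.nii.gz"))
  expect_equal(array(as.numeric(r10_back), dim(maps$r10)), maps$r10,
               tolerance = 1e-6)
  unlink(mdir, recursive = TRUE)
  back <- read_phantom_nifti(dir)
  expect_equal(back$dynamic$frames, ph$dynamic$frames, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(array(back$labels, dim(back$labels)),
                   array(as.integer(ph$labels), dim(ph$labels)))
  expect_equal(back$vfa$flip_angles_deg, ph$vfa$flip_angles_deg)
  expect_equal(back$aorta_mask, ph$aorta_mask, ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
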