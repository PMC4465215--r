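# gamma-variate bolus shape x^a exp(a (1 - x)), peak 1 at x = 1;
# width_factor(a) = FWHM in units of the time-to-peak tp
gamma_variate_width <- function(shape) {
  f <- function(x) x^shape * exp(shape * (1 - x)) - 0.5
  lo <- stats::uniroot(f, c(1e-9, 1), tol = 1e-12)$root
  hi <- stats::uniroot(f, c(1, 50), tol = 1e-12)$root
  hi - lo
}

#' Synthesize a blood-pool arterial input function
#'
#' Generates the arterial curve of an intravascular agent: a sharp
#' gamma-variate first pass scaled to a requested full width at half
#' maximum, followed by a recirculation plateau (a fraction of the peak,
#' rising over a few seconds and decaying with a long half-life, since a
#' blood-pool agent persists in the vasculature), plus optional Gaussian
#' noise. The defaults emulate an aortic curve whose amplitude is roughly
#' two orders of magnitude above the tissue curves.
#'
#' @param peak_amplitude first-pass peak height (relaxation-rate units 1/s).
#' @param arrival_s bolus arrival time in seconds.
#' @param fwhm_s full width at half maximum of the first pass (s).
#' @param plateau_fraction plateau height as a fraction of the peak.
#' @param duration_s curve duration (s); must leave room for the plateau
#'   window, i.e. at least `arrival_s + 90` s when the plateau statistic is
#'   to be computed.
#' @param step_s sampling interval (s); use the frame interval (1.5 s) for a
#'   measured-looking curve or a fine grid for a ground-truth curve.
#' @param noise_sd Gaussian noise SD (0 = noiseless truth).
#' @param seed integer seed (reproducible).
#' @param shape gamma-variate shape parameter.
#' @param plateau_rise_s plateau rise time constant (s).
#' @param plateau_halflife_s plateau decay half-life (s).
#' @param require_plateau_window error if `duration_s < arrival_s + 90`.
#' @return An [aif_estimate()] with the true arrival index set.
#' @export
synth_aif <- function(peak_amplitude = 60, arrival_s = 15, fwhm_s = 10,
                      plateau_fraction = 0.3, duration_s = 148.5,
                      step_s = 0.1, noise_sd = 0.25, seed = 1L,
                      shape = 3, plateau_rise_s = 12,
                      plateau_halflife_s = 600,
                      require_plateau_window = TRUE) {
  if (fwhm_s <= 0) stop("'fwhm_s' must be > 0", call. = FALSE)
  if (require_plateau_window && duration_s < arrival_s + 90)
    stop("duration_s too short: plateau window needs arrival_s + 90 s", call. = FALSE)
  tt <- seq(0, duration_s, by = step_s)
  tp <- fwhm_s / gamma_variate_width(shape)
  x <- pmax(tt - arrival_s, 0) / tp
  first_pass <- peak_amplitude * x^shape * exp(shape * (1 - x))
  ts <- pmax(tt - arrival_s, 0)
  plateau <- plateau_fraction * peak_amplitude *
    (1 - exp(-ts / plateau_rise_s)) * 0.5^(ts / plateau_halflife_s)
  plateau[tt <= arrival_s] <- 0
  v <- first_pass + plateau
  if (noise_sd > 0)
    v <- v + with_seed(seed, stats::rnorm(length(v), sd = noise_sd))
  aif_estimate(time_curve(v, step_s),
               arrival_index = floor(arrival_s / step_s) + 1L)
}

#' Synthesize a tissue curve from the forward compartment model
#'
#' Evaluates [forward_tissue()] on a dense grid, samples it at the dynamic
#' frame times, and adds Gaussian noise. The default compartments describe
#' resting skeletal muscle at a total perfusion of 10 mL/(min 100 cm^3)
#' split 60/40 between a slow capillary and a fast arteriolar compartment.
#'
#' @param aif ground-truth arterial input ([aif_estimate()] or
#'   [time_curve()]) on a dense grid.
#' @param compartments [compartment_params()] or list of them.
#' @param noise_sd Gaussian noise SD in curve units (default 0.04 1/s).
#' @param frame_interval_s dynamic frame interval (s).
#' @param seed integer seed.
#' @param step_s dense evaluation grid (s).
#' @return A [time_curve()] sampled at the frame interval.
#' @export
synth_tissue <- function(aif,
                         compartments = list(
                           compartment_params(1e-3, 12, 2.5, 2, label = "capillary"),
                           compartment_params(6.7e-4, 3, 1.2, 0.8, label = "arteriolar")),
                         noise_sd = 0.04, frame_interval_s = 1.5,
                         seed = 1L, step_s = 0.1) {
  dense <- forward_tissue(aif, compartments, step_s = step_s)
  td <- tc_time(dense)
  tf <- seq(0, td[length(td)], by = frame_interval_s)
  v <- stats::approx(td, dense$value, xout = tf, rule = 2)$y
  if (noise_sd > 0)
    v <- v + with_seed(seed, stats::rnorm(length(v), sd = noise_sd))
  time_curve(v, frame_interval_s, units = dense$units)
}

default_segment_volumes <- function(n_segments = 8L) {
  if (n_segments == 8L) {
    c(medial_thigh = 800, cranial_thigh = 700, lateral_thigh = 900,
      pelvic_thigh = 600, lower_leg = 1100, bone = 600, skin = 400, fat = 400)
  } else {
    stats::setNames(rep(5500 / n_segments, n_segments),
                    paste0("segment_", seq_len(n_segments)))
  }
}

#' Synthesize a complete multi-measurement perfusion study
#'
#' Generates the full statistical structure the analysis pipeline assumes:
#' subjects carrying up to three flow states each, heterogeneous segment
#' responsiveness (some segments do not respond to vasodilation, the lower
#' leg responds most strongly), flow increases assigned predominantly to
#' the fast arteriolar compartment, a per-measurement multiplicative
#' arterial plateau jitter (so the plateau normalization has work to do),
#' and Gaussian noise on tissue and arterial curves. Tissue curves are
#' generated from the *true* arterial input; the *measured* arterial curve
#' handed to the pipeline is the true one scaled by the jitter factor and
#' degraded by noise, emulating coil-dependent arterial signal differences.
#'
#' @param n_subjects number of subjects (default 7).
#' @param n_measurements total flow measurements (default 20, distributed
#'   as up to 3 per subject).
#' @param n_segments number of tissue segments (default 8).
#' @param flow_range_ml_min range the target total flows are drawn from.
#' @param aif_jitter_sdlog SD (log scale) of the lognormal per-measurement
#'   plateau jitter; 0 disables jitter.
#' @param tissue_noise_sd tissue curve noise SD (1/s).
#' @param aif_noise_sd arterial curve noise SD (1/s).
#' @param n_frames number of dynamic frames.
#' @param frame_interval_s dynamic frame interval (s).
#' @param aif_peak true arterial first-pass peak amplitude (1/s).
#' @param plateau_fraction arterial plateau fraction of peak.
#' @param segment_volumes_cm3 named vector of segment volumes; length must
#'   equal `n_segments`.
#' @param aif_sampling `"dense"` (default) emits the measured arterial
#'   curve on the generation grid; `"frames"` resamples it at the dynamic
#'   frame interval first, emulating the bolus-peak flattening of a
#'   view-shared acquisition.
#' @param seed integer master seed; the dataset is a pure function of the
#'   arguments and this seed.
#' @param step_s dense generation grid (s).
#' @return An object of class `dce_study`: list with `measurements` (each
#'   holding `segments`, `tissue` curves, measured `aif`,
#'   `reference_flow_ml_min` and a `truth` record) and `truth_table`, a
#'   per-measurement-per-segment ground-truth parameter table.
#' @export
synth_study <- function(n_subjects = 7L, n_measurements = 20L, n_segments = 8L,
                        flow_range_ml_min = c(142, 941),
                        aif_jitter_sdlog = 0.15,
                        tissue_noise_sd = 0.04, aif_noise_sd = 0.25,
                        n_frames = 100L, frame_interval_s = 1.5,
                        aif_peak = 60, plateau_fraction = 0.3,
                        segment_volumes_cm3 = default_segment_volumes(n_segments),
                        seed = 1L, step_s = 0.1,
                        aif_sampling = c("dense", "frames")) {
  aif_sampling <- match.arg(aif_sampling)
  if (any(flow_range_ml_min <= 0)) stop("flow range must be positive", call. = FALSE)
  if (length(segment_volumes_cm3) != n_segments)
    stop("segment_volumes_cm3 must have one entry per segment", call. = FALSE)
  seg_names <- names(segment_volumes_cm3)
  if (is.null(seg_names)) seg_names <- paste0("segment_", seq_len(n_segments))
  duration_s <- (n_frames - 1L) * frame_interval_s
  non_muscle <- seg_names %in% c("bone", "skin", "fat")

  # subject assignment: 3 states per subject until n_measurements is reached
  subject_of <- rep(seq_len(n_subjects), each = 3L)[seq_len(n_measurements)]

  state <- with_seed(seed, {
    subjects <- lapply(seq_len(n_subjects), function(s) {
      arche_p <- function(nm) if (nm) c(0.7, 0.3, 0.0) else c(0.45, 0.3, 0.25)
      w <- vapply(non_muscle, function(nm)
        sample(c(0, 1, 6), 1L, prob = arche_p(nm)), 0)
      w[seg_names == "lower_leg"] <- 6  # strongest responder
      list(
        baseline_perf = pmin(pmax(exp(stats::rnorm(n_segments, log(4.5), 0.25)), 2), 9),
        responsiveness = w,
        mtt_cap = stats::runif(n_segments, 8, 15),
        mtt_art = stats::runif(n_segments, 2, 3.5),
        delay_cap = stats::runif(n_segments, 1.5, 3.5),
        disp_cap = stats::runif(n_segments, 0.5, 1.5),
        delay_ratio = stats::runif(n_segments, 0.25, 0.7),
        disp_ratio = stats::runif(n_segments, 0.25, 0.7))
    })
    meas <- lapply(seq_len(n_measurements), function(m) {
      list(target_flow = stats::runif(1, flow_range_ml_min[1L], flow_range_ml_min[2L]),
           arrival_s = stats::runif(1, 12, 18),
           jitter = if (aif_jitter_sdlog > 0) exp(stats::rnorm(1, 0, aif_jitter_sdlog)) else 1)
    })
    list(subjects = subjects, meas = meas)
  })

  V <- as.numeric(segment_volumes_cm3)
  measurements <- vector("list", n_measurements)
  truth_rows <- list()
  for (m in seq_len(n_measurements)) {
    sj <- state$subjects[[subject_of[m]]]
    mm <- state$meas[[m]]
    Q <- mm$target_flow
    p0 <- sj$baseline_perf
    Q0 <- sum(p0 * V) / 100
    if (Q >= Q0) {
      w <- sj$responsiveness
      if (sum(w) == 0) w <- rep(1, n_segments)
      dp <- (Q - Q0) * 100 * w / sum(w * V)
      perf <- p0 + dp
      perf_cap <- 0.7 * p0
      perf_art <- 0.3 * p0 + dp
    } else {
      perf <- p0 * Q / Q0
      perf_cap <- 0.7 * perf
      perf_art <- 0.3 * perf
    }

    aif_true <- synth_aif(peak_amplitude = aif_peak, arrival_s = mm$arrival_s,
                          plateau_fraction = plateau_fraction,
                          duration_s = duration_s, step_s = step_s,
                          noise_sd = 0, seed = seed)
    comps <- lapply(seq_len(n_segments), function(s) {
      list(compartment_params(perf_cap[s] / 6000, sj$mtt_cap[s],
                              sj$delay_cap[s], sj$disp_cap[s], label = "capillary"),
           compartment_params(perf_art[s] / 6000, sj$mtt_art[s],
                              sj$delay_cap[s] * sj$delay_ratio[s],
                              sj$disp_cap[s] * sj$disp_ratio[s],
                              label = "arteriolar"))
    })
    tissue <- lapply(seq_len(n_segments), function(s) {
      synth_tissue(aif_true, comps[[s]], noise_sd = tissue_noise_sd,
                   frame_interval_s = frame_interval_s,
                   seed = seed + 101L * m + s, step_s = step_s)
    })
    names(tissue) <- seg_names

    # measured AIF: jittered amplitude plus noise. By default the curve is
    # emitted on the dense generation grid, so the pipeline sees the full
    # bolus shape; aif_sampling = "frames" resamples it at the dynamic
    # frame interval first, emulating the first-pass peak flattening of a
    # view-shared acquisition (which biases flow upward).
    if (aif_sampling == "frames") {
      tf <- seq(0, duration_s, by = frame_interval_s)
      td <- tc_time(aif_true$curve)
      v_meas <- stats::approx(td, aif_true$curve$value * mm$jitter,
                              xout = tf, rule = 2)$y
      aif_step <- frame_interval_s
    } else {
      v_meas <- aif_true$curve$value * mm$jitter
      aif_step <- step_s
    }
    if (aif_noise_sd > 0)
      v_meas <- v_meas + with_seed(seed + 7919L * m,
                                   stats::rnorm(length(v_meas), sd = aif_noise_sd))
    aif_meas <- aif_estimate(time_curve(v_meas, aif_step), n_voxels = 20L)

    segments <- data.frame(segment_id = seq_len(n_segments), name = seg_names,
                           volume_cm3 = V, stringsAsFactors = FALSE)
    truth_rows[[m]] <- data.frame(
      measurement_id = sprintf("m%02d", m), subject_id = subject_of[m],
      segment = seg_names, volume_cm3 = V,
      perfusion_ml_min_100cm3 = perf,
      perf_cap_ml_min_100cm3 = perf_cap, perf_art_ml_min_100cm3 = perf_art,
      mtt_cap_s = sj$mtt_cap, mtt_art_s = sj$mtt_art,
      delay_cap_s = sj$delay_cap,
      delay_art_s = sj$delay_cap * sj$delay_ratio,
      disp_cap_s = sj$disp_cap,
      disp_art_s = sj$disp_cap * sj$disp_ratio,
      stringsAsFactors = FALSE)
    measurements[[m]] <- list(
      measurement_id = sprintf("m%02d", m),
      index = m,
      subject_id = subject_of[m],
      segments = segments,
      tissue = tissue,
      aif = aif_meas,
      aif_true = aif_true,
      reference_flow_ml_min = Q,
      truth = list(perfusion = stats::setNames(perf, seg_names),
                   compartments = comps,
                   total_flow_ml_min = Q,
                   aif_jitter = mm$jitter,
                   aif_arrival_s = mm$arrival_s,
                   frame_interval_s = frame_interval_s))
  }
  structure(list(measurements = measurements,
                 truth_table = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
                 n_subjects = n_subjects,
                 seed = seed),
            class = "dce_study")
}

#' @export
print.dce_study <- function(x, ...) {
  ns <- nrow(x$measurements[[1L]]$segments)
  cat(sprintf("<dce_study> %d measurements, %d subjects, %d segments, seed %d\n",
              length(x$measurements), x$n_subjects, ns, x$seed))
  invisible(x)
}

#' Paint a synthetic 4D phantom for one measurement
#'
#' Renders a measurement of a synthetic study as image data: a label map of
#' segment blobs plus an aortic tube, a 4-flip-angle baseline stack, and a
#' dynamic spoiled gradient-echo signal series generated by the SPGR
#' forward model from per-voxel `R1(t) = R10 + dR1(t)`. This exercises the
#' full relaxometry + extraction path end to end. Segment volumes of the
#' returned measurement are recomputed as voxel count x voxel volume, and
#' the reference flow is rescaled accordingly.
#'
#' @param measurement one element of `synth_study()$measurements`.
#' @param grid_dim length-3 integer image dimensions.
#' @param voxel_dim_mm voxel edge lengths in mm.
#' @param m0 equilibrium magnetization painted into all voxels.
#' @param r10_tissue,r10_blood baseline relaxation rates (1/s).
#' @param tr_s repetition time (s).
#' @param flip_angles_deg baseline stack flip angles.
#' @param dyn_flip_angle_deg dynamic flip angle.
#' @param voxel_noise_sd per-voxel Gaussian noise on dR1 curves (1/s).
#' @param seed integer seed.
#' @return An object of class `dce_phantom`: list with `vfa`
#'   ([vfa_stack()]), `dynamic` ([dynamic_series()] of signal), `labels`
#'   (integer 3D array), `aorta_mask` (logical 3D array), `measurement`
#'   (volumes updated), and the painted `r10`/`m0` maps.
#' @export
synth_phantom_4d <- function(measurement, grid_dim = c(16L, 16L, 8L),
                             voxel_dim_mm = c(2.9, 2.9, 4.5),
                             m0 = 1000, r10_tissue = 0.8, r10_blood = 0.7,
                             tr_s = 0.00269,
                             flip_angles_deg = c(5, 10, 20, 30),
                             dyn_flip_angle_deg = 30,
                             voxel_noise_sd = 0, seed = 1L) {
  segs <- measurement$segments
  n_seg <- nrow(segs)
  nx <- grid_dim[1L]; ny <- grid_dim[2L]; nz <- grid_dim[3L]
  if (nx * ny < n_seg + 4L) stop("grid too small for the segment blobs", call. = FALSE)
  labels <- array(0L, grid_dim)
  aorta <- array(FALSE, grid_dim)
  aorta[1:2, 1:2, ] <- TRUE
  free <- which(!aorta)
  chunks <- split(free, cut(seq_along(free), n_seg, labels = FALSE))
  for (s in seq_len(n_seg)) labels[chunks[[s]]] <- s

  vox_cm3 <- prod(voxel_dim_mm) / 1000
  counts <- tabulate(labels[labels > 0L], nbins = n_seg)
  segs$volume_cm3 <- counts * vox_cm3
  truth <- measurement$truth
  truth$total_flow_ml_min <- sum(truth$perfusion * segs$volume_cm3) / 100

  # frame-sampled noiseless curves per region
  fi <- truth$frame_interval_s
  aif_true <- measurement$aif_true
  td <- tc_time(aif_true$curve)
  tf <- seq(0, td[length(td)], by = fi)
  nt <- length(tf)
  seg_curves <- vapply(seq_len(n_seg), function(s) {
    dense <- forward_tissue(aif_true, truth$compartments[[s]])
    stats::approx(tc_time(dense), dense$value, xout = tf, rule = 2)$y
  }, numeric(nt))
  aif_frames <- stats::approx(td, aif_true$curve$value, xout = tf, rule = 2)$y

  nvox <- prod(grid_dim)
  dR1 <- matrix(0, nvox, nt)
  lab_v <- as.integer(labels)
  for (s in seq_len(n_seg)) dR1[lab_v == s, ] <-
    matrix(seg_curves[, s], sum(lab_v == s), nt, byrow = TRUE)
  dR1[as.logical(aorta), ] <- matrix(aif_frames, sum(aorta), nt, byrow = TRUE)
  if (voxel_noise_sd > 0)
    dR1 <- dR1 + with_seed(seed, matrix(stats::rnorm(length(dR1), sd = voxel_noise_sd),
                                        nvox, nt))

  r10 <- array(r10_tissue, grid_dim)
  r10[aorta] <- r10_blood
  m0_map <- array(m0, grid_dim)
  R1 <- as.numeric(r10) + dR1
  S <- spgr_signal(as.numeric(m0_map), R1, dyn_flip_angle_deg, tr_s)
  dyn <- dynamic_series(array(S, c(grid_dim, nt)), fi, "signal", voxel_dim_mm)
  vfa <- vfa_stack(lapply(flip_angles_deg, function(a)
    array(spgr_signal(as.numeric(m0_map), as.numeric(r10), a, tr_s), grid_dim)),
    flip_angles_deg, tr_s)

  measurement$segments <- segs
  measurement$truth <- truth
  measurement$reference_flow_ml_min <- truth$total_flow_ml_min
  structure(list(vfa = vfa, dynamic = dyn, labels = labels, aorta_mask = aorta,
                 r10 = r10, m0 = m0_map, voxel_dim_mm = voxel_dim_mm,
                 measurement = measurement),
            class = "dce_phantom")
}

#' Write / read a phantom as NIfTI-1 volumes
#'
#' Writes the dynamic series, label map and baseline stack of a
#' [synth_phantom_4d()] phantom as NIfTI-1 files (`dynamic.nii.gz`,
#' `labels.nii.gz`, `aorta_mask.nii.gz`, `vfa_<angle>.nii.gz`) plus a JSON
#' sidecar with the acquisition parameters.
#'
#' @param phantom a `dce_phantom`.
#' @param dir output directory (created if needed).
#' @return `write_phantom_nifti` returns `dir` invisibly;
#'   `read_phantom_nifti` returns a list with `vfa`, `dynamic`, `labels`,
#'   `aorta_mask` reconstructed from disk.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  stopifnot(inherits(phantom, "dce_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pd <- phantom$voxel_dim_mm
  wn <- function(x, f) RNifti::writeNifti(RNifti::asNifti(x, pixdim = pd),
                                          file.path(dir, f))
  wn(phantom$dynamic$frames, "dynamic.nii.gz")
  wn(array(as.numeric(phantom$labels), dim(phantom$labels)), "labels.nii.gz")
  wn(array(as.numeric(phantom$aorta_mask), dim(phantom$aorta_mask)), "aorta_mask.nii.gz")
  for (i in seq_along(phantom$vfa$flip_angles_deg))
    wn(phantom$vfa$volumes[[i]],
       sprintf("vfa_%02d.nii.gz", phantom$vfa$flip_angles_deg[i]))
  meta <- list(flip_angles_deg = phantom$vfa$flip_angles_deg,
               tr_s = phantom$vfa$tr_s,
               frame_interval_s = phantom$dynamic$frame_interval_s,
               voxel_dim_mm = pd)
  jsonlite::write_json(meta, file.path(dir, "acquisition.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_phantom_nifti
#' @export
read_phantom_nifti <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "acquisition.json"),
                              simplifyVector = TRUE)
  rd <- function(f) {
    a <- RNifti::readNifti(file.path(dir, f))
    array(as.numeric(a), dim(a))
  }
  angles <- meta$flip_angles_deg
  vfa <- vfa_stack(lapply(angles, function(a) rd(sprintf("vfa_%02d.nii.gz", a))),
                   angles, meta$tr_s)
  dynamic <- dynamic_series(rd("dynamic.nii.gz"), meta$frame_interval_s,
                            "signal", meta$voxel_dim_mm)
  lab <- rd("labels.nii.gz")
  list(vfa = vfa, dynamic = dynamic,
       labels = array(as.integer(lab + 0.5), dim(lab)),
       aorta_mask = rd("aorta_mask.nii.gz") > 0.5)
}
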