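#' Study configuration
#'
#' Validated bundle of every tunable the pipeline uses. Unknown keys are
#' rejected, so typos cannot silently fall back to defaults.
#'
#' @param seed global integer seed for the deterministic multi-starts.
#' @param alpha F-test significance level.
#' @param window_s kinetic fit window (s).
#' @param fit_grid_step_s fitting grid step (s).
#' @param frame_interval_s dynamic frame interval (s).
#' @param baseline_frames pre-contrast frames (contrast injected after the
#'   fifth acquisition).
#' @param relaxivity contrast-agent relaxivity, L/(mmol s).
#' @param use_concentration convert curves to concentration before fitting
#'   (a global scale; fitted parameters are unchanged).
#' @param flip_angles_deg baseline variable-flip-angle set (degrees).
#' @param tr_s repetition time (s).
#' @param dyn_flip_angle_deg dynamic flip angle (degrees).
#' @param arrival_k_sigma,arrival_baseline_frames bolus-arrival detector
#'   settings (see [detect_arrival()]).
#' @param plateau_start_s,plateau_len_s plateau window (see [plateau_stat()]).
#' @param n_starts Latin-hypercube starts per model fit.
#' @param verbose emit per-stage log messages.
#' @return An object of class `study_config`.
#' @export
study_config <- function(seed = 1L, alpha = 0.05, window_s = 60,
                         fit_grid_step_s = 0.1, frame_interval_s = 1.5,
                         baseline_frames = 5L, relaxivity = 19,
                         use_concentration = FALSE,
                         flip_angles_deg = c(5, 10, 20, 30), tr_s = 0.00269,
                         dyn_flip_angle_deg = 30,
                         arrival_k_sigma = 3, arrival_baseline_frames = 5L,
                         plateau_start_s = 60, plateau_len_s = 20,
                         n_starts = 5L, verbose = TRUE) {
  cfg <- as.list(environment())
  num <- c("seed", "alpha", "window_s", "fit_grid_step_s", "frame_interval_s",
           "baseline_frames", "relaxivity", "tr_s", "dyn_flip_angle_deg",
           "arrival_k_sigma", "arrival_baseline_frames", "plateau_start_s",
           "plateau_len_s", "n_starts")
  for (k in num)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || !is.finite(cfg[[k]]))
      stop(sprintf("config key '%s' must be a single finite number", k), call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (cfg$relaxivity <= 0) stop("relaxivity must be > 0", call. = FALSE)
  structure(cfg, class = "study_config")
}

#' Read a study configuration from JSON
#'
#' @param path JSON file whose keys are [study_config()] arguments; unknown
#'   keys are an error.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  keys <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(keys), names(formals(study_config)))
  if (length(unknown))
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  do.call(study_config, keys)
}

log_msg <- function(cfg, stage, ...) {
  if (isTRUE(cfg$verbose))
    message(sprintf("[%s] %s", stage, sprintf(...)))
}

# extract the per-segment mean curves from a delta-R1 dynamic series
segment_curves <- function(dyn, labels, segments) {
  lapply(seq_len(nrow(segments)), function(s) {
    extract_aif(dyn, labels == segments$segment_id[s])$curve
  })
}

#' Run the kinetic analysis for a single flow measurement
#'
#' Orchestrates one measurement end to end: (optionally) relaxometry and
#' curve extraction from a 4D phantom or image set, bolus-arrival
#' detection, the arterial plateau statistic, one- and two-compartment
#' fits per segment with F-test selection, and the per-segment flow table.
#'
#' @param meas either one element of `synth_study()$measurements` (curves
#'   already extracted) or a `dce_phantom` (raw-signal path through
#'   [fit_vfa()], [dynamic_delta_r1()], [extract_aif()]).
#' @param config a [study_config()].
#' @return A list with `measurement_id`, `segments` (per-segment flow
#'   table), `fits`, `plateau_w`, `arrival_index`, `total_flow_ml_min`,
#'   `reference_flow_ml_min`.
#' @export
run_measurement <- function(meas, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  if (inherits(meas, "dce_phantom")) {
    log_msg(config, "relaxometry", "fitting VFA stack (%s voxels)",
            paste(dim(meas$vfa$volumes[[1L]]), collapse = "x"))
    maps <- fit_vfa(meas$vfa)
    dyn <- dynamic_delta_r1(meas$dynamic, maps,
                            alpha_deg = config$dyn_flip_angle_deg,
                            tr_s = config$tr_s,
                            baseline_frames = config$baseline_frames)
    inner <- meas$measurement
    tissue <- segment_curves(dyn, meas$labels, inner$segments)
    names(tissue) <- inner$segments$name
    aif <- extract_aif(dyn, meas$aorta_mask)
    meas <- inner
    meas$tissue <- tissue
    meas$aif <- aif
  }
  if (is.null(meas$tissue) || is.null(meas$aif))
    stop("measurement must carry tissue curves and an AIF", call. = FALSE)

  aif <- meas$aif
  # baseline window in frames is defined at the acquisition frame interval;
  # rescale it when the AIF lives on a finer grid
  n_base <- max(3L, round(config$arrival_baseline_frames *
                            config$frame_interval_s / aif$curve$step_s))
  aif$arrival_index <- detect_arrival(aif$curve,
                                      baseline_frames = n_base,
                                      k_sigma = config$arrival_k_sigma)
  aif$plateau_w <- plateau_stat(aif, config$plateau_start_s, config$plateau_len_s)
  log_msg(config, "aif", "%s: arrival frame %d, plateau w = %.3g",
          meas$measurement_id, aif$arrival_index, aif$plateau_w)

  conv <- function(tc) if (config$use_concentration)
    concentration(tc, config$relaxivity) else tc
  aif_fit <- aif
  aif_fit$curve <- conv(aif$curve)

  segments <- meas$segments
  fits <- vector("list", nrow(segments))
  rows <- vector("list", nrow(segments))
  for (s in seq_len(nrow(segments))) {
    fit <- dce_fit(conv(meas$tissue[[s]]), aif_fit, model = "auto",
                   window_s = config$window_s,
                   step_s = config$fit_grid_step_s,
                   alpha = config$alpha, n_starts = config$n_starts,
                   seed = config$seed)
    fits[[s]] <- fit
    rep <- perfusion_report(fit)
    cap <- rep[rep$compartment == "capillary", ]
    art <- rep[rep$compartment == "arteriolar", ]
    no_art <- nrow(art) == 0L
    rows[[s]] <- data.frame(
      segment_id = segments$segment_id[s], name = segments$name[s],
      volume_cm3 = segments$volume_cm3[s],
      model_order = fit$model_order,
      perfusion_ml_min_100cm3 = attr(rep, "total_perfusion"),
      flow_cap_ml_min_100cm3 = cap$perfusion_ml_min_100cm3,
      flow_art_ml_min_100cm3 = if (no_art) 0 else art$perfusion_ml_min_100cm3,
      mtt_cap_s = cap$mtt_s, mtt_art_s = if (no_art) NA_real_ else art$mtt_s,
      vb_cap = cap$vb, vb_art = if (no_art) 0 else art$vb,
      delay_cap_s = cap$delay_s,
      delay_art_s = if (no_art) NA_real_ else art$delay_s,
      disp_cap_s = cap$dispersion_s,
      disp_art_s = if (no_art) NA_real_ else art$dispersion_s,
      rss = fit$rss,
      f_stat = fit$selection$f_stat, p_value = fit$selection$p_value,
      stringsAsFactors = FALSE)
    log_msg(config, "fit", "%s/%s: %dC model, F = %.2f mL/(min 100cm^3)",
            meas$measurement_id, segments$name[s], fit$model_order,
            attr(rep, "total_perfusion"))
  }
  segments_out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(measurement_id = meas$measurement_id,
       subject_id = meas$subject_id,
       segments = segments_out,
       fits = fits,
       plateau_w = aif$plateau_w,
       arrival_index = aif$arrival_index,
       total_flow_ml_min = total_flow(segments_out),
       reference_flow_ml_min = meas$reference_flow_ml_min)
}

#' Run a whole study: per-measurement fits, plateau normalization,
#' validation statistics
#'
#' Applies [run_measurement()] to every measurement, normalizes flows by
#' the arterial plateau statistics ([normalize_flows()]), and - when
#' reference flows are available - regresses the estimated total flows
#' against them for the corrected, uncorrected, capillary-only and
#' arteriolar-only variants.
#'
#' @param study a `dce_study` from [synth_study()], or a plain list of
#'   measurements / `dce_phantom` objects.
#' @param config a [study_config()].
#' @param out_dir optional output directory; when given, per-measurement
#'   ROI tables, the study-level flow table and the statistics block are
#'   written as CSV/JSON (deterministic content, no timestamps).
#' @return An object of class `dce_study_result` with `measurements`
#'   (normalized), `flow_table`, and `stats`.
#' @export
run_study <- function(study, config = study_config(), out_dir = NULL) {
  meas_list <- if (inherits(study, "dce_study")) study$measurements else study
  if (length(meas_list) < 1L) stop("no measurements", call. = FALSE)
  results <- lapply(meas_list, run_measurement, config = config)
  results <- normalize_flows(results)
  if (length(results) == 1L)
    log_msg(config, "study", "single measurement: c1 = 1 by construction")

  flow_table <- do.call(rbind, c(lapply(results, function(m) data.frame(
    measurement_id = m$measurement_id,
    subject_id = if (is.null(m$subject_id)) NA_integer_ else m$subject_id,
    plateau_w = m$plateau_w,
    norm_factor = m$norm_factor,
    total_flow_ml_min = m$total_flow_ml_min,
    total_flow_uncorrected_ml_min = m$total_flow_uncorrected_ml_min,
    reference_flow_ml_min = if (is.null(m$reference_flow_ml_min)) NA_real_
                            else m$reference_flow_ml_min,
    stringsAsFactors = FALSE)), list(make.row.names = FALSE)))

  attribution <- compartment_attribution(results)
  stats_block <- NULL
  ref <- flow_table$reference_flow_ml_min
  if (sum(is.finite(ref)) >= 3L) {
    ok <- is.finite(ref)
    # a variant can be degenerate (e.g. no two-compartment fit selected
    # anywhere leaves all arteriolar flows at zero); report NULL for it
    safe_reg <- function(est) tryCatch(regress_validation(est[ok], ref[ok]),
                                       error = function(e) NULL)
    stats_block <- list(
      corrected = safe_reg(flow_table$total_flow_ml_min),
      uncorrected = safe_reg(flow_table$total_flow_uncorrected_ml_min),
      capillary = safe_reg(attribution$capillary_flow_ml_min),
      arteriolar = safe_reg(attribution$arteriolar_flow_ml_min))
  } else {
    log_msg(config, "study", "no (or too few) reference flows: regression skipped")
  }

  out <- structure(list(measurements = results, flow_table = flow_table,
                        attribution = attribution, stats = stats_block,
                        config = config),
                   class = "dce_study_result")
  if (!is.null(out_dir)) write_study_outputs(out, out_dir)
  out
}

write_study_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (m in result$measurements)
    utils::write.csv(format(m$segments, digits = 12, trim = TRUE),
                     file.path(out_dir, sprintf("roi_%s.csv", m$measurement_id)),
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(format(result$flow_table, digits = 12, trim = TRUE),
                   file.path(out_dir, "study_flows.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(result$stats))
    jsonlite::write_json(result$stats, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.dce_study_result <- function(x, ...) {
  cat(sprintf("<dce_study_result> %d measurements\n", nrow(x$flow_table)))
  print(x$flow_table, row.names = FALSE, digits = 4)
  for (variant in c("corrected", "uncorrected")) {
    s <- x$stats[[variant]]
    if (!is.null(s))
      cat(sprintf("%-11s vs reference: R = %.3f, slope = %.2f, intercept = %.1f mL/min, residual SD = %.1f mL/min\n",
                  variant, s$pearson_r, s$slope, s$intercept, s$residual_sd))
  }
  invisible(x)
}
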