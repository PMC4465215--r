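#' Arterial input function estimate
#'
#' Wraps a measured arterial curve together with the bolus-arrival index,
#' the number of voxels averaged, and (once computed) the steady-state
#' plateau statistic used for inter-measurement flow normalization.
#'
#' @param curve a [time_curve()].
#' @param n_voxels number of voxels averaged into the curve.
#' @param arrival_index integer index of bolus arrival (NA until detected).
#' @param plateau_w mean steady-state plateau value (NA until computed).
#' @return An object of class `aif_estimate`.
#' @export
aif_estimate <- function(curve, n_voxels = NA_integer_,
                         arrival_index = NA_integer_, plateau_w = NA_real_) {
  stopifnot(inherits(curve, "time_curve"))
  if (!is.na(arrival_index) &&
      (arrival_index < 1L || arrival_index > length(curve$value)))
    stop("arrival_index outside curve support", call. = FALSE)
  structure(list(curve = curve, n_voxels = as.integer(n_voxels),
                 arrival_index = as.integer(arrival_index),
                 plateau_w = as.numeric(plateau_w)),
            class = "aif_estimate")
}

#' @export
print.aif_estimate <- function(x, ...) {
  cat(sprintf("<aif_estimate> %d samples @ %.3g s, n_voxels = %s, arrival = %s, w = %s\n",
              length(x$curve$value), x$curve$step_s,
              ifelse(is.na(x$n_voxels), "?", x$n_voxels),
              ifelse(is.na(x$arrival_index), "undetected", x$arrival_index),
              ifelse(is.na(x$plateau_w), "uncomputed", sprintf("%.3g", x$plateau_w))))
  invisible(x)
}

# Accept an aif_estimate or a bare time_curve wherever an AIF is expected.
as_aif_curve <- function(aif) {
  if (inherits(aif, "aif_estimate")) return(aif$curve)
  if (inherits(aif, "time_curve")) return(aif)
  stop("expected an 'aif_estimate' or 'time_curve'", call. = FALSE)
}

#' Extract the arterial input function from a dynamic series
#'
#' Averages the curves of all voxels selected by `mask` (e.g. voxels fully
#' inside the abdominal aorta, chosen to avoid partial-volume effects) into
#' one arterial curve. Voxel-frames masked as invalid upstream are excluded
#' from the per-frame mean.
#'
#' @param dyn a [dynamic_series()] (`delta_r1` or `concentration`).
#' @param mask logical 3D array matching the spatial dimensions of `dyn`.
#' @return An [aif_estimate()] (arrival undetected).
#' @export
extract_aif <- function(dyn, mask) {
  stopifnot(inherits(dyn, "dynamic_series"))
  d <- dim(dyn$frames)
  if (!identical(dim(mask), d[1:3]))
    stop("mask shape must match the dynamic volume", call. = FALSE)
  idx <- which(as.logical(mask))
  if (length(idx) == 0L) stop("empty AIF mask", call. = FALSE)
  V <- matrix(dyn$frames, ncol = d[4L])[idx, , drop = FALSE]
  v <- colMeans(V, na.rm = TRUE)
  aif_estimate(time_curve(v, dyn$frame_interval_s,
                          units = if (dyn$quantity == "concentration") "mmol/L" else "s^-1"),
               n_voxels = length(idx))
}

#' Detect bolus arrival on a time curve
#'
#' Deterministic threshold detector: the arrival index is the first sample
#' exceeding `baseline mean + k_sigma * baseline SD` for at least two
#' consecutive samples, searching after the baseline window.
#'
#' @param curve a [time_curve()] or [aif_estimate()].
#' @param baseline_frames number of leading samples defining the baseline
#'   (>= 3).
#' @param k_sigma threshold multiplier on the baseline SD.
#' @return Integer arrival index. Throws a `dceflow_no_bolus` error if no
#'   sustained suprathreshold samples exist.
#' @export
detect_arrival <- function(curve, baseline_frames = 5L, k_sigma = 3) {
  tc <- as_aif_curve(curve)
  v <- tc$value
  if (baseline_frames < 3L) stop("baseline_frames must be >= 3", call. = FALSE)
  if (length(v) < baseline_frames + 2L)
    stop("curve too short for arrival detection", call. = FALSE)
  base <- v[seq_len(baseline_frames)]
  thr <- mean(base) + k_sigma * stats::sd(base)
  above <- v > thr
  for (i in (baseline_frames + 1L):(length(v) - 1L)) {
    if (above[i] && above[i + 1L]) return(i)
  }
  stop(structure(class = c("dceflow_no_bolus", "error", "condition"),
                 list(message = "no bolus arrival detected", call = sys.call())))
}

#' Vascular transport parameters (bolus delay and dispersion)
#'
#' @param delay_s bolus delay between the arterial measurement site and the
#'   tissue inlet, seconds (>= 0).
#' @param dispersion_s dispersion (effective transit) time `1/beta` of the
#'   exponential vascular transport function, seconds (>= 0; 0 disables
#'   dispersion).
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(delay_s = 0, dispersion_s = 0) {
  if (!is.finite(delay_s) || delay_s < 0)
    stop("'delay_s' must be finite and >= 0", call. = FALSE)
  if (!is.finite(dispersion_s) || dispersion_s < 0)
    stop("'dispersion_s' must be finite and >= 0", call. = FALSE)
  structure(list(delay_s = delay_s, dispersion_s = dispersion_s),
            class = "transport_params")
}

#' Discretized exponential vascular transport kernel
#'
#' Samples `h(t) = beta exp(-beta t)` on the grid, truncates the support at
#' `8 / beta` (tail mass exp(-8)), and renormalizes so that the trapezoidal
#' integral of the kernel is exactly 1 - i.e. unit mass in the same
#' quadrature [conv_causal()] uses, which is what makes transport
#' mass-preserving. If the support does not resolve two grid steps the
#' kernel degenerates to a point mass `1/step_s`. A warning is issued when
#' the grid is coarser than a fifth of the dispersion time.
#'
#' @param beta_per_s exponential rate `beta` in 1/s (> 0).
#' @param step_s grid step in seconds.
#' @param duration_s kernel support in seconds (default `8 / beta`).
#' @return Numeric vector of kernel samples (units 1/s).
#' @export
transport_kernel <- function(beta_per_s, step_s, duration_s = 8 / beta_per_s) {
  if (!is.finite(beta_per_s) || beta_per_s <= 0)
    stop("'beta_per_s' must be > 0", call. = FALSE)
  if (step_s > (1 / beta_per_s) / 5)
    warning("grid step exceeds dispersion_time/5; kernel is under-resolved")
  m <- floor(duration_s / step_s)
  if (m < 2L) return(1 / step_s)
  t <- (0:m) * step_s
  k <- beta_per_s * exp(-beta_per_s * t)
  mass <- step_s * (sum(k) - 0.5 * k[1L] - 0.5 * k[length(k)])
  k / mass
}

#' Delay- and dispersion-correct an arterial input function
#'
#' Produces the tissue-inlet AIF from the measured aortic curve: the curve is
#' interpolated once onto the fitting grid, shifted to later times by the
#' bolus delay (the tissue lies downstream of the aortic measurement site),
#' and convolved with the exponential transport kernel. The output is causal
#' and, on sufficient support, mass-preserving.
#'
#' @param aif an [aif_estimate()] or [time_curve()].
#' @param params a [transport_params()].
#' @param step_s fitting grid step in seconds (default 0.1).
#' @return A [time_curve()] on the fitting grid. If the delay pushes the
#'   bolus past the end of the curve a warning is raised and the attribute
#'   `truncated_support` is set.
#' @export
correct_aif <- function(aif, params, step_s = 0.1) {
  stopifnot(inherits(params, "transport_params"))
  tc <- tc_interp(as_aif_curve(aif), step_s)
  dur <- (length(tc$value) - 1L) * step_s
  truncated <- FALSE
  if (inherits(aif, "aif_estimate") && !is.na(aif$arrival_index)) {
    arrival_s <- (aif$arrival_index - 1L) * as_aif_curve(aif)$step_s
    if (arrival_s + params$delay_s >= dur) {
      warning("delay pushes the bolus outside the curve support")
      truncated <- TRUE
    }
  } else if (params$delay_s >= dur) {
    warning("delay exceeds the curve support")
    truncated <- TRUE
  }
  v <- shift_later(tc$value, params$delay_s, step_s)
  if (params$dispersion_s > 0) {
    k <- transport_kernel(1 / params$dispersion_s, step_s)
    v <- conv_causal(v, k, step_s)
  }
  out <- time_curve(v, step_s, units = tc$units, t0 = tc$t0)
  attr(out, "truncated_support") <- truncated
  out
}

#' Arterial steady-state plateau statistic
#'
#' Mean of the arterial curve over a window in the steady-state plateau,
#' by default the 20 seconds starting 60 seconds after bolus arrival. This
#' per-measurement statistic drives the inter-measurement flow
#' normalization (see [normalize_flows()]).
#'
#' @param aif an [aif_estimate()]; arrival is detected if not yet set.
#' @param window_start_s window start, seconds after bolus arrival.
#' @param window_len_s window length in seconds.
#' @param ... passed to [detect_arrival()] when arrival is unset.
#' @return The plateau mean `w` (same units as the curve).
#' @export
plateau_stat <- function(aif, window_start_s = 60, window_len_s = 20, ...) {
  stopifnot(inherits(aif, "aif_estimate"))
  arr <- aif$arrival_index
  if (is.na(arr)) arr <- detect_arrival(aif$curve, ...)
  tc <- aif$curve
  i0 <- arr + ceiling(window_start_s / tc$step_s)
  i1 <- arr + floor((window_start_s + window_len_s) / tc$step_s)
  if (i1 > length(tc$value))
    stop(structure(class = c("dceflow_short_curve", "error", "condition"),
                   list(message = sprintf(
                     "curve ends %.1f s after arrival; plateau window needs %.1f s",
                     (length(tc$value) - arr) * tc$step_s,
                     window_start_s + window_len_s), call = sys.call())))
  mean(tc$value[i0:i1])
}
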