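#' Total flow from a segment perfusion table
#'
#' Multiplies each segment's perfusion (mL/(min 100 cm^3)) by its volume
#' (cm^3) and sums the contributions: `Q = sum_s p_s V_s / 100` in mL/min.
#' Every listed segment must carry a perfusion value - total flow is only
#' meaningful over the entire perfused volume.
#'
#' @param segments a `data.frame` with columns `perfusion_ml_min_100cm3`
#'   and `volume_cm3` (one row per segment).
#' @return Total flow in mL/min.
#' @export
#' @examples
#' seg <- data.frame(perfusion_ml_min_100cm3 = 4.7, volume_cm3 = 5510.6)
#' total_flow(seg)  # ~259 mL/min
total_flow <- function(segments) {
  if (!all(c("perfusion_ml_min_100cm3", "volume_cm3") %in% names(segments)))
    stop("need columns perfusion_ml_min_100cm3 and volume_cm3", call. = FALSE)
  p <- segments$perfusion_ml_min_100cm3
  v <- segments$volume_cm3
  if (any(!is.finite(v)) || any(v <= 0))
    stop("segment volumes must be positive", call. = FALSE)
  if (any(!is.finite(p)))
    stop(structure(class = c("dceflow_incomplete_segments", "error", "condition"),
                   list(message = "missing perfusion for a listed segment",
                        call = sys.call())))
  sum(p * v) / 100
}

#' Normalize fitted flows by the arterial steady-state plateau
#'
#' The arterial plateau height varies between measurements (coil border
#' effects, shimming, inflow), which scales all fitted flows of a
#' measurement by the inverse of the same factor. With per-measurement
#' plateau statistics `w_n` (see [plateau_stat()]), the grand mean
#' `W = <w_n>` defines correction factors `c_n = w_n / W`; every segment
#' perfusion and the total flow of measurement `n` are multiplied by `c_n`.
#' The mean of the `c_n` is exactly 1, so normalization redistributes but
#' does not rescale the study.
#'
#' @param measurements list of measurement results (as returned by
#'   [run_measurement()]), each carrying `plateau_w`, a `segments` table
#'   and `total_flow_ml_min`.
#' @return The list with `norm_factor`, normalized segment perfusions and
#'   `total_flow_ml_min` updated; unnormalized totals are preserved in
#'   `total_flow_uncorrected_ml_min`.
#' @export
normalize_flows <- function(measurements) {
  if (length(measurements) < 1L) stop("no measurements", call. = FALSE)
  w <- vapply(measurements, function(m) m$plateau_w, 0)
  if (any(!is.finite(w) | w <= 0))
    stop("every measurement needs a positive plateau statistic", call. = FALSE)
  W <- mean(w)
  lapply(measurements, function(m) {
    cn <- m$plateau_w / W
    m$norm_factor <- cn
    m$total_flow_uncorrected_ml_min <- m$total_flow_ml_min
    keep <- grep("^(perfusion|flow_cap|flow_art)", names(m$segments), value = TRUE)
    m$segments[keep] <- lapply(m$segments[keep], function(col) col * cn)
    m$total_flow_ml_min <- total_flow(m$segments)
    m
  })
}

#' Ordinary least-squares validation regression
#'
#' Regresses pipeline-estimated flows on an independent reference (e.g.
#' an invasive flow probe) and reports the slope, intercept, Pearson
#' correlation with its two-sided significance, and the standard deviation
#' of the residuals about the regression line.
#'
#' @param estimated numeric vector of estimated flows (response).
#' @param reference numeric vector of reference flows (regressor).
#' @return List with `slope`, `intercept`, `pearson_r`, `p_value`,
#'   `residual_sd`, `n`.
#' @export
regress_validation <- function(estimated, reference) {
  n <- length(estimated)
  if (length(reference) != n) stop("length mismatch", call. = FALSE)
  if (n < 3L) stop("need at least 3 paired values", call. = FALSE)
  sx <- stats::sd(reference); sy <- stats::sd(estimated)
  if (sx == 0 || sy == 0)
    stop(structure(class = c("dceflow_degenerate_correlation", "error", "condition"),
                   list(message = "zero variance: correlation undefined",
                        call = sys.call())))
  mx <- mean(reference); my <- mean(estimated)
  sxy <- sum((reference - mx) * (estimated - my))
  slope <- sxy / sum((reference - mx)^2)
  intercept <- my - slope * mx
  r <- sxy / ((n - 1) * sx * sy)
  p_value <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  resid <- estimated - (intercept + slope * reference)
  list(slope = slope, intercept = intercept, pearson_r = r,
       p_value = p_value, residual_sd = sqrt(sum(resid^2) / (n - 2)), n = n)
}

#' Per-measurement capillary and arteriolar flow contributions
#'
#' Splits each measurement's total flow into the volume-weighted capillary
#' and arteriolar contributions (one-compartment fits count entirely as
#' capillary), for regressing each against the reference flow.
#'
#' @param measurements list of measurement results carrying `segments`
#'   tables with `flow_cap_ml_min_100cm3` and `flow_art_ml_min_100cm3`.
#' @return A `data.frame` with columns `measurement_id`,
#'   `capillary_flow_ml_min`, `arteriolar_flow_ml_min`.
#' @export
compartment_attribution <- function(measurements) {
  rows <- lapply(measurements, function(m) {
    s <- m$segments
    data.frame(
      measurement_id = m$measurement_id,
      capillary_flow_ml_min = sum(s$flow_cap_ml_min_100cm3 * s$volume_cm3) / 100,
      arteriolar_flow_ml_min = sum(s$flow_art_ml_min_100cm3 * s$volume_cm3) / 100,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
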