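#' Spoiled gradient-echo (SPGR) signal equation
#'
#' Steady-state SPGR signal
#' `S = M0 sin(a) (1 - E1) / (1 - E1 cos(a))` with `E1 = exp(-TR * R1)`.
#' This forward model underlies both the variable-flip-angle baseline fit
#' ([fit_vfa()]) and the dynamic inversion ([dynamic_delta_r1()]).
#'
#' @param m0 equilibrium magnetization (arbitrary units).
#' @param r1 longitudinal relaxation rate in 1/s.
#' @param alpha_deg flip angle in degrees, in (0, 90].
#' @param tr_s repetition time in seconds (> 0).
#' @return Signal in the units of `m0`. Vectorized over `m0` and `r1`.
#' @export
#' @examples
#' spgr_signal(1000, 0.8, 30, 0.00269)
spgr_signal <- function(m0, r1, alpha_deg, tr_s) {
  if (!all(is.finite(m0)) || !all(is.finite(r1)))
    stop("non-finite 'm0' or 'r1'", call. = FALSE)
  if (!is.finite(tr_s) || tr_s <= 0) stop("'tr_s' must be > 0", call. = FALSE)
  if (!is.finite(alpha_deg) || alpha_deg <= 0 || alpha_deg > 90)
    stop("'alpha_deg' must be in (0, 90]", call. = FALSE)
  a <- alpha_deg * pi / 180
  e1 <- exp(-tr_s * r1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Multi-flip-angle baseline stack
#'
#' Bundles the baseline spoiled gradient-echo volumes acquired at several
#' flip angles with their acquisition parameters, the input to [fit_vfa()].
#'
#' @param volumes list of 3D numeric arrays (one per flip angle, same shape),
#'   or a 4D array with the flip-angle dimension last.
#' @param flip_angles_deg numeric vector of flip angles in degrees; at least
#'   two distinct angles in (0, 90].
#' @param tr_s repetition time in seconds.
#' @return An object of class `vfa_stack`.
#' @export
vfa_stack <- function(volumes, flip_angles_deg, tr_s) {
  if (is.array(volumes) && length(dim(volumes)) == 4L) {
    volumes <- lapply(seq_len(dim(volumes)[4L]), function(i) volumes[, , , i])
  }
  if (!is.list(volumes) || length(volumes) < 2L)
    stop("need volumes for at least 2 flip angles", call. = FALSE)
  if (length(volumes) != length(flip_angles_deg))
    stop("one volume per flip angle required", call. = FALSE)
  if (length(unique(flip_angles_deg)) < 2L)
    stop("need at least 2 distinct flip angles", call. = FALSE)
  if (any(flip_angles_deg <= 0 | flip_angles_deg > 90))
    stop("flip angles must be in (0, 90] degrees", call. = FALSE)
  if (!is.finite(tr_s) || tr_s <= 0) stop("'tr_s' must be > 0", call. = FALSE)
  dims <- lapply(volumes, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all volumes must share one shape", call. = FALSE)
  structure(list(volumes = volumes,
                 flip_angles_deg = as.numeric(flip_angles_deg),
                 tr_s = tr_s),
            class = "vfa_stack")
}

#' Voxelwise baseline R10 / M0 mapping from a variable-flip-angle stack
#'
#' Estimates the baseline longitudinal relaxation rate `R10` and equilibrium
#' magnetization `M0` per voxel by least squares against [spgr_signal()].
#' The fit is seeded by the exact linearization (signal/sin(a) regressed on
#' signal/tan(a), whose slope is `E1`) and then refined by vectorized
#' Gauss-Newton iterations on (`M0`, `R10`), which removes the noise bias of
#' the linearized estimator. Voxels where the fit is undefined (all-zero
#' signal, slope outside (0, 1), divergence) are flagged invalid rather than
#' filled with sentinel values.
#'
#' @param stack a [vfa_stack()].
#' @param refine logical; run the Gauss-Newton refinement (default `TRUE`).
#' @param max_iter maximum Gauss-Newton iterations.
#' @return An object of class `relaxometry_maps`: list with 3D arrays `r10`
#'   (1/s), `m0`, and logical `valid_mask`, plus `tr_s`.
#' @export
fit_vfa <- function(stack, refine = TRUE, max_iter = 25L) {
  stopifnot(inherits(stack, "vfa_stack"))
  a <- stack$flip_angles_deg * pi / 180
  k <- length(a)
  dims <- dim(stack$volumes[[1L]])
  S <- vapply(stack$volumes, as.numeric, numeric(prod(dims)))  # nvox x k
  if (is.null(dim(S))) S <- matrix(S, nrow = 1L)
  if (any(S < 0, na.rm = TRUE)) stop("signals must be non-negative", call. = FALSE)

  sa <- sin(a); ta <- tan(a); ca <- cos(a)
  # linearized seed: y = E1 * x + M0 (1 - E1)
  Y <- sweep(S, 2L, sa, "/")
  X <- sweep(S, 2L, ta, "/")
  mx <- rowMeans(X); my <- rowMeans(Y)
  sxx <- rowSums((X - mx)^2)
  sxy <- rowSums((X - mx) * (Y - my))
  e1 <- sxy / sxx
  m0 <- (my - e1 * mx) / (1 - e1)
  valid <- is.finite(e1) & is.finite(m0) & e1 > 0 & e1 < 1 & m0 > 0 &
    rowSums(S) > 0
  r1 <- rep(NA_real_, length(e1))
  r1[valid] <- -log(e1[valid]) / stack$tr_s

  if (refine && any(valid)) {
    idx <- which(valid)
    m0v <- m0[idx]; r1v <- r1[idx]; Sv <- S[idx, , drop = FALSE]
    for (it in seq_len(max_iter)) {
      E1 <- exp(-stack$tr_s * outer(r1v, rep(1, k)))
      den <- 1 - sweep(E1, 2L, ca, "*")
      pred <- (m0v * sweep(1 - E1, 2L, sa, "*")) / den
      R <- Sv - pred
      # Jacobian: d/dm0 = pred / m0 ; d/dr1 = m0 sin(a) (cos(a)-1)/den^2 * dE1/dr1
      J1 <- pred / m0v
      dE1 <- -stack$tr_s * E1
      J2 <- (m0v * sweep(dE1, 2L, sa * (ca - 1), "*")) / den^2
      a11 <- rowSums(J1 * J1); a12 <- rowSums(J1 * J2); a22 <- rowSums(J2 * J2)
      b1 <- rowSums(J1 * R); b2 <- rowSums(J2 * R)
      det <- a11 * a22 - a12^2
      d_m0 <- (a22 * b1 - a12 * b2) / det
      d_r1 <- (a11 * b2 - a12 * b1) / det
      bad <- !is.finite(d_m0) | !is.finite(d_r1)
      d_m0[bad] <- 0; d_r1[bad] <- 0
      # damp steps to keep parameters positive
      d_m0 <- pmax(d_m0, -0.9 * m0v); d_r1 <- pmax(d_r1, -0.9 * r1v)
      m0v <- m0v + d_m0; r1v <- r1v + d_r1
      if (max(abs(d_r1 / pmax(r1v, 1e-12))) < 1e-12) break
    }
    ok <- is.finite(m0v) & is.finite(r1v) & m0v > 0 & r1v >= 0
    m0[idx[ok]] <- m0v[ok]; r1[idx[ok]] <- r1v[ok]
    valid[idx[!ok]] <- FALSE
  }

  m0[!valid] <- NA_real_; r1[!valid] <- NA_real_
  structure(list(r10 = array(r1, dims), m0 = array(m0, dims),
                 valid_mask = array(valid, dims), tr_s = stack$tr_s),
            class = "relaxometry_maps")
}

#' @export
print.relaxometry_maps <- function(x, ...) {
  cat(sprintf("<relaxometry_maps> %s voxels, %d valid (%.1f%%)\n",
              paste(dim(x$r10), collapse = "x"), sum(x$valid_mask),
              100 * mean(x$valid_mask)))
  invisible(x)
}

#' Write relaxometry maps as NIfTI-1 volumes
#'
#' Writes `r10.nii.gz`, `m0.nii.gz` and `valid_mask.nii.gz` (0/1) into a
#' directory.
#'
#' @param maps a `relaxometry_maps` object from [fit_vfa()].
#' @param dir output directory (created if needed).
#' @param voxel_dim_mm length-3 voxel edge lengths in mm.
#' @return `dir`, invisibly.
#' @export
write_relaxometry_nifti <- function(maps, dir, voxel_dim_mm = c(2.9, 2.9, 4.5)) {
  stopifnot(inherits(maps, "relaxometry_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wn <- function(x, f) RNifti::writeNifti(RNifti::asNifti(x, pixdim = voxel_dim_mm),
                                          file.path(dir, f))
  wn(maps$r10, "r10.nii.gz")
  wn(maps$m0, "m0.nii.gz")
  wn(array(as.numeric(maps$valid_mask), dim(maps$valid_mask)), "valid_mask.nii.gz")
  invisible(dir)
}

#' Dynamic 4D series container
#'
#' @param frames 4D numeric array (x, y, z, t).
#' @param frame_interval_s sampling interval of the dynamic frames (s).
#' @param quantity one of `"signal"`, `"delta_r1"`, `"concentration"`.
#' @param voxel_dim_mm length-3 voxel edge lengths in mm.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(frames, frame_interval_s,
                           quantity = c("signal", "delta_r1", "concentration"),
                           voxel_dim_mm = c(2.9, 2.9, 4.5)) {
  quantity <- match.arg(quantity)
  stopifnot(is.array(frames), length(dim(frames)) == 4L,
            is.finite(frame_interval_s), frame_interval_s > 0,
            length(voxel_dim_mm) == 3L)
  structure(list(frames = frames, frame_interval_s = frame_interval_s,
                 quantity = quantity, voxel_dim_mm = as.numeric(voxel_dim_mm),
                 voxel_volume_mm3 = prod(voxel_dim_mm)),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<dynamic_series> %s, %d frames @ %.3g s, quantity: %s\n",
              paste(d[1:3], collapse = "x"), d[4L], x$frame_interval_s,
              x$quantity))
  invisible(x)
}

#' Invert the dynamic SPGR series into relaxation-rate-change maps
#'
#' Per voxel and frame, solves the SPGR equation for `R1(t)` given the
#' baseline `M0` map (`E1 = (M0 sin a - S) / (M0 sin a - S cos a)`,
#' `R1 = -log(E1)/TR`), then subtracts the pre-contrast reference, the mean
#' of `R1(t)` over the first `baseline_frames` frames. Frames where the
#' inversion is undefined (`S >= M0 sin a`, or `E1` outside the clamp range
#' `(1e-9, 1 - 1e-9)`) are set to `NA` and counted; they are never silently
#' clipped into the curve.
#'
#' @param dyn a [dynamic_series()] with `quantity = "signal"`.
#' @param maps a `relaxometry_maps` object from [fit_vfa()].
#' @param alpha_deg flip angle of the dynamic acquisition (degrees).
#' @param tr_s repetition time (s).
#' @param baseline_frames number of pre-contrast frames used as the R1
#'   reference (contrast is injected after the fifth acquisition by default).
#' @return A [dynamic_series()] with `quantity = "delta_r1"` (units 1/s).
#'   Invalid voxel-frames are `NA`; attribute `n_masked` counts them.
#' @export
dynamic_delta_r1 <- function(dyn, maps, alpha_deg = 30, tr_s = maps$tr_s,
                             baseline_frames = 5L) {
  stopifnot(inherits(dyn, "dynamic_series"), inherits(maps, "relaxometry_maps"))
  if (dyn$quantity != "signal")
    stop("dynamic series must contain raw signal", call. = FALSE)
  if (baseline_frames < 1L) stop("baseline_frames must be >= 1", call. = FALSE)
  d <- dim(dyn$frames)
  nt <- d[4L]
  if (baseline_frames >= nt) stop("too few frames for baseline", call. = FALSE)
  a <- alpha_deg * pi / 180
  sa <- sin(a); ca <- cos(a)
  S <- matrix(dyn$frames, ncol = nt)         # nvox x nt
  m0 <- as.numeric(maps$m0)
  valid <- as.numeric(maps$valid_mask) > 0
  msa <- m0 * sa
  E1 <- (msa - S) / (msa - S * ca)
  bad <- !is.finite(E1) | E1 <= 1e-9 | E1 >= 1 - 1e-9 | S >= msa | !valid
  E1[bad] <- NA_real_
  R1 <- -log(E1) / tr_s
  ref <- rowMeans(R1[, seq_len(baseline_frames), drop = FALSE])
  dR1 <- R1 - ref
  n_masked <- sum(bad & valid)
  if (n_masked > 0)
    message(sprintf("dynamic_delta_r1: masked %d voxel-frames (undefined SPGR inversion)",
                    n_masked))
  out <- dynamic_series(array(dR1, d), dyn$frame_interval_s, "delta_r1",
                        dyn$voxel_dim_mm)
  attr(out, "n_masked") <- n_masked
  out
}

#' Convert relaxation-rate change to tracer concentration
#'
#' The relaxation-rate change is proportional to concentration,
#' `C = dR1 / relaxivity`. The default relaxivity is that of the blood-pool
#' agent gadofosveset at 1.5 T and 37 degrees C, 19 L/(mmol s). Because the
#' conversion is a global scale applied to tissue and arterial curves alike,
#' kinetic fitting may equally run directly on relaxation-rate-change curves.
#'
#' @param x a [time_curve()] or [dynamic_series()] holding `delta_r1` data.
#' @param relaxivity longitudinal relaxivity in L/(mmol s) (> 0).
#' @return Object of the same class in mmol/L.
#' @export
concentration <- function(x, relaxivity = 19) {
  if (!is.finite(relaxivity) || relaxivity <= 0)
    stop("'relaxivity' must be > 0", call. = FALSE)
  UseMethod("concentration")
}

#' @export
concentration.time_curve <- function(x, relaxivity = 19) {
  time_curve(x$value / relaxivity, x$step_s, units = "mmol/L", t0 = x$t0)
}

#' @export
concentration.dynamic_series <- function(x, relaxivity = 19) {
  if (x$quantity != "delta_r1")
    stop("concentration conversion requires a delta_r1 series", call. = FALSE)
  dynamic_series(x$frames / relaxivity, x$frame_interval_s, "concentration",
                 x$voxel_dim_mm)
}
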