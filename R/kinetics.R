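#' Exponential residue function
#'
#' Fraction of tracer remaining in a well-mixed compartment `t` seconds
#' after an idealized impulse input: `H(t) = exp(-t / T)` with mean transit
#' time `T`.
#'
#' @param t_s time in seconds (>= 0), vectorized.
#' @param mtt_t mean transit time in seconds (> 0).
#' @return Dimensionless fraction in (0, 1].
#' @export
residue <- function(t_s, mtt_t) {
  if (!is.finite(mtt_t) || mtt_t <= 0) stop("'mtt_t' must be > 0", call. = FALSE)
  if (any(t_s < 0)) stop("'t_s' must be >= 0", call. = FALSE)
  exp(-t_s / mtt_t)
}

#' Kinetic parameters of one vascular compartment
#'
#' Perfusion is carried internally in 1/s (mL blood per mL tissue per
#' second); multiply by 6000 for the clinical unit mL/(min 100 cm^3)
#' (see [perfusion_report()]). The fractional blood volume follows from the
#' central volume theorem, `vb = F * T`.
#'
#' @param flow_f perfusion `F` in 1/s (>= 0).
#' @param mtt_t mean transit time `T` in seconds (> 0).
#' @param delay_s bolus delay of the compartment inlet relative to the
#'   arterial measurement site, seconds (>= 0).
#' @param dispersion_s dispersion time `1/beta` of the vascular transport
#'   function, seconds (>= 0, 0 = no dispersion).
#' @param label optional compartment label (e.g. "capillary").
#' @return An object of class `compartment_params`.
#' @export
compartment_params <- function(flow_f, mtt_t, delay_s = 0, dispersion_s = 0,
                               label = NULL) {
  if (!is.finite(flow_f) || flow_f < 0) stop("'flow_f' must be >= 0", call. = FALSE)
  if (!is.finite(mtt_t) || mtt_t <= 0) stop("'mtt_t' must be > 0", call. = FALSE)
  vb <- flow_f * mtt_t
  if (vb >= 1)
    warning(sprintf("unphysical fractional blood volume vb = F*T = %.3g >= 1", vb))
  structure(list(flow_f = flow_f, mtt_t = mtt_t,
                 transport = transport_params(delay_s, dispersion_s),
                 delay_s = delay_s, dispersion_s = dispersion_s,
                 vb = vb, label = label),
            class = "compartment_params")
}

# normalize 'compartments' argument to a list of compartment_params
as_compartment_list <- function(compartments) {
  if (inherits(compartments, "compartment_params")) return(list(compartments))
  if (!is.list(compartments) ||
      !all(vapply(compartments, inherits, TRUE, "compartment_params")))
    stop("'compartments' must be compartment_params or a list of them", call. = FALSE)
  compartments
}

# Hot-path model evaluator: arterial curve samples on the fitting grid in,
# tissue model samples out. Exponential transport and residue convolutions
# are evaluated with the O(n) mass-conserving recursive filter.
tissue_model_values <- function(aif_v, step_s, comps) {
  total <- numeric(length(aif_v))
  for (cp in comps) {
    x <- aif_v
    if (cp$delay_s > 0) x <- shift_later(x, cp$delay_s, step_s)
    if (cp$dispersion_s > 0) x <- kexp_conv(x, 1 / cp$dispersion_s, step_s)
    total <- total + (cp$flow_f * cp$mtt_t) * kexp_conv(x, 1 / cp$mtt_t, step_s)
  }
  total
}

#' Forward tissue model: compartment convolution of the arterial input
#'
#' Evaluates the intravascular tissue model
#' `Cb(t) = sum_i F_i (CA_i (x) H_i)(t)` on the fitting grid, where each
#' compartment's input `CA_i` is the measured arterial curve corrected for
#' that compartment's delay and dispersion, and `H_i(t) = exp(-t/T_i)` is
#' its residue function. The per-compartment fractional blood volume is
#' `vb_i = F_i T_i` (central volume theorem); the volume-weighted
#' compartment concentrations therefore sum to exactly this expression.
#'
#' @param aif an [aif_estimate()] or [time_curve()].
#' @param compartments a [compartment_params()] or list of them (capillary
#'   first by convention when two).
#' @param step_s fitting grid step in seconds.
#' @param duration_s optional truncation of the output support, seconds.
#' @return A [time_curve()] of the modeled tissue curve on the fitting grid.
#' @export
#' @examples
#' aif <- time_curve(c(numeric(10), rep(1, 590)), 0.1)
#' cp <- compartment_params(flow_f = 1.667e-3, mtt_t = 8)
#' tis <- forward_tissue(aif, cp)
forward_tissue <- function(aif, compartments, step_s = 0.1, duration_s = NULL) {
  comps <- as_compartment_list(compartments)
  if (length(comps) < 1L || length(comps) > 2L)
    stop("1 or 2 compartments supported", call. = FALSE)
  vb_tot <- sum(vapply(comps, function(cp) cp$vb, 0))
  if (vb_tot >= 1)
    warning(sprintf("total fractional blood volume %.3g >= 1 is unphysical", vb_tot))
  tc <- tc_interp(as_aif_curve(aif), step_s)
  v <- tissue_model_values(tc$value, step_s, comps)
  if (!is.null(duration_s)) v <- v[seq_len(min(length(v), floor(duration_s / step_s) + 1L))]
  time_curve(v, step_s, units = tc$units, t0 = tc$t0)
}

#' Parameter bounds for kinetic fitting
#'
#' Physiologic box constraints used by [dce_fit()]: perfusion up to
#' 8.3e-2 1/s (about 500 mL/(min 100 cm^3), above the literature maximum for
#' exercising skeletal muscle), mean transit times 1.5-60 s, bolus delays
#' 0-10 s, and dispersion times 0.05-3 s. The transit-time floor and the
#' dispersion cap are deliberately tight: transit through a perfused
#' compartment takes at least on the order of the frame interval, and
#' vascular transport times between the aorta and a muscle inlet are short
#' compared with it. Looser boxes admit unidentifiable mirror solutions
#' (very short transit time + heavy dispersion) that reproduce the curve
#' and the blood volume while corrupting the flow estimate, because flow
#' enters only as `vb / T`.
#'
#' @param flow_f,mtt_t,delay_s,dispersion_s length-2 numeric ranges.
#' @return Named list of ranges.
#' @export
dce_bounds <- function(flow_f = c(0, 8.3e-2), mtt_t = c(1.5, 60),
                       delay_s = c(0, 10), dispersion_s = c(0.05, 3)) {
  list(flow_f = flow_f, mtt_t = mtt_t, delay_s = delay_s,
       dispersion_s = dispersion_s)
}

# Levenberg-Marquardt run with the per-start iteration-cap warning muffled:
# individual multi-start runs are allowed to stall, the fit object reports
# convergence of the winning start instead.
lm_quiet <- function(...) {
  withCallingHandlers(
    minpack.lm::nls.lm(...),
    warning = function(w) {
      if (grepl("lmdif|lmder|maxfev|maxiter", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# run code with a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# check-free compartment constructor for the optimizer hot path
comp_fast <- function(flow_f, mtt_t, delay_s, dispersion_s, label) {
  structure(list(flow_f = flow_f, mtt_t = mtt_t,
                 transport = structure(list(delay_s = delay_s,
                                            dispersion_s = dispersion_s),
                                       class = "transport_params"),
                 delay_s = delay_s, dispersion_s = dispersion_s,
                 vb = flow_f * mtt_t, label = label),
            class = "compartment_params")
}

# map a full *reported* parameter vector (direct physical values) to the
# compartment list
pars_to_comps <- function(p, order) {
  if (order == 1L) {
    list(comp_fast(p[1L], p[2L], p[3L], p[4L], label = "capillary"))
  } else {
    list(comp_fast(p[1L], p[2L], p[5L], p[7L], label = "capillary"),
         comp_fast(p[3L], p[4L], p[6L], p[8L], label = "arteriolar"))
  }
}

# The exponential transport and residue filters commute, so a compartment
# curve is invariant under exchanging the mean transit time and the
# dispersion time when the flow is rescaled by their ratio:
#   (F, T, 1/beta)  <->  (F*T/(1/beta), 1/beta, T).
# Physically the residence in the compartment is slow and the vascular
# transport fast, so the canonical labeling puts the larger time constant
# into the transit time. Exact (curve-preserving) relabeling.
canonicalize_comp <- function(f, mtt, dp) {
  if (dp > mtt) list(f = f * mtt / dp, mtt = dp, dp = mtt)
  else list(f = f, mtt = mtt, dp = dp)
}

# box constraints for the nonlinear *shape* parameters; the flows enter the
# model linearly and are profiled out exactly at every shape evaluation
# (variable projection), which removes the flow/shape trade-off directions
# from the search space and guarantees the nested-model rss ordering.
fit_box <- function(order, bounds) {
  if (order == 1L) {
    lo <- c(bounds$mtt_t[1L], bounds$delay_s[1L], bounds$dispersion_s[1L])
    hi <- c(bounds$mtt_t[2L], bounds$delay_s[2L], bounds$dispersion_s[2L])
    nm <- c("mtt_t", "delay_s", "dispersion_s")
    full <- c("flow_f", "mtt_t", "delay_s", "dispersion_s")
  } else {
    lo <- c(bounds$mtt_t[1L], bounds$mtt_t[1L], bounds$delay_s[1L], 0,
            bounds$dispersion_s[1L], 0)
    hi <- c(bounds$mtt_t[2L], bounds$mtt_t[2L], bounds$delay_s[2L],
            bounds$delay_s[2L], bounds$dispersion_s[2L],
            bounds$dispersion_s[2L] - bounds$dispersion_s[1L])
    nm <- c("mtt_cap", "mtt_art", "delay_art", "delay_extra_cap",
            "dispersion_art", "dispersion_extra_cap")
    full <- c("flow_cap", "mtt_cap", "flow_art", "mtt_art",
              "delay_cap", "delay_art", "dispersion_cap", "dispersion_art")
  }
  list(lo = lo, hi = hi, names = nm, full_names = full)
}

# shape vector + profiled flows -> reported parameter vector with the
# canonical (transit time >= dispersion time) labeling per compartment
shape_to_full <- function(p, f, order) {
  if (order == 1L) {
    cc <- canonicalize_comp(f[1L], p[1L], p[3L])
    c(cc$f, cc$mtt, p[2L], cc$dp)
  } else {
    cap <- canonicalize_comp(f[1L], p[1L], p[5L] + p[6L])
    art <- canonicalize_comp(f[2L], p[2L], p[5L])
    if (art$dp > cap$dp + 1e-9)
      warning("arteriolar dispersion exceeds capillary dispersion after canonical relabeling")
    c(cap$f, cap$mtt, art$f, art$mtt, p[3L] + p[4L], p[3L], cap$dp, art$dp)
  }
}

# per-compartment unit-flow basis curves for a shape vector, on the grid
shape_basis <- function(aif_v, step_s, p, order) {
  if (order == 1L) cbind(.comp_basis_cpp(aif_v, step_s, p[1L], p[2L], p[3L]))
  else cbind(.comp_basis_cpp(aif_v, step_s, p[1L], p[3L] + p[4L], p[5L] + p[6L]),
             .comp_basis_cpp(aif_v, step_s, p[2L], p[3L], p[5L]))
}

# exact nonnegative bounded least squares for 1 or 2 flow amplitudes
flows_solve <- function(M, y, fmax) {
  k <- ncol(M)
  g <- crossprod(M)
  b <- crossprod(M, y)
  clamp <- function(f) pmin(pmax(f, 0), fmax)
  if (k == 1L) return(if (g[1L] > 0) clamp(b[1L] / g[1L]) else 0)
  det <- g[1L, 1L] * g[2L, 2L] - g[1L, 2L]^2
  if (det > 1e-12 * max(g[1L, 1L] * g[2L, 2L], .Machine$double.xmin)) {
    f <- c(g[2L, 2L] * b[1L] - g[1L, 2L] * b[2L],
           g[1L, 1L] * b[2L] - g[1L, 2L] * b[1L]) / det
    if (all(f >= 0 & f <= fmax)) return(f)
  } else {
    f <- c(-1, -1)
  }
  cands <- list(
    c(if (g[1L, 1L] > 0) clamp(b[1L] / g[1L, 1L]) else 0, 0),
    c(0, if (g[2L, 2L] > 0) clamp(b[2L] / g[2L, 2L]) else 0),
    clamp(f))
  rss <- vapply(cands, function(fc) sum((y - M %*% fc)^2), 0)
  cands[[which.min(rss)]]
}

#' Fit the one- or two-compartment kinetic model to a tissue curve
#'
#' The workhorse estimator. The measured arterial and tissue curves are
#' taken on their acquired frame grid; the arterial curve is linearly
#' interpolated to the fitting grid (default 0.1 s), the model curve is
#' evaluated on that grid, and the residual sum of squares is computed at
#' the original acquired frame times inside the fit window only (the
#' interpolated samples carry no extra information and would inflate the
#' F-test degrees of freedom). Parameters are estimated by bounded
#' Levenberg-Marquardt least squares (see [dce_bounds()]) with the flows
#' profiled out exactly at every shape evaluation (variable projection)
#' and deterministic multi-starts: Latin-hypercube points, a transit-time
#' ladder, and - for the two-compartment model - seeds derived from the
#' one-compartment solution (which guarantee the nesting property
#' `rss_2C <= rss_1C`) plus a seed obtained by fitting a residue basis to
#' the one-compartment residual. The winner is polished by restarts and
#' reported in the canonical labeling (transit time >= dispersion time;
#' the two are exactly exchangeable otherwise, see the methods vignette).
#' For the two-compartment model the arteriolar delay and dispersion are
#' constrained by construction to be no larger than the capillary ones
#' (the arterioles feed the capillaries and lie closer to the measured
#' artery), via the reparameterization `delay_cap = delay_art + d1`,
#' `disp_cap = disp_art + d2` with `d1, d2 >= 0`.
#'
#' With `model = "auto"` both models are fitted and an F-test
#' ([f_test_select()]) at level `alpha` decides whether the 8-parameter
#' model earns its extra degrees of freedom; the returned fit carries the
#' selection in `$selection` and the rejected fit in `$alternative`.
#'
#' @param tissue a [time_curve()] of the tissue curve at the acquired frame
#'   interval (typically 1.5 s).
#' @param aif an [aif_estimate()] or [time_curve()] on the same time axis.
#' @param model `"auto"` (default), `"1C"`, or `"2C"`.
#' @param window_s fit window: frames with `t <= window_s` enter the rss
#'   (default the first 60 s of the acquisition).
#' @param step_s fitting grid step in seconds.
#' @param alpha F-test significance level for `model = "auto"`.
#' @param bounds parameter box from [dce_bounds()].
#' @param n_starts number of Latin-hypercube starts per model.
#' @param seed integer seed making the starts (and hence the fit) fully
#'   deterministic.
#' @return An object of class `dce_fit`; see [summary.dce_fit()],
#'   [coef.dce_fit()], [predict.dce_fit()], [perfusion_report()].
#' @export
dce_fit <- function(tissue, aif, model = c("auto", "1C", "2C"),
                    window_s = 60, step_s = 0.1, alpha = 0.05,
                    bounds = dce_bounds(), n_starts = 5L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(tissue, "time_curve"))
  aif_tc <- tc_interp(as_aif_curve(aif), step_s)
  # restrict the grid to the fit window (plus one step of headroom)
  ng <- min(length(aif_tc$value), floor(window_s / step_s) + 2L)
  aif_v <- aif_tc$value[seq_len(ng)]

  t_frames <- tc_time(tissue)
  idx_w <- which(t_frames <= window_s + 1e-9)
  y <- tissue$value[idx_w]
  tfr <- t_frames[idx_w]
  n_obs <- length(y)
  if (min(y) < -6 * stats::mad(diff(y)) / sqrt(2))
    warning("tissue curve goes substantially negative; fitting proceeds")

  gi <- tfr / step_s
  exact_grid <- all(abs(gi - round(gi)) < 1e-8) && max(round(gi)) + 1L <= ng
  gi <- round(gi) + 1L
  sample_frames <- if (exact_grid) {
    function(v) v[gi]
  } else {
    tg <- (seq_len(ng) - 1L) * step_s
    function(v) stats::approx(tg, v, xout = tfr, rule = 2)$y
  }
  sample_mat <- if (exact_grid) {
    function(B) B[gi, , drop = FALSE]
  } else {
    function(B) apply(B, 2L, sample_frames)
  }

  fit_order <- function(order, extra_starts = NULL) {
    box <- fit_box(order, bounds)
    np_full <- if (order == 1L) 4L else 8L
    if (n_obs <= np_full)
      stop(sprintf("need more than %d frames in the fit window", np_full), call. = FALSE)
    starts <- with_seed(seed, lhs::randomLHS(n_starts, length(box$lo)))
    starts <- sweep(sweep(starts, 2L, box$hi - box$lo, "*"), 2L, box$lo, "+")
    if (!is.null(extra_starts)) starts <- rbind(starts, extra_starts)
    fmax <- bounds$flow_f[2L]
    res_fun <- function(p) {
      M <- sample_mat(shape_basis(aif_v, step_s, p, order))
      as.numeric(M %*% flows_solve(M, y, fmax)) - y
    }
    best <- NULL
    start_rss <- rep(NA_real_, nrow(starts))
    for (s in seq_len(nrow(starts))) {
      fit <- tryCatch(
        lm_quiet(par = pmin(pmax(starts[s, ], box$lo), box$hi),
                           lower = box$lo, upper = box$hi, fn = res_fun,
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-10, ptol = 1e-10,
                             maxiter = 200L, maxfev = 2000L)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(fit$fvec^2)
      start_rss[s] <- rss
      if (is.null(best) || rss < best$rss - 1e-15) best <- list(fit = fit, rss = rss)
    }
    if (is.null(best))
      stop(structure(class = c("dceflow_fit_failure", "error", "condition"),
                     list(message = sprintf(
                       "all %d starts failed for the %dC model", nrow(starts), order),
                       call = sys.call())))
    # polishing restarts: once from the best start (fresh trust region) and
    # once from its canonical relabeling (transit time >= dispersion time),
    # which has identical rss but often sits in a better-conditioned region
    run_lm <- function(p0) tryCatch(
      lm_quiet(par = pmin(pmax(p0, box$lo), box$hi),
                         lower = box$lo, upper = box$hi, fn = res_fun,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-10,
                           maxiter = 200L, maxfev = 2000L)),
      error = function(e) NULL)
    canonical_shape <- function(p) {
      if (order == 1L) {
        if (p[3L] > p[1L]) p[c(3L, 2L, 1L)] else p
      } else {
        dc <- p[5L] + p[6L]
        mc <- if (dc > p[1L]) c(dc, p[1L]) else c(p[1L], dc)
        ma <- if (p[5L] > p[2L]) c(p[5L], p[2L]) else c(p[2L], p[5L])
        if (ma[2L] <= mc[2L]) c(mc[1L], ma[1L], p[3L], p[4L], ma[2L], mc[2L] - ma[2L])
        else p
      }
    }
    for (p0 in list(best$fit$par, canonical_shape(best$fit$par))) {
      polish <- run_lm(p0)
      if (!is.null(polish) && sum(polish$fvec^2) < best$rss)
        best <- list(fit = polish, rss = sum(polish$fvec^2))
    }
    p_shape <- best$fit$par
    M <- sample_mat(shape_basis(aif_v, step_s, p_shape, order))
    fl <- flows_solve(M, y, fmax)
    p <- shape_to_full(p_shape, fl, order)
    comps <- pars_to_comps(p, order)
    names(comps) <- vapply(comps, function(cp) cp$label, "")
    vb_tot <- sum(vapply(comps, function(cp) cp$vb, 0))
    if (vb_tot >= 1)
      warning(sprintf("fitted total blood volume vb = %.3g >= 1 is unphysical", vb_tot))
    if (order == 2L) {
      d <- c(abs(comps[[1L]]$mtt_t - comps[[2L]]$mtt_t),
             abs(comps[[1L]]$delay_s - comps[[2L]]$delay_s),
             abs(comps[[1L]]$dispersion_s - comps[[2L]]$dispersion_s))
      if (all(d < c(0.5, 0.05, 0.05)))
        warning("two-compartment fit is collinear: both compartments converged to the same kinetics")
    }
    grid_v <- tissue_model_values(aif_v, step_s, comps)
    structure(list(
      model_order = order,
      compartments = comps,
      par = stats::setNames(p, box$full_names),
      rss = best$rss,
      n_obs = n_obs, n_params = length(p),
      fitted_frames = sample_frames(grid_v),
      fitted_curve = time_curve(grid_v, step_s, units = aif_tc$units),
      frame_times = tfr,
      data = y,
      tissue = tissue, aif = aif,
      window_s = window_s, step_s = step_s,
      start_rss = start_rss,
      converged = best$fit$info %in% 1:4,
      seed = seed,
      call = match.call(expand.dots = FALSE)
    ), class = "dce_fit")
  }

  # seed the arteriolar compartment by fitting an exponential-residue basis
  # to the residual of the 1C fit: whatever bolus shape the one-compartment
  # model could not explain is the natural starting guess for the fast
  # second compartment.
  residual_seed <- function(f1) {
    r1 <- f1$data - f1$fitted_frames
    box1 <- fit_box(1L, bounds)
    rf <- function(p) {
      b <- sample_frames(shape_basis(aif_v, step_s, p, 1L)[, 1L])
      d <- sum(b * b)
      a <- if (d > 0) sum(b * r1) / d else 0
      a * b - r1
    }
    ft <- tryCatch(
      lm_quiet(par = c(2, 1, 0.3), lower = box1$lo, upper = box1$hi,
                         fn = rf,
                         control = minpack.lm::nls.lm.control(maxiter = 100L)),
      error = function(e) NULL)
    if (is.null(ft)) return(NULL)
    p1 <- f1$par
    dl1 <- p1[["delay_s"]]; dp1 <- p1[["dispersion_s"]]
    dla <- min(ft$par[2L], dl1); dpa <- min(ft$par[3L], dp1)
    rbind(c(p1[["mtt_t"]], ft$par[1L], dla, dl1 - dla, dpa, dp1 - dpa))
  }
  seeds_2c <- function(f1) rbind(seed_from_1c(f1), residual_seed(f1),
                                 c(12, 3.5, 1, 1, 0.3, 0.7))
  # deterministic transit-time ladder supplementing the Latin-hypercube
  # starts of the 3-parameter 1C search
  seeds_1c <- cbind(c(2, 8, 20, 45), 2, 0.3)

  if (model == "1C") return(fit_order(1L, extra_starts = seeds_1c))
  if (model == "2C") {
    f1 <- fit_order(1L, extra_starts = seeds_1c)
    return(fit_order(2L, extra_starts = seeds_2c(f1)))
  }
  f1 <- fit_order(1L, extra_starts = seeds_1c)
  f2 <- fit_order(2L, extra_starts = seeds_2c(f1))
  sel <- f_test_select(f1, f2, alpha = alpha)
  chosen <- if (sel$chosen_order == 2L) f2 else f1
  chosen$selection <- sel
  chosen$alternative <- if (sel$chosen_order == 2L) f1 else f2
  chosen
}

# shape-start vectors for the 2C fit derived from a converged 1C fit. The
# first seed reuses the 1C shape for the capillary compartment; because the
# flows are profiled out exactly, evaluating it can never do worse than the
# 1C solution (F_art = 0 is inside the profiled set), which guarantees
# rss_2C <= rss_1C. Further seeds pair a slow capillary with a fast
# arteriolar compartment at shorter delay/dispersion.
seed_from_1c <- function(f1) {
  p <- f1$par
  mtt <- p[["mtt_t"]]; dl <- p[["delay_s"]]; dp <- p[["dispersion_s"]]
  rbind(
    c(mtt, 2, 0, dl, 0.05, max(0, dp - 0.05)),
    c(max(mtt, 12), 2, dl / 2, dl / 2, max(0.05, dp / 2), dp / 2),
    c(max(mtt, 8), 1, dl / 2, dl / 2, max(0.05, dp / 2), dp / 2))
}

#' F-test selection between nested kinetic fits
#'
#' Decides whether the extra parameters of the two-compartment fit are
#' statistically justified: `F = ((rss1 - rss2) / (p2 - p1)) /
#' (rss2 / (n - p2))` referred to the F distribution with `(p2 - p1,
#' n - p2)` degrees of freedom, where `n` counts the acquired frames in the
#' fit window. The two-compartment model is chosen iff `p < alpha` and it
#' actually improved the rss; if an optimizer artifact makes `rss2 > rss1`
#' the statistic is reported as 0 and the simpler model kept.
#'
#' @param fit1,fit2 `dce_fit` objects for the nested (1C) and richer (2C)
#'   model, fitted on the same frames.
#' @param alpha significance level.
#' @return An object of class `dce_ftest`: list with `f_stat`, `p_value`,
#'   `chosen_order`, `alpha`, `df1`, `df2`.
#' @export
f_test_select <- function(fit1, fit2, alpha = 0.05) {
  stopifnot(inherits(fit1, "dce_fit"), inherits(fit2, "dce_fit"))
  if (fit1$n_obs != fit2$n_obs)
    stop("fits must share the same observations", call. = FALSE)
  if (fit2$n_params <= fit1$n_params)
    stop("'fit2' must have more parameters than 'fit1'", call. = FALSE)
  n <- fit1$n_obs; p1 <- fit1$n_params; p2 <- fit2$n_params
  if (n <= p2)
    stop(sprintf("insufficient data: n = %d <= p2 = %d", n, p2), call. = FALSE)
  df1 <- p2 - p1; df2 <- n - p2
  if (fit2$rss < fit1$rss && fit2$rss > 0) {
    f_stat <- ((fit1$rss - fit2$rss) / df1) / (fit2$rss / df2)
    p_value <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  } else if (fit2$rss == 0 && fit1$rss > 0) {
    f_stat <- Inf; p_value <- 0
  } else {
    f_stat <- 0; p_value <- 1
  }
  structure(list(f_stat = f_stat, p_value = p_value,
                 chosen_order = if (p_value < alpha && fit2$rss < fit1$rss) 2L else 1L,
                 alpha = alpha, df1 = df1, df2 = df2),
            class = "dce_ftest")
}

#' @export
print.dce_ftest <- function(x, ...) {
  cat(sprintf("F-test model selection: F(%d, %d) = %.3g, p = %.3g -> %dC model (alpha = %g)\n",
              x$df1, x$df2, x$f_stat, x$p_value, x$chosen_order, x$alpha))
  invisible(x)
}

#' Convenience wrappers for a fixed model order
#'
#' @inheritParams dce_fit
#' @param ... passed to [dce_fit()].
#' @return A `dce_fit` object.
#' @export
fit_1c <- function(tissue, aif, ...) dce_fit(tissue, aif, model = "1C", ...)

#' @rdname fit_1c
#' @export
fit_2c <- function(tissue, aif, ...) dce_fit(tissue, aif, model = "2C", ...)

#' Tabulate fitted perfusion in clinical units
#'
#' Converts the fitted compartment parameters into a per-compartment table:
#' perfusion in mL/(min 100 cm^3) (factor 6000 from 1/s), mean transit
#' time, fractional blood volume `vb = F T`, delay, and dispersion time.
#' The total perfusion is the sum over compartments.
#'
#' @param fit a `dce_fit`.
#' @return A `data.frame` with one row per compartment and attribute
#'   `total_perfusion` (mL/(min 100 cm^3)).
#' @export
perfusion_report <- function(fit) {
  stopifnot(inherits(fit, "dce_fit"))
  rows <- lapply(fit$compartments, function(cp) {
    data.frame(compartment = cp$label,
               flow_per_s = cp$flow_f,
               perfusion_ml_min_100cm3 = cp$flow_f * 6000,
               mtt_s = cp$mtt_t,
               vb = cp$vb,
               delay_s = cp$delay_s,
               dispersion_s = cp$dispersion_s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "total_perfusion") <- sum(out$perfusion_ml_min_100cm3)
  out
}
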