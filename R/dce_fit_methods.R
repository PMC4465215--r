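#' @export
print.dce_fit <- function(x, ...) {
  cat(sprintf("%d-compartment kinetic fit (%d frames, window %.0f s)\n",
              x$model_order, x$n_obs, x$window_s))
  rep <- perfusion_report(x)
  for (i in seq_len(nrow(rep)))
    cat(sprintf("  %-10s F = %6.2f mL/(min 100cm^3), T = %5.2f s, vb = %.4f, delay = %.2f s, 1/beta = %.2f s\n",
                rep$compartment[i], rep$perfusion_ml_min_100cm3[i], rep$mtt_s[i],
                rep$vb[i], rep$delay_s[i], rep$dispersion_s[i]))
  cat(sprintf("  total perfusion %.2f mL/(min 100cm^3), rss = %.4g\n",
              attr(rep, "total_perfusion"), x$rss))
  if (!is.null(x$selection)) print(x$selection)
  invisible(x)
}

#' Summarize a kinetic fit
#'
#' @param object a `dce_fit`.
#' @param ... unused.
#' @return An object of class `summary.dce_fit` carrying the per-compartment
#'   perfusion table, total perfusion, rss, residual standard deviation at
#'   the acquired frames, and the F-test selection when present.
#' @export
summary.dce_fit <- function(object, ...) {
  rep <- perfusion_report(object)
  structure(list(
    report = rep,
    total_perfusion = attr(rep, "total_perfusion"),
    model_order = object$model_order,
    rss = object$rss,
    sigma = sqrt(object$rss / (object$n_obs - object$n_params)),
    n_obs = object$n_obs, n_params = object$n_params,
    converged = object$converged,
    selection = object$selection
  ), class = "summary.dce_fit")
}

#' @export
print.summary.dce_fit <- function(x, ...) {
  cat(sprintf("%d-compartment kinetic fit: total perfusion %.2f mL/(min 100cm^3)\n",
              x$model_order, x$total_perfusion))
  print(x$report, row.names = FALSE)
  cat(sprintf("rss = %.4g on %d frames (%d parameters), residual SD = %.4g\n",
              x$rss, x$n_obs, x$n_params, x$sigma))
  if (!x$converged) cat("warning: optimizer did not report convergence\n")
  if (!is.null(x$selection)) print(x$selection)
  invisible(x)
}

#' @export
coef.dce_fit <- function(object, ...) object$par

#' @export
fitted.dce_fit <- function(object, ...) object$fitted_frames

#' @export
residuals.dce_fit <- function(object, ...) object$data - object$fitted_frames

#' Evaluate the fitted tissue model
#'
#' @param object a `dce_fit`.
#' @param times optional numeric vector of times (s); defaults to the
#'   fitting grid.
#' @param ... unused.
#' @return Numeric vector of model values.
#' @export
predict.dce_fit <- function(object, times = NULL, ...) {
  fc <- object$fitted_curve
  if (is.null(times)) return(fc$value)
  stats::approx(tc_time(fc), fc$value, xout = times, rule = 2)$y
}

#' Plot a kinetic fit
#'
#' Data frames as points, fitted model as a line, with the per-compartment
#' contributions dashed for a two-compartment fit.
#'
#' @param x a `dce_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dce_fit <- function(x, ...) {
  tt <- tc_time(x$tissue)
  graphics::plot(tt, x$tissue$value, pch = 1, cex = 0.6,
                 xlab = "time [s]",
                 ylab = sprintf("tissue curve [%s]", x$tissue$units), ...)
  ft <- tc_time(x$fitted_curve)
  graphics::lines(ft, x$fitted_curve$value, lwd = 2)
  if (x$model_order == 2L) {
    aif_tc <- tc_interp(as_aif_curve(x$aif), x$step_s)
    v <- aif_tc$value[seq_len(min(length(aif_tc$value), length(ft)))]
    for (i in seq_along(x$compartments)) {
      ci <- tissue_model_values(v, x$step_s, x$compartments[i])
      graphics::lines(ft[seq_along(ci)], ci, lty = i + 1)
    }
    graphics::legend("topleft", bty = "n", lty = c(1, 2, 3), lwd = c(2, 1, 1),
                     legend = c("total", names(x$compartments)))
  }
  graphics::abline(v = x$window_s, lty = 3, col = "grey")
  invisible(x)
}

#' Simulate noisy replicates from a fitted kinetic model
#'
#' Draws Gaussian noise around the fitted frame values, with SD defaulting
#' to the residual standard deviation of the fit.
#'
#' @param object a `dce_fit`.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param noise_sd noise SD; default the fit's residual SD.
#' @param ... unused.
#' @return A matrix with `n_obs` rows and `nsim` columns.
#' @export
simulate.dce_fit <- function(object, nsim = 1, seed = NULL, noise_sd = NULL, ...) {
  s <- summary(object)
  if (is.null(noise_sd)) noise_sd <- s$sigma
  draw <- function() object$fitted_frames +
    stats::rnorm(object$n_obs, sd = noise_sd)
  out <- if (is.null(seed)) replicate(nsim, draw())
  else with_seed(seed, replicate(nsim, draw()))
  matrix(out, ncol = nsim)
}
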