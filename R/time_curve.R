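#' Uniformly sampled time curve
#'
#' Container for a scalar time series sampled on a uniform grid, the basic
#' currency of the package: relaxation-rate-change curves (units `"s^-1"`),
#' concentration curves (`"mmol/L"`), and arterial input functions all travel
#' as `time_curve` objects.
#'
#' @param value numeric vector of samples.
#' @param step_s sampling interval in seconds (> 0).
#' @param units unit label carried along for bookkeeping; conversions are
#'   explicit (see [concentration()]).
#' @param t0 time of the first sample in seconds.
#' @return An object of class `time_curve`: a list with elements `value`,
#'   `step_s`, `units`, `t0`.
#' @seealso [tc_time()], [tc_interp()], [read_curve_csv()]
#' @export
#' @examples
#' tc <- time_curve(sin(seq(0, 2 * pi, length.out = 50)), step_s = 0.5)
#' head(tc_time(tc))
time_curve <- function(value, step_s, units = "s^-1", t0 = 0) {
  if (!is.numeric(value) || length(value) == 0L)
    stop("'value' must be a non-empty numeric vector", call. = FALSE)
  if (!is.numeric(step_s) || length(step_s) != 1L || !is.finite(step_s) || step_s <= 0)
    stop("'step_s' must be a single positive number", call. = FALSE)
  structure(
    list(value = as.numeric(value), step_s = as.numeric(step_s),
         units = as.character(units)[1L], t0 = as.numeric(t0)[1L]),
    class = "time_curve"
  )
}

#' @export
print.time_curve <- function(x, ...) {
  cat(sprintf("<time_curve> %d samples @ %.4g s, t = [%.4g, %.4g] s, units: %s\n",
              length(x$value), x$step_s, x$t0,
              x$t0 + (length(x$value) - 1L) * x$step_s, x$units))
  invisible(x)
}

#' Sample times of a time curve
#'
#' @param tc a [time_curve()].
#' @return Numeric vector of sample times in seconds.
#' @export
tc_time <- function(tc) {
  stopifnot(inherits(tc, "time_curve"))
  tc$t0 + (seq_along(tc$value) - 1L) * tc$step_s
}

#' Linear interpolation of a time curve onto a finer grid
#'
#' Curves are resampled once, by linear interpolation, onto the fitting grid
#' (default 0.1 s) before any transport correction or model fitting.
#'
#' @param tc a [time_curve()].
#' @param step_s target sampling interval in seconds.
#' @return A [time_curve()] on the new grid spanning the same support.
#' @export
tc_interp <- function(tc, step_s = 0.1) {
  stopifnot(inherits(tc, "time_curve"))
  if (isTRUE(all.equal(tc$step_s, step_s))) return(tc)
  t_old <- tc_time(tc)
  t_new <- seq(tc$t0, t_old[length(t_old)] + 1e-9, by = step_s)
  v <- stats::approx(t_old, tc$value, xout = t_new, rule = 2)$y
  time_curve(v, step_s, units = tc$units, t0 = tc$t0)
}

#' @export
as.data.frame.time_curve <- function(x, ...) {
  data.frame(time_s = tc_time(x), value = x$value, units = x$units)
}

#' Read and write time curves as CSV
#'
#' Curves are exchanged as plain CSV with columns `time_s,value,units`.
#' `read_curve_csv` checks that the time grid is uniform.
#'
#' @param tc a [time_curve()].
#' @param path file path.
#' @return `read_curve_csv` returns a [time_curve()]; `write_curve_csv`
#'   returns `path` invisibly.
#' @export
write_curve_csv <- function(tc, path) {
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("curve CSV needs columns time_s,value", call. = FALSE)
  dt <- diff(df$time_s)
  if (length(dt) == 0L || any(abs(dt - dt[1L]) > 1e-6 * dt[1L]))
    stop("curve CSV must be uniformly sampled", call. = FALSE)
  units <- if ("units" %in% names(df)) df$units[1L] else "s^-1"
  time_curve(df$value, step_s = dt[1L], units = units, t0 = df$time_s[1L])
}
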