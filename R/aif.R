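#' Arterial input function
#'
#' Container for an arterial input function (AIF): the contrast-agent
#' concentration in a feeding artery sampled on a uniform time grid, with a
#' pre-contrast baseline over which the concentration is zero. Concentration
#' units are arbitrary because the signal calibration is absorbed into the
#' kinetic parameters.
#'
#' @param times Sample times in seconds, strictly increasing with constant
#'   spacing.
#' @param values Arterial concentration at `times` (arbitrary units);
#'   finite, non-negative, and zero over the baseline.
#' @param baseline Duration of the pre-contrast baseline in seconds.
#' @return An object of class `"aif"`: a list with elements `times`,
#'   `values`, `baseline` and `dt` (the sampling interval).
#' @seealso [population_aif()], [read_aif()], [sample_aif()]
#' @export
aif <- function(times, values, baseline = 0) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 2L || length(times) != length(values))
    stop("'times' and 'values' must have equal length >= 2")
  dts <- diff(times)
  if (any(dts <= 0)) stop("'times' must be strictly increasing")
  if (diff(range(dts)) > 1e-6 * mean(dts))
    stop("AIF must be sampled on a uniform time grid")
  if (any(!is.finite(values)) || any(values < -1e-12))
    stop("AIF values must be finite and non-negative")
  if (baseline > 0 && any(values[times < baseline - 1e-9] != 0))
    stop("AIF values must be zero over the baseline")
  structure(list(times = times, values = values, baseline = baseline,
                 dt = mean(dts)),
            class = "aif")
}

#' Population arterial input function
#'
#' A smooth literature-style population AIF: after a pre-contrast baseline,
#' a bolus with exponential rise (time constant `tau_rise`) and
#' biexponential washout. The functional form is
#' `c(u) = (1 - exp(-u/tau_rise)) * (a1*exp(-u/tau1) + a2*exp(-u/tau2))`
#' with `u` the time since bolus arrival. Default constants give a
#' first-pass peak roughly 10 s after arrival followed by a slow washout,
#' in arbitrary concentration units.
#'
#' @param duration Total duration in seconds (including baseline).
#' @param dt Sampling interval in seconds.
#' @param baseline Pre-contrast baseline duration in seconds (default 15 s,
#'   padded with zeroes).
#' @param a1,tau1 Amplitude and decay time (s) of the fast washout term.
#' @param a2,tau2 Amplitude and decay time (s) of the slow washout term.
#' @param tau_rise Bolus rise time constant in seconds.
#' @return An [aif] object.
#' @examples
#' ca <- population_aif(120, dt = 0.1)
#' max(ca$values)
#' @export
population_aif <- function(duration, dt = 0.1, baseline = 15,
                           a1 = 4, tau1 = 20, a2 = 1, tau2 = 300,
                           tau_rise = 3) {
  times <- seq(0, duration, by = dt)
  u <- times - baseline
  v <- ifelse(u > 0,
              (1 - exp(-u / tau_rise)) *
                (a1 * exp(-u / tau1) + a2 * exp(-u / tau2)),
              0)
  aif(times, v, baseline = baseline)
}

#' Sample an AIF at arbitrary times
#'
#' Linear interpolation of the AIF onto a new time grid; times outside the
#' recorded range are extrapolated with the nearest recorded value.
#'
#' @param x An [aif] object.
#' @param times Times (seconds) at which to sample.
#' @return Numeric vector of concentrations at `times`.
#' @export
sample_aif <- function(x, times) {
  stopifnot(inherits(x, "aif"))
  stats::approx(x$times, x$values, xout = times, rule = 2)$y
}

#' Read / write an AIF as a two-column CSV
#'
#' The on-disk format is a CSV with a header row and two columns,
#' `time_s` and `concentration`.
#'
#' @param path Path to the CSV file.
#' @param baseline Baseline duration in seconds (reader only; defaults to
#'   the time of the last zero-concentration leading sample).
#' @return `read_aif()` returns an [aif] object; `write_aif()` returns
#'   `path` invisibly.
#' @export
read_aif <- function(path, baseline = NULL) {
  tab <- utils::read.csv(path)
  if (!all(c("time_s", "concentration") %in% names(tab)))
    stop("AIF CSV needs columns 'time_s' and 'concentration'")
  if (is.null(baseline)) {
    nz <- which(tab$concentration > 0)
    baseline <- if (length(nz) && nz[1] > 1) tab$time_s[nz[1] - 1] else 0
  }
  aif(tab$time_s, tab$concentration, baseline = baseline)
}

#' @rdname read_aif
#' @param x An [aif] object to write.
#' @export
write_aif <- function(x, path) {
  stopifnot(inherits(x, "aif"))
  utils::write.csv(data.frame(time_s = x$times, concentration = x$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.aif <- function(x, ...) {
  cat(sprintf(
    "Arterial input function: %d samples, dt = %.4g s, baseline = %.3g s, peak = %.4g\n",
    length(x$times), x$dt, x$baseline, max(x$values)))
  invisible(x)
}
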