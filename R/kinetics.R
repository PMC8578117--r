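# Tracer-kinetic forward models and per-pixel fitting for DCE-MRI
# renography. Flows are carried in the conventional mL/min/100 mL units and
# converted to 1/s internally: 1 mL/min/100 mL = 1/6000 s^-1.

#' Flow unit conversion
#'
#' Conversion factor between clinical flow units (mL/min/100 mL of tissue)
#' and the 1/s rate constants used internally:
#' 1 mL/min/100 mL = 1 mL / (60 s * 100 mL) = 1/6000 per second.
#' @keywords internal
FLOW_PER_SECOND <- 1 / 6000

#' Two-compartment filtration model parameters
#'
#' Kinetic parameters of the renal two-compartment filtration model (2CFM):
#' a plasma compartment with flow `FP` and mean transit time `TP` feeding a
#' tubular compartment at rate `FT` with mean transit time `TT`.
#'
#' @param FP Plasma flow, mL/min/100 mL.
#' @param TP Plasma mean transit time, seconds.
#' @param FT Tubular flow, mL/min/100 mL.
#' @param TT Tubular mean transit time, seconds.
#' @return An object of class `"kinetic_params_2cfm"`.
#' @details All four parameters must be non-negative. Kidney-like tissue has
#'   `TP < TT`; a violation triggers a warning, not an error.
#' @export
kinetic_params <- function(FP, TP, FT, TT) {
  p <- c(FP = FP, TP = TP, FT = FT, TT = TT)
  if (any(!is.finite(p)) || any(p < 0))
    stop("kinetic parameters must be finite and non-negative")
  if (TP >= TT)
    warning("TP >= TT: not kidney-like (plasma transit should be faster)")
  structure(as.list(p), class = "kinetic_params_2cfm")
}

#' Running time integral of a sampled series
#'
#' Cumulative trapezoid integration over time (single or double), the
#' quadrature rule used throughout the linearised model fit. The first
#' output sample is always zero.
#'
#' @param x Numeric vector, or matrix with time running down the rows
#'   (one column per pixel).
#' @param dt Uniform sampling interval in seconds.
#' @param order 1 for the running integral, 2 for the running integral of
#'   the running integral.
#' @param times Optional sample times; if supplied they must be uniformly
#'   spaced (this is checked) and `dt` is derived from them.
#' @return Object of the same shape as `x`.
#' @examples
#' cumulative_integral(rep(1, 5), dt = 1)  # 0 1 2 3 4
#' @export
cumulative_integral <- function(x, dt = NULL, order = 1, times = NULL) {
  if (!is.null(times)) {
    dts <- diff(times)
    if (length(dts) < 1 || any(dts <= 0) ||
        diff(range(dts)) > 1e-6 * mean(dts))
      stop("invalid sampling: 'times' must be uniformly spaced and increasing")
    dt <- mean(dts)
  }
  if (is.null(dt) || !is.finite(dt) || dt <= 0)
    stop("invalid sampling: 'dt' must be a positive scalar")
  if (!order %in% c(1, 2)) stop("'order' must be 1 or 2")
  ctz <- function(v) {
    n <- length(v)
    c(0, cumsum(0.5 * dt * (v[-1] + v[-n])))
  }
  f <- function(v) if (order == 1) ctz(v) else ctz(ctz(v))
  if (is.matrix(x)) apply(x, 2, f) else f(x)
}

# Biexponential impulse response of the 2CFM, on time grid t (seconds).
# Flows fp, ft already in 1/s. Handles the degenerate equal-transit-time
# limit with the t*exp(-t/T) term.
impulse_response_2cfm <- function(fp, TP, ft, TT, t) {
  if (abs(TP - TT) < 1e-8 * max(TP, TT)) {
    fp * exp(-t / TP) + (ft / TP) * t * exp(-t / TP)
  } else {
    a <- ft * TT / (TT - TP)
    (fp - a) * exp(-t / TP) + a * exp(-t / TT)
  }
}

#' Simulate tissue concentration with the two-compartment filtration model
#'
#' Forward simulation of the renal 2CFM: the tissue concentration is the
#' convolution of the arterial input function with a biexponential impulse
#' response. The plasma compartment (mean transit time `TP`) is fed by
#' `FP * ca(t)`; the tubular compartment (mean transit time `TT`) is fed at
#' rate `FT` from the plasma concentration. Implemented as a discrete
#' trapezoid convolution with the analytical impulse response, so it is
#' robust for stiff parameter combinations.
#'
#' @param params A [kinetic_params()] object.
#' @param input An [aif] object; it is resampled to the simulation grid by
#'   linear interpolation if its sampling interval differs from `dt`.
#' @param dt Simulation time step in seconds; should be well below
#'   `min(TP, TT)` for accuracy.
#' @param duration Total duration in seconds (default: span of the AIF).
#' @return Numeric vector of concentrations on `seq(0, duration, by = dt)`,
#'   with `C(0) = 0`.
#' @examples
#' ca <- population_aif(60, dt = 0.1, baseline = 5)
#' p <- kinetic_params(FP = 150, TP = 10, FT = 50, TT = 120)
#' C <- simulate_concentration_2cfm(p, ca, dt = 0.1)
#' @export
simulate_concentration_2cfm <- function(params, input, dt = 0.1,
                                        duration = NULL) {
  stopifnot(inherits(params, "kinetic_params_2cfm"), inherits(input, "aif"))
  if (params$TP <= 0 || params$TT <= 0)
    stop("TP and TT must be positive")
  if (is.null(duration)) duration <- max(input$times) - min(input$times)
  t <- seq(0, duration, by = dt)
  ca <- sample_aif(input, t + min(input$times))
  fp <- params$FP * FLOW_PER_SECOND
  ft <- params$FT * FLOW_PER_SECOND
  h <- impulse_response_2cfm(fp, params$TP, ft, params$TT, t)
  n <- length(t)
  # trapezoid-weighted discrete convolution, O(n log n) via FFT
  full <- stats::convolve(h, rev(ca), type = "open")[seq_len(n)]
  C <- dt * (full - 0.5 * h[1] * ca - 0.5 * h * ca[1])
  C[1] <- 0
  C
}

#' Convert concentrations to signal and back
#'
#' With the calibration factor absorbed into the kinetic parameters the DCE
#' signal model is simply `S = S0 + C` elementwise; `S0` may be a scalar,
#' a per-pixel map matching the spatial grid of `conc`, or an object of the
#' same shape as `conc`.
#'
#' @param S0 Pre-contrast signal (scalar, spatial map, or full stack).
#' @param conc Concentration stack (spatial dims x frames) or vector.
#' @return Signal object of the same shape as `conc`.
#' @export
concentration_to_signal <- function(S0, conc) {
  .add_s0(S0, conc, +1)
}

#' @rdname concentration_to_signal
#' @param signal Signal stack to convert back to concentration.
#' @export
signal_to_concentration <- function(S0, signal) {
  .add_s0(S0, signal, -1)
}

.add_s0 <- function(S0, x, sign) {
  if (length(S0) == 1L) return(x + sign * S0)
  dx <- dim(x)
  if (is.null(dx)) {
    if (length(S0) != length(x)) stop("shape mismatch between S0 and data")
    return(x + sign * S0)
  }
  nspace <- prod(dx[-length(dx)])
  if (length(S0) == length(x)) return(x + sign * S0)
  if (length(S0) != nspace) stop("shape mismatch between S0 and data")
  array(as.vector(x) + sign * rep(as.vector(S0), times = dx[length(dx)]),
        dim = dx)
}

# Flatten a dynamic series to a frames x pixels matrix.
series_matrix <- function(series) {
  d <- dim(series$data)
  nt <- d[length(d)]
  matrix(series$data, nrow = prod(d[-length(d)]), ncol = nt) |> t()
}

# Inverse of series_matrix for a fitted stack.
matrix_to_stack <- function(m, spatial_dim) {
  array(t(m), dim = c(spatial_dim, nrow(m)))
}

#' Pixel-by-pixel linearised two-compartment model fit
#'
#' Fits the linearised 2CFM to every pixel of a dynamic series by ordinary
#' least squares. The pre-contrast signal `S0` is the mean of the first `n0`
#' frames; the baseline-subtracted signal `y = S - S0` is regressed (without
#' intercept) on its own single and double running integrals and those of
#' the arterial input function, all computed with the cumulative trapezoid
#' rule. The fitted curves form the registration target for model-driven
#' registration. Rank-deficient pixels (e.g. a flat signal) return zero
#' coefficients and a constant target at `S0`, flagged but never an error,
#' so whole-image fitting cannot abort mid-registration.
#'
#' @param series A [dynamic_series()] object.
#' @param input An [aif] object, sampled at (or interpolated to) the frame
#'   times.
#' @param n0 Number of pre-contrast frames (default: from `series`).
#' @return Object of class `"linear_2cfm_fit"`: list with `coefficients`
#'   (4 x pixels matrix, rows `alpha1`, `alpha2`, `beta1`, `beta2`), `S0`
#'   (spatial map), `fitted` (model-predicted stack, same shape as the
#'   input data), `ok` (logical map, `FALSE` where degenerate), `dt`, `n0`.
#' @export
fit_linear_2cfm <- function(series, input, n0 = NULL) {
  stopifnot(inherits(series, "dynamic_series"), inherits(input, "aif"))
  if (is.null(n0)) n0 <- series$n0
  d <- dim(series$data)
  nt <- d[length(d)]
  if (nt < 5L) stop("need at least 5 frames to fit 4 regressors")
  if (n0 < 1L || n0 >= nt) stop("n0 must be in [1, n_frames)")
  dt <- series$frame_dt
  ca <- sample_aif(input, series$frame_times)
  ca1 <- cumulative_integral(ca, dt = dt, order = 1)
  ca2 <- cumulative_integral(ca, dt = dt, order = 2)
  Y <- series_matrix(series)
  res <- cpp_fit2cfm(Y, as.integer(n0), dt, ca1, ca2)
  spatial <- d[-length(d)]
  rownames(res$coef) <- c("alpha1", "alpha2", "beta1", "beta2")
  structure(list(coefficients = res$coef,
                 S0 = array(res$s0, dim = spatial),
                 fitted = matrix_to_stack(res$fitted, spatial),
                 ok = array(res$ok, dim = spatial),
                 dt = dt, n0 = n0, model = "linear_2cfm"),
            class = "linear_2cfm_fit")
}

#' Kinetic parameters from linearised model coefficients
#'
#' Inverts the coefficient-to-parameter mapping of the linearised 2CFM.
#' The two rate constants `1/TP` and `1/TT` are the roots of the quadratic
#' implied by `(alpha1, alpha2)`; the flows follow from `(beta1, beta2)`.
#' The convention `TP < TT` (plasma faster than tubule) fixes the branch.
#' Complex or non-positive roots yield `NA` parameters with the `ok` flag
#' cleared rather than an error. In the one-compartment limit
#' (`alpha2 = beta2 = 0`) the single transit time is returned in `TP` and
#' `TT`/`FT` are flagged absent (`NA`).
#'
#' @param coeffs Numeric vector `c(alpha1, alpha2, beta1, beta2)`, a 4 x P
#'   coefficient matrix, or a `"linear_2cfm_fit"` object.
#' @param dt Sampling interval in seconds, used to report the
#'   dimensionless discretisation quantities `eps1 = dt/TP + dt/TT` and
#'   `eps2 = dt/sqrt(TP*TT)` (attached as attribute `"epsilons"`).
#' @return A data.frame with columns `FP`, `TP`, `FT`, `TT`
#'   (mL/min/100 mL and seconds) and `ok`.
#' @export
coeffs_to_params <- function(coeffs, dt = NULL) {
  if (inherits(coeffs, "linear_2cfm_fit")) {
    if (is.null(dt)) dt <- coeffs$dt
    coeffs <- coeffs$coefficients
  }
  if (is.null(dim(coeffs))) coeffs <- matrix(coeffs, nrow = 4)
  a1 <- coeffs[1, ]; a2 <- coeffs[2, ]
  b1 <- coeffs[3, ]; b2 <- coeffs[4, ]
  P <- length(a1)
  FP <- TP <- FT <- TT <- rep(NA_real_, P)
  ok <- rep(FALSE, P)
  one_cpt <- abs(a2) < 1e-14 & abs(b2) < 1e-14
  disc <- a1^2 + 4 * a2
  # general two-compartment branch
  gen <- !one_cpt & disc >= 0
  lam_fast <- (-a1[gen] + sqrt(disc[gen])) / 2
  lam_slow <- (-a1[gen] - sqrt(disc[gen])) / 2
  good <- lam_fast > 0 & lam_slow > 0
  idx <- which(gen)[good]
  TPg <- 1 / lam_fast[good]   # faster rate = shorter transit = plasma
  TTg <- 1 / lam_slow[good]
  FPg <- b1[idx] * 6000
  FTg <- (b2[idx] - b1[idx] / TTg) * TPg * 6000
  TP[idx] <- TPg; TT[idx] <- TTg; FP[idx] <- FPg; FT[idx] <- FTg
  ok[idx] <- TRUE
  # one-compartment limit
  oc <- which(one_cpt & a1 < 0)
  TP[oc] <- -1 / a1[oc]
  FP[oc] <- b1[oc] * 6000
  ok[oc] <- TRUE
  out <- data.frame(FP = FP, TP = TP, FT = FT, TT = TT, ok = ok)
  if (!is.null(dt)) {
    attr(out, "epsilons") <- data.frame(
      eps1 = dt / TP + dt / TT,
      eps2 = dt / sqrt(TP * TT))
  }
  out
}

#' Linearised model coefficients from kinetic parameters
#'
#' Forward companion of [coeffs_to_params()]: the exact continuous-time
#' coefficients of the linearised 2CFM are
#' `alpha1 = -(1/TP + 1/TT)`, `alpha2 = -1/(TP*TT)`, `beta1 = fP`,
#' `beta2 = fP/TT + fT/TP` with the flows in 1/s.
#'
#' @param params A [kinetic_params()] object.
#' @return Named numeric vector of the four coefficients.
#' @export
params_to_coeffs <- function(params) {
  stopifnot(inherits(params, "kinetic_params_2cfm"))
  fp <- params$FP * FLOW_PER_SECOND
  ft <- params$FT * FLOW_PER_SECOND
  c(alpha1 = -(1 / params$TP + 1 / params$TT),
    alpha2 = -1 / (params$TP * params$TT),
    beta1 = fp,
    beta2 = fp / params$TT + ft / params$TP)
}

#' Pixel-by-pixel modified Tofts fit
#'
#' Fits the simplified 3-parameter modified Tofts model
#' `C = vp*ca + Ktrans * exp(-kep*t) (x) ca` to every pixel, used to probe
#' the effect of kinetic-model bias on registration. The solve is a
#' deterministic grid search: for every `kep` on a log-spaced grid the
#' `(vp, Ktrans)` pair is obtained by exact non-negative least squares and
#' the grid point with the smallest residual wins.
#'
#' @inheritParams fit_linear_2cfm
#' @param kep_grid Log-spaced grid of efflux rates (1/s).
#' @return Object of class `"tofts_fit"`: `coefficients` (3 x pixels, rows
#'   `vp`, `ktrans`, `kep`), `S0`, `fitted`, `ok`, `dt`, `n0`.
#' @export
fit_modified_tofts <- function(series, input, n0 = NULL,
                               kep_grid = 10^seq(-4, 0, length.out = 30)) {
  stopifnot(inherits(series, "dynamic_series"), inherits(input, "aif"))
  if (is.null(n0)) n0 <- series$n0
  d <- dim(series$data)
  nt <- d[length(d)]
  if (nt < 5L) stop("need at least 5 frames")
  dt <- series$frame_dt
  t_rel <- series$frame_times - series$frame_times[1]
  ca <- sample_aif(input, series$frame_times)
  n <- length(t_rel)
  B <- vapply(kep_grid, function(k) {
    h <- exp(-k * t_rel)
    full <- stats::convolve(h, rev(ca), type = "open")[seq_len(n)]
    b <- dt * (full - 0.5 * h[1] * ca - 0.5 * h * ca[1])
    b[1] <- 0
    b
  }, numeric(n))
  Y <- series_matrix(series)
  res <- cpp_fit_tofts(Y, as.integer(n0), ca, B, kep_grid)
  spatial <- d[-length(d)]
  rownames(res$coef) <- c("vp", "ktrans", "kep")
  structure(list(coefficients = res$coef,
                 S0 = array(res$s0, dim = spatial),
                 fitted = matrix_to_stack(res$fitted, spatial),
                 ok = array(res$ok, dim = spatial),
                 dt = dt, n0 = n0, model = "modified_tofts"),
            class = "tofts_fit")
}
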