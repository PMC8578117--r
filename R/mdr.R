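# Model-driven registration engine: alternating per-pixel kinetic model
# fitting and per-frame free-form-deformation fitting of the same joint
# least-squares cost, inside a multi-resolution schedule that starts with a
# control-point spacing equal to the field of view and halves it down to a
# user-defined minimum.

#' MDR configuration
#'
#' Tuning parameters of the model-driven registration optimizer.
#'
#' @param grid_spacing_min Minimum control-point spacing in pixels. The
#'   multi-resolution schedule starts at the field of view and halves the
#'   spacing while it stays at or above this value. 32 pixels is a good
#'   operating point for 2D renography-scale images; 4 for coarse 3D data.
#' @param tolerance Convergence tolerance in pixels: a frame's gradient
#'   descent stops once the accepted update changes no control point by
#'   more than this, and a resolution level stops once no frame produces a
#'   larger change. 0.3 px suits 2D clinical data; 0.2 px sharp synthetic
#'   data and 3D data.
#' @param n0 Number of pre-contrast frames used for the baseline signal
#'   (default 15; taken from the series when `NULL`).
#' @param model Signal model that generates the registration targets:
#'   `"linear_2cfm"` (linearised two-compartment filtration model, the
#'   production model) or `"modified_tofts"` (used to probe model bias).
#' @param max_line_search Maximum back-tracking trials per descent step.
#' @param max_outer Safety cap on outer (model fit + sweep) iterations per
#'   resolution level.
#' @param verbose Print per-level progress.
#' @return A list of class `"mdr_config"`.
#' @export
mdr_config <- function(grid_spacing_min = 32, tolerance = 0.3, n0 = NULL,
                       model = c("linear_2cfm", "modified_tofts"),
                       max_line_search = 20, max_outer = 50,
                       verbose = FALSE) {
  model <- match.arg(model)
  if (grid_spacing_min < 1) stop("grid_spacing_min must be >= 1 pixel")
  if (tolerance <= 0) stop("tolerance must be positive")
  structure(list(grid_spacing_min = grid_spacing_min, tolerance = tolerance,
                 n0 = n0, model = model,
                 max_line_search = as.integer(max_line_search),
                 max_outer = as.integer(max_outer), verbose = verbose),
            class = "mdr_config")
}

#' Joint registration cost
#'
#' The least-squares cost of model-driven registration:
#' `chi^2 = 1/2 * sum((S_D - Sigma)^2)` over all pixels and frames.
#'
#' @param series_deformed Deformed (motion-corrected) data array.
#' @param target Model-fitted target array of the same shape.
#' @return Scalar cost.
#' @export
mdr_cost <- function(series_deformed, target) {
  if (!identical(dim(series_deformed), dim(target)) &&
      length(series_deformed) != length(target))
    stop("shape mismatch between data and target")
  0.5 * sum((series_deformed - target)^2)
}

#' Analytical cost gradient over control points
#'
#' The partial derivatives of the joint cost with respect to the
#' control-point displacements of one frame:
#' `G_j = sum_x W_j(x) R(x) (grad S)_D(x)`, where `R` is the residual
#' between the deformed frame and its target, the sum runs over the tent
#' support of control point `j`, and `(grad S)_D` is the spatial gradient
#' of the deformed image, computed exactly from the tent-kernel interpolant
#' so that the analytical gradient matches finite differences of the cost.
#'
#' @param grid A [control_grid()].
#' @param image The source (undeformed) frame.
#' @param target The target frame from the model fit.
#' @param t Frame index into the grid.
#' @return Matrix of gradient vectors, one row per control point.
#' @export
gradient_control_points <- function(grid, image, target, t = 1) {
  stopifnot(inherits(grid, "control_grid"))
  image <- as.array(image)
  w <- cpp_warp_ffd(image, frame_disp(grid, t), as.integer(grid$ctrl_dim),
                    grid$spacing, as.integer(grid$img_dim), TRUE)
  resid <- as.vector(w$value) - as.vector(target)
  cpp_grad_ctrl(resid, w$grad, as.integer(grid$ctrl_dim), grid$spacing,
                as.integer(grid$img_dim))
}

#' Residual derivative matrix of the linearised model
#'
#' The derivative of the per-pixel residual vector with respect to the
#' deformed signal samples, for the linearised 2CFM whose target depends on
#' the data through the baseline average and the running integrals:
#' `dR = (I - alpha1*L - alpha2*L^2) (I - M0)`, where `L` is the cumulative
#' trapezoid integration matrix (including the time step) and `M0` averages
#' the first `n0` samples into every row. With `alpha = 0` and `n0 -> Inf`
#' this reduces to the identity, which is the approximation adopted by the
#' registration engine.
#'
#' @param alpha1,alpha2 Fitted coefficients of the signal-integral terms.
#' @param dt Frame interval in seconds.
#' @param n0 Number of baseline frames.
#' @param n_frames Number of frames.
#' @return An `n_frames` x `n_frames` matrix.
#' @export
residual_derivative_matrix <- function(alpha1, alpha2, dt, n0, n_frames) {
  Tn <- n_frames
  n0 <- min(n0, Tn)
  L <- matrix(0, Tn, Tn)
  for (t in 2:Tn) {
    L[t, 1:t] <- dt * c(0.5, rep(1, t - 2), 0.5)
    if (t == 2) L[t, 1:2] <- dt * c(0.5, 0.5)
  }
  M0 <- matrix(0, Tn, Tn)
  M0[, seq_len(n0)] <- 1 / n0
  (diag(Tn) - alpha1 * L - alpha2 * (L %*% L)) %*% (diag(Tn) - M0)
}

#' Generalised (moving-target) residual
#'
#' Diagnostic for the groupwise formulation of MDR: because the linearised
#' model's target is itself a function of the data, the exact cost gradient
#' replaces the residual `R(x, s)` by
#' `RR(x, s) = sum_t R(x, t) * dR[t, s]` with `dR` from
#' [residual_derivative_matrix()]. The engine itself uses the approximation
#' `dR = I` (for which `RR = R` exactly); this function quantifies what
#' that approximation neglects.
#'
#' @param residuals Residual matrix, frames x pixels.
#' @param coeffs 4 x pixels coefficient matrix from [fit_linear_2cfm()]
#'   (or a `"linear_2cfm_fit"` object).
#' @param dt Frame interval in seconds.
#' @param n0 Number of baseline frames.
#' @param identity Force `dR = I` (returns `residuals` unchanged).
#' @return Matrix of generalised residuals, frames x pixels.
#' @export
generalized_residual <- function(residuals, coeffs, dt, n0,
                                 identity = FALSE) {
  if (inherits(coeffs, "linear_2cfm_fit")) coeffs <- coeffs$coefficients
  if (is.null(dim(residuals))) residuals <- matrix(residuals, ncol = 1)
  if (identity) return(residuals)
  Tn <- nrow(residuals)
  out <- residuals
  for (p in seq_len(ncol(residuals))) {
    dR <- residual_derivative_matrix(coeffs[1, p], coeffs[2, p], dt, n0, Tn)
    out[, p] <- as.vector(residuals[, p] %*% dR)
  }
  out
}

# One frame of gradient-descent deformation fitting against a frozen
# target: back-tracking line search, preconditioned with the previous
# accepted step, expanding x2 on first-try success. Returns the updated
# displacement matrix, warped frame, per-frame cost, the largest accepted
# control-point change (pixels) and the step memory.
fit_deformation_frame_impl <- function(image, target, disp, ctrl_dim,
                                       spacing, img_dim, tolerance,
                                       step = NULL, max_line_search = 20L,
                                       max_iter = 1000L) {
  target <- as.vector(target)
  w <- cpp_warp_ffd(image, disp, ctrl_dim, spacing, img_dim, TRUE)
  cost <- 0.5 * sum((as.vector(w$value) - target)^2)
  max_change <- 0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) break
    resid <- as.vector(w$value) - target
    G <- cpp_grad_ctrl(resid, w$grad, ctrl_dim, spacing, img_dim)
    gmax <- sqrt(max(rowSums(G^2)))
    if (!is.finite(gmax) || gmax == 0) break
    if (is.null(step)) step <- 1 / gmax  # first trial moves at most 1 px
    accepted <- FALSE
    best <- NULL
    for (trial in seq_len(max_line_search)) {
      cand <- disp - step * G
      wc <- cpp_warp_ffd(image, cand, ctrl_dim, spacing, img_dim, TRUE)
      cost_c <- 0.5 * sum((as.vector(wc$value) - target)^2)
      if (is.null(best) || cost_c < best$cost) {
        if (cost_c < cost) {
          accepted <- TRUE
          best <- list(disp = cand, w = wc, cost = cost_c, step = step)
          step <- step * 2  # keep expanding while it improves
          next
        }
      }
      if (accepted) {     # expansion stopped improving: keep the best
        step <- best$step
        break
      }
      step <- step / 2    # back-track
    }
    if (!accepted) break  # line search exhausted: frame converged
    change <- best$step * gmax
    disp <- best$disp
    w <- best$w
    cost <- best$cost
    max_change <- max(max_change, change)
    if (change < tolerance) break
  }
  list(disp = disp, warped = w$value, cost = cost, max_change = max_change,
       step = step)
}

#' Deformation fit of a single frame
#'
#' Gradient descent with back-tracking line search of one frame's
#' free-form deformation against a frozen target, as used inside [mdr()].
#' The per-frame cost never increases; the search stops when the accepted
#' update changes no control point by more than the tolerance, or when the
#' line search can no longer find descent.
#'
#' @param image Source (undeformed) frame.
#' @param target Target frame (from the model fit).
#' @param grid A [control_grid()].
#' @param t Frame index.
#' @param config An [mdr_config()].
#' @param step Initial line-search step (preconditioning memory); `NULL`
#'   scales the first trial to a maximum displacement of 1 pixel.
#' @return List with the updated `grid`, the warped frame, the per-frame
#'   `cost`, the largest accepted control-point change `max_change`
#'   (pixels) and the accepted `step` for preconditioning the next search.
#' @export
fit_deformation_frame <- function(image, target, grid, t = 1,
                                  config = mdr_config(), step = NULL) {
  stopifnot(inherits(grid, "control_grid"))
  res <- fit_deformation_frame_impl(
    as.array(image), as.array(target), frame_disp(grid, t),
    as.integer(grid$ctrl_dim), grid$spacing, as.integer(grid$img_dim),
    config$tolerance, step, config$max_line_search)
  grid$disp[, , t] <- res$disp
  res$grid <- grid
  res
}

# model fit dispatcher used by the engine
fit_model_stack <- function(series, input, model, n0) {
  if (model == "linear_2cfm") fit_linear_2cfm(series, input, n0 = n0)
  else fit_modified_tofts(series, input, n0 = n0)
}

#' Model-driven registration
#'
#' Motion-corrects a dynamic contrast-enhanced series by model-driven
#' registration: per-pixel fitting of a tracer-kinetic signal model
#' provides target images, every frame is co-registered to its target by
#' free-form deformation, and the two steps alternate on the same joint
#' least-squares cost until convergence, within a multi-resolution schedule
#' whose control-point spacing starts at the field of view and halves down
#' to `grid_spacing_min`. The optimization is fully deterministic.
#'
#' @param series A [dynamic_series()].
#' @param input An [aif] object (resampled to the frame times internally).
#' @param config An [mdr_config()]; individual settings can also be passed
#'   through `...` for convenience, e.g. `mdr(s, ca, tolerance = 0.2)`.
#' @param ... Settings forwarded to [mdr_config()] when `config` is not
#'   given.
#' @return An object of class `"mdr"` with components
#'   \describe{
#'     \item{corrected}{the motion-corrected [dynamic_series()]}
#'     \item{fitted}{the final model-fitted target stack}
#'     \item{coefficients}{per-pixel model coefficients of the final fit}
#'     \item{params}{kinetic parameter maps `FP`, `TP`, `FT`, `TT`
#'       (linearised 2CFM only)}
#'     \item{grid}{the final [control_grid()] with per-frame displacements}
#'     \item{fields}{dense displacement fields, voxels x axes x frames}
#'     \item{trace}{data.frame cost trace: level, spacing, outer iteration,
#'       event, frame, chi2, max displacement change}
#'     \item{config, series, input}{the inputs, for provenance}
#'   }
#' @seealso [print.mdr()], [summary.mdr()], [coef.mdr()], [plot.mdr()]
#' @export
mdr <- function(series, input, config = NULL, ...) {
  stopifnot(inherits(series, "dynamic_series"), inherits(input, "aif"))
  if (is.null(config)) config <- mdr_config(...)
  stopifnot(inherits(config, "mdr_config"))
  n0 <- if (is.null(config$n0)) series$n0 else config$n0
  sdim <- spatial_dim(series)
  d <- length(sdim)
  nt <- n_frames(series)
  img_dim <- as.integer(sdim)

  # multi-resolution schedule: spacing = field of view, halving while the
  # largest axis spacing stays at or above the minimum
  spacings <- list(as.numeric(sdim))
  while (max(spacings[[length(spacings)]] / 2) >= config$grid_spacing_min)
    spacings[[length(spacings) + 1]] <- spacings[[length(spacings)]] / 2

  Sd <- series$data               # identity initialisation: exact copy
  work <- series                  # carries the deformed data for model fits
  grid <- control_grid(sdim, spacings[[1]], n_frames = nt)
  steps <- rep(list(NULL), nt)    # line-search preconditioning per frame
  trace <- list()
  sigma <- NULL
  frame_costs <- rep(NA_real_, nt)
  chi2 <- Inf
  iters_per_level <- integer(length(spacings))

  for (lev in seq_along(spacings)) {
    if (lev > 1) grid <- refine_grid(grid)
    steps <- rep(list(NULL), nt)  # gradient scale changes with the lattice
    converged <- FALSE
    for (outer in seq_len(config$max_outer)) {
      # step 1: model fit at fixed deformation
      work$data <- Sd
      fit <- fit_model_stack(work, input, config$model, n0)
      if (mean(!is.finite(fit$fitted)) > 0.5)
        stop("model fit failed on more than half of the pixels")
      chi2_new <- mdr_cost(Sd, fit$fitted)
      if (chi2_new <= chi2 || is.null(sigma)) {
        # accept the refit (moving-target safeguard: never let a refit
        # increase the logged cost)
        sigma <- fit$fitted
        chi2 <- chi2_new
        fm <- matrix(Sd - sigma, ncol = nt)  # pixels x frames
        frame_costs <- 0.5 * colSums(fm^2)
      }
      trace[[length(trace) + 1]] <- data.frame(
        level = lev, spacing = max(grid$spacing), outer = outer,
        event = "model_fit", frame = NA_integer_, chi2 = chi2,
        max_change = NA_real_)
      # step 2: per-frame deformation fit against the frozen target
      sweep_changes <- numeric(nt)
      for (t in seq_len(nt)) {
        res <- fit_deformation_frame_impl(
          get_frame(series, t), sigma_frame(sigma, t), frame_disp(grid, t),
          as.integer(grid$ctrl_dim), grid$spacing, img_dim,
          config$tolerance, steps[[t]], config$max_line_search)
        grid$disp[, , t] <- res$disp
        steps[[t]] <- res$step
        chi2 <- chi2 - frame_costs[t] + res$cost
        frame_costs[t] <- res$cost
        Sd <- set_frame(Sd, t, res$warped)
        sweep_changes[t] <- res$max_change
        trace[[length(trace) + 1]] <- data.frame(
          level = lev, spacing = max(grid$spacing), outer = outer,
          event = "deform", frame = t, chi2 = chi2,
          max_change = res$max_change)
      }
      iters_per_level[lev] <- outer
      if (config$verbose)
        message(sprintf(
          "level %d (spacing %.4g px) outer %d: chi2 = %.6g, max change = %.3g px",
          lev, max(grid$spacing), outer, chi2, max(sweep_changes)))
      if (all(sweep_changes <= config$tolerance)) {
        converged <- TRUE
        break
      }
    }
  }

  # final model fit on the corrected series for the reported maps
  work$data <- Sd
  final_fit <- fit_model_stack(work, input, config$model, n0)
  params <- NULL
  if (config$model == "linear_2cfm") {
    pp <- coeffs_to_params(final_fit, dt = series$frame_dt)
    params <- lapply(c(FP = "FP", TP = "TP", FT = "FT", TT = "TT"),
                     function(k) array(pp[[k]], dim = sdim))
  }
  fields <- array(0, dim = c(prod(sdim), d, nt))
  for (t in seq_len(nt)) fields[, , t] <- dense_displacement_field(grid, t)

  corrected <- series
  corrected$data <- Sd
  structure(list(corrected = corrected, fitted = final_fit$fitted,
                 coefficients = final_fit$coefficients,
                 S0 = final_fit$S0, ok = final_fit$ok, params = params,
                 grid = grid, fields = fields,
                 trace = do.call(rbind, trace),
                 iters_per_level = iters_per_level,
                 converged = converged, config = config, n0 = n0,
                 series = series, input = input, call = match.call()),
            class = "mdr")
}

sigma_frame <- function(sigma, t) {
  d <- dim(sigma)
  if (length(d) == 3L) sigma[, , t] else sigma[, , , t]
}

set_frame <- function(stack, t, frame) {
  d <- dim(stack)
  if (length(d) == 3L) stack[, , t] <- frame else stack[, , , t] <- frame
  stack
}

#' @export
print.mdr <- function(x, ...) {
  tr <- x$trace
  cat("Model-driven registration\n")
  cat(sprintf("  model: %s | levels: %d | frames: %d\n",
              x$config$model, length(x$iters_per_level),
              n_frames(x$series)))
  cat(sprintf("  chi2: %.6g -> %.6g\n", tr$chi2[1], tr$chi2[nrow(tr)]))
  dn <- sqrt(rowSums(matrix(aperm(x$fields, c(1, 3, 2)),
                            ncol = dim(x$fields)[2])^2))
  cat(sprintf("  mean |displacement|: %.3g px\n", mean(dn)))
  invisible(x)
}

#' Summarise a model-driven registration
#'
#' @param object An `"mdr"` object.
#' @param ... Unused.
#' @return A list of class `"summary.mdr"` with the cost trace endpoints,
#'   per-level iteration counts, displacement statistics and (for the
#'   linearised model) kinetic parameter map summaries.
#' @export
summary.mdr <- function(object, ...) {
  tr <- object$trace
  disp_norm <- sqrt(rowSums(matrix(aperm(object$fields, c(1, 3, 2)),
                                   ncol = dim(object$fields)[2])^2))
  out <- list(
    model = object$config$model,
    chi2_start = tr$chi2[1], chi2_end = tr$chi2[nrow(tr)],
    iters_per_level = object$iters_per_level,
    converged = object$converged,
    displacement = summary(disp_norm),
    params = if (!is.null(object$params))
      lapply(object$params, function(m) summary(as.vector(m))))
  class(out) <- "summary.mdr"
  out
}

#' @export
print.summary.mdr <- function(x, ...) {
  cat("Model-driven registration summary\n")
  cat(sprintf("  model: %s, converged: %s\n", x$model, x$converged))
  cat(sprintf("  chi2: %.6g -> %.6g\n", x$chi2_start, x$chi2_end))
  cat(sprintf("  outer iterations per level: %s\n",
              paste(x$iters_per_level, collapse = ", ")))
  cat("  displacement magnitude (px):\n")
  print(x$displacement)
  if (!is.null(x$params)) {
    cat("  kinetic parameter maps:\n")
    for (k in names(x$params)) {
      cat(sprintf("   %s: median %.4g\n", k, x$params[[k]]["Median"]))
    }
  }
  invisible(x)
}

#' @export
coef.mdr <- function(object, type = c("kinetic", "model"), ...) {
  type <- match.arg(type)
  if (type == "model" || is.null(object$params)) return(object$coefficients)
  object$params
}

#' @export
fitted.mdr <- function(object, ...) object$fitted

#' @export
residuals.mdr <- function(object, ...) object$corrected$data - object$fitted

#' Diagnostic plots for a model-driven registration
#'
#' `which = "cost"` draws the chi-squared trace across all accepted
#' updates; `which = "timecut"` draws space-time cuts of the series before
#' and after correction (vertical line through `index`).
#'
#' @param x An `"mdr"` object.
#' @param which `"cost"` or `"timecut"`.
#' @param axis,index Cut geometry for `which = "timecut"`; defaults to a
#'   vertical line through the image centre.
#' @param ... Passed to the underlying plotting functions.
#' @export
plot.mdr <- function(x, which = c("cost", "timecut"), axis = 2,
                     index = NULL, ...) {
  which <- match.arg(which)
  if (which == "cost") {
    tr <- x$trace
    graphics::plot(seq_len(nrow(tr)), tr$chi2, type = "l", log = "y",
                   xlab = "accepted update", ylab = expression(chi^2),
                   main = "MDR cost trace", ...)
    lv <- which(diff(tr$level) > 0)
    if (length(lv)) graphics::abline(v = lv + 0.5, lty = 3)
  } else {
    if (is.null(index))
      index <- floor(spatial_dim(x$series)[-axis] / 2)
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    before <- time_cut(x$series, axis = axis, index = index)
    after <- time_cut(x$corrected, axis = axis, index = index)
    graphics::image(t(before), main = "before", xlab = "frame",
                    ylab = "position", col = grDevices::gray.colors(128))
    graphics::image(t(after), main = "after MDR", xlab = "frame",
                    ylab = "position", col = grDevices::gray.colors(128))
  }
  invisible(x)
}
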