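# Kidney digital reference object (DRO): a synthetic phantom with
# ground-truth kinetic parameter maps, motion-free dynamics simulated at
# pseudo-continuous temporal resolution, rigid or non-rigid motion
# corruption applied by backward warping, and CNR-controlled Gaussian
# noise. Every random operation is seed-deterministic.

# run expr with a local, restored RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Digital reference object specification
#'
#' Describes the kidney-mimicking phantom: matrix size, frame timing,
#' region geometry with per-region kinetic parameters, motion type and
#' noise level. Defaults reproduce the reference configuration: a 135 x 135
#' matrix, 120 dynamics at 1.1 s intervals simulated at 0.1 s and
#' down-sampled, a 15 s pre-contrast baseline, two kidneys built from three
#' concentric ellipses each (cortex ring, medulla ring, pelvis core), and
#' per-region parameters spanning plasma flow 30-300 mL/min/100 mL, plasma
#' transit 6-20 s, tubular flow 40-60 mL/min/100 mL and tubular transit
#' 90-300 s.
#'
#' @param matrix Image matrix size in pixels (2 values).
#' @param n_frames Number of dynamics.
#' @param frame_dt Frame interval in seconds; must be an integer multiple
#'   of `fine_dt`.
#' @param fine_dt Pseudo-continuous simulation step in seconds.
#' @param baseline Pre-contrast baseline duration in seconds.
#' @param regions Region layout: a list of kidneys, each a list with
#'   `centre` (pixels), and for each of `cortex`, `medulla`, `pelvis` a
#'   list with elliptical semi-`axes` (pixels) and `params`
#'   ([kinetic_params()]). `NULL` builds the default two-kidney layout
#'   scaled to `matrix`.
#' @param motion `"none"`, `"rigid"` or `"nonrigid"`.
#' @param amplitude Motion amplitude in pixels (peak vertical shift for
#'   rigid motion; maximum control-point amplitude for non-rigid motion).
#' @param period Breathing period in seconds.
#' @param cnr Contrast-to-noise ratio `max(ca)/SD` of the added Gaussian
#'   noise, or `NULL`/`Inf` for noise-free data.
#' @param seed Integer seed for noise and non-rigid field generation.
#' @return A list of class `"dro_spec"`.
#' @export
dro_spec <- function(matrix = c(135, 135), n_frames = 120, frame_dt = 1.1,
                     fine_dt = 0.1, baseline = 15, regions = NULL,
                     motion = c("none", "rigid", "nonrigid"),
                     amplitude = 12, period = 4, cnr = NULL, seed = 1) {
  motion <- match.arg(motion)
  matrix <- as.integer(rep_len(matrix, 2))
  ratio <- frame_dt / fine_dt
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("frame_dt must be an integer multiple of fine_dt")
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (is.null(regions)) regions <- default_kidney_regions(matrix)
  structure(list(matrix = matrix, n_frames = as.integer(n_frames),
                 frame_dt = frame_dt, fine_dt = fine_dt,
                 baseline = baseline, regions = regions, motion = motion,
                 amplitude = amplitude, period = period, cnr = cnr,
                 seed = as.integer(seed)),
            class = "dro_spec")
}

# default geometry: two vertically oriented kidneys, three concentric
# ellipses each, scaled from the 135 x 135 reference layout; parameters at
# the endpoints/midpoints of the reference ranges
default_kidney_regions <- function(matrix) {
  sc <- matrix / 135
  kidney <- function(cx) list(
    centre = c(cx, 67 * sc[2]),
    cortex = list(axes = c(14, 24) * min(sc),
                  params = kinetic_params(FP = 300, TP = 6,
                                          FT = 60, TT = 90)),
    medulla = list(axes = c(9.5, 17) * min(sc),
                   params = kinetic_params(FP = 150, TP = 13,
                                           FT = 50, TT = 195)),
    pelvis = list(axes = c(5, 9) * min(sc),
                  params = kinetic_params(FP = 30, TP = 20,
                                          FT = 40, TT = 300)))
  list(left = kidney(44 * sc[1]), right = kidney(90 * sc[1]))
}

# label map: 0 background, then one label per (kidney, shell); errors if
# kidneys overlap
region_labels <- function(spec) {
  nx <- spec$matrix[1]; ny <- spec$matrix[2]
  x <- matrix(rep(0:(nx - 1), ny), nx, ny)
  y <- matrix(rep(0:(ny - 1), each = nx), nx, ny)
  lab <- matrix(0L, nx, ny)
  params <- list()
  li <- 0L
  outer_masks <- list()
  for (k in seq_along(spec$regions)) {
    kd <- spec$regions[[k]]
    inside <- function(axes)
      ((x - kd$centre[1]) / axes[1])^2 + ((y - kd$centre[2]) / axes[2])^2 <= 1
    shells <- list(cortex = inside(kd$cortex$axes),
                   medulla = inside(kd$medulla$axes),
                   pelvis = inside(kd$pelvis$axes))
    if (any(shells$cortex & (x < 0 | x >= nx | y < 0 | y >= ny)))
      stop("kidney region extends outside the matrix")
    outer_masks[[k]] <- shells$cortex
    masks <- list(cortex = shells$cortex & !shells$medulla,
                  medulla = shells$medulla & !shells$pelvis,
                  pelvis = shells$pelvis)
    for (nm in names(masks)) {
      li <- li + 1L
      lab[masks[[nm]]] <- li
      params[[li]] <- kd[[nm]]$params
    }
  }
  if (length(outer_masks) > 1) {
    for (i in seq_along(outer_masks)[-1])
      for (j in seq_len(i - 1))
        if (any(outer_masks[[i]] & outer_masks[[j]]))
          stop("overlapping kidneys in the region layout")
  }
  list(labels = lab, params = params)
}

#' Build the motion-free phantom
#'
#' Generates the ground-truth parameter maps and the motion-free dynamic
#' series: per-region concentrations are simulated with the 2CFM at the
#' pseudo-continuous resolution `fine_dt`, converted to signal with
#' `S0 = 1`, and block-averaged down to the frame grid (frame-centred
#' averaging over `frame_dt/fine_dt` fine samples). Background pixels stay
#' at `S0 = 1`. The arterial input function is down-sampled the same way so
#' that fitting uses an input consistent with the data.
#'
#' @param spec A [dro_spec()].
#' @param input An [aif] at the fine resolution; `NULL` uses
#'   [population_aif()] over the full duration with the spec's baseline.
#' @return An object of class `"dro"` (motion-free part): ground-truth
#'   maps, motion-free [dynamic_series()], frame-grid AIF, label map.
#' @export
build_phantom <- function(spec, input = NULL) {
  stopifnot(inherits(spec, "dro_spec"))
  duration <- spec$n_frames * spec$frame_dt
  if (is.null(input))
    input <- population_aif(duration, dt = spec$fine_dt,
                            baseline = spec$baseline)
  ratio <- as.integer(round(spec$frame_dt / spec$fine_dt))
  nfine <- spec$n_frames * ratio
  t_fine <- (seq_len(nfine) - 1) * spec$fine_dt
  ca_fine <- sample_aif(input, t_fine)
  reg <- region_labels(spec)
  # per-region fine-resolution signals, then block average to frames
  block_avg <- function(v) colMeans(matrix(v, nrow = ratio))
  frame_curves <- lapply(reg$params, function(p) {
    C <- simulate_concentration_2cfm(p, input, dt = spec$fine_dt,
                                     duration = (nfine - 1) * spec$fine_dt)
    block_avg(1 + C)
  })
  ca_frames <- block_avg(ca_fine)
  frame_times <- block_avg(t_fine)
  n0 <- max(1L, floor(spec$baseline / spec$frame_dt))
  nx <- spec$matrix[1]; ny <- spec$matrix[2]
  data <- array(1, dim = c(nx, ny, spec$n_frames))
  labv <- as.vector(reg$labels)
  for (li in seq_along(frame_curves)) {
    pix <- which(labv == li)
    for (t in seq_len(spec$n_frames))
      data[pix + (t - 1) * nx * ny] <- frame_curves[[li]][t]
  }
  truth <- lapply(c(FP = "FP", TP = "TP", FT = "FT", TT = "TT"),
                  function(k) {
                    m <- matrix(0, nx, ny)
                    for (li in seq_along(reg$params))
                      m[reg$labels == li] <- reg$params[[li]][[k]]
                    m
                  })
  truth$S0 <- matrix(1, nx, ny)
  series <- dynamic_series(data, frame_times = frame_times, n0 = n0)
  structure(list(spec = spec, input = input,
                 aif_frames = aif(frame_times, ca_frames,
                                  baseline = n0 * spec$frame_dt),
                 truth = truth, labels = reg$labels,
                 series_motion_free = series,
                 series = series, fields = NULL, moving_FP = NULL),
            class = "dro")
}

#' Rigid sinusoidal motion fields
#'
#' Uniform vertical-shift backward-warp fields
#' `shift(t) = amplitude * sin(2 pi t / period)`, zero at `t = 0`.
#'
#' @param amplitude Peak shift in pixels.
#' @param period Breathing period in seconds.
#' @param frame_times Frame times in seconds.
#' @param img_dim Spatial image dimensions.
#' @param axis Shift axis (2 = vertical/superior-inferior).
#' @return Array (voxels x axes x frames) of dense displacement fields.
#' @export
rigid_motion_fields <- function(amplitude, period, frame_times, img_dim,
                                axis = 2) {
  if (period <= 0) stop("period must be positive")
  d <- length(img_dim)
  nvox <- prod(img_dim)
  nt <- length(frame_times)
  fields <- array(0, dim = c(nvox, d, nt))
  shift <- amplitude * sin(2 * pi * frame_times / period)
  for (t in seq_len(nt)) fields[, axis, t] <- shift[t]
  fields
}

#' Synthetic smooth non-rigid motion fields
#'
#' A seeded stand-in for breathing-like non-rigid motion: displacements on
#' a coarse control lattice follow sinusoidal trajectories with random
#' per-point amplitude and phase, interpolated to dense fields by the FFD
#' model. Amplitudes are larger along the vertical (superior-inferior)
#' axis, mimicking breathing. The resulting maps are checked for
#' invertibility: the minimum grid-sampled Jacobian determinant must stay
#' positive, otherwise an error reports the offending frame.
#'
#' @param spec A [dro_spec()] (uses `matrix`, `amplitude`, `period`,
#'   `seed`).
#' @param frame_times Frame times in seconds.
#' @param n_ctrl Control points per axis of the coarse motion lattice.
#' @return Array (voxels x axes x frames) of dense displacement fields.
#' @export
synthetic_nonrigid_fields <- function(spec, frame_times,
                                      n_ctrl = 4) {
  stopifnot(inherits(spec, "dro_spec"))
  img_dim <- spec$matrix
  d <- 2L
  nt <- length(frame_times)
  spacing <- (img_dim - 1) / (n_ctrl - 1)
  grid <- control_grid(img_dim, spacing, n_frames = nt)
  nctrl <- prod(grid$ctrl_dim)
  with_seed(spec$seed, {
    amp <- cbind(stats::runif(nctrl, 0.2, 0.5),
                 stats::runif(nctrl, 0.5, 1)) * spec$amplitude
    # breathing is coherent across the organ: one global phase per axis
    # with a small per-point jitter, keeping the dense map invertible
    phase <- matrix(stats::runif(d, 0, 2 * pi), nctrl, d, byrow = TRUE) +
      matrix(stats::runif(nctrl * d, 0, 0.5), nctrl, d)
  })
  nvox <- prod(img_dim)
  fields <- array(0, dim = c(nvox, d, nt))
  for (t in seq_len(nt)) {
    ph <- 2 * pi * frame_times[t] / spec$period
    # subtract the t = 0 state so motion starts from rest
    grid$disp[, , t] <- amp * (sin(ph + phase) - sin(phase))
    fields[, , t] <- dense_displacement_field(grid, t)
    jmin <- min_jacobian(fields[, , t], img_dim)
    if (jmin <= 0)
      stop(sprintf("non-rigid field folds at frame %d (min Jacobian %.3g)",
                   t, jmin))
  }
  fields
}

# minimum forward-difference Jacobian determinant of x + disp on the grid
min_jacobian <- function(field, img_dim) {
  nx <- img_dim[1]; ny <- img_dim[2]
  ux <- matrix(field[, 1], nx, ny)
  uy <- matrix(field[, 2], nx, ny)
  dxx <- 1 + diff(ux)[, -ny, drop = FALSE]          # d(x+ux)/dx
  dyx <- t(diff(t(ux)))[-nx, , drop = FALSE]        # d(x+ux)/dy
  dxy <- diff(uy)[, -ny, drop = FALSE]
  dyy <- 1 + t(diff(t(uy)))[-nx, , drop = FALSE]
  min(dxx * dyy - dyx * dxy)
}

#' Apply motion fields to a phantom
#'
#' Warps every frame of the motion-free series with that frame's dense
#' backward-warp field, and co-deforms the ground-truth plasma-flow map
#' with the identical fields so that a motion-frozen reconstruction can be
#' compared against the matching breathing state.
#'
#' @param dro A `"dro"` object from [build_phantom()].
#' @param fields Dense displacement array (voxels x axes x frames).
#' @return The `"dro"` with `series` replaced by the corrupted series, and
#'   `fields` and per-frame `moving_FP` maps attached.
#' @export
apply_motion <- function(dro, fields) {
  stopifnot(inherits(dro, "dro"))
  sdim <- spatial_dim(dro$series_motion_free)
  nt <- n_frames(dro$series_motion_free)
  if (!all(dim(fields) == c(prod(sdim), length(sdim), nt)))
    stop("shape mismatch between fields and series")
  data <- dro$series_motion_free$data
  moving_FP <- array(0, dim = c(prod(sdim), nt))
  for (t in seq_len(nt)) {
    data <- set_frame(data, t,
                      warp_image(get_frame(dro$series_motion_free, t),
                                 fields[, , t]))
    moving_FP[, t] <- as.vector(warp_image(dro$truth$FP, fields[, , t]))
  }
  dro$series <- dro$series_motion_free
  dro$series$data <- data
  dro$fields <- fields
  dro$moving_FP <- moving_FP
  dro
}

#' Warp all ground-truth maps to one breathing state
#'
#' @param dro A `"dro"` with motion fields attached.
#' @param frame Frame index of the breathing state.
#' @return Named list of warped truth maps (`FP`, `TP`, `FT`, `TT`, `S0`).
#' @export
moving_truth_maps <- function(dro, frame) {
  stopifnot(inherits(dro, "dro"))
  if (is.null(dro$fields)) return(dro$truth)
  lapply(dro$truth, function(m) warp_image(m, dro$fields[, , frame]))
}

#' Add CNR-controlled Gaussian noise
#'
#' Adds independent Gaussian noise to every voxel of every frame with
#' standard deviation `max(ca) / cnr`, where `ca` is the arterial input
#' function — the contrast-to-noise ratio convention of the phantom.
#'
#' @param series A [dynamic_series()].
#' @param cnr Contrast-to-noise ratio; `NULL` or `Inf` returns the series
#'   unchanged.
#' @param input The [aif] defining the contrast scale.
#' @param seed Integer seed.
#' @return The noisy series.
#' @export
add_noise <- function(series, cnr, input, seed = 1) {
  stopifnot(inherits(series, "dynamic_series"))
  if (is.null(cnr) || !is.finite(cnr)) return(series)
  if (cnr <= 0) stop("cnr must be positive")
  sd <- max(input$values) / cnr
  noise <- with_seed(seed,
                     stats::rnorm(length(series$data), sd = sd))
  series$data <- series$data + array(noise, dim = dim(series$data))
  series
}

#' Build a complete digital reference object
#'
#' Convenience pipeline: [build_phantom()], then motion corruption per the
#' spec (`none`, `rigid`, or `nonrigid`), then [add_noise()]. Noise is
#' added after motion corruption.
#'
#' @inheritParams build_phantom
#' @return A `"dro"` object with `series` holding the corrupted (noisy)
#'   series, `series_motion_free` the clean phantom, `truth` the
#'   ground-truth maps, `fields` the applied motion and `moving_FP` the
#'   co-deformed plasma-flow maps.
#' @examples
#' spec <- dro_spec(matrix = c(32, 32), n_frames = 40, motion = "rigid",
#'                  amplitude = 3)
#' phantom <- build_dro(spec)
#' @export
build_dro <- function(spec, input = NULL) {
  dro <- build_phantom(spec, input)
  ft <- dro$series_motion_free$frame_times
  if (spec$motion == "rigid") {
    fields <- rigid_motion_fields(spec$amplitude, spec$period, ft,
                                  spec$matrix)
    dro <- apply_motion(dro, fields)
  } else if (spec$motion == "nonrigid") {
    fields <- synthetic_nonrigid_fields(spec, ft)
    dro <- apply_motion(dro, fields)
  }
  dro$series <- add_noise(dro$series, spec$cnr, dro$input, seed = spec$seed)
  dro
}

#' @export
print.dro <- function(x, ...) {
  cat(sprintf(
    "Kidney DRO: %s matrix, %d frames at %.3g s, motion = %s%s\n",
    paste(x$spec$matrix, collapse = " x "), x$spec$n_frames,
    x$spec$frame_dt, x$spec$motion,
    if (is.null(x$spec$cnr)) ", noise-free"
    else sprintf(", CNR = %g", x$spec$cnr)))
  invisible(x)
}

#' Kidney mask of the phantom
#'
#' @param dro A `"dro"` object.
#' @return Logical matrix: `TRUE` inside either kidney.
#' @export
kidney_mask <- function(dro) {
  stopifnot(inherits(dro, "dro"))
  dro$labels > 0
}

#' Select the ground-truth breathing state
#'
#' A motion-frozen reconstruction is not wrong just because it froze the
#' anatomy in a breathing state different from the static truth. This
#' selector returns the frame whose co-deformed ground-truth plasma-flow
#' map is closest (in sum of squared differences) to the reconstructed
#' plasma-flow map; ties go to the earliest frame.
#'
#' @param recon_FP Reconstructed plasma-flow map.
#' @param moving_FP Per-frame moving truth maps: a (voxels x frames)
#'   matrix, or a `"dro"` object with motion applied.
#' @return List with `frame` (index) and `ssd` (per-frame sums of squared
#'   differences).
#' @export
select_reference_state <- function(recon_FP, moving_FP) {
  if (inherits(moving_FP, "dro")) {
    if (is.null(moving_FP$moving_FP)) {
      nt <- n_frames(moving_FP$series_motion_free)
      moving_FP <- matrix(as.vector(moving_FP$truth$FP), ncol = nt,
                          nrow = length(moving_FP$truth$FP))
    } else moving_FP <- moving_FP$moving_FP
  }
  r <- as.vector(recon_FP)
  if (length(r) != nrow(moving_FP)) stop("map sizes do not match")
  good <- is.finite(r)  # degenerate pixels carry no information
  ssd <- colSums((moving_FP[good, , drop = FALSE] - r[good])^2)
  list(frame = which.min(ssd), ssd = ssd)
}
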