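#' Dynamic image series
#'
#' Container for a 2D or 3D image stack over acquisition times: the object
#' being motion-corrected. Data are stored as a numeric array with spatial
#' axes first and time last, i.e. (x, y[, z], t).
#'
#' @param data Numeric array (x, y\[, z\], t) with at least 2 frames and all
#'   spatial dimensions >= 2.
#' @param voxel_dims Voxel size in mm per spatial axis (recycled).
#' @param frame_times Frame acquisition times in seconds, uniformly spaced;
#'   alternatively give `frame_dt`.
#' @param frame_dt Uniform frame interval in seconds (used when
#'   `frame_times` is missing; times start at `frame_dt/2`).
#' @param n0 Number of pre-contrast (baseline) frames; must satisfy
#'   `1 <= n0 < n_frames`. Around 10-20 frames is typical for renography.
#' @return Object of class `"dynamic_series"`.
#' @export
dynamic_series <- function(data, voxel_dims = 1, frame_times = NULL,
                           frame_dt = NULL, n0 = 15) {
  data <- as.array(data)
  d <- dim(data)
  if (length(d) < 3L || length(d) > 4L)
    stop("data must be a 3- or 4-dimensional array: (x, y[, z], t)")
  nt <- d[length(d)]
  sdim <- d[-length(d)]
  if (nt < 2L) stop("need at least 2 frames")
  if (any(sdim < 2L)) stop("all spatial dimensions must be >= 2")
  if (is.null(frame_times)) {
    if (is.null(frame_dt)) stop("give either frame_times or frame_dt")
    frame_times <- (seq_len(nt) - 0.5) * frame_dt
  } else {
    if (length(frame_times) != nt) stop("frame_times length mismatch")
    dts <- diff(frame_times)
    if (any(dts <= 0) || diff(range(dts)) > 1e-6 * mean(dts))
      stop("frame_times must be uniformly spaced and increasing")
    frame_dt <- mean(dts)
  }
  n0 <- as.integer(n0)
  if (n0 < 1L || n0 >= nt) stop("n0 must satisfy 1 <= n0 < n_frames")
  voxel_dims <- rep_len(as.numeric(voxel_dims), length(sdim))
  structure(list(data = data, voxel_dims = voxel_dims,
                 frame_times = frame_times, frame_dt = frame_dt, n0 = n0),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Dynamic series: %s voxels x %d frames (dt = %.4g s, n0 = %d baseline frames)\n",
    paste(d[-length(d)], collapse = " x "), d[length(d)], x$frame_dt, x$n0))
  invisible(x)
}

# spatial dimensions of a series
spatial_dim <- function(series) {
  d <- dim(series$data)
  d[-length(d)]
}

n_frames <- function(series) {
  d <- dim(series$data)
  d[length(d)]
}

get_frame <- function(series, t) {
  d <- dim(series$data)
  if (length(d) == 3L) series$data[, , t] else series$data[, , , t]
}
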