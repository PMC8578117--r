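# Free-form deformation model: control-point lattices with linear (tent)
# interpolation, backward image warping, grid refinement and image
# gradients. Coordinates are voxel-centre, 0-based, in pixel units; a
# deformation maps corrected-frame coordinates to source-frame coordinates
# (backward warping). Out-of-bounds source samples are clamped to the edge
# so that large shifts do not inject zeros into the kinetic fit.

#' Free-form deformation control grid
#'
#' A rectangular lattice of control points covering the image domain, with
#' one displacement vector per control point per frame. The lattice starts
#' at the image corner (coordinate 0) with the given spacing; the last
#' control point lies on or beyond the opposite corner. Displacements are
#' stored relative to the control-point positions, so a zero array is the
#' identity deformation.
#'
#' @param img_dim Integer spatial image dimensions (2 or 3 values).
#' @param spacing Control-point spacing in pixels per axis (recycled;
#'   anisotropic spacing is allowed).
#' @param n_frames Number of frames the grid carries displacements for.
#' @return Object of class `"control_grid"`: list with `img_dim`,
#'   `spacing`, `ctrl_dim` (lattice size per axis), and `disp`, an array
#'   of dimension (n_control_points, n_axes, n_frames) initialised to zero.
#' @export
control_grid <- function(img_dim, spacing, n_frames = 1) {
  img_dim <- as.integer(img_dim)
  d <- length(img_dim)
  if (!d %in% 2:3) stop("img_dim must have 2 or 3 axes")
  spacing <- rep_len(as.numeric(spacing), d)
  if (any(spacing < 1)) stop("control-point spacing must be >= 1 pixel")
  ctrl_dim <- as.integer(ceiling((img_dim - 1) / spacing) + 1)
  nctrl <- prod(ctrl_dim)
  structure(list(img_dim = img_dim, spacing = spacing, ctrl_dim = ctrl_dim,
                 disp = array(0, dim = c(nctrl, d, n_frames))),
            class = "control_grid")
}

#' @export
print.control_grid <- function(x, ...) {
  cat(sprintf(
    "FFD control grid: %s points, spacing %s px, %d frame(s)\n",
    paste(x$ctrl_dim, collapse = " x "),
    paste(signif(x$spacing, 4), collapse = " x "),
    dim(x$disp)[3]))
  invisible(x)
}

# control-point lattice coordinates (pixels), one row per point, matching
# the column-major storage order of disp
control_points <- function(grid) {
  axes <- lapply(seq_along(grid$ctrl_dim), function(a)
    (seq_len(grid$ctrl_dim[a]) - 1) * grid$spacing[a])
  as.matrix(expand.grid(axes))
}

#' Tent (linear interpolation) weight
#'
#' The separable linear kernel of the FFD model: `w(u) = 1 - |u|` for
#' `|u| <= 1` and zero otherwise, multiplied across axes. Inside the
#' lattice the weights over the `2^d` enclosing control points sum to one.
#'
#' @param u Dimensionless per-axis offsets: a vector (one point) or a
#'   matrix with one row per point and one column per axis.
#' @return Numeric vector of weights in `[0, 1]`.
#' @export
tent_weight <- function(u) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  w <- matrix(pmax(0, 1 - abs(u)), nrow = nrow(u))
  apply(w, 1, prod)
}

#' Interpolate control-point displacements at arbitrary points
#'
#' Evaluates the piecewise-linear deformation field at the given points for
#' one frame. Points outside the lattice hull are clamped to it and flagged
#' via the `"clamped"` attribute of the result.
#'
#' @param grid A [control_grid()].
#' @param x Point coordinates in pixels: vector (one point) or matrix with
#'   one row per point.
#' @param t Frame index.
#' @return Matrix of displacement vectors (one row per point), with a
#'   logical `"clamped"` attribute marking points outside the hull.
#' @export
interpolate_displacement <- function(grid, x, t = 1) {
  stopifnot(inherits(grid, "control_grid"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  d <- length(grid$ctrl_dim)
  if (ncol(x) != d) stop("points must have one column per image axis")
  npts <- nrow(x)
  i0 <- matrix(0L, npts, d)
  fr <- matrix(0, npts, d)
  clamped <- rep(FALSE, npts)
  for (a in seq_len(d)) {
    v <- x[, a] / grid$spacing[a]
    m <- grid$ctrl_dim[a]
    clamped <- clamped | v < 0 | v > m - 1
    v <- pmin(pmax(v, 0), m - 1)
    i <- pmin(floor(v), m - 2)
    i0[, a] <- as.integer(i)
    fr[, a] <- v - i
  }
  stride <- cumprod(c(1, grid$ctrl_dim[-d]))
  disp <- grid$disp[, , t, drop = FALSE]
  out <- matrix(0, npts, d)
  for (corner in 0:(2^d - 1)) {
    bits <- bitwAnd(corner, 2^(seq_len(d) - 1)) > 0
    w <- rep(1, npts)
    idx <- rep(1L, npts)
    for (a in seq_len(d)) {
      w <- w * if (bits[a]) fr[, a] else 1 - fr[, a]
      idx <- idx + (i0[, a] + as.integer(bits[a])) * stride[a]
    }
    for (a in seq_len(d)) out[, a] <- out[, a] + w * disp[idx, a, 1]
  }
  attr(out, "clamped") <- clamped
  out
}

#' Dense displacement field of a control grid
#'
#' The deformation field evaluated at every voxel centre for one frame.
#'
#' @inheritParams interpolate_displacement
#' @return Matrix with one row per voxel (column-major, x fastest) and one
#'   column per axis.
#' @export
dense_displacement_field <- function(grid, t = 1) {
  stopifnot(inherits(grid, "control_grid"))
  cpp_ffd_dense(frame_disp(grid, t), as.integer(grid$ctrl_dim),
                grid$spacing, as.integer(grid$img_dim))
}

#' Backward-warp an image with a control grid
#'
#' Samples the source image at the deformed coordinates `x + D(x, t)` using
#' the same tent-kernel interpolation between voxel centres as the
#' deformation model itself. Out-of-bounds source coordinates are clamped
#' to the image edge.
#'
#' @param image Numeric 2D or 3D array (one frame).
#' @param grid A [control_grid()] covering the image.
#' @param t Frame index into the grid's displacements.
#' @return Warped image of the same dimensions.
#' @export
deform_image <- function(image, grid, t = 1) {
  stopifnot(inherits(grid, "control_grid"))
  image <- as.array(image)
  if (!identical(as.integer(dim(image)), grid$img_dim))
    stop("image dimensions do not match the control grid")
  res <- cpp_warp_ffd(image, frame_disp(grid, t),
                      as.integer(grid$ctrl_dim), grid$spacing,
                      as.integer(grid$img_dim), FALSE)
  res$value
}

# displacement matrix (nctrl x d) of one frame
frame_disp <- function(grid, t) {
  d <- length(grid$ctrl_dim)
  matrix(grid$disp[, , t], ncol = d)
}

#' Backward-warp an image with a dense displacement field
#'
#' Like [deform_image()] but with a free per-voxel displacement field,
#' e.g. the synthetic motion fields of the digital reference object.
#'
#' @param image Numeric 2D or 3D array.
#' @param field Dense displacement matrix (voxels x axes), as returned by
#'   [dense_displacement_field()].
#' @return Warped image of the same dimensions.
#' @export
warp_image <- function(image, field) {
  image <- as.array(image)
  res <- cpp_warp_dense(image, field, as.integer(dim(image)), FALSE)
  res$value
}

#' Refine a control grid to half the spacing
#'
#' Builds the lattice at spacing `spacing/2` and samples the new control
#' displacements from the existing piecewise-linear field. Because the new
#' lattice nodes sit at the old nodes and their midpoints, the dense
#' deformation field is reproduced exactly.
#'
#' @param grid A [control_grid()] with spacing >= 2 pixels on every axis.
#' @return A refined `control_grid` representing the identical dense field.
#' @export
refine_grid <- function(grid) {
  stopifnot(inherits(grid, "control_grid"))
  if (any(grid$spacing < 2))
    stop("refusing to refine: spacing would fall below 1 pixel")
  nt <- dim(grid$disp)[3]
  out <- control_grid(grid$img_dim, grid$spacing / 2, n_frames = nt)
  pts <- control_points(out)
  for (t in seq_len(nt)) {
    out$disp[, , t] <- interpolate_displacement(grid, pts, t)
  }
  out
}

#' Spatial image gradient
#'
#' Finite-difference gradient of a single frame: central differences in the
#' interior, one-sided at the borders, in intensity units per pixel.
#'
#' @param image Numeric 2D or 3D array with at least 2 voxels per axis.
#' @param voxel_dims Voxel size per axis (accepted for interface
#'   completeness; the gradient is returned per pixel as used by the
#'   registration, which works in pixel coordinates).
#' @return Array of dimension `c(dim(image), n_axes)`.
#' @export
image_gradient <- function(image, voxel_dims = 1) {
  image <- as.array(image)
  dm <- dim(image)
  d <- length(dm)
  if (any(dm < 2)) stop("need at least 2 voxels per axis")
  out <- array(0, dim = c(dm, d))
  idx <- function(a, i) {
    ix <- rep(list(quote(expr = )), d)
    ix[[a]] <- i
    ix
  }
  for (a in seq_len(d)) {
    n <- dm[a]
    ga <- array(0, dim = dm)
    hi <- do.call(`[`, c(list(image), idx(a, c(2:n, n))))
    lo <- do.call(`[`, c(list(image), idx(a, c(1, 1:(n - 1)))))
    den <- array(2, dim = dm)
    den <- do.call(`[<-`, c(list(den), idx(a, c(1, n)), list(1)))
    ga <- (hi - lo) / den
    ix <- rep(list(quote(expr = )), d + 1)
    ix[[d + 1]] <- a
    out <- do.call(`[<-`, c(list(out), ix, list(ga)))
  }
  out
}
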