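# Registration-accuracy metrics: percent-error maps against ground truth,
# bias/precision summaries, Hausdorff distance between binary masks, and
# space-time cuts for visual motion assessment.

#' Percent-error map
#'
#' Pixelwise percent error of a reconstructed parameter map against the
#' ground truth, normalised by the maximum of the truth map over the whole
#' field: `E = (recon - truth) / max(truth) * 100`.
#'
#' @param recon Reconstructed map.
#' @param truth Ground-truth map of the same shape with a positive maximum.
#' @param mask Optional logical mask restricting later summaries; attached
#'   as the `"mask"` attribute.
#' @return Percent-error array of the same shape, class `"error_map"`.
#' @export
percent_error <- function(recon, truth, mask = NULL) {
  if (length(recon) != length(truth)) stop("map sizes do not match")
  mx <- max(truth, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0)
    stop("ground-truth map must have a positive maximum")
  e <- (recon - truth) / mx * 100
  if (!is.null(mask)) {
    if (length(mask) != length(e)) stop("mask size does not match")
    attr(e, "mask") <- as.logical(mask)
  }
  class(e) <- c("error_map", class(e))
  e
}

#' Bias and precision of an error map
#'
#' Bias is the median percent error across evaluated pixels; precision is
#' the width of the equal-tailed 90% confidence interval (95th minus 5th
#' percentile, linear-interpolation percentile rule).
#'
#' @param error An error map from [percent_error()] (or any numeric
#'   vector/array of percent errors).
#' @param mask Optional logical mask of pixels to evaluate (defaults to
#'   the map's own mask attribute, else all pixels). At least 10 pixels
#'   are required.
#' @return List with `bias` and `precision` (both percent).
#' @export
bias_precision <- function(error, mask = NULL) {
  if (is.null(mask)) mask <- attr(error, "mask")
  e <- as.vector(error)
  if (!is.null(mask)) e <- e[as.logical(mask)]
  e <- e[is.finite(e)]
  if (length(e) < 10) stop("need at least 10 evaluated pixels")
  q <- stats::quantile(e, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  list(bias = q[2], precision = q[3] - q[1])
}

# boundary voxels: mask minus its erosion (face-connected neighbourhood)
mask_boundary <- function(mask) {
  mask <- as.array(mask) > 0
  dm <- dim(mask)
  d <- length(dm)
  er <- mask
  for (a in seq_len(d)) {
    ix <- function(i) {
      l <- rep(list(quote(expr = )), d)
      l[[a]] <- i
      l
    }
    n <- dm[a]
    up <- do.call(`[`, c(list(mask), ix(c(2:n, n))))
    dn <- do.call(`[`, c(list(mask), ix(c(1, 1:(n - 1)))))
    # voxels on the array border count as boundary
    edge <- array(FALSE, dm)
    edge <- do.call(`[<-`, c(list(edge), ix(c(1, n)), list(TRUE)))
    er <- er & up & dn & !edge
  }
  mask & !er
}

#' Hausdorff distance between binary masks
#'
#' The classical symmetric Hausdorff distance in voxel units: the maximum
#' over both masks of the distance from a boundary voxel to the nearest
#' boundary voxel of the other mask (Euclidean, on voxel indices).
#' Boundaries are extracted by morphological erosion.
#'
#' @param a,b Binary masks (logical or 0/1 arrays) of identical shape,
#'   both non-empty.
#' @return Hausdorff distance in voxels.
#' @export
hausdorff_distance <- function(a, b) {
  a <- as.array(a) > 0
  b <- as.array(b) > 0
  if (!identical(dim(a), dim(b))) stop("masks must share a grid")
  if (!any(a) || !any(b)) stop("masks must be non-empty")
  pa <- which(mask_boundary(a), arr.ind = TRUE)
  pb <- which(mask_boundary(b), arr.ind = TRUE)
  directed <- function(p, q) {
    # max over p of min over q of Euclidean distance
    mx <- 0
    for (i in seq_len(nrow(p))) {
      dmin <- min(sqrt(rowSums((q - matrix(p[i, ], nrow(q), ncol(q),
                                           byrow = TRUE))^2)))
      if (dmin > mx) mx <- dmin
    }
    mx
  }
  max(directed(pa, pb), directed(pb, pa))
}

#' Space-time cut of a dynamic series
#'
#' Extracts the 1D spatial line along `axis` through the given fixed
#' `index` on the remaining spatial axes, at every frame, stacked into a
#' (space x time) image — the standard visual check for residual motion.
#'
#' @param series A [dynamic_series()].
#' @param axis Spatial axis retained in the cut (e.g. 2 for the vertical /
#'   superior-inferior direction of a 2D coronal series).
#' @param index Position(s) on the other spatial axis(es), in order, 1-based.
#' @return Matrix (positions along `axis` x frames).
#' @export
time_cut <- function(series, axis = 2, index = NULL) {
  stopifnot(inherits(series, "dynamic_series"))
  sdim <- spatial_dim(series)
  d <- length(sdim)
  if (!axis %in% seq_len(d)) stop("axis out of range")
  others <- setdiff(seq_len(d), axis)
  if (is.null(index)) index <- floor(sdim[others] / 2)
  if (length(index) != length(others)) stop("need one index per other axis")
  if (any(index < 1 | index > sdim[others])) stop("index out of range")
  args <- rep(list(quote(expr = )), d + 1)
  for (i in seq_along(others)) args[[others[i]]] <- index[i]
  out <- do.call(`[`, c(list(series$data), args))
  matrix(out, nrow = sdim[axis])
}
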