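# Standard-format readers and writers: NIfTI for image stacks, parameter
# maps and deformation fields (float32 on disk, float64 in computation),
# CSV for the AIF and the cost trace, JSON for sidecars and run manifests,
# YAML for run configuration.

#' Read a dynamic series from NIfTI
#'
#' Reads a 3- or 4-dimensional NIfTI file as a [dynamic_series()]. The
#' last dimension is time; a 3-dimensional file is interpreted as a 2D
#' series over time. Frame timing is taken from the time-axis pixdim when
#' present, otherwise `frame_dt` is required. With `slicewise = TRUE` a
#' 4-dimensional (x, y, z, t) file is split into one 2D series per slice,
#' the convention for multi-slice 2D acquisitions registered slice by
#' slice.
#'
#' @param path NIfTI file path.
#' @param frame_dt Frame interval in seconds (overrides/supplies timing).
#' @param n0 Number of pre-contrast frames.
#' @param slicewise Split a 4D file into per-slice 2D series.
#' @return A [dynamic_series()], or a list of them when `slicewise`.
#' @export
read_series <- function(path, frame_dt = NULL, n0 = 15, slicewise = FALSE) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) < 3 || length(dm) > 4)
    stop("expected a NIfTI file with 3 or 4 dimensions: (x, y[, z], t)")
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  if (is.null(frame_dt)) {
    td <- if (length(pd) >= length(dm)) pd[length(dm)] else 0
    if (!is.finite(td) || td <= 0)
      stop("no frame timing in the header: supply frame_dt")
    frame_dt <- td
  }
  vox <- pd[seq_len(length(dm) - 1)]
  vox[!is.finite(vox) | vox <= 0] <- 1
  data <- array(as.numeric(img), dim = dm)
  if (slicewise && length(dm) == 4) {
    return(lapply(seq_len(dm[3]), function(z)
      dynamic_series(data[, , z, ], voxel_dims = vox[1:2],
                     frame_dt = frame_dt, n0 = n0)))
  }
  dynamic_series(data, voxel_dims = vox, frame_dt = frame_dt, n0 = n0)
}

#' Write a dynamic series (or any image array) to NIfTI
#'
#' Data are stored as float32; voxel dimensions and the frame interval go
#' into the header pixdims.
#'
#' @param x A [dynamic_series()] or a numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_dims,frame_dt Header geometry when `x` is a plain array.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path, voxel_dims = 1, frame_dt = 1) {
  if (inherits(x, "dynamic_series")) {
    data <- x$data
    voxel_dims <- x$voxel_dims
    frame_dt <- x$frame_dt
  } else data <- as.array(x)
  nd <- length(dim(data))
  attr(data, "pixdim") <- c(rep_len(voxel_dims, nd - 1), frame_dt)
  RNifti::writeNifti(data, path, datatype = "float")
  invisible(path)
}

#' Write the complete result of a model-driven registration
#'
#' Writes, with deterministic file names under `dir`: the corrected series
#' (`corrected.nii.gz`), one NIfTI per kinetic parameter map
#' (`map_FP.nii.gz`, ...), the deformation fields as a single NIfTI stack
#' (`fields.nii.gz`, dimensions x, y\[, z\], axis, frame) with a JSON
#' sidecar describing the control grid (`fields.json`), the cost trace
#' (`cost_trace.csv`) and a run manifest (`manifest.json`) echoing the
#' configuration after default filling.
#'
#' @param result An `"mdr"` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_mdr_result <- function(result, dir) {
  stopifnot(inherits(result, "mdr"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  p <- file.path(dir, "corrected.nii.gz")
  write_series(result$corrected, p)
  paths["corrected"] <- p
  if (!is.null(result$params)) {
    for (k in names(result$params)) {
      p <- file.path(dir, sprintf("map_%s.nii.gz", k))
      m <- result$params[[k]]
      m[!is.finite(m)] <- 0
      write_series(m, p, voxel_dims = result$series$voxel_dims,
                   frame_dt = result$series$frame_dt)
      paths[paste0("map_", k)] <- p
    }
  }
  sdim <- spatial_dim(result$series)
  fields <- array(result$fields, dim = c(sdim, dim(result$fields)[2:3]))
  p <- file.path(dir, "fields.nii.gz")
  write_series(fields, p, voxel_dims = result$series$voxel_dims,
               frame_dt = result$series$frame_dt)
  paths["fields"] <- p
  p <- file.path(dir, "fields.json")
  jsonlite::write_json(list(spacing = result$grid$spacing,
                            ctrl_dim = result$grid$ctrl_dim,
                            origin = rep(0, length(sdim)),
                            units = "pixels",
                            convention = "backward_warp_displacement"),
                       p, auto_unbox = FALSE, digits = NA)
  paths["fields_json"] <- p
  p <- file.path(dir, "cost_trace.csv")
  utils::write.csv(result$trace, p, row.names = FALSE)
  paths["cost_trace"] <- p
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(run_manifest(result), p, auto_unbox = TRUE,
                       digits = NA)
  paths["manifest"] <- p
  invisible(paths)
}

#' Run manifest of a registration
#'
#' A reproducibility record: package version, timestamp, the full
#' configuration after default filling, data dimensions and per-level
#' iteration counts.
#'
#' @param result An `"mdr"` object.
#' @return A named list (serialisable to JSON).
#' @export
run_manifest <- function(result) {
  stopifnot(inherits(result, "mdr"))
  cfg <- unclass(result$config)
  cfg$n0 <- result$n0
  list(package = "mdreg",
       version = as.character(utils::packageVersion("mdreg")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config = cfg,
       data_dim = dim(result$series$data),
       frame_dt = result$series$frame_dt,
       iters_per_level = result$iters_per_level,
       converged = result$converged,
       chi2_final = result$trace$chi2[nrow(result$trace)])
}

#' Read / write an MDR run configuration as YAML
#'
#' The YAML schema mirrors the [mdr_config()] arguments; unknown keys are
#' rejected so that typos fail loudly.
#'
#' @param path YAML file path.
#' @return `read_mdr_config()` returns an [mdr_config()].
#' @export
read_mdr_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("grid_spacing_min", "tolerance", "n0", "model",
             "max_line_search", "max_outer", "verbose")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(mdr_config, y)
}

#' @rdname read_mdr_config
#' @param config An [mdr_config()] to write.
#' @export
write_mdr_config <- function(config, path) {
  stopifnot(inherits(config, "mdr_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
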