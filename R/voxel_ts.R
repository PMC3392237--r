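#' Masked voxel-by-frame BOLD time-series container
#'
#' Bundles an in-mask voxel x frame matrix with the grid geometry needed by
#' the rest of the pipeline: 0-based integer voxel coordinates, the
#' voxel-to-world affine, the frame interval (TR) and run boundaries.
#' Rows follow mask scan order (x fastest), and every downstream
#' voxel-indexed vector or matrix uses this ordering.
#'
#' @param values numeric matrix, n_voxels x n_frames, BOLD arbitrary units
#'   (conventionally mode-1000 normalized).
#' @param coords integer matrix, n_voxels x 3, 0-based grid coordinates.
#'   Must be unique per voxel.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to world
#'   mm coordinates. Defaults to an identity grid with `voxel_size` mm
#'   spacing.
#' @param frame_interval frame spacing (TR) in seconds.
#' @param run_boundaries integer vector of 0-based frame indices at which
#'   each run starts; first element must be 0.
#' @param voxel_size isotropic voxel edge in mm, used only for the default
#'   affine.
#'
#' @return An object of class `voxel_ts`.
#' @export
voxel_ts <- function(values, coords, affine = NULL, frame_interval = 2.16,
                     run_boundaries = 0L, voxel_size = 4) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' must be finite with no missing entries")
  if (ncol(values) < 2L)
    stop("need at least 2 frames")
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(values) || ncol(coords) != 3L)
    stop("'coords' must be an n_voxels x 3 matrix")
  storage.mode(coords) <- "integer"
  if (anyDuplicated(apply(coords, 1L, paste, collapse = ",")))
    stop("voxel coordinates must be unique")
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size, 3), 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  run_boundaries <- sort(unique(as.integer(run_boundaries)))
  if (length(run_boundaries) == 0L || run_boundaries[1L] != 0L)
    stop("'run_boundaries' must start at frame 0")
  if (any(run_boundaries < 0L) || any(run_boundaries >= ncol(values)))
    stop("run boundaries out of frame range")
  structure(
    list(values = values, coords = coords, affine = affine,
         frame_interval = frame_interval, run_boundaries = run_boundaries),
    class = "voxel_ts")
}

#' @export
print.voxel_ts <- function(x, ...) {
  cat("Voxel time series:", nrow(x$values), "voxels x", ncol(x$values),
      "frames\n")
  cat("  frame interval:", x$frame_interval, "s;",
      length(x$run_boundaries), "run(s)\n")
  cat("  value range: [", format(min(x$values), digits = 5), ", ",
      format(max(x$values), digits = 5), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.voxel_ts <- function(x) dim(x$values)

n_frames <- function(ts) ncol(ts$values)
n_voxels <- function(ts) nrow(ts$values)

# frame index ranges (1-based) of each run
run_slices <- function(ts) {
  starts <- ts$run_boundaries + 1L
  ends <- c(ts$run_boundaries[-1L], n_frames(ts))
  mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
}

# world-mm coordinates of each voxel centre (n x 3)
voxel_world_coords <- function(ts) {
  ijk1 <- cbind(ts$coords, 1)
  t(ts$affine %*% t(ijk1))[, 1:3, drop = FALSE]
}

#' Add square-wave intensity spikes to selected frames
#'
#' Test fixture for motion scrubbing: adds `amplitude` to every voxel at the
#' listed frames, leaving all other values untouched. On a mode-1000 series
#' a 20-unit spike produces DVARS of exactly 2% at the two affected
#' transitions.
#'
#' @param ts a [voxel_ts()] object.
#' @param frames integer vector of 0-based frame indices to perturb.
#' @param amplitude added signal, same units as the series.
#' @return The perturbed `voxel_ts`.
#' @export
inject_spikes <- function(ts, frames, amplitude) {
  stopifnot(inherits(ts, "voxel_ts"))
  frames <- as.integer(frames)
  if (length(frames) && (min(frames) < 0L || max(frames) >= n_frames(ts)))
    stop("spike frame index out of range [0, ", n_frames(ts) - 1L, "]")
  ts$values[, frames + 1L] <- ts$values[, frames + 1L] + amplitude
  ts
}

#' Read a 4D BOLD volume and 3D mask into a voxel time-series
#'
#' Voxels where the mask is nonzero are extracted in mask scan order
#' (x fastest, then y, then z), which fixes the voxel ordering used by every
#' voxel-indexed artifact downstream. The volume affine is retained for
#' mm conversions (seeded initialization, ROI spheres).
#'
#' @param volume_path path to a 4D NIfTI volume.
#' @param mask_path path to a 3D NIfTI mask on the same grid.
#' @param frame_interval TR in seconds; if `NULL`, taken from the volume
#'   header's 4th pixdim.
#' @param run_boundaries 0-based frame indices of run starts.
#' @return A [voxel_ts()] object.
#' @export
load_timeseries <- function(volume_path, mask_path, frame_interval = NULL,
                            run_boundaries = 0L) {
  vol <- RNifti::readNifti(volume_path)
  msk <- RNifti::readNifti(mask_path)
  if (length(dim(vol)) != 4L)
    stop("'", volume_path, "' is not a 4D volume")
  if (!all(dim(vol)[1:3] == dim(msk)[1:3]))
    stop("grid mismatch between '", volume_path, "' and '", mask_path, "'")
  a_vol <- unclass(RNifti::xform(vol))
  a_msk <- unclass(RNifti::xform(msk))
  if (max(abs(a_vol - a_msk)) > 1e-4)
    stop("affine mismatch between '", volume_path, "' and '", mask_path, "'")
  idx <- which(msk != 0)           # column-major: x fastest
  if (length(idx) == 0L) stop("mask '", mask_path, "' is empty")
  coords <- arrayInd(idx, dim(msk)) - 1L
  nt <- dim(vol)[4L]
  mat <- matrix(as.numeric(vol), prod(dim(vol)[1:3]), nt)[idx, , drop = FALSE]
  if (is.null(frame_interval)) {
    frame_interval <- RNifti::pixdim(vol)[4L]
    if (!is.finite(frame_interval) || frame_interval <= 0)
      frame_interval <- 1
  }
  voxel_ts(mat, coords, affine = a_vol, frame_interval = frame_interval,
           run_boundaries = run_boundaries)
}

#' Write a voxel time-series as NIfTI volume + mask
#'
#' Inverse of [load_timeseries()]: scatters the in-mask rows back onto the
#' bounding grid, writes the 4D volume and the binary mask, and returns the
#' two paths. Out-of-mask voxels are zero.
#'
#' @param ts a [voxel_ts()] object.
#' @param volume_path,mask_path output NIfTI paths.
#' @return Invisibly, `c(volume = volume_path, mask = mask_path)`.
#' @export
write_timeseries <- function(ts, volume_path, mask_path) {
  stopifnot(inherits(ts, "voxel_ts"))
  dims <- apply(ts$coords, 2L, max) + 1L
  arr <- array(0, c(dims, n_frames(ts)))
  lin <- 1L + ts$coords[, 1L] + dims[1L] * (ts$coords[, 2L] +
         dims[2L] * ts$coords[, 3L])
  nvol <- prod(dims)
  for (t in seq_len(n_frames(ts)))
    arr[lin + (t - 1L) * nvol] <- ts$values[, t]
  msk <- array(0, dims)
  msk[lin] <- 1
  # pixdim must be set before the sform: RNifti rescales an existing
  # transform when the pixel dimensions change
  pd <- c(abs(ts$affine[1, 1]), abs(ts$affine[2, 2]), abs(ts$affine[3, 3]),
          ts$frame_interval)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pd
  img <- RNifti::`sform<-`(img, structure(ts$affine, code = 2L))
  RNifti::writeNifti(img, volume_path)
  mimg <- RNifti::asNifti(msk)
  RNifti::pixdim(mimg) <- pd[1:3]
  mimg <- RNifti::`sform<-`(mimg, structure(ts$affine, code = 2L))
  RNifti::writeNifti(mimg, mask_path)
  invisible(c(volume = volume_path, mask = mask_path))
}

#' Write a per-voxel statistic as a 3D NIfTI map on the mask grid
#'
#' @param x numeric vector, one value per in-mask voxel.
#' @param ts the `voxel_ts` providing grid geometry.
#' @param path output NIfTI path.
#' @return Invisibly, `path`.
#' @export
write_voxel_map <- function(x, ts, path) {
  stopifnot(length(x) == n_voxels(ts))
  dims <- apply(ts$coords, 2L, max) + 1L
  arr <- array(0, dims)
  lin <- 1L + ts$coords[, 1L] + dims[1L] * (ts$coords[, 2L] +
         dims[2L] * ts$coords[, 3L])
  arr[lin] <- x
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(ts$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
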