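#' Remove linear trends voxelwise, per run
#'
#' Subtracts the least-squares line (intercept + slope) from every voxel's
#' time course within each run, so each residual run has mean zero and no
#' linear drift.
#'
#' @param ts a [voxel_ts()] object; every run must have at least 3 frames.
#' @return The detrended `voxel_ts`.
#' @export
detrend <- function(ts) {
  stopifnot(inherits(ts, "voxel_ts"))
  for (fr in run_slices(ts)) {
    if (length(fr) < 3L)
      stop("run of ", length(fr), " frames is too short to detrend (need 3)")
    X <- cbind(1, seq_along(fr))
    Q <- qr.Q(qr(X))
    seg <- ts$values[, fr, drop = FALSE]
    ts$values[, fr] <- seg - (seg %*% Q) %*% t(Q)
  }
  ts
}

#' Zero-phase low-pass filter of voxel time courses
#'
#' Applies a 2nd-order Butterworth low-pass forward and backward
#' ([signal::filtfilt()]) within each run, retaining fluctuations below
#' `cutoff`. The bidirectional pass gives zero phase shift (no temporal lag
#' that would distort correlations) and unit DC gain; the effective
#' magnitude response is the square of the single-pass Butterworth response.
#'
#' @param ts a [voxel_ts()] object.
#' @param cutoff cutoff frequency in Hz; must be below the Nyquist
#'   frequency `1 / (2 * frame_interval)`.
#' @param order Butterworth order of the single pass.
#' @return The filtered `voxel_ts`.
#' @export
lowpass <- function(ts, cutoff = 0.1, order = 2L) {
  stopifnot(inherits(ts, "voxel_ts"))
  nyquist <- 1 / (2 * ts$frame_interval)
  if (cutoff >= nyquist)
    stop("cutoff ", cutoff, " Hz is not below Nyquist ", nyquist, " Hz")
  bf <- signal::butter(order, cutoff / nyquist, type = "low")
  for (fr in run_slices(ts)) {
    seg <- ts$values[, fr, drop = FALSE]
    ts$values[, fr] <- t(apply(seg, 1L, function(v) filtfilt_refl(bf, v)))
  }
  ts
}

# forward-backward filtering with odd-reflection padding at both ends, so
# the filter state has settled before the data proper begins (plain
# filtfilt starts from a zero state and rings at the edges)
filtfilt_refl <- function(bf, x) {
  n <- length(x)
  L <- min(n - 1L, 50L)
  pre <- 2 * x[1L] - x[(L + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - L)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(L + 1L):(L + n)]
}

#' Regress nuisance signals out of every voxel
#'
#' Ordinary least-squares residualization of each voxel's time course
#' against an intercept plus the supplied regressors (typically the six
#' rigid-body motion parameters, their temporal derivatives, and the global
#' mean signal).
#'
#' @param ts a [voxel_ts()] object.
#' @param regressors numeric matrix, n_frames x p. An intercept column is
#'   always added internally.
#' @param add_global if `TRUE`, append the global signal (mean over in-mask
#'   voxels) as an extra regressor.
#' @return The residual `voxel_ts`.
#' @export
regress_nuisance <- function(ts, regressors = NULL, add_global = FALSE) {
  stopifnot(inherits(ts, "voxel_ts"))
  nt <- n_frames(ts)
  R <- if (is.null(regressors)) matrix(0, nt, 0) else as.matrix(regressors)
  if (nrow(R) != nt)
    stop("regressor matrix has ", nrow(R), " rows; expected ", nt)
  if (add_global) {
    R <- cbind(R, global = colMeans(ts$values))
  }
  if (ncol(R) + 1L >= nt)
    stop("need fewer regressors than frames")
  X <- cbind(intercept = 1, R)
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    bad <- colnames(X)[qd$pivot[(qd$rank + 1L):ncol(X)]]
    if (is.null(bad)) bad <- qd$pivot[(qd$rank + 1L):ncol(X)]
    stop("nuisance design is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  Q <- qr.Q(qd)
  ts$values <- ts$values - (ts$values %*% Q) %*% t(Q)
  ts
}

#' Compute DVARS and a frame-censoring mask
#'
#' DVARS at frame t is the root-mean-square over voxels of the signal
#' change from frame t-1 to t, expressed as a percentage of the mode-1000
#' intensity scale (i.e. divided by 10). The first frame of each run has
#' DVARS 0 by convention. Frames whose DVARS exceeds `threshold` percent
#' are censored — for an isolated spike these are exactly the spike frame
#' and the one after it, since both backward differences are corrupted.
#' The comparison is strict: a frame with DVARS exactly at the threshold
#' is kept. `censor_preceding` additionally drops the frame before each
#' super-threshold transition.
#'
#' @param ts a [voxel_ts()] object on the mode-1000 scale.
#' @param threshold censoring threshold in percent of mode-1000.
#' @param censor_preceding also censor the frame preceding each
#'   super-threshold transition (default `FALSE`).
#' @return A list of class `frame_censor` with components `dvars`
#'   (percent, per frame) and `keep` (logical, per frame).
#' @export
compute_dvars <- function(ts, threshold = 0.5, censor_preceding = FALSE) {
  stopifnot(inherits(ts, "voxel_ts"))
  nt <- n_frames(ts)
  dvars <- numeric(nt)
  for (fr in run_slices(ts)) {
    if (length(fr) < 2L) next
    d <- ts$values[, fr[-1L], drop = FALSE] -
         ts$values[, fr[-length(fr)], drop = FALSE]
    dvars[fr[-1L]] <- sqrt(colMeans(d^2)) / 10
  }
  over <- dvars > threshold
  keep <- !over
  if (censor_preceding && any(over)) {
    prev <- which(over) - 1L
    prev <- prev[prev >= 1L]
    keep[prev] <- FALSE
  }
  structure(list(dvars = dvars, keep = keep, threshold = threshold),
            class = "frame_censor")
}

#' @export
print.frame_censor <- function(x, ...) {
  cat("Frame censor mask:", sum(!x$keep), "of", length(x$keep),
      "frames censored (DVARS >", x$threshold, "%)\n")
  invisible(x)
}

#' Voxel-by-voxel Pearson correlation map
#'
#' Computes the Pearson correlation between the time courses of every pair
#' of voxels over the retained frames. Row k of the resulting n x n matrix
#' is the correlation profile of voxel k — the feature vector consumed by
#' the clustering.
#'
#' @param ts a [voxel_ts()] object.
#' @param censor optional [compute_dvars()] mask; only frames with
#'   `keep == TRUE` enter the correlation.
#' @return An object of class `corr_map`: list with `r` (n x n correlation
#'   matrix), `n`, and the grid geometry (`coords`, `affine`) inherited
#'   from `ts` for initialization.
#' @export
correlation_map <- function(ts, censor = NULL) {
  stopifnot(inherits(ts, "voxel_ts"))
  keep <- if (is.null(censor)) rep(TRUE, n_frames(ts)) else censor$keep
  if (length(keep) != n_frames(ts))
    stop("censor mask length does not match frame count")
  if (sum(keep) < 3L) stop("need at least 3 retained frames")
  V <- ts$values[, keep, drop = FALSE]
  sds <- apply(V, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance voxel(s) over kept frames: ",
         paste(utils::head(which(sds == 0) - 1L, 5L), collapse = ", "))
  r <- stats::cor(t(V))
  r[r > 1] <- 1; r[r < -1] <- -1
  corr_map(r, coords = ts$coords, affine = ts$affine)
}

#' Construct a correlation-map feature object
#'
#' @param r symmetric n x n correlation matrix with unit diagonal.
#' @param coords optional n x 3 0-based voxel grid coordinates (needed for
#'   cube-based random initialization).
#' @param affine optional 4x4 voxel-to-world affine (needed for seeded
#'   initialization in mm).
#' @return An object of class `corr_map`.
#' @export
corr_map <- function(r, coords = NULL, affine = NULL) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("correlation map must be square")
  if (max(abs(r - t(r))) > 1e-8) stop("correlation map must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("diagonal must be 1")
  if (min(r) < -1 - 1e-8 || max(r) > 1 + 1e-8)
    stop("entries must lie in [-1, 1]")
  structure(list(r = r, n = nrow(r), coords = coords, affine = affine),
            class = "corr_map")
}

#' @export
print.corr_map <- function(x, ...) {
  cat("Correlation map:", x$n, "x", x$n, "voxels; off-diagonal range [",
      format(min(x$r[upper.tri(x$r)]), digits = 3), ",",
      format(max(x$r[upper.tri(x$r)]), digits = 3), "]\n")
  invisible(x)
}

#' @export
dim.corr_map <- function(x) dim(x$r)

#' Entrywise average of correlation maps across subjects
#'
#' @param maps list of [corr_map()] objects on the same voxel set.
#' @return A `corr_map` holding the arithmetic mean; geometry is taken
#'   from the first map.
#' @export
group_average <- function(maps) {
  if (inherits(maps, "corr_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1L, all(vapply(maps, inherits, TRUE, "corr_map")))
  n <- maps[[1L]]$n
  if (!all(vapply(maps, function(m) m$n, 1L) == n))
    stop("correlation maps differ in size")
  r <- Reduce(`+`, lapply(maps, `[[`, "r")) / length(maps)
  corr_map(r, coords = maps[[1L]]$coords, affine = maps[[1L]]$affine)
}

#' Standard temporal preprocessing chain
#'
#' Runs the fixed stage order detrend -> low-pass -> nuisance/global-signal
#' regression -> DVARS censoring and returns the correlation-map features.
#' Each stage can be toggled for diagnostic purposes; the order itself is
#' not configurable.
#'
#' @param ts a [voxel_ts()] object (mode-1000 scale).
#' @param regressors optional n_frames x p nuisance matrix (e.g. motion
#'   parameters and their derivatives).
#' @param cutoff low-pass cutoff in Hz.
#' @param dvars_threshold censoring threshold in percent.
#' @param global_signal include the in-mask mean signal as a regressor.
#' @param do_detrend,do_lowpass,do_regress stage toggles.
#' @return A list with `features` (a [corr_map()]), `censor` (the
#'   [compute_dvars()] mask) and `ts` (the cleaned series).
#' @export
preprocess_bold <- function(ts, regressors = NULL, cutoff = 0.1,
                            dvars_threshold = 0.5, global_signal = TRUE,
                            do_detrend = TRUE, do_lowpass = TRUE,
                            do_regress = TRUE) {
  stopifnot(inherits(ts, "voxel_ts"))
  if (do_detrend) ts <- detrend(ts)
  if (do_lowpass) ts <- lowpass(ts, cutoff = cutoff)
  if (do_regress && (!is.null(regressors) || global_signal))
    ts <- regress_nuisance(ts, regressors, add_global = global_signal)
  # censoring follows the cleaning stages; DVARS units stay % of mode 1000
  # because only frame-to-frame differences enter
  censor <- compute_dvars(ts, threshold = dvars_threshold)
  features <- correlation_map(ts, censor)
  list(features = features, censor = censor, ts = ts)
}
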