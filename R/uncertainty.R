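#' Voxelwise classification uncertainty of a soft partition
#'
#' The geometric mean of each voxel's membership weights,
#' \deqn{CU_k = \Big(\prod_{i=1}^{c} u_{ik}\Big)^{1/c},}
#' computed as the exponential of the mean log weight for numerical
#' stability, with any zero weight short-circuiting to 0. By the AM-GM
#' inequality CU is at most 1/c, attained exactly at uniform memberships;
#' a crisp voxel has CU 0. High values flag voxels shared between
#' networks.
#'
#' @param solution an [fcm()] object or a column-stochastic membership
#'   matrix (c x n).
#' @return An object of class `uncertainty_map`: numeric vector of per-
#'   voxel uncertainties with attribute `c`.
#' @export
classification_uncertainty <- function(solution) {
  u <- if (inherits(solution, "fcm")) solution$u else as.matrix(solution)
  c_ <- nrow(u)
  cu <- numeric(ncol(u))
  pos <- colSums(u == 0) == 0L
  if (any(pos)) cu[pos] <- exp(colMeans(log(u[, pos, drop = FALSE])))
  structure(cu, c = c_, class = "uncertainty_map")
}

#' @export
print.uncertainty_map <- function(x, ...) {
  c_ <- attr(x, "c")
  cat("Classification uncertainty over", length(x), "voxels (c =", c_,
      ")\n")
  cat("  range [", format(min(x), digits = 4), ",",
      format(max(x), digits = 4), "], bound 1/c =",
      format(1 / c_, digits = 4), "\n")
  invisible(x)
}

#' Association of the uncertainty map with each cluster
#'
#' Spatial similarity between the voxelwise uncertainty vector and every
#' cluster's membership vector, indicating which networks the uncertain
#' (shared-membership) voxels belong to. A constant uncertainty map has no
#' spatial direction and yields 0 under centering.
#'
#' @param cu an [classification_uncertainty()] map.
#' @param solution the `fcm` solution it derives from (same voxel set).
#' @param centering `"raw"` or `"centered"` (see [spatial_similarity()]).
#' @param labels optional cluster labels.
#' @return Named numeric vector of length c.
#' @export
uncertainty_association <- function(cu, solution,
                                    centering = c("centered", "raw"),
                                    labels = NULL) {
  centering <- match.arg(centering)
  u <- solution$u
  if (length(cu) != ncol(u)) stop("voxel-set mismatch")
  cuv <- as.numeric(cu)
  if (centering == "raw" && stats::sd(cuv) == 0 && all(cuv == 0))
    stop("uncertainty map is identically zero")
  out <- vapply(seq_len(nrow(u)), function(i)
    spatial_similarity(cuv, u[i, ], centering), numeric(1))
  names(out) <- if (is.null(labels)) paste0("C", seq_len(nrow(u))) else labels
  out
}
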