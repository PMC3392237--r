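# accept a corr_map or a plain numeric matrix of feature rows
feature_matrix <- function(x) {
  if (inherits(x, "corr_map")) return(x$r)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite feature values")
  x
}

# squared Euclidean distances, c x n, between centroid rows and point rows
squared_dists <- function(X, V) {
  d2 <- matrix(rowSums(V^2), nrow(V), nrow(X)) +
        matrix(rowSums(X^2), nrow(V), nrow(X), byrow = TRUE) -
        2 * tcrossprod(V, X)
  d2[d2 < 0] <- 0
  d2
}

#' Fuzzy membership update
#'
#' Computes the membership of every point in every cluster from the current
#' centroids, using the standard fuzzy-c-means update with Euclidean
#' distance:
#' \deqn{u_{ik} = \left[\sum_j \left(\frac{\|X_k - V_i\|}{\|X_k - V_j\|}\right)^{2/(M-1)}\right]^{-1}.}
#' A point coincident with a centroid receives full membership in the
#' first coincident cluster (the standard singularity rule).
#'
#' @param x feature object ([corr_map()] or matrix of feature rows).
#' @param v centroid matrix, c x d.
#' @param m fuzzifier, > 1.
#' @return Membership matrix U, c x n; every column sums to 1.
#' @export
update_memberships <- function(x, v, m = 1.2) {
  if (m <= 1) stop("fuzzifier must exceed 1")
  X <- feature_matrix(x)
  v <- as.matrix(v)
  d2 <- squared_dists(X, v)
  e <- 1 / (m - 1)
  dmin <- apply(d2, 2L, min)
  sing <- dmin == 0
  # scale by the column minimum before the negative power: ratios are >= 1,
  # so no overflow even at small m (large exponents)
  W <- sweep(d2, 2L, pmax(dmin, .Machine$double.xmin), "/")^(-e)
  U <- sweep(W, 2L, colSums(W), "/")
  if (any(sing)) {
    for (k in which(sing)) {
      col <- numeric(nrow(v))
      col[which(d2[, k] == 0)[1L]] <- 1
      U[, k] <- col
    }
  }
  U
}

#' Centroid update
#'
#' Recomputes each cluster centre as the membership-weighted mean of the
#' feature rows,
#' \deqn{V_i = \sum_k u_{ik}^M X_k \big/ \sum_k u_{ik}^M.}
#'
#' @inheritParams update_memberships
#' @param u membership matrix, c x n, column-stochastic.
#' @return Centroid matrix, c x d.
#' @export
update_centroids <- function(x, u, m = 1.2) {
  X <- feature_matrix(x)
  u <- as.matrix(u)
  W <- u^m
  w <- rowSums(W)
  if (any(w == 0)) stop("cluster with all-zero membership weight")
  (W %*% X) / w
}

#' Xie-Beni cluster validity index
#'
#' Compactness-to-separation ratio
#' \deqn{XB = \frac{\sum_i \sum_k u_{ik}^M \|X_k - V_i\|^2}{n \cdot \min_{i \ne j} \|V_i - V_j\|^2},}
#' used here as the convergence monitor of the iteration. Invariant to a
#' common rescaling of features and centroids.
#'
#' @inheritParams update_centroids
#' @param v centroid matrix, c x d, with c >= 2 distinct rows.
#' @return The index (unitless, >= 0).
#' @export
xie_beni <- function(x, u, v, m = 1.2) {
  X <- feature_matrix(x)
  v <- as.matrix(v)
  if (nrow(v) < 2L) stop("Xie-Beni requires at least 2 clusters")
  d2 <- squared_dists(X, v)
  sep <- min(stats::dist(v)^2)
  if (sep == 0) stop("coincident centroids: separation is zero")
  sum(u^m * d2) / (ncol(d2) * sep)
}

# the FCM objective J_M; non-increasing over the alternating updates
fcm_objective <- function(X, u, v, m) {
  sum(u^m * squared_dists(X, as.matrix(v)))
}

#' Random cube initialization
#'
#' For each cluster, a voxel is drawn uniformly at random as the centre of
#' an axis-aligned cube of `cube_edge` voxels per dimension; the centroid is
#' the mean feature row over the in-mask voxels inside the cube. Duplicate
#' centroids trigger a redraw.
#'
#' @param x a [corr_map()] carrying voxel grid coordinates.
#' @param c number of clusters (>= 2).
#' @param seed integer RNG seed.
#' @param cube_edge cube side length in voxels (odd).
#' @return Centroid matrix c x d with attribute `seed_info`.
#' @export
init_random <- function(x, c, seed = NULL, cube_edge = 3L) {
  stopifnot(inherits(x, "corr_map"))
  if (is.null(x$coords)) stop("feature object carries no voxel coordinates")
  if (c < 2L) stop("need at least 2 clusters")
  if (x$n < c) stop("fewer voxels than clusters")
  half <- (cube_edge - 1L) %/% 2L
  if (!is.null(seed)) {
    rs <- local_rng(seed)
    on.exit(restore_rng(rs))
  }
  V <- matrix(NA_real_, c, x$n)
  centers <- integer(c)
  for (i in seq_len(c)) {
    for (try in 1:100) {
      ctr <- sample.int(x$n, 1L)
      inside <- apply(abs(sweep(x$coords, 2L, x$coords[ctr, ], "-")) <= half,
                      1L, all)
      cand <- colMeans(x$r[inside, , drop = FALSE])
      dup <- i > 1L &&
        any(rowSums(sweep(V[seq_len(i - 1L), , drop = FALSE], 2L, cand,
                          "-")^2) == 0)
      if (!dup) break
      if (try == 100) stop("could not draw ", c, " distinct centroids")
    }
    V[i, ] <- cand
    centers[i] <- ctr
  }
  attr(V, "seed_info") <- list(method = "random-cube", seed = seed,
                               cube_edge = cube_edge,
                               center_voxels = centers - 1L)
  V
}

#' Seeded-sphere initialization from ROI coordinates
#'
#' Each centroid is the mean feature row over in-mask voxels whose
#' world-space (mm) position lies within `radius` of an ROI coordinate,
#' e.g. stereotaxic seeds of canonical resting-state networks.
#'
#' @param x a [corr_map()] carrying coordinates and an affine.
#' @param rois data frame with columns `name`, `x`, `y`, `z` (mm).
#' @param radius sphere radius in mm.
#' @return Centroid matrix (one row per ROI) with attribute `seed_info`
#'   echoing the ROI table.
#' @export
init_seeded <- function(x, rois, radius = 5) {
  stopifnot(inherits(x, "corr_map"))
  if (is.null(x$coords) || is.null(x$affine))
    stop("feature object carries no grid geometry")
  rois <- as.data.frame(rois)
  if (!all(c("name", "x", "y", "z") %in% names(rois)))
    stop("'rois' needs columns name, x, y, z")
  world <- t(x$affine %*% t(cbind(x$coords, 1)))[, 1:3, drop = FALSE]
  V <- matrix(NA_real_, nrow(rois), x$n)
  for (i in seq_len(nrow(rois))) {
    d <- sqrt(rowSums(sweep(world, 2L, as.numeric(rois[i, c("x", "y", "z")]),
                            "-")^2))
    inside <- d <= radius
    if (!any(inside))
      stop("ROI '", rois$name[i], "' has no in-mask voxel within ",
           radius, " mm")
    V[i, ] <- colMeans(x$r[inside, , drop = FALSE])
  }
  rownames(V) <- rois$name
  attr(V, "seed_info") <- list(method = "seeded-sphere", radius = radius,
                               rois = rois)
  V
}

#' The seven canonical resting-state network seeds
#'
#' Stereotaxic (Talairach) mm coordinates of one representative region per
#' network, for seeded initialization at c = 7: precuneus (DMN), right
#' dorsolateral prefrontal cortex (FPC), left superior temporal gyrus
#' (LAN), right middle frontal gyrus (VAN), left parietal operculum (SMN),
#' superior occipital gyrus (VIS) and right frontal eye field (DAN).
#'
#' @return A 7-row data frame with columns `name`, `x`, `y`, `z`.
#' @export
rsn_seed_table <- function() {
  data.frame(
    name = c("DMN", "FPC", "LAN", "VAN", "SMN", "VIS", "DAN"),
    x = c(0, 43, -54, 24, -45, -13, 23),
    y = c(-65, 22, -23, 38, -30, -93, -8),
    z = c(31, 34, -3, 25, 22, 18, 55))
}

#' Fit a fuzzy-c-means soft clustering
#'
#' Alternates the membership and centroid updates from an initial centroid
#' set until the Xie-Beni index changes by less than `tol` over `patience`
#' consecutive iterations. The fuzzifier default M = 1.2 gives memberships
#' soft enough to expose shared-membership voxels yet close to a hard
#' partition.
#'
#' @param x features: a [corr_map()] or a numeric matrix whose rows are the
#'   points to cluster.
#' @param c number of clusters.
#' @param m fuzzifier (> 1).
#' @param init initial centroid matrix (c x d), e.g. from [init_random()]
#'   or [init_seeded()]. If `NULL`, random-cube initialization with `seed`.
#' @param tol convergence tolerance on the change of the Xie-Beni index.
#' @param patience number of consecutive sub-`tol` changes required.
#' @param max_iter iteration cap.
#' @param seed RNG seed used when `init` is `NULL`.
#' @return An object of class `fcm`: membership matrix `u` (c x n),
#'   centroids `v` (c x d), per-iteration `xie_beni_trace` and
#'   `objective_trace`, convergence flag, and initialization record.
#' @seealso [fcm_consensus()] for multi-run averaging, [fcm_sweep()] for
#'   selecting c, [classification_uncertainty()] for voxelwise uncertainty.
#' @export
fcm <- function(x, c, m = 1.2, init = NULL, tol = 1e-4, patience = 5L,
                max_iter = 1000L, seed = NULL) {
  X <- feature_matrix(x)
  if (c == 1L) {
    # degenerate but well-defined: everything in one cluster at the mean
    U <- matrix(1, 1L, nrow(X))
    V <- matrix(colMeans(X), 1L)
    return(structure(
      list(u = U, v = V, c = 1L, m = m, xie_beni_trace = numeric(0),
           objective_trace = fcm_objective(X, U, V, m), converged = TRUE,
           n_iter = 0L, tol = tol, patience = patience,
           seed_info = list(method = "degenerate"), call = match.call()),
      class = "fcm"))
  }
  if (is.null(init)) {
    if (inherits(x, "corr_map") && !is.null(x$coords)) {
      init <- init_random(x, c, seed = seed)
    } else {
      if (!is.null(seed)) {
        rs <- local_rng(seed)
        on.exit(restore_rng(rs))
      }
      rows <- sample.int(nrow(X), c)
      init <- X[rows, , drop = FALSE]
      attr(init, "seed_info") <- list(method = "random-rows", seed = seed,
                                      rows = rows)
    }
  }
  V <- as.matrix(init)
  if (nrow(V) != c) stop("'init' must have ", c, " rows")
  if (ncol(V) != ncol(X)) stop("'init' dimension does not match features")

  xb_trace <- numeric(0)
  obj_trace <- numeric(0)
  converged <- FALSE
  stable <- 0L
  U <- NULL
  for (it in seq_len(max_iter)) {
    U <- update_memberships(X, V, m)
    V <- update_centroids(X, U, m)
    xb <- xie_beni(X, U, V, m)
    obj_trace <- c(obj_trace, fcm_objective(X, U, V, m))
    if (length(xb_trace) && abs(xb - xb_trace[length(xb_trace)]) < tol) {
      stable <- stable + 1L
    } else stable <- 0L
    xb_trace <- c(xb_trace, xb)
    if (stable >= patience) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(u = U, v = V, c = as.integer(c), m = m,
         xie_beni_trace = xb_trace, objective_trace = obj_trace,
         converged = converged, n_iter = length(xb_trace),
         tol = tol, patience = patience,
         seed_info = attr(init, "seed_info"),
         call = match.call()),
    class = "fcm")
}

#' @export
print.fcm <- function(x, ...) {
  cat("Fuzzy c-means solution: c =", x$c, ", M =", x$m, "\n")
  cat("  ", ncol(x$u), "points;",
      if (x$converged) paste("converged in", x$n_iter, "iterations")
      else paste("NOT converged after", x$n_iter, "iterations"), "\n")
  cat("  final Xie-Beni index:",
      format(utils::tail(x$xie_beni_trace, 1L), digits = 5), "\n")
  sizes <- tabulate(hard_labels(x), nbins = x$c)
  cat("  hard cluster sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.fcm <- function(object, ...) {
  hl <- hard_labels(object)
  maxu <- apply(object$u, 2L, max)
  cu <- classification_uncertainty(object)
  out <- list(c = object$c, m = object$m, n = ncol(object$u),
              converged = object$converged, n_iter = object$n_iter,
              xie_beni = utils::tail(object$xie_beni_trace, 1L),
              objective = utils::tail(object$objective_trace, 1L),
              sizes = tabulate(hl, nbins = object$c),
              mean_max_membership = mean(maxu),
              mean_uncertainty = mean(cu))
  class(out) <- "summary.fcm"
  out
}

#' @export
print.summary.fcm <- function(x, ...) {
  cat("Fuzzy c-means: c =", x$c, ", M =", x$m, ",", x$n, "points\n")
  cat("  converged:", x$converged, "(", x$n_iter, "iterations )\n")
  cat("  Xie-Beni:", format(x$xie_beni, digits = 5),
      " objective:", format(x$objective, digits = 5), "\n")
  cat("  hard sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("  mean max membership:", format(x$mean_max_membership, digits = 4),
      " mean uncertainty:", format(x$mean_uncertainty, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.fcm <- function(object, ...) object$v

#' @export
fitted.fcm <- function(object, ...) object$u

#' @export
#' @describeIn fcm membership matrix of new feature rows against the
#'   fitted centroids.
predict.fcm <- function(object, newdata, ...) {
  update_memberships(newdata, object$v, object$m)
}

#' @export
plot.fcm <- function(x, ...) {
  graphics::plot(seq_along(x$xie_beni_trace), x$xie_beni_trace, type = "b",
                 pch = 20, xlab = "iteration", ylab = "Xie-Beni index",
                 main = sprintf("FCM convergence (c = %d, M = %g)",
                                x$c, x$m), ...)
  invisible(x)
}

#' Hard cluster labels of a soft solution
#'
#' @param solution an `fcm` object or a membership matrix.
#' @return Integer vector of argmax cluster indices per point.
#' @export
hard_labels <- function(solution) {
  u <- if (inherits(solution, "fcm")) solution$u else as.matrix(solution)
  apply(u, 2L, which.max)
}
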