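#' Cluster dispersion of a soft partition
#'
#' Ratio of the membership-weighted within-cluster squared dispersion to
#' the total dispersion about the grand mean:
#' \deqn{CD = \frac{\sum_i \sum_k u_{ik}^M \|X_k - V_i\|^2}{\sum_k \|X_k - \bar{x}\|^2}.}
#' The denominator equals the numerator of the single-cluster solution
#' (all memberships 1, centroid at the grand mean), so CD = 1 exactly at
#' c = 1 and smaller values indicate members closer to their centroids.
#' Invariant to a global rescaling of the features.
#'
#' @param x features: a [corr_map()] or matrix of feature rows.
#' @param solution an [fcm()] object (or any list with `u`, `v`, `m`).
#' @return The dispersion (unitless, >= 0).
#' @export
cluster_dispersion <- function(x, solution) {
  X <- feature_matrix(x)
  xbar <- colMeans(X)
  den <- sum(sweep(X, 2L, xbar, "-")^2)
  if (den == 0) stop("all feature rows identical: total dispersion is zero")
  fcm_objective(X, solution$u, solution$v, solution$m) / den
}

#' Sweep the number of clusters and record cluster dispersion
#'
#' For each candidate c, fits a consensus clustering ([fcm_consensus()])
#' and evaluates [cluster_dispersion()]. The resulting curve is inspected
#' with [local_minima()] to propose optimal cluster numbers; multiple
#' minima are reported, not adjudicated, since several scales of a
#' hierarchy can be simultaneously meaningful.
#'
#' @inheritParams fcm_consensus
#' @param c_min,c_max inclusive range of cluster numbers.
#' @param runs_per_c random restarts per candidate c.
#' @param seed integer seed from which per-c seeds are drawn.
#' @param c_values explicit cluster numbers to evaluate (overrides
#'   `c_min`/`c_max`).
#' @return An object of class `dispersion_curve`: data frame with columns
#'   `c`, `cd`, `n_converged`, plus the per-c solutions in attribute
#'   `solutions`.
#' @export
fcm_sweep <- function(x, c_min = 2L, c_max = 20L, m = 1.2,
                      runs_per_c = 20L, seed = NULL, tol = 1e-4,
                      patience = 5L, max_iter = 1000L, c_values = NULL) {
  X <- feature_matrix(x)
  cs <- if (is.null(c_values)) {
    if (c_min > c_max) stop("'c_min' must not exceed 'c_max'")
    seq.int(c_min, c_max)
  } else sort(unique(as.integer(c_values)))
  if (max(cs) > nrow(X)) stop("largest c exceeds the number of points")
  if (!is.null(seed)) {
    rs <- local_rng(seed)
    on.exit(restore_rng(rs))
  }
  c_seeds <- sample.int(.Machine$integer.max, length(cs))
  solutions <- vector("list", length(cs))
  cd <- rep(NA_real_, length(cs))
  ncv <- rep(NA_integer_, length(cs))
  for (i in seq_along(cs)) {
    sol <- tryCatch(
      fcm_consensus(x, cs[i], m = m, n_runs = runs_per_c,
                    seed = c_seeds[i], tol = tol, patience = patience,
                    max_iter = max_iter),
      error = function(e) {
        warning("c = ", cs[i], " failed: ", conditionMessage(e))
        NULL
      })
    if (!is.null(sol)) {
      solutions[[i]] <- sol
      cd[i] <- cluster_dispersion(x, sol)
      ncv[i] <- sol$n_converged
    }
  }
  out <- data.frame(c = cs, cd = cd, n_converged = ncv)
  attr(out, "solutions") <- stats::setNames(solutions, cs)
  attr(out, "m") <- m
  class(out) <- c("dispersion_curve", "data.frame")
  out
}

#' @export
print.dispersion_curve <- function(x, ...) {
  cat("Cluster-dispersion curve over c =", min(x$c), "..", max(x$c), "\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  lm_ <- if (nrow(x) >= 3L) local_minima(x) else integer(0)
  if (length(lm_))
    cat("local minima at c =", paste(lm_, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.dispersion_curve <- function(x, ...) {
  graphics::plot(x$c, x$cd, type = "b", pch = 20, xlab = "number of clusters",
                 ylab = "cluster dispersion", ...)
  lm_ <- if (nrow(x) >= 3L) local_minima(x) else integer(0)
  if (length(lm_))
    graphics::points(lm_, x$cd[match(lm_, x$c)], pch = 1, cex = 2,
                     col = "red3")
  invisible(x)
}

#' Extract a per-c solution from a sweep
#'
#' @param curve a [fcm_sweep()] result.
#' @param c the cluster number.
#' @return The stored `fcm_consensus` solution.
#' @export
sweep_solution <- function(curve, c) {
  sol <- attr(curve, "solutions")[[as.character(c)]]
  if (is.null(sol)) stop("no solution stored for c = ", c)
  sol
}

#' Interior local minima of a dispersion curve
#'
#' A cluster number c is a local minimum iff CD(c) < CD(c-1) and
#' CD(c) < CD(c+1), both strictly; endpoints are never reported and ties
#' disqualify both neighbours.
#'
#' @param curve a [fcm_sweep()] result, or a data frame with columns `c`
#'   and `cd` (at least 3 rows, strictly increasing c).
#' @return Integer vector of local-minimum cluster numbers (possibly
#'   empty).
#' @export
local_minima <- function(curve) {
  cc <- curve$c; cd <- curve$cd
  if (length(cc) < 3L) stop("need at least 3 curve entries")
  if (any(diff(cc) <= 0)) stop("'c' values must be strictly increasing")
  keep <- !is.na(cd)
  cc <- cc[keep]; cd <- cd[keep]
  i <- seq.int(2L, length(cd) - 1L)
  cc[i][cd[i] < cd[i - 1L] & cd[i] < cd[i + 1L]]
}
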