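#' Consensus fuzzy-c-means over repeated random initializations
#'
#' Runs [fcm()] `n_runs` times with independent random-cube
#' initializations, aligns each run's clusters to a reference run — the
#' converged run with the lowest objective \eqn{J_M} — by optimal
#' one-to-one assignment on raw spatial similarity, averages the aligned
#' membership matrices entrywise (column sums remain 1), and recomputes
#' the centroids from the averaged memberships. Averaging without
#' alignment would mix unrelated clusters, since cluster indices are
#' arbitrary across runs; anchoring on the best-objective run keeps the
#' alignment target from being a run stuck in a poor local optimum.
#'
#' Runs that fail to converge are excluded from the average with a
#' warning; the count is recorded in the result.
#'
#' @inheritParams fcm
#' @param n_runs number of random restarts.
#' @param seed integer seed from which the per-run seeds are drawn.
#' @return An object of class `c("fcm_consensus", "fcm")`. In addition to
#'   the `fcm` fields: `n_runs`, `n_converged`, and `run_similarity`
#'   (n_runs x c matrix of each run's matched spatial similarities against
#'   the reference run; `NA` rows for non-converged runs).
#' @export
fcm_consensus <- function(x, c, m = 1.2, n_runs = 20L, seed = NULL,
                          tol = 1e-4, patience = 5L, max_iter = 1000L) {
  if (n_runs < 1L) stop("need at least one run")
  if (!is.null(seed)) {
    rs <- local_rng(seed)
    on.exit(restore_rng(rs))
  }
  run_seeds <- sample.int(.Machine$integer.max, n_runs)
  runs <- lapply(run_seeds, function(s)
    fcm(x, c, m = m, seed = s, tol = tol, patience = patience,
        max_iter = max_iter))
  ok <- vapply(runs, `[[`, TRUE, "converged")
  if (!any(ok)) stop("no run converged")
  if (any(!ok))
    warning(sum(!ok), " of ", n_runs,
            " runs did not converge and were excluded")
  objs <- vapply(runs, function(r) utils::tail(r$objective_trace, 1L),
                 numeric(1))
  ref <- runs[[which(ok)[which.min(objs[ok])]]]

  run_similarity <- matrix(NA_real_, n_runs, c)
  u_sum <- matrix(0, c, ncol(ref$u))
  for (j in which(ok)) {
    mt <- match_clusters(runs[[j]], ref, mode = "spatial")
    run_similarity[j, ] <- mt$scores[order(mt$assignment)]
    u_sum[mt$assignment, ] <- u_sum[mt$assignment, ] + runs[[j]]$u
  }
  u_bar <- u_sum / sum(ok)
  v_bar <- update_centroids(x, u_bar, m)

  out <- list(u = u_bar, v = v_bar, c = as.integer(c), m = m,
              xie_beni_trace = if (c >= 2)
                xie_beni(x, u_bar, v_bar, m) else numeric(0),
              objective_trace = fcm_objective(feature_matrix(x),
                                              u_bar, v_bar, m),
              converged = TRUE, n_iter = ref$n_iter,
              tol = tol, patience = patience,
              seed_info = list(method = "consensus", seed = seed,
                               run_seeds = run_seeds),
              n_runs = n_runs, n_converged = sum(ok),
              run_similarity = run_similarity,
              call = match.call())
  class(out) <- c("fcm_consensus", "fcm")
  out
}

#' @export
print.fcm_consensus <- function(x, ...) {
  cat("Consensus of", x$n_converged, "converged /", x$n_runs,
      "fuzzy c-means runs\n")
  NextMethod()
}

#' Run-to-run stability of a consensus solution
#'
#' Summarises how reproducible the clustering is across random restarts:
#' for each run, the minimum matched spatial similarity against the
#' reference run, and the fraction of runs in which every cluster was
#' recovered with similarity at or above `level`.
#'
#' @param solution an [fcm_consensus()] result.
#' @param level similarity level defining a "stable" run.
#' @return A list with `per_run_min`, `fraction_stable`, and the per-run,
#'   per-cluster similarity matrix.
#' @export
consensus_stability <- function(solution, level = 0.9) {
  stopifnot(inherits(solution, "fcm_consensus"))
  rs <- solution$run_similarity
  per_run_min <- apply(rs, 1L, min)
  ok <- !is.na(per_run_min)
  list(per_run_min = per_run_min,
       fraction_stable = mean(per_run_min[ok] >= level),
       level = level, run_similarity = rs)
}
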