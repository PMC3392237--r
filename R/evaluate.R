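#' Recovery accuracy of a clustering against planted ground truth
#'
#' Aligns the estimated clusters with the planted networks by optimal
#' one-to-one assignment on raw spatial similarity between membership
#' matrices, then scores each voxel as recovered if its (relabeled) hard
#' cluster attains the maximum of its true membership column.
#'
#' A planted hard label only exists where the true membership has a unique
#' maximum; voxels planted with tied 50/50 memberships have no hard label
#' by construction (their soft recovery is the business of
#' [classification_uncertainty()]). The primary `accuracy` is therefore
#' computed over voxels with a unique planted label; `accuracy_all`
#' additionally includes tied voxels, counting them correct when the
#' estimate attains one of the tied maxima.
#'
#' @param solution an [fcm()] object with as many clusters as planted
#'   networks.
#' @param truth ground-truth list from [simulate_bold()].
#' @return A list: `accuracy` (over voxels with a unique planted label),
#'   `accuracy_all` (all voxels, ties count either way), `assignment`
#'   (planted network index per estimated cluster), `matched_similarity`
#'   (per-cluster spatial similarity to its planted network).
#' @export
recovery_accuracy <- function(solution, truth) {
  U_true <- truth$true_membership
  if (ncol(U_true) != ncol(solution$u)) stop("voxel-set mismatch")
  if (nrow(U_true) != nrow(solution$u))
    stop("cluster count differs from planted network count")
  ref <- list(u = U_true)
  mt <- match_clusters(solution, ref, mode = "spatial")
  est_net <- mt$assignment[hard_labels(solution)]
  maxu <- apply(U_true, 2L, max)
  hit <- U_true[cbind(est_net, seq_along(est_net))] >= maxu - 1e-12
  unique_lab <- colSums(U_true >= rep(maxu, each = nrow(U_true)) - 1e-12) ==
    1L
  list(accuracy = mean(hit[unique_lab]), accuracy_all = mean(hit),
       assignment = mt$assignment, matched_similarity = mt$scores)
}

#' Identify the task-negative and task-positive clusters of a two-cluster
#' solution
#'
#' Labels each cluster of a c = 2 solution by the planted system over
#' whose voxels its mean membership is larger.
#'
#' @param solution an [fcm()] object with c = 2.
#' @param truth ground-truth list from [simulate_bold()].
#' @return Character vector of length 2: the system label of each cluster.
#' @export
system_labels <- function(solution, truth) {
  stopifnot(solution$c == 2L)
  tn <- truth$true_system == "task-negative"
  m1 <- c(mean(solution$u[1L, tn]), mean(solution$u[1L, !tn]))
  if (m1[1L] >= m1[2L]) c("task-negative", "task-positive")
  else c("task-positive", "task-negative")
}
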