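# small planted structures used across test files

tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(n_networks = 2, system_of_network = c("task-negative",
                                               "task-positive"),
         voxels_per_network = 20, fuzzy_fraction = 0, n_frames = 60,
         seed = 1L),
    list(...))
  do.call(hierarchy_spec, args)
}

# a voxel_ts from a plain matrix with a trivial line of voxel coordinates
ts_from_matrix <- function(values, frame_interval = 2.16,
                           run_boundaries = 0L) {
  n <- nrow(values)
  voxel_ts(values, cbind(seq_len(n) - 1L, 0L, 0L),
           frame_interval = frame_interval,
           run_boundaries = run_boundaries)
}

# textbook Pearson correlation, written out as the independent oracle
pearson_oracle <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# direct evaluation of the membership formula for one point
membership_oracle <- function(x, V, m) {
  d <- sqrt(rowSums(sweep(V, 2L, x, "-")^2))
  if (any(d == 0)) {
    u <- numeric(nrow(V)); u[which(d == 0)[1L]] <- 1
    return(u)
  }
  sapply(seq_len(nrow(V)), function(i) 1 / sum((d[i] / d)^(2 / (m - 1))))
}

# exhaustive best permutation for small assignment problems
best_permutation <- function(s) {
  n <- nrow(s)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1L, function(p) !anyDuplicated(p)), ,
                 drop = FALSE]
  tot <- apply(perms, 1L, function(p) sum(s[cbind(seq_len(n), p)]))
  list(perm = as.integer(perms[which.max(tot), ]), total = max(tot))
}
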