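#' Spatial similarity of two membership (weight) vectors
#'
#' Normalized inner product between two voxelwise weight vectors. In `raw`
#' mode this is the plain cosine \eqn{\langle u_1, u_2\rangle /
#' (\|u_1\|\,\|u_2\|)}, which equals 1 for identical vectors. In `centered`
#' mode each vector's mean is removed first; membership vectors are
#' nonnegative, so centering is what allows negative spatial similarities
#' (e.g. between a cluster and the system it does not belong to).
#'
#' @param u1,u2 numeric vectors of equal length (one weight per voxel).
#' @param centering `"raw"` or `"centered"`.
#' @return Similarity in [-1, 1].
#' @export
spatial_similarity <- function(u1, u2, centering = c("raw", "centered")) {
  centering <- match.arg(centering)
  if (length(u1) != length(u2)) stop("weight vectors differ in length")
  if (centering == "centered") {
    u1 <- u1 - mean(u1)
    u2 <- u2 - mean(u2)
  }
  n1 <- sqrt(sum(u1^2)); n2 <- sqrt(sum(u2^2))
  if (n1 == 0 || n2 == 0) {
    if (centering == "centered") return(0)  # constant vector: no direction
    stop("zero-norm weight vector")
  }
  max(-1, min(1, sum(u1 * u2) / (n1 * n2)))
}

#' Temporal similarity of two centroid vectors
#'
#' Normalized inner product \eqn{\langle v_1, v_2\rangle /
#' (\|v_1\|\,\|v_2\|)} between two cluster centres. With correlation-map
#' features the centroids live in correlation space rather than literal
#' time-course space; the inner product measures how similarly the two
#' clusters relate to the rest of the brain, and is negative for
#' anticorrelated systems.
#'
#' @param v1,v2 numeric centroid vectors of equal length.
#' @return Similarity in [-1, 1].
#' @export
temporal_similarity <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("centroid vectors differ in length")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero-norm centroid vector")
  max(-1, min(1, sum(v1 * v2) / (n1 * n2)))
}

# all-pairs similarity matrix between the clusters of two solutions
pairwise_similarity <- function(solA, solB, mode = c("spatial", "temporal"),
                                centering = "raw") {
  mode <- match.arg(mode)
  if (mode == "spatial") {
    a <- solA$u; b <- solB$u
    if (ncol(a) != ncol(b)) stop("solutions cover different voxel sets")
    outer(seq_len(nrow(a)), seq_len(nrow(b)),
          Vectorize(function(i, j)
            spatial_similarity(a[i, ], b[j, ], centering)))
  } else {
    a <- solA$v; b <- solB$v
    if (ncol(a) != ncol(b)) stop("solutions cover different feature spaces")
    outer(seq_len(nrow(a)), seq_len(nrow(b)),
          Vectorize(function(i, j) temporal_similarity(a[i, ], b[j, ])))
  }
}

# optimal one-to-one assignment maximizing total similarity; rows of `s`
# are assigned to columns. Solved as maximum-weight perfect matching on the
# complete bipartite graph after shifting weights positive (a constant
# shift does not change the optimal perfect matching).
assign_clusters <- function(s) {
  stopifnot(nrow(s) == ncol(s))
  w <- s - min(s) + 1
  g <- igraph::graph_from_biadjacency_matrix(w, weighted = TRUE)
  m <- igraph::max_bipartite_match(g)$matching
  # matching maps row-vertices 1..a to column-vertices a+1..a+b
  as.integer(m[seq_len(nrow(s))]) - nrow(s)
}

#' Match the clusters of one solution to a reference solution
#'
#' With equal cluster counts, finds the one-to-one assignment maximizing
#' the total similarity (optimal assignment). With unequal counts, each
#' cluster of `solution` is labeled by its best-matching (argmax) reference
#' cluster, many-to-one allowed; clusters sharing a reference stem are
#' suffixed `1`, `2`, ... in order of decreasing similarity, mirroring the
#' convention of naming the two subdivisions of a network NET1 and NET2.
#'
#' @param solution,reference `fcm` objects over the same voxel set.
#' @param mode `"spatial"` (membership vectors) or `"temporal"`
#'   (centroids).
#' @param centering for spatial mode, `"raw"` (default, used for matching)
#'   or `"centered"`.
#' @param reference_labels optional character labels of the reference
#'   clusters (default `C1..Cc`).
#' @return A list of class `cluster_match`: `assignment` (reference index
#'   per cluster of `solution`), `labels` (character labels), `scores`
#'   (similarity of each matched pair), `similarity` (the full a x b
#'   matrix), `mode`, `centering`.
#' @export
match_clusters <- function(solution, reference,
                           mode = c("spatial", "temporal"),
                           centering = "raw", reference_labels = NULL) {
  mode <- match.arg(mode)
  s <- pairwise_similarity(solution, reference, mode, centering)
  cA <- nrow(s); cB <- ncol(s)
  if (is.null(reference_labels)) reference_labels <- paste0("C", seq_len(cB))
  if (cA == cB) {
    asg <- assign_clusters(s)
    labels <- reference_labels[asg]
  } else {
    asg <- apply(s, 1L, which.max)
    labels <- reference_labels[asg]
    for (ref in unique(asg[duplicated(asg)])) {
      idx <- which(asg == ref)
      ord <- order(s[cbind(idx, ref)], decreasing = TRUE)
      labels[idx[ord]] <- paste0(reference_labels[ref], seq_along(idx))
    }
  }
  structure(
    list(assignment = asg, labels = labels,
         scores = s[cbind(seq_len(cA), asg)], similarity = s,
         mode = mode, centering = if (mode == "spatial") centering else NA),
    class = "cluster_match")
}

#' @export
print.cluster_match <- function(x, ...) {
  cat("Cluster matching (", x$mode,
      if (!is.na(x$centering)) paste0(", ", x$centering), "):\n", sep = "")
  for (i in seq_along(x$assignment))
    cat(sprintf("  cluster %d -> %s (similarity %.3f)\n",
                i, x$labels[i], x$scores[i]))
  invisible(x)
}

#' Cross-solution similarity matrix
#'
#' All-pairs spatial (membership) or temporal (centroid) similarities
#' between the clusters of two solutions, e.g. a fine parcellation against
#' the two-system solution. Rows are labeled via [match_clusters()] against
#' the second solution.
#'
#' @param solA,solB `fcm` objects over the same voxel set.
#' @param mode `"spatial"` or `"temporal"`.
#' @param centering for spatial mode only: `"raw"` or `"centered"`.
#' @param labelsB optional labels for the clusters of `solB`.
#' @return A list of class `similarity_matrix` with `values`
#'   (c_A x c_B matrix), row/column labels, `mode`, `centering`.
#' @export
cross_solution_matrix <- function(solA, solB,
                                  mode = c("spatial", "temporal"),
                                  centering = "raw", labelsB = NULL) {
  mode <- match.arg(mode)
  if (mode == "temporal" && !identical(centering, "raw"))
    stop("temporal similarity has no centering option")
  s <- pairwise_similarity(solA, solB, mode, centering)
  if (is.null(labelsB)) labelsB <- paste0("C", seq_len(nrow(solB$u)))
  mt <- match_clusters(solA, solB, mode = "spatial", centering = "raw",
                       reference_labels = labelsB)
  dimnames(s) <- list(mt$labels, labelsB)
  structure(list(values = s, row_labels = mt$labels, col_labels = labelsB,
                 mode = mode,
                 centering = if (mode == "spatial") centering else NA),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("Cross-solution ", x$mode, " similarity",
      if (!is.na(x$centering)) paste0(" (", x$centering, ")"),
      ":\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}

#' @export
plot.similarity_matrix <- function(x, ...) {
  v <- x$values[nrow(x$values):1, , drop = FALSE]
  graphics::image(t(v), zlim = c(-1, 1), axes = FALSE,
                  col = grDevices::hcl.colors(65, "Blue-Red 2"),
                  main = paste("Cross-solution", x$mode, "similarity"), ...)
  graphics::axis(1, at = seq(0, 1, length.out = ncol(v)),
                 labels = colnames(v), las = 2, cex.axis = 0.8)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(v)),
                 labels = rownames(v), las = 2, cex.axis = 0.8)
  invisible(x)
}
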