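#' Specification of a planted hierarchical network structure
#'
#' Describes the two-level (system -> network) modular covariance planted in
#' synthetic BOLD data: a set of networks, each belonging to either the
#' task-negative or task-positive system, with a configurable fraction of
#' "fuzzy" voxels whose factor loadings are split between two networks.
#'
#' The generative model is a linear factor model (see [simulate_bold()]),
#' chosen because it admits a closed-form expected correlation matrix
#' ([expected_correlation()]) usable as an analytic oracle.
#'
#' Defaults emulate the study conditions the pipeline is validated under:
#' seven networks, three task-negative and four task-positive, 100 voxels
#' each, within-network loading sqrt(0.5) against unit-variance factors and
#' noise sd sqrt(0.5) (within-network correlation around 0.5), a modest
#' shared system signal with opposite sign across systems (anticorrelated
#' systems), TR 2.16 s, 300 frames.
#'
#' @param n_networks number of networks (>= 2).
#' @param system_of_network character vector of length `n_networks` with
#'   values `"task-negative"` or `"task-positive"`; each system needs at
#'   least one network. `NULL` splits the networks roughly in half
#'   (task-negative first).
#' @param voxels_per_network integer vector (recycled) of voxels per network.
#' @param fuzzy_fraction proportion in [0, 1) of voxels per network whose
#'   loadings are split 50/50 with a partner network.
#' @param fuzzy_pairing `"cross-system"` (default) pairs each network with
#'   a network of the opposite system, so shared-membership voxels sit
#'   between the two anticorrelated systems — where uncertainty
#'   concentrates on real data; `"within-system"` pairs within a system.
#' @param loading_within factor loading on the network signal (unitless,
#'   against unit-variance factors).
#' @param loading_system loading on the shared system signal; its sign is
#'   +1 for task-positive and -1 for task-negative networks.
#' @param noise_sd sd of white voxel noise.
#' @param n_frames number of frames (>= 10).
#' @param frame_interval TR in seconds.
#' @param seed integer RNG seed making the simulation deterministic.
#' @return An object of class `hierarchy_spec`.
#' @export
hierarchy_spec <- function(n_networks = 7,
                           system_of_network = NULL,
                           voxels_per_network = 100,
                           fuzzy_fraction = 0.1,
                           fuzzy_pairing = c("cross-system",
                                             "within-system"),
                           loading_within = sqrt(0.5),
                           loading_system = 0.35,
                           noise_sd = sqrt(0.5),
                           n_frames = 300,
                           frame_interval = 2.16,
                           seed = 1L) {
  n_networks <- as.integer(n_networks)
  if (n_networks < 2L) stop("need at least 2 networks")
  if (is.null(system_of_network))
    system_of_network <- rep(c("task-negative", "task-positive"),
                             c(n_networks %/% 2L,
                               n_networks - n_networks %/% 2L))
  system_of_network <- rep_len(as.character(system_of_network), n_networks)
  if (!all(system_of_network %in% c("task-negative", "task-positive")))
    stop("systems must be 'task-negative' or 'task-positive'")
  if (length(unique(system_of_network)) < 2L)
    stop("need at least one network in each system")
  voxels_per_network <- rep_len(as.integer(voxels_per_network), n_networks)
  if (any(voxels_per_network <= 0L)) stop("voxel counts must be positive")
  fuzzy_pairing <- match.arg(fuzzy_pairing)
  if (fuzzy_fraction < 0 || fuzzy_fraction >= 1)
    stop("'fuzzy_fraction' must lie in [0, 1)")
  if (!all(is.finite(c(loading_within, loading_system, noise_sd))))
    stop("loadings and noise sd must be finite")
  if (as.integer(n_frames) < 10L) stop("need at least 10 frames")
  structure(
    list(n_networks = n_networks, system_of_network = system_of_network,
         voxels_per_network = voxels_per_network,
         fuzzy_fraction = fuzzy_fraction, fuzzy_pairing = fuzzy_pairing,
         loading_within = loading_within,
         loading_system = loading_system, noise_sd = noise_sd,
         n_frames = as.integer(n_frames), frame_interval = frame_interval,
         seed = as.integer(seed)),
    class = "hierarchy_spec")
}

#' @export
print.hierarchy_spec <- function(x, ...) {
  cat("Hierarchy spec:", x$n_networks, "networks,",
      sum(x$voxels_per_network), "voxels,", x$n_frames, "frames\n")
  cat("  systems:", paste(x$system_of_network, collapse = ", "), "\n")
  cat("  loadings: within", format(x$loading_within, digits = 4),
      "| system", format(x$loading_system, digits = 4),
      "| noise sd", format(x$noise_sd, digits = 4),
      "| fuzzy", x$fuzzy_fraction, "\n")
  invisible(x)
}

# loading matrix L (n_voxels x (n_networks + 1)) and bookkeeping shared by
# the simulator and the analytic oracle. Last column is the signed system
# loading. Fuzzy voxels split the within loading over two networks of the
# same system, each at loading_within/sqrt(2) so total within variance is
# preserved; normalized loadings give the 0.5/0.5 ground-truth membership.
plant_loadings <- function(spec) {
  nets <- spec$n_networks
  nv <- sum(spec$voxels_per_network)
  network_of_voxel <- rep(seq_len(nets), spec$voxels_per_network)
  sys_sign <- ifelse(spec$system_of_network == "task-positive", 1, -1)

  # partner network for fuzzy voxels: by default the next network of the
  # opposite system (cyclic), otherwise the next of the same system
  pairing <- if (is.null(spec$fuzzy_pairing)) "cross-system"
             else spec$fuzzy_pairing
  partner <- integer(nets)
  for (i in seq_len(nets)) {
    pool <- if (pairing == "cross-system")
      which(spec$system_of_network != spec$system_of_network[i])
    else setdiff(which(spec$system_of_network ==
                       spec$system_of_network[i]), i)
    if (!length(pool)) pool <- setdiff(seq_len(nets), i)
    nxt <- pool[pool > i]
    partner[i] <- if (length(nxt)) nxt[1L] else pool[1L]
  }

  L <- matrix(0, nv, nets)
  boundary <- logical(nv)
  offset <- 0L
  for (i in seq_len(nets)) {
    nv_i <- spec$voxels_per_network[i]
    rows <- offset + seq_len(nv_i)
    n_fuzzy <- round(spec$fuzzy_fraction * nv_i)
    core <- rows[seq_len(nv_i - n_fuzzy)]
    fuzz <- setdiff(rows, core)
    L[core, i] <- spec$loading_within
    if (length(fuzz)) {
      L[fuzz, i] <- spec$loading_within / sqrt(2)
      L[fuzz, partner[i]] <- spec$loading_within / sqrt(2)
      boundary[fuzz] <- TRUE
    }
    offset <- offset + nv_i
  }
  # each voxel's system loading follows its membership-weighted system
  # sign: core voxels get their network's sign, shared voxels bridging
  # the two systems get zero net system drive
  W <- L / pmax(rowSums(L), .Machine$double.eps)
  sys_loading <- spec$loading_system * as.numeric(W %*% sys_sign)
  list(L = cbind(L, sys_loading), network_of_voxel = network_of_voxel,
       boundary = boundary, sys_sign = sys_sign)
}

#' Simulate BOLD-like voxel time series with planted network structure
#'
#' Draws from the factor model
#' \deqn{x_v(t) = \sum_i w_{vi} s_i(t) + \lambda_v g(t) + \sigma \epsilon_v(t) + 1000,}
#' where the \eqn{s_i} are iid standard-normal network signals, \eqn{g} is a
#' shared system signal entering with loading `+loading_system` for
#' task-positive and `-loading_system` for task-negative voxels, and
#' \eqn{\epsilon} is white noise. The constant offset realises the mode-1000
#' intensity convention (the temporal mean of every voxel is exactly 1000).
#' Voxels are laid out in contiguous cuboid blocks per network on a 3-D
#' grid, so that cube-based random initialization is meaningful.
#'
#' @param spec a [hierarchy_spec()].
#' @return A list with components `ts` (a [voxel_ts()]) and `truth`, the
#'   ground truth: `true_membership` (network x voxel, columns sum to 1),
#'   `true_network` / `true_system` labels per voxel, and `boundary_mask`
#'   flagging voxels with split loadings.
#' @export
simulate_bold <- function(spec) {
  stopifnot(inherits(spec, "hierarchy_spec"))
  pl <- plant_loadings(spec)
  nv <- nrow(pl$L)
  nt <- spec$n_frames

  rs <- local_rng(spec$seed)
  on.exit(restore_rng(rs))
  factors <- matrix(stats::rnorm((spec$n_networks + 1L) * nt),
                    spec$n_networks + 1L, nt)
  eps <- matrix(stats::rnorm(nv * nt), nv, nt)
  x <- pl$L %*% factors + spec$noise_sd * eps
  x <- x - rowMeans(x) + 1000          # mode-1000 convention

  coords <- network_block_coords(spec$voxels_per_network)
  ts <- voxel_ts(x, coords, frame_interval = spec$frame_interval)

  W <- t(pl$L[, seq_len(spec$n_networks), drop = FALSE])
  cs <- colSums(W)
  U <- sweep(W, 2L, cs, "/")
  truth <- list(
    true_membership = U,
    true_network = pl$network_of_voxel,
    true_system = spec$system_of_network[pl$network_of_voxel],
    boundary_mask = pl$boundary)
  list(ts = ts, truth = truth, spec = spec)
}

# contiguous 4x4xH cuboid of grid coordinates per network, stacked along z
network_block_coords <- function(voxels_per_network) {
  out <- vector("list", length(voxels_per_network))
  z0 <- 0L
  for (i in seq_along(voxels_per_network)) {
    nv_i <- voxels_per_network[i]
    h <- ceiling(nv_i / 16)
    g <- expand.grid(x = 0:3, y = 0:3, z = z0 + seq_len(h) - 1L)
    out[[i]] <- as.matrix(g[seq_len(nv_i), , drop = FALSE])
    z0 <- z0 + h + 1L                  # gap so cubes never straddle networks
  }
  coords <- do.call(rbind, out)
  dimnames(coords) <- NULL
  coords
}

#' Analytic correlation matrix implied by a hierarchy specification
#'
#' Closed form for the factor model of [simulate_bold()]:
#' \eqn{\Sigma = L L^\top + \sigma^2 I} with the planted loading matrix
#' \eqn{L}, converted to a correlation matrix. The empirical correlation of
#' simulated data converges to this as the number of frames grows, which
#' makes it the test oracle for every downstream stage.
#'
#' @param spec a [hierarchy_spec()].
#' @return n_voxels x n_voxels correlation matrix.
#' @export
expected_correlation <- function(spec) {
  stopifnot(inherits(spec, "hierarchy_spec"))
  L <- plant_loadings(spec)$L
  S <- tcrossprod(L)
  diag(S) <- diag(S) + spec$noise_sd^2
  stats::cov2cor(S)
}

#' Write a synthetic dataset to disk
#'
#' Persists the simulated volume and mask as NIfTI, the ground truth as CSV
#' (voxel id, grid coordinates, per-network true weights, system label,
#' boundary flag) and the generating specification as JSON.
#'
#' @param sim result of [simulate_bold()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named vector of the four file paths.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(volume = file.path(dir, "bold.nii"),
             mask = file.path(dir, "mask.nii"),
             truth = file.path(dir, "ground_truth.csv"),
             spec = file.path(dir, "spec.json"))
  write_timeseries(sim$ts, paths[["volume"]], paths[["mask"]])
  U <- t(sim$truth$true_membership)
  colnames(U) <- paste0("w_net", seq_len(ncol(U)))
  df <- data.frame(voxel = seq_len(nrow(U)) - 1L,
                   i = sim$ts$coords[, 1L], j = sim$ts$coords[, 2L],
                   k = sim$ts$coords[, 3L], U,
                   network = sim$truth$true_network,
                   system = sim$truth$true_system,
                   boundary = as.integer(sim$truth$boundary_mask))
  utils::write.csv(df, paths[["truth"]], row.names = FALSE)
  jsonlite::write_json(unclass(sim$spec), paths[["spec"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# seed handling in the style of stats::simulate: set the seed locally and
# hand back the previous global state
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}
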