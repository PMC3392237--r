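#' Assemble and validate a pipeline configuration
#'
#' A declarative description of a full analysis: input source (either a
#' synthetic-data specification or NIfTI paths), preprocessing parameters,
#' clustering parameters, and the output directory. Unknown keys are
#' rejected so that typos fail loudly rather than silently using a
#' default.
#'
#' @param config a named list, or path to a JSON file holding one. Keys:
#'   \describe{
#'     \item{output_dir}{directory for all artifacts (required).}
#'     \item{simulate}{list of [hierarchy_spec()] arguments; mutually
#'       exclusive with `volume`/`mask`.}
#'     \item{volume, mask}{NIfTI input paths.}
#'     \item{regressors}{optional path to a whitespace/CSV table, one row
#'       per frame.}
#'     \item{cutoff}{low-pass cutoff in Hz (default 0.1).}
#'     \item{dvars_threshold}{censoring threshold in percent (default 0.5).}
#'     \item{global_signal}{regress out the in-mask mean (default TRUE).}
#'     \item{m}{fuzzifier (default 1.2).}
#'     \item{tol, patience, max_iter}{convergence controls.}
#'     \item{runs}{random restarts per c (default 20).}
#'     \item{c_values}{cluster numbers to fit and compare (default 2:20).}
#'     \item{seed}{master RNG seed (default 1).}
#'     \item{write_nifti}{write membership/uncertainty volumes (default
#'       TRUE when grid geometry is available).}
#'   }
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  known <- c("output_dir", "simulate", "volume", "mask", "regressors",
             "cutoff", "dvars_threshold", "global_signal", "m", "tol",
             "patience", "max_iter", "runs", "c_values", "seed",
             "write_nifti", "frame_interval", "run_boundaries")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(config$output_dir)) stop("'output_dir' is required")
  has_sim <- !is.null(config$simulate)
  has_vol <- !is.null(config$volume)
  if (has_sim == has_vol)
    stop("exactly one of 'simulate' or 'volume'+'mask' must be given")
  if (has_vol && is.null(config$mask))
    stop("'mask' is required alongside 'volume'")
  defaults <- list(cutoff = 0.1, dvars_threshold = 0.5,
                   global_signal = TRUE, m = 1.2, tol = 1e-4,
                   patience = 5L, max_iter = 1000L, runs = 20L,
                   c_values = 2:20, seed = 1L, write_nifti = TRUE,
                   frame_interval = NULL, run_boundaries = 0L)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (config$m <= 1) stop("'m' must exceed 1")
  if (config$dvars_threshold < 0) stop("'dvars_threshold' must be >= 0")
  config$c_values <- sort(unique(as.integer(config$c_values)))
  if (any(config$c_values < 2L)) stop("'c_values' must be >= 2")
  class(config) <- "pipeline_config"
  config
}

#' Run the full parcellation pipeline from a configuration
#'
#' Executes, in order: input acquisition (simulation or NIfTI loading),
#' temporal preprocessing and DVARS censoring, correlation-map features,
#' consensus clustering at every requested c with cluster dispersion and
#' local-minimum reporting, cross-solution similarity against the
#' coarsest solution, and classification uncertainty per solution. Every
#' artifact is written under `output_dir` together with a manifest
#' (parameters, seeds, package version, MD5 checksums), so a rerun with
#' the same configuration reproduces the numeric artifacts.
#'
#' @param config a [pipeline_config()] (or list / JSON path coercible to
#'   one).
#' @return Invisibly, a list with the in-memory results: `ts`, `censor`,
#'   `features`, `curve`, `solutions`, `uncertainty`, `cross`, and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  ts <- stage("input", {
    if (!is.null(cfg$simulate)) {
      sim <- do.call(hierarchy_spec, cfg$simulate)
      simd <- simulate_bold(sim)
      truth <- simd$truth
      write_synthetic_dataset(simd, file.path(cfg$output_dir, "input"))
      simd$ts
    } else {
      load_timeseries(cfg$volume, cfg$mask,
                      frame_interval = cfg$frame_interval,
                      run_boundaries = cfg$run_boundaries)
    }
  })

  regressors <- stage("regressors", {
    if (is.null(cfg$regressors)) NULL
    else as.matrix(utils::read.table(cfg$regressors, header = FALSE))
  })

  prep <- stage("preprocess",
    preprocess_bold(ts, regressors = regressors, cutoff = cfg$cutoff,
                    dvars_threshold = cfg$dvars_threshold,
                    global_signal = cfg$global_signal))
  utils::write.table(as.integer(prep$censor$keep),
                     file.path(cfg$output_dir, "frame_keep.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(
    data.frame(frame = seq_along(prep$censor$dvars) - 1L,
               dvars_pct = prep$censor$dvars,
               keep = as.integer(prep$censor$keep)),
    file.path(cfg$output_dir, "dvars.csv"), row.names = FALSE)

  cs <- cfg$c_values
  curve <- stage("cluster",
    fcm_sweep(prep$features, m = cfg$m, c_values = cs,
              runs_per_c = cfg$runs, seed = cfg$seed, tol = cfg$tol,
              patience = cfg$patience, max_iter = cfg$max_iter))
  utils::write.csv(as.data.frame(curve),
                   file.path(cfg$output_dir, "dispersion.csv"),
                   row.names = FALSE)
  solutions <- lapply(cs, function(cc) sweep_solution(curve, cc))
  names(solutions) <- cs

  cross <- list()
  unc <- list()
  ref <- solutions[[1L]]
  for (i in seq_along(solutions)) {
    cc <- cs[i]
    sol <- solutions[[i]]
    if (i > 1L) {
      for (md in c("spatial", "temporal")) {
        sm <- cross_solution_matrix(sol, ref, mode = md,
                                    centering = if (md == "spatial")
                                      "centered" else "raw")
        utils::write.csv(sm$values,
                         file.path(cfg$output_dir,
                                   sprintf("cross_%s_c%d_vs_c%d.csv",
                                           md, cc, cs[1L])))
        cross[[sprintf("%s_c%d", md, cc)]] <- sm
      }
    }
    cu <- classification_uncertainty(sol)
    unc[[as.character(cc)]] <- cu
    assoc <- uncertainty_association(cu, sol)
    utils::write.csv(data.frame(cluster = names(assoc),
                                association = as.numeric(assoc)),
                     file.path(cfg$output_dir,
                               sprintf("uncertainty_assoc_c%d.csv", cc)),
                     row.names = FALSE)
    if (isTRUE(cfg$write_nifti)) {
      write_voxel_map(as.numeric(cu), ts,
                      file.path(cfg$output_dir,
                                sprintf("uncertainty_c%d.nii", cc)))
      for (k in seq_len(sol$c))
        write_voxel_map(sol$u[k, ], ts,
                        file.path(cfg$output_dir,
                                  sprintf("membership_c%d_cluster%d.nii",
                                          cc, k)))
    }
  }

  manifest <- list(
    package = "fcmparc",
    version = as.character(utils::packageVersion("fcmparc")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg),
    local_minima = if (nrow(curve) >= 3L && all(diff(curve$c) == 1L))
      local_minima(curve) else integer(0),
    artifacts = NULL)
  files <- list.files(cfg$output_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$artifacts <- data.frame(
    file = substring(files, nchar(cfg$output_dir) + 2L),
    md5 = as.character(tools::md5sum(files)), row.names = NULL)
  jsonlite::write_json(manifest,
                       file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(ts = ts, truth = truth, censor = prep$censor,
                 features = prep$features, curve = curve,
                 solutions = solutions, cross = cross, uncertainty = unc,
                 manifest = manifest))
}
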