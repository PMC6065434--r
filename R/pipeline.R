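#' Write / read a recording as TSV
#'
#' Recordings are stored as plain tab-separated text, one column per channel
#' with a header row of channel labels; the sampling rate lives in the
#' dataset manifest.
#'
#' @param recording A `meg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "meg_recording"))
  data.table::fwrite(as.data.frame(recording$data), path, sep = "\t")
  invisible(path)
}

#' @rdname write_recording
#' @param fs,subject_id Metadata for the reconstructed object (normally
#'   supplied by the manifest).
#' @export
read_recording <- function(path, fs, subject_id = basename(path)) {
  if (!file.exists(path)) stop(sprintf("recording file not found: %s", path))
  M <- as.matrix(data.table::fread(path, sep = "\t"))
  meg_recording(M, fs, subject_id = subject_id,
                channel_labels = colnames(M))
}

#' Write / read a dataset manifest
#'
#' The manifest is a YAML file listing the per-subject recording files, the
#' sampling rate, and channel labels (optionally with MNI coordinates).
#'
#' @param recordings List of `meg_recording`.
#' @param dir Directory receiving the manifest and per-subject TSV files.
#' @param coordinates Optional channels x 3 matrix of region coordinates.
#' @return Path of the manifest file.
#' @export
write_manifest <- function(recordings, dir, coordinates = NULL) {
  recordings <- check_recordings(recordings)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(recordings))
  for (s in seq_along(recordings)) {
    files[s] <- sprintf("subject_%s.tsv", recordings[[s]]$subject_id)
    write_recording(recordings[[s]], file.path(dir, files[s]))
  }
  manifest <- list(
    fs = recordings[[1L]]$fs,
    channel_labels = recordings[[1L]]$channel_labels,
    subjects = lapply(seq_along(recordings), function(s)
      list(id = as.character(recordings[[s]]$subject_id), file = files[s]))
  )
  if (!is.null(coordinates))
    manifest$coordinates <- apply(coordinates, 1L, as.numeric, simplify = FALSE)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  path
}

#' @rdname write_manifest
#' @param path Manifest file path.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  manifest <- yaml::read_yaml(path)
  dir <- dirname(path)
  recs <- lapply(manifest$subjects, function(sub) {
    f <- file.path(dir, sub$file)
    if (!file.exists(f))
      stop(sprintf("manifest lists missing recording file: %s", sub$file))
    r <- read_recording(f, manifest$fs, subject_id = sub$id)
    if (!is.null(manifest$channel_labels)) {
      if (length(manifest$channel_labels) != ncol(r$data))
        stop(sprintf("channel label count does not match %s", sub$file))
      r$channel_labels <- manifest$channel_labels
      colnames(r$data) <- manifest$channel_labels
    }
    r
  })
  recs
}

#' Pipeline configuration
#'
#' Bundles every stage's options for [run_pipeline()]. Either a simulation
#' (`sim`) or a dataset manifest (`manifest`) supplies the input recordings.
#'
#' @param sim Optional list with `config` (a `simulation_config`) and `specs`
#'   (list of `state_spec`), e.g. from [two_state_demo()].
#' @param manifest Optional path to a dataset manifest.
#' @param K Number of HMM states.
#' @param window A `lag_window`; its `fs` is overridden by the data's.
#' @param n_components PCA components (default twice the channel count).
#' @param signflip Run sign-flip disambiguation before embedding.
#' @param signflip_lags Lag offsets for the sign-flip correlations.
#' @param fit FitOptions overrides, passed to [fit_options()].
#' @param mt Multitaper overrides, passed to [multitaper_config()].
#' @param n_modes NNMF frequency modes.
#' @param out_dir Output directory (NULL for no file output).
#' @param seed Master seed; recorded in the outputs.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, manifest = NULL, K = 2L,
                            window = lag_window(), n_components = NULL,
                            signflip = FALSE, signflip_lags = -10:10,
                            fit = list(), mt = list(), n_modes = 4L,
                            out_dir = NULL, seed = 1L) {
  if (is.null(sim) && is.null(manifest))
    stop("provide either `sim` or `manifest`")
  structure(list(sim = sim, manifest = manifest, K = as.integer(K),
                 window = window, n_components = n_components,
                 signflip = signflip, signflip_lags = signflip_lags,
                 fit = fit, mt = mt, n_modes = as.integer(n_modes),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load or simulate the recordings; standardize;
#' optionally disambiguate channel signs; time-delay embed and PCA-reduce;
#' fit the variational HMM; estimate state-wise spectra and NNMF frequency
#' modes; compute temporal statistics and state distances. With a fixed seed
#' and full-batch inference, re-running reproduces the state time courses
#' exactly. If `out_dir` is set, per-stage tables are written as TSV and the
#' configuration as YAML.
#'
#' @param config A `pipeline_config`.
#' @return A `pipeline_result`: list with `recordings`, `embedded`, `fit`
#'   (posterior + state time courses + Viterbi), `spectra`, `modes`,
#'   `temporal` (visits, intervals, fractional occupancy), `distances`
#'   (per decomposition mode), `flips` (if sign flipping ran), `ground_truth`
#'   (if simulated), and `report` (stage log and written files).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(seed = config$seed, stages = character(0), files = character(0),
                 warnings = character(0))
  note <- function(stage) {
    report$stages <<- c(report$stages, stage)
    message(sprintf("[tdehmm] %s", stage))
  }
  ground_truth <- NULL
  if (!is.null(config$sim)) {
    note("simulate: generating Markov-switching oscillator dataset")
    sim <- simulate_dataset(config$sim$config, config$sim$specs)
    recordings <- sim$recordings
    ground_truth <- sim$ground_truth
  } else {
    note(sprintf("load: reading manifest %s", config$manifest))
    recordings <- read_manifest(config$manifest)
  }
  fs <- recordings[[1L]]$fs
  note("standardize: per-subject unit-variance channels")
  recordings <- standardize(recordings)
  flips <- NULL
  if (isTRUE(config$signflip)) {
    note("signflip: greedy alignment of channel polarity across subjects")
    rho <- lagged_partial_correlations(recordings, config$signflip_lags)
    sf <- greedy_signflip(rho, n_restarts = 10L, seed = config$seed)
    flips <- sf$flips
    recordings <- apply_flips(recordings, flips)
  }
  note("embed: time-delay embedding + PCA")
  window <- config$window
  window$fs <- fs
  emb <- embed_dataset(recordings, window, config$n_components)
  note(sprintf("fit: variational HMM with K = %d", config$K))
  fopt <- do.call(fit_options,
                  utils::modifyList(list(K = config$K, seed = config$seed),
                                    config$fit))
  fit <- hmm_fit(emb, fopt)
  note("spectra: state-wise multitaper + NNMF frequency modes")
  mt <- do.call(multitaper_config,
                utils::modifyList(list(fs = fs), config$mt))
  spectra <- statewise_multitaper(recordings, fit$stc$gamma, mt)
  modes <- nnmf_frequency_modes(spectra, config$n_modes,
                                seed = config$seed, n_restarts = 5L)
  note("stats: temporal dynamics and state distances")
  visits <- do.call(rbind, lapply(seq_along(fit$viterbi), function(s)
    extract_visits(fit$viterbi[[s]], fs, subject_id = s)))
  intervals <- state_intervals(visits, fs)
  fo <- t(vapply(fit$stc$gamma, fractional_occupancy,
                 numeric(ncol(fit$stc$gamma[[1L]]))))
  covs <- state_autocovariances(recordings, fit$stc, window)
  distances <- list(
    full = state_distance_decomposition(covs, "full"),
    power_only = state_distance_decomposition(covs, "power_only"),
    coherence_only = state_distance_decomposition(covs, "coherence_only"))
  result <- structure(list(
    recordings = recordings, embedded = emb, fit = fit, spectra = spectra,
    modes = modes,
    temporal = list(visits = visits, intervals = intervals,
                    fractional_occupancy = fo),
    distances = distances, flips = flips, ground_truth = ground_truth,
    report = report), class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    result$report$files <- write_pipeline_outputs(result, config)
  }
  result
}

write_pipeline_outputs <- function(result, config) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(obj, name) {
    p <- file.path(dir, name)
    data.table::fwrite(obj, p, sep = "\t")
    files <<- c(files, p)
  }
  for (s in seq_along(result$fit$stc$gamma)) {
    put(as.data.frame(result$fit$stc$gamma[[s]]),
        sprintf("gamma_subject%02d.tsv", s))
    put(data.frame(state = result$fit$viterbi[[s]]),
        sprintf("viterbi_subject%02d.tsv", s))
  }
  put(result$temporal$visits, "visits.tsv")
  put(result$temporal$intervals, "intervals.tsv")
  put(as.data.frame(result$temporal$fractional_occupancy),
      "fractional_occupancy.tsv")
  put(as.data.frame(result$modes$H), "frequency_modes_H.tsv")
  put(data.frame(component = seq_along(result$embedded$explained_variance_fraction),
                 explained_variance = result$embedded$explained_variance_fraction),
      "pca_explained_variance.tsv")
  for (m in names(result$distances))
    put(as.data.frame(result$distances[[m]]), sprintf("distance_%s.tsv", m))
  if (!is.null(result$flips))
    put(as.data.frame(result$flips), "signflips.tsv")
  cfgpath <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(seed = config$seed, K = config$K,
                        window_lags = config$window$lags,
                        n_modes = config$n_modes), cfgpath)
  c(files, cfgpath)
}

#' @export
print.pipeline_result <- function(x, ...) {
  K <- x$fit$posterior$K
  cat(sprintf("<pipeline_result> %d subjects, %d states\n",
              length(x$recordings), K))
  fo <- colMeans(x$temporal$fractional_occupancy)
  cat("  fractional occupancy:", paste(sprintf("%.3f", fo), collapse = " "), "\n")
  dw <- stats::aggregate(dwell_ms ~ state, x$temporal$visits, mean)
  cat("  mean dwell times (ms):",
      paste(sprintf("%.0f", dw$dwell_ms), collapse = " "), "\n")
  invisible(x)
}
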