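#' State-wise multitaper power, cross-spectra and coherence
#'
#' Estimates each state's spectral content on the original (unembedded)
#' channels, so the estimate carries no bias from the PCA reduction used for
#' model inference.
#'
#' Under `"soft"` weighting, DPSS-tapered cross-periodograms over sliding
#' windows are averaged with per-window state weights (the mean state
#' probability over the window). Because each window's weights sum to one
#' over states, the occupancy-weighted sum of the state spectra is exactly
#' the static (whole-recording) spectrum.
#'
#' Under `"hard"` weighting, a hard state path (e.g. the Viterbi path or a
#' simulation's ground-truth path) is cut into maximal visits; each visit is
#' tapered at its own length, zero-padded to the configured FFT length, and
#' its cross-periodogram is averaged into the state's spectrum weighted by
#' the visit length. This recovers frequency content of visits much shorter
#' than an oscillation cycle, because many separated sub-cycle wave segments
#' are combined.
#'
#' @param recordings List of `meg_recording` (original channels).
#' @param state_courses Per-subject state time courses, aligned sample by
#'   sample to the recordings: a list of gamma matrices (time x K) for soft
#'   weighting, or a list of integer paths (NA allowed at trimmed edges) for
#'   hard weighting. The `stc`/`viterbi` fields of [hmm_fit()] output can be
#'   passed directly.
#' @param config A `multitaper_config`; its `weighting` field selects the
#'   estimator.
#' @return A `state_spectra` object: list with `frequencies`, `psd`
#'   (K x C x F), `csd` (complex K x C x C x F), `coherence` (K x C x C x F),
#'   `occupancy_weights`, `n_states`, `config`.
#' @export
statewise_multitaper <- function(recordings, state_courses, config) {
  recordings <- check_recordings(recordings)
  stopifnot(inherits(config, "multitaper_config"))
  C <- ncol(recordings[[1L]]$data)
  soft <- config$weighting == "soft"
  courses <- normalize_courses(state_courses, recordings, soft)
  K <- courses$K
  nb <- length(config$bins)
  acc <- array(0+0i, dim = c(K, C, C, nb))
  wsum <- numeric(K)
  for (s in seq_along(recordings)) {
    X <- recordings[[s]]$data
    if (soft) {
      g <- courses$gamma[[s]]
      step <- max(1L, round(config$nfft * (1 - config$overlap)))
      if (nrow(X) < config$nfft) {
        warning(sprintf("recording %d shorter than one window; skipped", s))
        next
      }
      starts <- seq(1L, nrow(X) - config$nfft + 1L, by = step)
      for (st in starts) {
        idx <- st:(st + config$nfft - 1L)
        w <- colMeans(g[idx, , drop = FALSE])
        csd_w <- segment_csd(X[idx, , drop = FALSE], config)
        for (k in seq_len(K)) {
          if (w[k] > 0) acc[k, , , ] <- acc[k, , , ] + w[k] * csd_w
        }
        wsum <- wsum + w
      }
    } else {
      path <- courses$paths[[s]]
      segs <- path_segments(path, config$min_segment, config$nfft)
      for (i in seq_len(nrow(segs))) {
        idx <- segs$start[i]:segs$end[i]
        k <- segs$state[i]
        csd_w <- segment_csd(X[idx, , drop = FALSE], config)
        wt <- length(idx)
        acc[k, , , ] <- acc[k, , , ] + wt * csd_w
        wsum[k] <- wsum[k] + wt
      }
    }
  }
  psd <- array(NA_real_, dim = c(K, C, nb))
  coh <- array(NA_real_, dim = c(K, C, C, nb))
  for (k in seq_len(K)) {
    if (wsum[k] <= 0) {
      warning(sprintf("state %d has zero total weight; spectra undefined", k))
      next
    }
    acc[k, , , ] <- acc[k, , , ] / wsum[k]
    for (j in seq_len(C)) psd[k, j, ] <- Re(acc[k, j, j, ])
    for (j in seq_len(C)) for (l in seq_len(C)) {
      den <- sqrt(psd[k, j, ] * psd[k, l, ])
      co <- Mod(acc[k, j, l, ]) / den
      co[den <= 0] <- NA_real_
      coh[k, j, l, ] <- pmin(co, 1)
    }
  }
  structure(list(frequencies = config$frequencies, psd = psd, csd = acc,
                 coherence = coh,
                 occupancy_weights = wsum / sum(wsum),
                 n_states = K, n_channels = C, config = config),
            class = "state_spectra")
}

normalize_courses <- function(state_courses, recordings, soft) {
  if (inherits(state_courses, "state_time_courses"))
    state_courses <- state_courses$gamma
  if (!is.list(state_courses))
    state_courses <- list(state_courses)
  if (soft) {
    gamma <- lapply(state_courses, as.matrix)
    for (s in seq_along(gamma))
      if (nrow(gamma[[s]]) != nrow(recordings[[s]]$data))
        stop("gamma must align sample-by-sample with the recording")
    list(gamma = gamma, K = ncol(gamma[[1L]]))
  } else {
    paths <- lapply(state_courses, as.integer)
    for (s in seq_along(paths))
      if (length(paths[[s]]) != nrow(recordings[[s]]$data))
        stop("path must align sample-by-sample with the recording")
    list(paths = paths, K = max(unlist(paths), na.rm = TRUE))
  }
}

# maximal constant runs of a hard path, chopped to at most `cap` samples and
# dropping runs shorter than `min_len`; NA samples separate runs
path_segments <- function(path, min_len, cap) {
  T <- length(path)
  r <- rle(ifelse(is.na(path), -1L, path))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list(state = integer(0), start = integer(0), end = integer(0))
  for (v in seq_along(r$values)) {
    if (r$values[v] < 0L) next
    s0 <- starts[v]
    while (s0 <= ends[v]) {
      e0 <- min(s0 + cap - 1L, ends[v])
      if (e0 - s0 + 1L >= min_len) {
        out$state <- c(out$state, r$values[v])
        out$start <- c(out$start, s0)
        out$end <- c(out$end, e0)
      }
      s0 <- e0 + 1L
    }
  }
  as.data.frame(out)
}

#' Static (whole-recording) multitaper spectra
#'
#' Convenience wrapper: the state-wise estimator with a single always-active
#' state, i.e. the temporally averaged spectral description of the data.
#'
#' @param recordings List of `meg_recording`.
#' @param config A `multitaper_config`.
#' @return A `state_spectra` with one state.
#' @export
static_multitaper <- function(recordings, config) {
  recordings <- check_recordings(recordings)
  config$weighting <- "soft"
  gam <- lapply(recordings, function(r) matrix(1, nrow(r$data), 1L))
  statewise_multitaper(recordings, gam, config)
}

#' Data-driven frequency modes by non-negative matrix factorisation
#'
#' Concatenates the coherence spectra of every (state, region pair) into a
#' non-negative matrix A with one column per frequency bin, and factorises
#' `A ~ W H` by multiplicative updates under the Frobenius objective. The
#' rows of H are the frequency modes: non-negative spectral profiles that
#' typically align with the classical delta/theta, alpha, beta and gamma
#' bands. The best of several random restarts (lowest reconstruction error)
#' is returned, with modes sorted by ascending peak frequency. Projections of
#' power reuse the H estimated from coherence.
#'
#' @param spectra A `state_spectra`.
#' @param n_modes Number of modes (4 gives the classical band granularity;
#'   the highest, gamma-range mode is usually reported but down-weighted in
#'   interpretation).
#' @param seed Optional integer seed (local to this call).
#' @param n_restarts Random restarts.
#' @param max_iter,tol Multiplicative-update iteration controls.
#' @return A `frequency_modes` object: `A`, `W`, `H`, `relative_error`,
#'   `frequencies`, per-mode `power_maps` (K x C x modes) and
#'   `coherence_networks` (K x C x C x modes).
#' @export
nnmf_frequency_modes <- function(spectra, n_modes = 4L, seed = NULL,
                                 n_restarts = 10L, max_iter = 10000L,
                                 tol = 1e-8) {
  stopifnot(inherits(spectra, "state_spectra"), n_modes >= 1L)
  A <- coherence_matrix_A(spectra)
  fit <- nnmf(A, n_modes, seed = seed, n_restarts = n_restarts,
              max_iter = max_iter, tol = tol)
  # stable mode order: ascending peak frequency of the H rows
  peaks <- apply(fit$H, 1L, function(h) spectra$frequencies[which.max(h)])
  ord <- order(peaks)
  H <- fit$H[ord, , drop = FALSE]
  W <- fit$W[, ord, drop = FALSE]
  K <- spectra$n_states
  C <- spectra$n_channels
  power_maps <- array(NA_real_, dim = c(K, C, n_modes))
  networks <- array(NA_real_, dim = c(K, C, C, n_modes))
  for (k in seq_len(K)) {
    for (j in seq_len(C)) {
      power_maps[k, j, ] <- project_onto_modes(spectra$psd[k, j, ], H)
      for (l in seq_len(C))
        networks[k, j, l, ] <- project_onto_modes(spectra$coherence[k, j, l, ], H)
    }
  }
  structure(list(A = A, W = W, H = H, relative_error = fit$relative_error,
                 frequencies = spectra$frequencies,
                 power_maps = power_maps, coherence_networks = networks,
                 peak_frequencies = sort(peaks)),
            class = "frequency_modes")
}

# (states * pairs) x F matrix of coherence values, upper-triangle pairs
coherence_matrix_A <- function(spectra) {
  K <- spectra$n_states
  C <- spectra$n_channels
  nb <- length(spectra$frequencies)
  ut <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  A <- matrix(NA_real_, K * nrow(ut), nb)
  row <- 1L
  for (k in seq_len(K)) {
    for (p in seq_len(nrow(ut))) {
      A[row, ] <- spectra$coherence[k, ut[p, 1L], ut[p, 2L], ]
      row <- row + 1L
    }
  }
  A[!is.finite(A)] <- 0
  A
}

#' Non-negative matrix factorisation by multiplicative updates
#'
#' Minimises `||A - W H||_F` with elementwise-nonnegative factors, using the
#' classical multiplicative update rules (objective non-increasing at every
#' step). Factors are initialized uniformly at random; the best of
#' `n_restarts` is returned.
#'
#' @param A Non-negative matrix.
#' @param rank Number of components.
#' @param seed Optional integer seed (local to this call).
#' @param n_restarts,max_iter,tol Iteration controls; convergence is declared
#'   when the relative objective decrease drops below `tol`.
#' @return List with `W`, `H`, `relative_error` and `objective_trace`.
#' @export
nnmf <- function(A, rank, seed = NULL, n_restarts = 10L, max_iter = 10000L,
                 tol = 1e-8) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("NNMF input must be non-negative")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  n <- nrow(A); m <- ncol(A)
  normA <- sqrt(sum(A^2))
  eps <- 1e-12
  best <- NULL
  for (r in seq_len(n_restarts)) {
    W <- matrix(stats::runif(n * rank, 0.1, 1), n, rank) * sqrt(mean(A) / rank)
    H <- matrix(stats::runif(rank * m, 0.1, 1), rank, m) * sqrt(mean(A) / rank)
    obj <- Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, A)) / (crossprod(W) %*% H + eps)
      W <- W * (A %*% t(H)) / (W %*% tcrossprod(H) + eps)
      if (it %% 10L == 0L || it == max_iter) {
        new_obj <- sqrt(sum((A - W %*% H)^2))
        trace <- c(trace, new_obj)
        if (is.finite(obj) && (obj - new_obj) <= tol * max(obj, eps)) {
          obj <- new_obj
          break
        }
        obj <- new_obj
      }
    }
    if (is.null(best) || obj < best$obj)
      best <- list(W = W, H = H, obj = obj, trace = trace)
  }
  list(W = best$W, H = best$H,
       relative_error = best$obj / max(normA, eps),
       objective_trace = best$trace)
}

#' Project a spectrum onto frequency modes
#'
#' Inner product of a spectral vector with each row of H; linear in the
#' input.
#'
#' @param spectrum Numeric vector over the frequency grid.
#' @param H Modes x frequencies matrix.
#' @return One scalar per mode.
#' @export
project_onto_modes <- function(spectrum, H) {
  stopifnot(length(spectrum) == ncol(H))
  as.numeric(H %*% spectrum)
}

#' Wideband average of a spectrum
#'
#' Arithmetic mean over the frequency grid (equivalent to projecting onto a
#' flat mode with weight 1/F).
#'
#' @param spectrum Numeric vector.
#' @return Scalar.
#' @export
wideband_average <- function(spectrum) mean(spectrum)

#' Threshold functional connections by a two-Gaussian mixture
#'
#' Separates the population of connection values into background and
#' strong-connection components by fitting one- and two-component Gaussian
#' mixtures (EM, model selection by BIC). If the two-component model wins,
#' values whose posterior favours the higher-mean component are kept; if a
#' single Gaussian describes the population, no connection stands out and
#' none is kept.
#'
#' @param values Numeric vector of connection strengths (length >= 10).
#' @param seed Optional integer seed (local to this call).
#' @return List with `keep` (logical mask), `n_components`, and `model`
#'   (the fitted mixture).
#' @importFrom mclust mclustBIC
#' @export
gmm_connection_threshold <- function(values, seed = NULL) {
  stopifnot(length(values) >= 10L)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  if (stats::sd(values) == 0)
    return(list(keep = rep(FALSE, length(values)), n_components = 1L,
                model = NULL))
  fit <- tryCatch(
    mclust::Mclust(values, G = 1:2, modelNames = c("E", "V"), verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixture fit failed; keeping no connections")
    return(list(keep = rep(FALSE, length(values)), n_components = 1L,
                model = NULL))
  }
  if (fit$G == 1L)
    return(list(keep = rep(FALSE, length(values)), n_components = 1L,
                model = fit))
  hi <- which.max(fit$parameters$mean)
  list(keep = fit$classification == hi, n_components = 2L, model = fit)
}

#' Threshold a power map at a deviation percentile
#'
#' Keeps the entries whose absolute deviation from a reference lies in the
#' top `percentile` percent. For a states x channels matrix the reference
#' defaults to the across-state mean of each channel (maps are interpreted
#' relative to the temporal average); for a vector it defaults to zero.
#'
#' @param power Numeric vector, or states x channels matrix.
#' @param percentile Percentage of entries to keep, in (0, 100].
#' @param reference Optional explicit reference (scalar or per-channel).
#' @return Logical mask of the same shape as `power`.
#' @export
threshold_power_map <- function(power, percentile, reference = NULL) {
  stopifnot(percentile > 0, percentile <= 100)
  if (is.matrix(power)) {
    if (is.null(reference)) reference <- colMeans(power)
    dev <- abs(sweep(power, 2L, reference))
    out <- power
    out[] <- FALSE
    for (k in seq_len(nrow(power))) {
      thr <- stats::quantile(dev[k, ], 1 - percentile / 100, names = FALSE)
      out[k, ] <- dev[k, ] >= thr
    }
    return(out == 1)
  }
  if (is.null(reference)) reference <- 0
  dev <- abs(power - reference)
  thr <- stats::quantile(dev, 1 - percentile / 100, names = FALSE)
  dev >= thr
}
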