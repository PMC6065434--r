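#' Extract state visits from a hard state path
#'
#' A visit is a maximal run of one state. Visits tile the path without
#' overlap; NA samples (e.g. padded edges) are skipped.
#'
#' @param path Integer state sequence (NA allowed).
#' @param fs Sampling rate in Hz, used to express durations in ms.
#' @param subject_id Optional identifier attached to the output rows.
#' @return data.frame with columns `state`, `onset` (1-based sample),
#'   `length` (samples), `dwell_ms`, `subject`.
#' @export
extract_visits <- function(path, fs, subject_id = "s1") {
  if (length(path) == 0L) stop("empty path")
  r <- rle(ifelse(is.na(path), -1L, as.integer(path)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values > 0L
  data.frame(state = r$values[keep], onset = starts[keep],
             length = r$lengths[keep],
             dwell_ms = r$lengths[keep] / fs * 1000,
             subject = subject_id)
}

#' Interval times between consecutive visits to each state
#'
#' @param visits data.frame from [extract_visits()].
#' @param fs Sampling rate in Hz.
#' @return data.frame with columns `state`, `interval_samples`,
#'   `interval_ms`, `subject` (one row per gap between consecutive visits to
#'   the same state, within subject).
#' @export
state_intervals <- function(visits, fs) {
  out <- lapply(split(visits, list(visits$subject, visits$state), drop = TRUE),
                function(v) {
    if (nrow(v) < 2L) return(NULL)
    v <- v[order(v$onset), ]
    gaps <- v$onset[-1L] - (v$onset[-nrow(v)] + v$length[-nrow(v)])
    data.frame(state = v$state[1L], interval_samples = gaps,
               interval_ms = gaps / fs * 1000, subject = v$subject[1L])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(state = integer(0), interval_samples = numeric(0),
                      interval_ms = numeric(0), subject = character(0))
  rownames(out) <- NULL
  out
}

#' Fractional occupancy of each state
#'
#' Soft version (gamma matrix input): column means of the state
#' probabilities. Hard version (integer path input): proportion of samples
#' assigned to each state. Both sum to one.
#'
#' @param x A time x K gamma matrix, or an integer path (NA ignored).
#' @param K Number of states (required for paths where some state may be
#'   absent; inferred otherwise).
#' @return Numeric vector of per-state fractions.
#' @export
fractional_occupancy <- function(x, K = NULL) {
  if (is.matrix(x)) {
    fo <- colMeans(x)
    return(fo / sum(fo))
  }
  x <- x[!is.na(x)]
  if (is.null(K)) K <- max(x)
  tabulate(x, nbins = K) / length(x)
}

#' Empirical survival curve of interval times
#'
#' Returns the proportion of intervals strictly longer than each duration
#' (one minus the empirical CDF): a right-continuous, non-increasing curve
#' starting at 1. Long tails of the interval distribution show up directly.
#'
#' @param intervals Positive durations (any unit).
#' @return List with `fn` (a vectorized function of duration), and a `grid`
#'   data.frame (`duration`, `proportion_longer`) evaluated at the sorted
#'   unique durations.
#' @export
interval_survival <- function(intervals) {
  stopifnot(length(intervals) >= 1L)
  F <- stats::ecdf(intervals)
  fn <- function(x) 1 - F(x)
  xs <- sort(unique(intervals))
  list(fn = fn,
       grid = data.frame(duration = xs, proportion_longer = 1 - F(xs)))
}

#' Spectrum of the state-onset point process
#'
#' Treats the onsets of a state's visits as a binary point process and
#' estimates its multitaper spectrum, to reveal whether states recur
#' rhythmically. A moving-block bootstrap of the onset indicator series
#' (default 10 s blocks) supplies a pointwise percentile confidence band.
#'
#' @param path Integer state path (one subject).
#' @param fs Sampling rate in Hz.
#' @param config Optional `multitaper_config`; default 10 s windows over
#'   0.1-20 Hz.
#' @param n_boot Bootstrap replicates (0 disables the band).
#' @param block_seconds Bootstrap block length.
#' @param level Confidence level for the band.
#' @param states Which states to analyse (default all present).
#' @return List per state with `frequencies`, `spectrum`, `lower`, `upper`,
#'   `n_onsets`.
#' @export
onset_spectrum <- function(path, fs, config = NULL, n_boot = 200L,
                           block_seconds = 10, level = 0.99,
                           states = NULL) {
  if (is.null(config))
    config <- multitaper_config(fs, window_seconds = 10, f_range = c(0.1, 20))
  if (is.null(states)) states <- sort(unique(path[!is.na(path)]))
  visits <- extract_visits(path, fs)
  out <- list()
  for (k in states) {
    onsets <- visits$onset[visits$state == k]
    if (length(onsets) < 2L) {
      warning(sprintf("state %d has fewer than 2 onsets", k))
      next
    }
    ind <- numeric(length(path))
    ind[onsets] <- 1
    est <- indicator_spectrum(ind, config)
    lo <- hi <- NULL
    if (n_boot > 0L) {
      Lb <- max(2L, round(block_seconds * fs))
      boots <- matrix(NA_real_, n_boot, length(est$spectrum))
      for (b in seq_len(n_boot)) {
        boots[b, ] <- indicator_spectrum(block_resample(ind, Lb), config)$spectrum
      }
      a <- (1 - level) / 2
      lo <- apply(boots, 2L, stats::quantile, probs = a)
      hi <- apply(boots, 2L, stats::quantile, probs = 1 - a)
    }
    out[[as.character(k)]] <- list(frequencies = est$frequencies,
                                   spectrum = est$spectrum,
                                   lower = lo, upper = hi,
                                   n_onsets = length(onsets))
  }
  out
}

indicator_spectrum <- function(ind, config) {
  x <- ind - mean(ind)
  nfft <- config$nfft
  nwin <- floor(length(x) / nfft)
  if (nwin < 1L) stop("series shorter than one spectral window")
  acc <- numeric(length(config$bins))
  tap <- get_tapers(nfft, config$time_bandwidth, config$n_tapers)
  for (w in seq_len(nwin)) {
    seg <- x[((w - 1L) * nfft + 1L):(w * nfft)]
    ft <- stats::mvfft(seg * tap)
    acc <- acc + rowMeans(Mod(ft[config$bins, , drop = FALSE])^2) / config$fs
  }
  list(frequencies = config$frequencies, spectrum = acc / nwin)
}

block_resample <- function(x, block_len) {
  n <- length(x)
  nblocks <- ceiling(n / block_len)
  starts <- sample.int(max(1L, n - block_len + 1L), nblocks, replace = TRUE)
  idx <- unlist(lapply(starts, function(s) s:(s + block_len - 1L)))
  x[idx[seq_len(n)]]
}

#' Permutation test of one state against the others
#'
#' Tests, for each state, whether its value (power, connectivity, a temporal
#' statistic...) exceeds the mean of the other states, using the
#' between-subject variability. A shared set of permutations shuffles the
#' state labels within each subject; the statistic is the group-mean
#' difference between a state's value and the mean of the remaining states.
#' P-values use the permutation-inclusive (add-one) estimator, so the
#' smallest attainable p is `1 / (1 + n_perm)`.
#'
#' @param values States x subjects numeric matrix.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed (local to this call).
#' @param alternative `"greater"` (default) tests for larger-than-others.
#' @return Numeric vector of per-state p-values.
#' @export
permutation_test_across_states <- function(values, n_perm = 5000L, seed = NULL,
                                           alternative = c("greater", "two.sided")) {
  values <- as.matrix(values)
  alternative <- match.arg(alternative)
  K <- nrow(values)
  N <- ncol(values)
  stopifnot(K >= 2L, N >= 2L)
  if (n_perm < 100L) warning("fewer than 100 permutations is unreliable")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  stat <- function(v) {
    m <- rowMeans(v)
    m - (sum(m) - m) / (K - 1)
  }
  obs <- stat(values)
  exceed <- numeric(K)
  for (p in seq_len(n_perm)) {
    perm <- values
    for (s in seq_len(N)) perm[, s] <- values[sample.int(K), s]
    st <- stat(perm)
    if (alternative == "greater") exceed <- exceed + (st >= obs)
    else exceed <- exceed + (abs(st) >= abs(obs))
  }
  (1 + exceed) / (1 + n_perm)
}

#' Affine-invariant Riemannian distance between covariance matrices
#'
#' The geodesic distance on the manifold of symmetric positive-definite
#' matrices: the square root of the summed squared logarithms of the
#' generalized eigenvalues of the pair. It is symmetric, vanishes only for
#' equal matrices, and is invariant under any joint congruence
#' `C -> M C M'`. A `literal` variant computing
#' `sqrt(sum(log eig(C1 C2)))` is provided for comparison only: it is not a
#' metric (it does not vanish at C1 = C2 and can be imaginary).
#'
#' @param C1,C2 Symmetric positive-definite matrices.
#' @param literal Use the non-metric product form (returns a complex number
#'   when the sum of log-eigenvalues is negative).
#' @return Scalar distance.
#' @export
riemannian_distance <- function(C1, C2, literal = FALSE) {
  check_spd(C1)
  check_spd(C2)
  if (literal) {
    ev <- Re(eigen(C1 %*% C2, only.values = TRUE)$values)
    s <- sum(log(ev))
    return(if (s >= 0) sqrt(s) else sqrt(as.complex(s)))
  }
  U <- chol(C1)
  Ui <- backsolve(U, diag(nrow(C1)))
  M <- crossprod(Ui, C2 %*% Ui)  # symmetric; spectrum of C1^{-1} C2
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(ev)^2))
}

check_spd <- function(C) {
  C <- as.matrix(C)
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop("matrix is not symmetric")
  ev_min <- min(eigen((C + t(C)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values)
  if (ev_min <= 0)
    stop(sprintf("matrix is not positive definite (smallest eigenvalue %g)",
                 ev_min))
  invisible(C)
}

#' State autocovariances in the embedded space
#'
#' Gamma-weighted scatter of the embedded (pre-PCA) data per state: the
#' full-rank autocovariance matrices that characterise each state's power
#' (within-channel lag blocks) and phase-coupling (cross-channel blocks).
#'
#' @param recordings List of standardized `meg_recording`.
#' @param stc State time courses from [hmm_fit()] (gamma padded to the
#'   original recording lengths).
#' @param window The `lag_window` used for the fit.
#' @return List of d x d matrices (one per state) with attribute
#'   `lag_layout`.
#' @export
state_autocovariances <- function(recordings, stc, window = lag_window()) {
  recordings <- check_recordings(recordings)
  gammas <- if (inherits(stc, "state_time_courses")) stc$gamma else stc
  K <- ncol(gammas[[1L]])
  w <- max(abs(window$lags))
  covs <- NULL
  occ <- numeric(K)
  for (s in seq_along(recordings)) {
    E <- embed_lags(recordings[[s]], window)
    g <- gammas[[s]]
    if (nrow(g) == nrow(recordings[[s]]$data))
      g <- g[(w + 1L):(nrow(g) - w), , drop = FALSE]
    if (nrow(g) != nrow(E)) stop("gamma does not align with the embedding")
    if (is.null(covs))
      covs <- replicate(K, matrix(0, ncol(E), ncol(E)), simplify = FALSE)
    for (k in seq_len(K)) {
      covs[[k]] <- covs[[k]] + crossprod(E * sqrt(g[, k]))
      occ[k] <- occ[k] + sum(g[, k])
    }
  }
  out <- lapply(seq_len(K), function(k) covs[[k]] / occ[k])
  attr(out, "lag_layout") <- attr(embed_lags(recordings[[1L]], window),
                                  "lag_layout")
  out
}

#' Pairwise Riemannian state distances from power and/or coherence
#'
#' Decomposes what drives the dissimilarity between states by manipulating
#' the channel-block structure of their embedded-space autocovariances
#' before measuring the affine-invariant distance:
#' `"full"` leaves the matrices untouched (power and coherence);
#' `"power_only"` zeroes every cross-channel block, keeping only the
#' within-channel lag blocks (autocorrelation/power structure);
#' `"coherence_only"` rescales each channel's block rows/columns so every
#' within-channel block has unit average diagonal, removing power
#' differences while preserving cross-channel structure.
#'
#' @param covs List of d x d SPD matrices with a `lag_layout` attribute
#'   (e.g. from [state_autocovariances()]), or supply `n_channels`/`n_lags`.
#' @param mode One of `"full"`, `"power_only"`, `"coherence_only"`.
#' @param n_channels,n_lags Block layout if `covs` carries no attribute.
#' @param ridge Diagonal loading added after manipulation to keep matrices
#'   positive definite.
#' @return K x K symmetric distance matrix.
#' @export
state_distance_decomposition <- function(covs,
                                         mode = c("full", "power_only",
                                                  "coherence_only"),
                                         n_channels = NULL, n_lags = NULL,
                                         ridge = 1e-10) {
  mode <- match.arg(mode)
  layout <- attr(covs, "lag_layout")
  if (!is.null(layout)) {
    n_channels <- layout$n_channels
    n_lags <- layout$n_lags
  }
  if (is.null(n_channels) || is.null(n_lags))
    stop("supply `n_channels` and `n_lags` (or a lag_layout attribute)")
  d <- n_channels * n_lags
  stopifnot(all(vapply(covs, function(C) all(dim(C) == d), logical(1L))))
  mod <- lapply(covs, manipulate_blocks, mode = mode,
                n_channels = n_channels, n_lags = n_lags)
  K <- length(mod)
  D <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (j <= i) next
    Ci <- mod[[i]] + diag(ridge * mean(diag(mod[[i]])), d)
    Cj <- mod[[j]] + diag(ridge * mean(diag(mod[[j]])), d)
    D[i, j] <- D[j, i] <- riemannian_distance(Ci, Cj)
  }
  D
}

manipulate_blocks <- function(C, mode, n_channels, n_lags) {
  if (mode == "full") return(C)
  block <- function(j) ((j - 1L) * n_lags + 1L):(j * n_lags)
  if (mode == "power_only") {
    out <- matrix(0, nrow(C), ncol(C))
    for (j in seq_len(n_channels)) {
      b <- block(j)
      out[b, b] <- C[b, b]
    }
    return(out)
  }
  # coherence_only: per-channel scale removed by diagonal congruence
  scales <- vapply(seq_len(n_channels),
                   function(j) mean(diag(C[block(j), block(j)])), numeric(1L))
  s <- rep(1 / sqrt(scales), each = n_lags)
  C * tcrossprod(s)
}
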