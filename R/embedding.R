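#' Lag window for time-delay embedding
#'
#' Defines the symmetric set of integer lags used to augment each time point
#' with lagged copies of all channels. The default, 15 lags from -7 to +7 at
#' 250 Hz, spans a 60 ms window.
#'
#' @param lags Integer offsets, symmetric about zero (e.g. `-7:7`).
#' @param fs Sampling rate in Hz.
#' @return A `lag_window` object with elements `lags`, `fs`, `window_samples`
#'   and `window_ms`.
#' @export
lag_window <- function(lags = -7:7, fs = 250) {
  lags <- as.integer(sort(lags))
  if (!identical(lags, as.integer(sort(-lags))))
    stop("`lags` must be symmetric about 0")
  structure(list(lags = lags, fs = fs,
                 window_samples = length(lags),
                 window_ms = length(lags) / fs * 1000),
            class = "lag_window")
}

#' Dimension of the embedded space
#'
#' @param n_channels Number of channels.
#' @param n_lags Number of lags in the embedding window.
#' @return `n_channels * n_lags`.
#' @seealso [offdiag_param_count()]
#' @export
embedding_dimension <- function(n_channels, n_lags) {
  stopifnot(n_channels >= 1, n_lags >= 1)
  as.integer(n_channels) * as.integer(n_lags)
}

#' Number of off-diagonal parameters of a d x d covariance
#'
#' The per-state autocovariance over the embedded space has `d (d - 1) / 2`
#' free off-diagonal entries; this count is what motivates the PCA reduction.
#'
#' @param d Matrix dimension.
#' @return `d * (d - 1) / 2`.
#' @export
offdiag_param_count <- function(d) {
  stopifnot(d >= 1)
  d * (d - 1) / 2
}

#' Time-delay embed a recording
#'
#' Builds the matrix whose row t holds the channel values at t + lag for
#' every (channel, lag) combination. Rows are only formed where the full
#' window fits, so `max(lags) - min(lags)` edge rows are dropped. Columns are
#' grouped by channel: channel 1 at all lags, then channel 2, and so on -- the
#' layout assumed by the power/coherence block decomposition of state
#' autocovariances.
#'
#' @param x A `meg_recording` or a numeric time x channels matrix.
#' @param window A `lag_window`.
#' @return Numeric matrix, (T - n_lags + 1) x (channels x n_lags), with an
#'   attribute `lag_layout` recording `n_channels`, `n_lags` and the lags.
#' @export
embed_lags <- function(x, window = lag_window()) {
  X <- if (inherits(x, "meg_recording")) x$data else as.matrix(x)
  lags <- window$lags
  W <- length(lags)
  T <- nrow(X)
  C <- ncol(X)
  if (T <= W) stop("recording is shorter than the embedding window")
  w <- max(abs(lags))
  valid <- (w + 1L):(T - w)
  E <- matrix(0, length(valid), C * W)
  for (j in seq_len(C)) {
    for (l in seq_len(W)) {
      E[, (j - 1L) * W + l] <- X[valid + lags[l], j]
    }
  }
  colnames(E) <- as.vector(t(outer(seq_len(C), lags,
                                   function(j, l) sprintf("ch%d.lag%+d", j, l))))
  attr(E, "lag_layout") <- list(n_channels = C, n_lags = W, lags = lags)
  E
}

#' Embed and PCA-reduce a multi-subject dataset
#'
#' Standardized recordings are embedded per subject (so no embedded row mixes
#' samples from two subjects), concatenated, and reduced by PCA computed from
#' the global covariance of the embedded space via eigendecomposition.
#' Components are not whitened: reduced scores retain their variances, and
#' the eigenvalue spectrum is reported as explained-variance fractions.
#' Component sign is fixed by making the largest-magnitude loading positive.
#'
#' @param recordings List of (standardized) `meg_recording`.
#' @param window A `lag_window`.
#' @param n_components Number of principal components to keep. The
#'   conventional rule is twice the channel count; a value that is not a
#'   multiple of the channel count triggers a warning, since surplus
#'   components explain variance from an essentially arbitrary channel
#'   subset.
#' @return An `embedded_dataset`: list with `reduced` (valid_time x
#'   n_components), `basis`, `center`, `explained_variance_fraction`,
#'   `boundaries` (per-subject row ranges plus the trimmed edge width) and
#'   `lag_layout`.
#' @export
embed_dataset <- function(recordings, window = lag_window(),
                          n_components = NULL) {
  recordings <- check_recordings(recordings)
  C <- ncol(recordings[[1L]]$data)
  W <- window$window_samples
  d <- C * W
  if (is.null(n_components)) n_components <- 2L * C
  if (n_components > d) stop("`n_components` cannot exceed channels x lags")
  if (n_components %% C != 0L)
    warning(sprintf(paste0("n_components = %d is not a multiple of the ",
                           "channel count %d; the surplus %d components will ",
                           "explain variance from an arbitrary channel subset"),
                    n_components, C, n_components %% C))
  embedded <- lapply(recordings, embed_lags, window = window)
  nrows <- vapply(embedded, nrow, integer(1L))
  ends <- cumsum(nrows)
  starts <- ends - nrows + 1L
  E <- do.call(rbind, embedded)
  p <- pca_reduce(E, n_components)
  structure(list(
    reduced = p$scores,
    basis = p$basis,
    center = p$center,
    explained_variance_fraction = p$explained_variance_fraction,
    eigenvalues = p$eigenvalues,
    boundaries = data.frame(
      subject = vapply(recordings, function(r) as.character(r$subject_id),
                       character(1L)),
      start = starts, end = ends,
      n_original = vapply(recordings, function(r) nrow(r$data), integer(1L))
    ),
    trim = max(abs(window$lags)),
    window = window,
    lag_layout = attr(embedded[[1L]], "lag_layout")
  ), class = "embedded_dataset")
}

#' @export
print.embedded_dataset <- function(x, ...) {
  cat(sprintf("<embedded_dataset> %d rows x %d components (of %d embedded dims), %d subjects\n",
              nrow(x$reduced), ncol(x$reduced),
              length(x$explained_variance_fraction), nrow(x$boundaries)))
  cat(sprintf("  explained variance kept: %.1f%%\n",
              100 * sum(x$explained_variance_fraction[seq_len(ncol(x$reduced))])))
  invisible(x)
}

#' PCA-reduce an embedded data matrix
#'
#' Computes the principal components of a (possibly very tall) matrix through
#' an eigendecomposition of its column covariance, which stays memory-bounded
#' because the embedded dimension is small. Scores are centred projections and
#' are not whitened. Component sign is fixed by making the largest-magnitude
#' loading positive, so results are deterministic.
#'
#' @param E Numeric matrix (rows are observations).
#' @param n_components Components to keep; values beyond the numerical rank
#'   are truncated with a warning.
#' @return List with `scores`, `basis` (columns orthonormal), `center`,
#'   `explained_variance_fraction` (all eigenvalues, non-increasing) and
#'   `eigenvalues`.
#' @export
pca_reduce <- function(E, n_components) {
  E <- as.matrix(E)
  n <- nrow(E)
  stopifnot(n_components >= 1, n_components <= ncol(E), n >= 2)
  mu <- colMeans(E)
  Ec <- sweep(E, 2L, mu)
  S <- crossprod(Ec) / (n - 1)
  eg <- eigen(S, symmetric = TRUE)
  evals <- pmax(eg$values, 0)
  rank <- sum(evals > max(evals) * 1e-12)
  k <- n_components
  if (k > rank) {
    warning(sprintf("requested %d components but rank is %d; truncating",
                    k, rank))
    k <- rank
  }
  basis <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) basis[, j] <- -basis[, j]
  }
  list(scores = Ec %*% basis, basis = basis, center = mu,
       explained_variance_fraction = evals / sum(evals), eigenvalues = evals)
}

# internal: split concatenated rows back into per-subject blocks
split_by_subject <- function(M, boundaries) {
  lapply(seq_len(nrow(boundaries)), function(i)
    M[boundaries$start[i]:boundaries$end[i], , drop = FALSE])
}
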