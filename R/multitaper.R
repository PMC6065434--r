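#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, as the leading eigenvectors of the symmetric tridiagonal
#' Slepian matrix. Tapers are normalized to unit energy and returned in
#' decreasing order of spectral concentration.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (bandwidth is `nw / n` cycles/sample).
#' @param k Number of tapers; at most `2 nw - 1` is recommended.
#' @return n x k matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 4, k = 7L) {
  stopifnot(n >= 2L, nw > 0, k >= 1L, k <= n)
  if (k > 2 * nw - 1)
    warning("k > 2*nw - 1 tapers have poor spectral concentration")
  W <- nw / n
  i <- seq_len(n) - 1
  M <- matrix(0, n, n)
  diag(M) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  off <- (seq_len(n - 1) * (n - seq_len(n - 1))) / 2
  M[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  M[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  eg <- eigen(M, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  # unit energy; fix polarity so the mean (or the first half-lobe) is positive
  for (j in seq_len(k)) {
    v <- V[, j] / sqrt(sum(V[, j]^2))
    s <- sum(v)
    if (abs(s) < 1e-8) s <- sum(v[seq_len(ceiling(n / 2))])
    if (s < 0) v <- -v
    V[, j] <- v
  }
  V
}

# memoised taper cache keyed by (n, nw, k)
taper_cache <- new.env(parent = emptyenv())
get_tapers <- function(n, nw, k) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (is.null(taper_cache[[key]]))
    taper_cache[[key]] <- dpss_tapers(n, nw, k)
  taper_cache[[key]]
}

#' Multitaper configuration
#'
#' @param fs Sampling rate in Hz.
#' @param window_seconds Analysis window length in seconds; also sets the FFT
#'   length, hence the frequency-bin spacing `1 / window_seconds` Hz.
#' @param time_bandwidth DPSS time-bandwidth product.
#' @param n_tapers Number of DPSS tapers (at most `2 * time_bandwidth - 1`).
#' @param f_range Two-element frequency range in Hz to retain.
#' @param weighting `"soft"` weights sliding windows by the mean state
#'   probability over each window; `"hard"` estimates spectra from the
#'   maximal runs (visits) of a hard state path, which preserves frequency
#'   content of visits far shorter than the analysis window.
#' @param overlap Fractional overlap of sliding windows (soft weighting).
#' @param min_segment Minimum visit length in samples used under hard
#'   weighting.
#' @return A `multitaper_config`.
#' @export
multitaper_config <- function(fs, window_seconds = 2, time_bandwidth = 4,
                              n_tapers = 7L, f_range = c(1, 45),
                              weighting = c("soft", "hard"),
                              overlap = 0.5, min_segment = 10L) {
  weighting <- match.arg(weighting)
  stopifnot(fs > 0, window_seconds > 0, n_tapers >= 1L,
            length(f_range) == 2L, f_range[1L] < f_range[2L],
            overlap >= 0, overlap < 1)
  if (n_tapers > 2 * time_bandwidth - 1)
    stop("n_tapers must be <= 2 * time_bandwidth - 1")
  nfft <- round(window_seconds * fs)
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  bins <- which(freqs >= f_range[1L] - 1e-9 & freqs <= f_range[2L] + 1e-9)
  structure(list(fs = fs, window_seconds = window_seconds,
                 time_bandwidth = time_bandwidth, n_tapers = as.integer(n_tapers),
                 f_range = f_range, weighting = weighting, overlap = overlap,
                 min_segment = as.integer(min_segment),
                 nfft = nfft, bins = bins, frequencies = freqs[bins]),
            class = "multitaper_config")
}

# cross-spectral array (C x C x nbins) of one segment, averaged over tapers
segment_csd <- function(seg, config) {
  L <- nrow(seg)
  C <- ncol(seg)
  tap <- get_tapers(L, config$time_bandwidth, config$n_tapers)
  K_t <- ncol(tap)
  nb <- length(config$bins)
  # tapered, zero-padded FFTs: nbins x K_t per channel
  Fall <- array(0+0i, dim = c(nb, K_t, C))
  pad <- matrix(0, config$nfft, K_t)
  for (c in seq_len(C)) {
    pad[] <- 0
    pad[seq_len(L), ] <- seg[, c] * tap
    ft <- stats::mvfft(pad)
    Fall[, , c] <- ft[config$bins, , drop = FALSE]
  }
  csd <- array(0+0i, dim = c(C, C, nb))
  for (j in seq_len(C)) {
    for (k in j:C) {
      s <- rowSums(Fall[, , j, drop = FALSE] *
                     Conj(Fall[, , k, drop = FALSE])) / (K_t * config$fs)
      csd[j, k, ] <- s
      if (k != j) csd[k, j, ] <- Conj(s)
    }
  }
  csd
}
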