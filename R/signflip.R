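#' Lagged partial correlations across subjects
#'
#' For each subject, every channel is residualized on all other channels at
#' lag zero (regression coefficients from the shrunk inverse of the lag-0
#' covariance), and the residual series are then correlated at each lag
#' offset. This "direct" measure removes the influence of the remaining
#' channels from each pairwise sign relation, and is exactly sign-equivariant:
#' negating channel j of one subject negates row j and column j of that
#' subject's correlation matrices at every lag.
#'
#' @param recordings List of `meg_recording`.
#' @param lag_offsets Integer lags, e.g. `-10:10` (the default, 21 lags).
#' @param shrinkage Either `"auto"` (Ledoit-Wolf-style intensity toward the
#'   diagonal, computed per subject) or a fixed number in \[0, 1\].
#' @return A `lagged_pcorr` object: list with `rho` (array subjects x lags x
#'   channels x channels), `lag_offsets`, `n_subjects`, `n_channels`.
#' @export
lagged_partial_correlations <- function(recordings, lag_offsets = -10:10,
                                        shrinkage = "auto") {
  recordings <- check_recordings(recordings)
  lag_offsets <- as.integer(sort(lag_offsets))
  S <- length(recordings)
  C <- ncol(recordings[[1L]]$data)
  L <- length(lag_offsets)
  w <- max(abs(lag_offsets))
  rho <- array(NA_real_, dim = c(S, L, C, C))
  for (s in seq_len(S)) {
    X <- scale(recordings[[s]]$data, scale = FALSE)
    T <- nrow(X)
    if (T <= 4L * w)
      stop("recording too short relative to the largest lag offset")
    Sig <- stats::cov(X)
    lam <- if (identical(shrinkage, "auto")) lw_shrinkage(X, Sig) else shrinkage
    Sig <- (1 - lam) * Sig + lam * diag(diag(Sig), C)
    P <- tryCatch(solve(Sig), error = function(e) {
      warning("singular covariance; increasing diagonal shrinkage")
      solve(Sig + diag(mean(diag(Sig)) * 0.1, C))
    })
    # residual of channel j on all others: e_j = (P x)_j / P_jj
    Eres <- X %*% P
    Eres <- sweep(Eres, 2L, diag(P), "/")
    valid <- (w + 1L):(T - w)
    E0 <- Eres[valid, , drop = FALSE]
    for (l in seq_len(L)) {
      El <- Eres[valid + lag_offsets[l], , drop = FALSE]
      rho[s, l, , ] <- stats::cor(E0, El)
    }
  }
  structure(list(rho = rho, lag_offsets = lag_offsets,
                 n_subjects = S, n_channels = C),
            class = "lagged_pcorr")
}

# Ledoit-Wolf-style shrinkage intensity toward the diagonal target
lw_shrinkage <- function(X, Sig) {
  n <- nrow(X)
  Xc <- scale(X, scale = FALSE)
  # variance of the off-diagonal sample covariances
  V <- crossprod(Xc^2) / n - (crossprod(Xc) / n)^2
  num <- sum(V[upper.tri(V)]) / n
  den <- sum(Sig[upper.tri(Sig)]^2)
  if (den <= 0) return(0)
  max(0, min(1, num / den))
}

#' Sign-alignment gain of a flip assignment
#'
#' The objective maximised by sign disambiguation: for every channel pair and
#' lag, the magnitude of the across-subject mean of the (sign-adjusted)
#' lagged partial correlations, summed over pairs and lags. Correctly aligned
#' signs prevent genuine correlations of opposite polarity from cancelling in
#' the group mean. Negating all channels of a single subject leaves the gain
#' unchanged, so flips are only identifiable up to a per-subject global sign.
#'
#' @param flips Subjects x channels matrix of +/-1.
#' @param rho_set A `lagged_pcorr` object.
#' @return Non-negative scalar.
#' @export
signflip_gain <- function(flips, rho_set) {
  stopifnot(inherits(rho_set, "lagged_pcorr"))
  flips <- as.matrix(flips)
  S <- rho_set$n_subjects
  C <- rho_set$n_channels
  if (!all(dim(flips) == c(S, C))) stop("`flips` must be subjects x channels")
  if (!all(flips %in% c(-1, 1))) stop("`flips` entries must be -1 or +1")
  M <- flip_weighted_sum(flips, rho_set$rho)
  sum(abs(M)) / S
}

# sum over subjects of f_{s,j1} f_{s,j2} rho_s  (lags x C x C array)
flip_weighted_sum <- function(flips, rho) {
  S <- dim(rho)[1L]; L <- dim(rho)[2L]; C <- dim(rho)[3L]
  M <- array(0, dim = c(L, C, C))
  for (s in seq_len(S)) {
    F_s <- tcrossprod(flips[s, ])
    for (l in seq_len(L)) M[l, , ] <- M[l, , ] + rho[s, l, , ] * F_s
  }
  M
}

#' Greedy sign-flip search with random restarts
#'
#' Finds a flip assignment (approximately) maximising [signflip_gain()].
#' Each restart initializes signs at random and sweeps over (subject,
#' channel) cells in random order, accepting a single-cell flip only when it
#' strictly increases the gain; sweeps repeat until none is accepted. Gain
#' updates are incremental (only the flipped channel's row/column terms are
#' recomputed). The exact problem is a hard integer programme, so only this
#' local search is provided.
#'
#' @param rho_set A `lagged_pcorr` object.
#' @param n_restarts Number of random initializations; the best local optimum
#'   is returned.
#' @param seed Optional integer seed (local to this call).
#' @return List with `flips` (subjects x channels of +/-1), `gain`, and
#'   `trace` (gain after each accepted move of the best restart,
#'   non-decreasing).
#' @export
greedy_signflip <- function(rho_set, n_restarts = 10L, seed = NULL) {
  stopifnot(inherits(rho_set, "lagged_pcorr"), n_restarts >= 1L)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  S <- rho_set$n_subjects
  C <- rho_set$n_channels
  rho <- rho_set$rho
  best <- NULL
  for (r in seq_len(n_restarts)) {
    flips <- matrix(sample(c(-1, 1), S * C, replace = TRUE), S, C)
    if (r == 1L) flips[] <- 1  # one deterministic start from the identity
    M <- flip_weighted_sum(flips, rho)
    gain <- sum(abs(M)) / S
    trace <- gain
    repeat {
      improved <- FALSE
      cells <- sample.int(S * C)
      for (cell in cells) {
        s <- ((cell - 1L) %% S) + 1L
        j <- ((cell - 1L) %/% S) + 1L
        upd <- flip_cell_update(M, rho, flips, s, j)
        delta <- (sum(abs(upd$M_new_rows)) - sum(abs(upd$M_old_rows))) / S
        if (delta > 1e-12) {
          M[, j, ] <- upd$new_row
          M[, , j] <- upd$new_col
          M[, j, j] <- upd$new_diag
          flips[s, j] <- -flips[s, j]
          gain <- gain + delta
          trace <- c(trace, gain)
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    if (is.null(best) || gain > best$gain)
      best <- list(flips = flips, gain = gain, trace = trace)
  }
  best
}

# incremental update of the flip-weighted sum when cell (s, j) flips:
# only row j and column j of M change, by -2 * f_sj * f_s. * rho_s[., j, .]
flip_cell_update <- function(M, rho, flips, s, j) {
  L <- dim(M)[1L]; C <- dim(M)[2L]
  f <- flips[s, ]
  contrib_row <- rho[s, , j, , drop = FALSE]  # 1 x L x C slice as row j
  contrib_col <- rho[s, , , j, drop = FALSE]
  dim(contrib_row) <- c(L, C)
  dim(contrib_col) <- c(L, C)
  fj <- f[j]
  new_row <- M[, j, ] - 2 * fj * sweep(contrib_row, 2L, f, "*")
  new_col <- M[, , j] - 2 * fj * sweep(contrib_col, 2L, f, "*")
  # diagonal cell (j, j): f_sj^2 = 1 is unchanged by the flip
  new_diag <- M[, j, j]
  new_row[, j] <- new_diag
  new_col[, j] <- new_diag
  old_rows <- cbind(M[, j, ], M[, , j][, -j, drop = FALSE])
  new_rows <- cbind(new_row, new_col[, -j, drop = FALSE])
  list(new_row = new_row, new_col = new_col, new_diag = new_diag,
       M_old_rows = old_rows, M_new_rows = new_rows)
}

#' Apply a sign-flip assignment to recordings
#'
#' Multiplies channel j of subject s by `flips[s, j]`. Applying the same
#' assignment twice restores the original data.
#'
#' @param recordings List of `meg_recording`.
#' @param flips Subjects x channels matrix of +/-1.
#' @return List of flipped `meg_recording`.
#' @export
apply_flips <- function(recordings, flips) {
  recordings <- check_recordings(recordings)
  flips <- as.matrix(flips)
  if (nrow(flips) != length(recordings) ||
      ncol(flips) != ncol(recordings[[1L]]$data))
    stop("`flips` must be subjects x channels, matching the recordings")
  lapply(seq_along(recordings), function(s) {
    r <- recordings[[s]]
    r$data <- sweep(r$data, 2L, flips[s, ], "*")
    r
  })
}

#' Exhaustively maximise the sign-flip gain (tiny problems only)
#'
#' Enumerates all `2^(S*C)` assignments; used as a test oracle for the greedy
#' search.
#'
#' @param rho_set A `lagged_pcorr` object with at most 16 (subject, channel)
#'   cells.
#' @return List with `flips` and `gain` of the global maximum.
#' @export
exhaustive_signflip <- function(rho_set) {
  S <- rho_set$n_subjects
  C <- rho_set$n_channels
  ncells <- S * C
  if (ncells > 16L) stop("exhaustive search limited to S*C <= 16")
  best <- NULL
  for (code in 0:(2^ncells - 1L)) {
    bits <- as.integer(intToBits(code))[seq_len(ncells)]
    flips <- matrix(ifelse(bits == 1L, -1, 1), S, C)
    g <- signflip_gain(flips, rho_set)
    if (is.null(best) || g > best$gain) best <- list(flips = flips, gain = g)
  }
  best
}

#' Agreement between two flip assignments up to the gain's gauge freedoms
#'
#' The gain is exactly invariant to (i) negating all channels of one subject
#' and (ii) negating one channel across all subjects -- the latter merely
#' changes the group-level sign convention of that region and does not
#' affect cross-subject alignment. Recovered flips are therefore compared to
#' the truth after choosing the per-subject global signs (and, if
#' `channel_gauge = TRUE`, also the per-channel global signs, enumerated
#' exhaustively) that maximise agreement.
#'
#' @param flips,truth Subjects x channels matrices of +/-1.
#' @param channel_gauge Also mod out the per-channel global sign (requires
#'   at most 16 channels).
#' @return Fraction of (subject, channel) cells that agree, in \[0.5, 1\].
#' @export
flip_agreement <- function(flips, truth, channel_gauge = FALSE) {
  stopifnot(all(dim(flips) == dim(truth)))
  per_subject <- function(target) {
    agree <- 0L
    for (s in seq_len(nrow(flips))) {
      m <- sum(flips[s, ] == target[s, ])
      agree <- agree + max(m, ncol(flips) - m)
    }
    agree / length(flips)
  }
  if (!channel_gauge) return(per_subject(truth))
  C <- ncol(truth)
  if (C > 16L) stop("channel-gauge enumeration limited to 16 channels")
  best <- 0
  for (code in 0:(2^C - 1L)) {
    g <- ifelse(as.integer(intToBits(code))[seq_len(C)] == 1L, -1, 1)
    best <- max(best, per_subject(sweep(truth, 2L, g, "*")))
  }
  best
}
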