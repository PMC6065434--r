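#' Specification of one simulated network state
#'
#' Each hidden state imposes oscillatory structure on the channels: a carrier
#' frequency, per-channel oscillation amplitudes (random phase per visit, so
#' channels are not phase-locked through these), and explicitly phase-coupled
#' channel pairs that share a common per-visit phase up to a fixed lag. The
#' coupled pairs are what give a state its coherence network.
#'
#' @param state_id Integer state label (1-based).
#' @param carrier_freq Oscillation frequency in Hz; must be below fs/2.
#' @param coupled_pairs List of couplings, each a list/vector with elements
#'   `a`, `b` (channel indices), `phase_lag` (radians) and `amplitude`.
#' @param channel_amplitudes Per-channel amplitude of the incoherent carrier
#'   oscillation; scalar is recycled. Default 0 (coupling only).
#' @param noise_sd Per-channel additive Gaussian noise SD; scalar recycled.
#' @return A `state_spec` object.
#' @export
state_spec <- function(state_id, carrier_freq, coupled_pairs = list(),
                       channel_amplitudes = 0, noise_sd = 1) {
  stopifnot(carrier_freq > 0)
  coupled_pairs <- lapply(coupled_pairs, function(p) {
    p <- as.list(p)
    if (is.null(names(p)) || !all(c("a", "b") %in% names(p)))
      names(p)[seq_along(p)] <- c("a", "b", "phase_lag", "amplitude")[seq_along(p)]
    if (is.null(p$phase_lag)) p$phase_lag <- 0
    if (is.null(p$amplitude)) p$amplitude <- 1
    stopifnot(p$amplitude >= 0)
    p
  })
  structure(list(state_id = as.integer(state_id), carrier_freq = carrier_freq,
                 coupled_pairs = coupled_pairs,
                 channel_amplitudes = channel_amplitudes,
                 noise_sd = noise_sd),
            class = "state_spec")
}

#' Simulation configuration for the Markov-switching oscillator model
#'
#' @param n_subjects Number of subjects to simulate.
#' @param n_channels Number of channels (regions).
#' @param fs Sampling rate in Hz.
#' @param duration Recording length per subject in seconds.
#' @param transition_matrix K x K row-stochastic matrix of state transition
#'   probabilities.
#' @param initial_probs K-vector of initial state probabilities; default the
#'   uniform distribution.
#' @param flip_probability Probability that a given (subject, channel) time
#'   course has its sign inverted, emulating dipole polarity ambiguity.
#' @param background_sd Standard deviation of an optional 1/f-like
#'   background (white noise through a first-order recursive filter), added
#'   independently per channel; 0 (default) disables it.
#' @param background_ar First-order filter coefficient of the background
#'   (closer to 1 concentrates more power at low frequencies).
#' @param seed Master seed; all randomness in the simulation flows from it.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_subjects, n_channels, fs, duration,
                              transition_matrix,
                              initial_probs = NULL,
                              flip_probability = 0,
                              background_sd = 0, background_ar = 0.95,
                              seed = 1L) {
  transition_matrix <- as.matrix(transition_matrix)
  K <- nrow(transition_matrix)
  check_stochastic_matrix(transition_matrix)
  if (is.null(initial_probs)) initial_probs <- rep(1 / K, K)
  if (abs(sum(initial_probs) - 1) > 1e-8 || any(initial_probs < 0))
    stop("`initial_probs` must be a probability vector summing to 1")
  stopifnot(flip_probability >= 0, flip_probability <= 1,
            n_subjects >= 1, n_channels >= 1, fs > 0, duration > 0,
            background_sd >= 0, abs(background_ar) < 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_channels = as.integer(n_channels),
                 fs = fs, duration = duration,
                 transition_matrix = transition_matrix,
                 initial_probs = initial_probs,
                 flip_probability = flip_probability,
                 background_sd = background_sd,
                 background_ar = background_ar,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

check_stochastic_matrix <- function(P) {
  if (nrow(P) != ncol(P)) stop("transition matrix must be square")
  if (any(P < 0) || any(P > 1))
    stop("transition matrix entries must lie in [0, 1]")
  if (any(abs(rowSums(P) - 1) > 1e-8))
    stop("transition matrix rows must each sum to 1")
  invisible(P)
}

#' Simulate a first-order Markov chain
#'
#' @param transition_matrix K x K row-stochastic matrix.
#' @param initial_probs K-vector of initial probabilities.
#' @param n_samples Length of the path.
#' @param seed Optional integer seed (local to this call).
#' @return Integer vector of states in 1..K.
#' @export
simulate_markov_chain <- function(transition_matrix, initial_probs, n_samples,
                                  seed = NULL) {
  P <- as.matrix(transition_matrix)
  check_stochastic_matrix(P)
  K <- nrow(P)
  stopifnot(length(initial_probs) == K, n_samples >= 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  path <- integer(n_samples)
  path[1L] <- sample.int(K, 1L, prob = initial_probs)
  if (n_samples > 1L) {
    # draw all uniforms up front; invert the per-row CDF as we walk the chain
    u <- stats::runif(n_samples - 1L)
    cdf <- t(apply(P, 1L, cumsum))
    for (t in 2L:n_samples) {
      path[t] <- sum(u[t - 1L] > cdf[path[t - 1L], ]) + 1L
    }
  }
  path
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Simulate one subject recording given a state path
#'
#' Within each state visit, every coupled pair carries a shared sinusoid at
#' the state's carrier frequency with the specified phase lag between the two
#' channels; per-channel carrier amplitudes add an oscillation with an
#' independent random phase. Phases are drawn fresh at each state onset
#' (uniform on \eqn{[0, 2\pi)}) and are continuous within a visit, so there is
#' no artificial phase locking across separate visits. Independent Gaussian
#' noise is added per channel.
#'
#' @param config A `simulation_config` (supplies `fs` and `n_channels`).
#' @param specs List of `state_spec`, covering every state that occurs in
#'   `path`.
#' @param path Integer state path (one entry per sample).
#' @param subject_id Subject identifier for the returned recording.
#' @return A `meg_recording`.
#' @export
simulate_recording <- function(config, specs, path, subject_id = "s1") {
  fs <- config$fs
  C <- config$n_channels
  ids <- vapply(specs, function(s) s$state_id, integer(1L))
  if (!all(unique(path) %in% ids))
    stop("`specs` must cover every state appearing in `path`")
  for (s in specs) {
    if (s$carrier_freq >= fs / 2)
      stop(sprintf("carrier_freq %g Hz is not below the Nyquist frequency %g Hz",
                   s$carrier_freq, fs / 2))
    for (p in s$coupled_pairs)
      if (p$a > C || p$b > C || p$a < 1 || p$b < 1)
        stop("coupled pair references a channel outside 1..n_channels")
  }
  T <- length(path)
  X <- matrix(0, T, C)
  # visits = maximal runs of a constant state
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (v in seq_along(r$values)) {
    st <- specs[[match(r$values[v], ids)]]
    idx <- starts[v]:ends[v]
    tt <- (idx - starts[v]) / fs
    omega <- 2 * pi * st$carrier_freq
    amps <- rep_len(st$channel_amplitudes, C)
    if (any(amps != 0)) {
      ph <- stats::runif(C, 0, 2 * pi)
      carrier <- sin(outer(omega * tt, ph, "+"))
      X[idx, ] <- X[idx, ] + sweep(carrier, 2L, amps, "*")
    }
    for (p in st$coupled_pairs) {
      psi <- stats::runif(1L, 0, 2 * pi)
      X[idx, p$a] <- X[idx, p$a] + p$amplitude * sin(omega * tt + psi)
      X[idx, p$b] <- X[idx, p$b] + p$amplitude * sin(omega * tt + psi + p$phase_lag)
    }
  }
  nsd <- rep_len(specs[[1L]]$noise_sd, C)
  # noise level may differ per state; apply per visit if the specs differ
  per_state_noise <- vapply(specs, function(s) any(rep_len(s$noise_sd, C) != nsd),
                            logical(1L))
  if (any(per_state_noise)) {
    for (v in seq_along(r$values)) {
      st <- specs[[match(r$values[v], ids)]]
      idx <- starts[v]:ends[v]
      sd_v <- rep_len(st$noise_sd, C)
      X[idx, ] <- X[idx, ] +
        matrix(stats::rnorm(length(idx) * C), length(idx), C) %*% diag(sd_v, C)
    }
  } else if (any(nsd > 0)) {
    X <- X + matrix(stats::rnorm(T * C), T, C) %*% diag(nsd, C)
  }
  bsd <- config$background_sd
  if (!is.null(bsd) && bsd > 0) {
    # 1/f-like background: white noise through a first-order recursive
    # filter, rescaled to the requested standard deviation per channel
    a <- config$background_ar
    for (c in seq_len(C)) {
      b <- as.numeric(stats::filter(stats::rnorm(T), a, method = "recursive"))
      X[, c] <- X[, c] + b * (bsd / stats::sd(b))
    }
  }
  meg_recording(X, fs, subject_id = subject_id)
}

#' Randomly invert channel signs across subjects
#'
#' Emulates the dipole polarity ambiguity of source reconstruction: each
#' (subject, channel) time course is independently multiplied by -1 with the
#' stated probability.
#'
#' @param recordings List of `meg_recording`.
#' @param flip_probability Probability in \[0, 1\].
#' @param seed Optional integer seed (local to this call).
#' @return List with elements `recordings` (flipped copies) and `flips`
#'   (subjects x channels matrix of +/-1).
#' @export
apply_random_flips <- function(recordings, flip_probability, seed = NULL) {
  recordings <- check_recordings(recordings)
  stopifnot(flip_probability >= 0, flip_probability <= 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  S <- length(recordings)
  C <- ncol(recordings[[1L]]$data)
  flips <- matrix(ifelse(stats::runif(S * C) < flip_probability, -1, 1), S, C)
  list(recordings = apply_flips(recordings, flips), flips = flips)
}

#' Simulate a full multi-subject dataset with ground truth
#'
#' Drives [simulate_markov_chain()] and [simulate_recording()] once per
#' subject, then applies random sign flips. A per-subject seed is derived
#' deterministically from the master seed, so the same configuration always
#' yields the same dataset.
#'
#' @param config A `simulation_config`.
#' @param specs List of `state_spec` (one per state).
#' @return List with `recordings` (sign-flipped), `clean_recordings` (before
#'   flipping), and `ground_truth` (list: `paths`, `flips`, `specs`).
#' @export
simulate_dataset <- function(config, specs) {
  n <- round(config$duration * config$fs)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  paths <- vector("list", config$n_subjects)
  recs <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    set.seed(config$seed + 1000L * s)
    paths[[s]] <- simulate_markov_chain(config$transition_matrix,
                                        config$initial_probs, n)
    recs[[s]] <- simulate_recording(config, specs, paths[[s]],
                                    subject_id = sprintf("s%02d", s))
  }
  fl <- apply_random_flips(recs, config$flip_probability,
                           seed = config$seed + 7L)
  list(recordings = fl$recordings, clean_recordings = recs,
       ground_truth = list(paths = paths, flips = fl$flips, specs = specs))
}

#' Bundled two-state coupled-oscillator example configuration
#'
#' A desk-scale reference dataset used throughout the tests and the worked
#' examples: 5 subjects x 60 s at 250 Hz over 8 channels, two states with a
#' mean dwell time of 0.8 s. State 1 phase-couples channels 1-2 at 4 Hz,
#' state 2 couples channels 3-4 at 10 Hz; a coupled pair's oscillation is
#' entirely the shared sinusoid (coupled-oscillator semantics), while the
#' remaining channels carry the state's carrier at amplitude 0.7 with
#' visit-random phase. Unit-variance Gaussian noise puts the coupled
#' components near SNR 1.
#'
#' @param seed Master seed for the simulation.
#' @param n_subjects,duration Optionally scale the dataset down.
#' @return List with `config` and `specs`, ready for [simulate_dataset()].
#' @export
two_state_demo <- function(seed = 1L, n_subjects = 5L, duration = 60) {
  P <- matrix(c(0.995, 0.005,
                0.005, 0.995), 2L, 2L, byrow = TRUE)
  config <- simulation_config(
    n_subjects = n_subjects, n_channels = 8L, fs = 250, duration = duration,
    transition_matrix = P, flip_probability = 0, seed = seed)
  specs <- list(
    state_spec(1L, carrier_freq = 4,
               coupled_pairs = list(list(a = 1L, b = 2L, phase_lag = pi / 3,
                                         amplitude = 1)),
               channel_amplitudes = c(0, 0, rep(0.7, 6L)), noise_sd = 1),
    state_spec(2L, carrier_freq = 10,
               coupled_pairs = list(list(a = 3L, b = 4L, phase_lag = pi / 3,
                                         amplitude = 1)),
               channel_amplitudes = c(0.7, 0.7, 0, 0, rep(0.7, 4L)),
               noise_sd = 1)
  )
  list(config = config, specs = specs)
}
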