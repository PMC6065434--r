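# Shared fixtures, all generated in code.

# Markov-switching chain-coupled oscillators: every channel belongs to a
# coupled pair, so all signs are identifiable; per-visit phase resets keep
# partial correlations informative.
chain_coupled_sim <- function(seed, n_subjects = 5L, n_channels = 6L,
                              duration = 30, flip_probability = 0.5) {
  P <- matrix(c(0.99, 0.01, 0.01, 0.99), 2L, 2L, byrow = TRUE)
  cfg <- simulation_config(n_subjects, n_channels, 250, duration, P,
                           flip_probability = flip_probability, seed = seed)
  pairs <- lapply(seq_len(n_channels - 1L), function(j)
    list(a = j, b = j + 1L, phase_lag = pi / 4, amplitude = 1))
  specs <- list(
    state_spec(1L, 4, coupled_pairs = pairs, channel_amplitudes = 0,
               noise_sd = 1),
    state_spec(2L, 10, coupled_pairs = pairs, channel_amplitudes = 0,
               noise_sd = 1))
  simulate_dataset(cfg, specs)
}

# one-hot gamma matrices from hard paths
onehot_gamma <- function(paths, K) {
  lapply(paths, function(p) {
    g <- matrix(0, length(p), K)
    g[cbind(seq_along(p), p)] <- 1
    g
  })
}

random_spd <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(d * d), d, d)
  crossprod(A) + diag(0.1, d)
}

# brute-force posterior over all K^T paths under expected-log parameters;
# independent oracle for forward-backward / Viterbi
enumerate_hmm <- function(Y, posterior) {
  logB <- tdehmm:::expected_loglik_matrix(Y, posterior)
  eA <- t(apply(posterior$transition_posterior, 1L, tdehmm:::elog_dirichlet))
  epi <- tdehmm:::elog_dirichlet(posterior$initial_posterior)
  T <- nrow(Y)
  K <- posterior$K
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  lp <- apply(paths, 1L, function(z) {
    s <- epi[z[1L]] + logB[1L, z[1L]]
    if (T > 1L) for (t in 2L:T) s <- s + eA[z[t - 1L], z[t]] + logB[t, z[t]]
    s
  })
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  gamma <- sapply(seq_len(K), function(k)
    sapply(seq_len(T), function(t) sum(w[paths[, t] == k])))
  xi <- array(0, dim = c(T - 1L, K, K))
  for (t in seq_len(T - 1L)) for (j in seq_len(K)) for (k in seq_len(K))
    xi[t, j, k] <- sum(w[paths[, t] == j & paths[, t + 1L] == k])
  list(gamma = gamma, xi = xi,
       viterbi = as.integer(paths[which.max(lp), ]),
       loglik = log(sum(exp(lp - max(lp)))) + max(lp))
}

# fit the bundled two-state demo once per session and cache the result;
# several tests and the acceptance suite reuse it
fit_two_state_demo <- local({
  cache <- NULL
  function(seed = 1L) {
    if (!is.null(cache) && cache$seed == seed) return(cache)
    demo <- two_state_demo(seed = seed)
    sim <- simulate_dataset(demo$config, demo$specs)
    recs <- standardize(sim$recordings)
    emb <- embed_dataset(recs, lag_window(-7:7, 250))
    fit <- hmm_fit(emb, fit_options(2L, seed = seed))
    m <- match_state_labels(unlist(fit$viterbi),
                            unlist(sim$ground_truth$paths), K = 2L)
    cache <<- list(seed = seed, sim = sim, recs = recs, emb = emb, fit = fit,
                   match = m)
    cache
  }
})
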