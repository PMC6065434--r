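test_that("DPSS tapers are orthonormal and concentration-ordered", {
  for (n in c(64, 250)) {
    V <- dpss_tapers(n, 4, 7)
    expect_equal(crossprod(V), diag(7), tolerance = 1e-8)
    # in-band energy fraction decreases with taper order
    W <- 4 / n
    conc <- apply(V, 2, function(v) {
      pad <- c(v, rep(0, 8 * n))
      p <- Mod(fft(pad))^2
      f <- (seq_along(pad) - 1) / length(pad)
      sum(p[f <= W | f >= 1 - W]) / sum(p)
    })
    expect_true(all(diff(conc) < 1e-6))
    expect_gt(conc[1], 0.999)
  }
})

test_that("multitaper coherence has the right structure", {
  set.seed(51)
  fs <- 250
  x <- sin(2 * pi * 10 * (1:5000) / fs) + rnorm(5000, sd = 0.5)
  rec <- meg_recording(cbind(a = x, b = x, c = rnorm(5000)), fs)
  cfg <- multitaper_config(fs)
  sp <- static_multitaper(list(rec), cfg)
  f <- sp$frequencies
  expect_equal(length(f), 89)  # 0.5 Hz grid from 1 to 45
  # duplicate channel: coherence 1 at every bin
  expect_true(all(abs(sp$coherence[1, 1, 2, ] - 1) < 1e-6))
  # self-coherence 1; bounded in [0, 1]; psd peak at 10 Hz
  expect_true(all(abs(sp$coherence[1, 3, 3, ] - 1) < 1e-12))
  expect_true(all(sp$coherence[1, , , ] <= 1 + 1e-12))
  expect_lte(abs(f[which.max(sp$psd[1, 1, ])] - 10), 0.5)
  # independent channel: low coherence
  expect_lt(max(sp$coherence[1, 1, 3, ]), 0.5)
  # csd is Hermitian
  expect_equal(sp$csd[1, 3, 1, 5], Conj(sp$csd[1, 1, 3, 5]))
})

test_that("single always-active state equals the plain spectrum", {
  set.seed(52)
  rec <- meg_recording(matrix(rnorm(3000 * 2), 3000, 2), 250)
  cfg <- multitaper_config(250)
  g1 <- list(matrix(1, 3000, 1))
  a <- statewise_multitaper(list(rec), g1, cfg)
  b <- static_multitaper(list(rec), cfg)
  expect_equal(a$psd[1, , ], b$psd[1, , ], tolerance = 1e-10)
  expect_equal(a$csd, b$csd, tolerance = 1e-10)
})

test_that("occupancy-weighted state spectra reproduce the static spectrum", {
  sim <- chain_coupled_sim(53, n_subjects = 2L, duration = 16,
                           flip_probability = 0)
  recs <- standardize(sim$recordings)
  gam <- onehot_gamma(sim$ground_truth$paths, 2)
  # soften the weights a little so both states touch every window
  gam <- lapply(gam, function(g) 0.8 * g + 0.1)
  cfg <- multitaper_config(250, weighting = "soft")
  sp <- statewise_multitaper(recs, gam, cfg)
  stat <- static_multitaper(recs, cfg)
  w <- sp$occupancy_weights
  mix <- w[1] * sp$psd[1, , ] + w[2] * sp$psd[2, , ]
  rel <- abs(mix - stat$psd[1, , ]) / stat$psd[1, , ]
  expect_lt(max(rel), 0.02)
})

test_that("visit-based estimation recovers coupling from sub-cycle visits", {
  K <- 3
  P <- matrix(0.02, K, K); diag(P) <- 0.96  # mean dwell 25 samples = 100 ms
  cfg <- simulation_config(3, 4, 250, 60, P, seed = 54)
  specs <- list(
    state_spec(1L, 4, coupled_pairs = list(list(a = 1L, b = 2L,
                                                phase_lag = pi / 3,
                                                amplitude = 1)),
               channel_amplitudes = 0, noise_sd = 1),
    state_spec(2L, 10, channel_amplitudes = c(0.7, 0.7, 0, 0), noise_sd = 1),
    state_spec(3L, 20, channel_amplitudes = c(0.7, 0.7, 0, 0), noise_sd = 1))
  sim <- simulate_dataset(cfg, specs)
  mean_dwell <- mean(extract_visits(sim$ground_truth$paths[[1]], 250)$dwell_ms)
  expect_lt(mean_dwell, 150)
  sp <- statewise_multitaper(standardize(sim$recordings),
                             sim$ground_truth$paths,
                             multitaper_config(250, weighting = "hard"))
  i4 <- which(sp$frequencies == 4)
  coupled <- sp$coherence[1, 1, 2, i4]
  expect_gte(coupled, 2 * sp$coherence[2, 1, 2, i4])
  expect_gte(coupled, 2 * sp$coherence[3, 1, 2, i4])
})

test_that("NNMF dimensions, recovery and objective behave as specified", {
  # dimensional bookkeeping for the canonical 12-state, 42-region analysis
  fake <- structure(list(n_states = 12L, n_channels = 42L,
                         frequencies = seq(1, 45, by = 0.5),
                         coherence = array(0.1, dim = c(12, 42, 42, 89))),
                    class = "state_spectra")
  A <- tdehmm:::coherence_matrix_A(fake)
  expect_equal(nrow(A), 10332)
  expect_equal(42 * 41 / 2, 861)

  # exact nonnegative rank-2 recovery up to permutation and scaling; the
  # mixing matrix contains anchor rows (one component only) so the
  # factorisation is identifiable
  set.seed(55)
  H0 <- rbind(c(rep(1, 25), rep(0, 64)), c(rep(0, 45), rep(1, 30), rep(0, 14)))
  W0 <- matrix(runif(300 * 2, 0.2, 1), 300, 2)
  W0[1:60, 2] <- 0
  W0[61:120, 1] <- 0
  fit <- nnmf(W0 %*% H0, 2, seed = 1, n_restarts = 3, tol = 1e-12,
              max_iter = 30000)
  expect_lte(fit$relative_error, 1e-4)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  cs <- apply(outer(1:2, 1:2, Vectorize(function(i, j)
    cosine(fit$H[i, ], H0[j, ]))), 1, max)
  expect_true(all(cs >= 0.99))
  # objective trace non-increasing
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  # overcomplete factorisation drives the error toward zero (multiplicative
  # updates converge with a slow tail, so near- rather than exactly zero)
  Afull <- matrix(runif(40 * 10), 40, 10)
  expect_lte(nnmf(Afull, 10, seed = 2, n_restarts = 3, tol = 0,
                  max_iter = 20000)$relative_error, 1e-3)
  expect_error(nnmf(matrix(c(-1, 1, 1, 1), 2), 1), "non-negative")
})

test_that("frequency modes split band-limited coherence structure", {
  # synthetic spectra: two states coherent in disjoint bands
  f <- seq(1, 45, by = 0.5)
  nb <- length(f)
  coh <- array(0.05, dim = c(2, 4, 4, nb))
  band1 <- f >= 3 & f <= 7
  band2 <- f >= 9 & f <= 13
  for (j in 1:4) for (l in 1:4) {
    coh[1, j, l, band1] <- coh[1, j, l, band1] + 0.6
    coh[2, j, l, band2] <- coh[2, j, l, band2] + 0.6
  }
  psd <- array(1, dim = c(2, 4, nb))
  sp <- structure(list(n_states = 2L, n_channels = 4L, frequencies = f,
                       coherence = coh, psd = psd),
                  class = "state_spectra")
  fm <- nnmf_frequency_modes(sp, n_modes = 2, seed = 3, n_restarts = 5)
  # one mode per band, sorted by ascending peak frequency
  expect_true(fm$peak_frequencies[1] >= 3 && fm$peak_frequencies[1] <= 7)
  expect_true(fm$peak_frequencies[2] >= 9 && fm$peak_frequencies[2] <= 13)
  m1 <- fm$H[1, ] / max(fm$H[1, ])
  expect_gt(mean(m1[band1]), 5 * mean(m1[band2]))
  # mode projections: state 1 coherence loads on mode 1
  expect_gt(fm$coherence_networks[1, 1, 2, 1], fm$coherence_networks[1, 1, 2, 2])
})

test_that("mode projection is linear and the wideband average is flat", {
  H <- rbind(c(rep(0.5, 10), rep(0, 10)), rep(1 / 20, 20))
  s1 <- runif(20); s2 <- runif(20)
  p <- project_onto_modes(3 * s1 + 2 * s2, H)
  expect_equal(p, 3 * project_onto_modes(s1, H) + 2 * project_onto_modes(s2, H),
               tolerance = 1e-12)
  expect_equal(project_onto_modes(rep(0, 20), H), c(0, 0))
  # indicator row on a flat spectrum = level x band width (in weighted bins)
  expect_equal(project_onto_modes(rep(2, 20), H)[1], 2 * 0.5 * 10)
  expect_equal(wideband_average(rep(7, 20)), 7)
  expect_equal(wideband_average(1:90), 45.5)
  expect_equal(wideband_average(s1), project_onto_modes(s1, rbind(rep(1 / 20, 20)))[1])
})

test_that("two-Gaussian thresholding keeps only the strong-connection mode", {
  set.seed(56)
  v <- c(rnorm(400, 0.1, 0.01), rnorm(40, 0.6, 0.01))
  g <- gmm_connection_threshold(v, seed = 1)
  expect_equal(g$n_components, 2L)
  expect_identical(which(g$keep), 401:440)
  # identical values: nothing kept
  expect_false(any(gmm_connection_threshold(rep(0.3, 50))$keep))
  # unimodal population: none kept in most seeds
  none <- vapply(1:50, function(s) {
    set.seed(s)
    !any(gmm_connection_threshold(rnorm(500, 0.3, 0.05), seed = s)$keep)
  }, logical(1))
  expect_gte(mean(none), 0.9)
})

test_that("power-map thresholding keeps top deviations from the reference", {
  expect_equal(which(threshold_power_map(c(1, 2, 3, 4), 50, reference = 0)),
               c(3L, 4L))
  expect_true(all(threshold_power_map(c(1, 2, 3, 4), 100, reference = 0)))
  expect_equal(which(threshold_power_map(c(-5, 1, 2, 5), 50, reference = 0)),
               c(1L, 4L))
  # matrix form: reference defaults to the across-state mean per channel,
  # so both strong deviations of each state are flagged
  m <- rbind(state1 = c(10, 0, 0, 0), state2 = c(0, 0, 0, -8))
  mask <- threshold_power_map(m, 50)
  expect_true(mask[1, 1] && mask[2, 4])
  expect_equal(sum(mask), 4)
})
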