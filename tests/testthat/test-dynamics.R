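test_that("visit extraction tiles the path and measures intervals", {
  v <- extract_visits(c(1, 1, 2, 2, 2, 1), fs = 1000)
  expect_equal(v$state, c(1, 2, 1))
  expect_equal(v$onset, c(1, 3, 6))
  expect_equal(v$length, c(2, 3, 1))
  expect_equal(v$dwell_ms, c(2, 3, 1))
  iv <- state_intervals(v, fs = 1000)
  expect_equal(iv$interval_samples[iv$state == 1], 3)
  # constant path: one visit, no intervals
  vc <- extract_visits(rep(2L, 10), 250)
  expect_equal(nrow(vc), 1)
  expect_equal(nrow(state_intervals(vc, 250)), 0)
  # visits partition the path
  set.seed(61)
  p <- sample(1:3, 500, replace = TRUE)
  expect_equal(sum(extract_visits(p, 250)$length), 500)
  expect_error(extract_visits(integer(0), 250), "empty")
})

test_that("fractional occupancy agrees between soft and hard views", {
  g <- matrix(1 / 3, 90, 3)
  expect_equal(fractional_occupancy(g), rep(1 / 3, 3))
  expect_equal(fractional_occupancy(c(1L, 1L, 2L, 2L)), c(0.5, 0.5))
  # near-deterministic gamma: soft and hard agree closely
  set.seed(62)
  path <- simulate_markov_chain(matrix(c(.98, .02, .02, .98), 2, 2,
                                       byrow = TRUE), c(.5, .5), 5000)
  g2 <- matrix(0.01, 5000, 2)
  g2[cbind(1:5000, path)] <- 0.99
  expect_lt(max(abs(fractional_occupancy(g2) - fractional_occupancy(path))),
            0.02)
  expect_equal(sum(fractional_occupancy(path)), 1, tolerance = 1e-8)
})

test_that("interval survival curve matches its definition and the exponential law", {
  s <- interval_survival(c(1, 2, 3, 4))
  expect_equal(s$fn(2.5), 0.5)
  expect_equal(s$fn(0), 1)
  expect_equal(s$fn(4), 0)
  expect_true(all(diff(s$grid$proportion_longer) <= 0))
  # exponential intervals: survival matches exp(-lambda x)
  set.seed(63)
  iv <- rexp(1e5, rate = 2)
  se <- interval_survival(iv)
  xs <- seq(0, 3, by = 0.05)
  expect_lt(max(abs(se$fn(xs) - exp(-2 * xs))), 0.02)
})

test_that("onset point-process spectra detect rhythmicity and rate", {
  # strictly periodic onsets every 0.5 s: peak at 2 Hz
  path <- rep(c(1L, rep(2L, 124L)), 48)
  os <- onset_spectrum(path, 250, n_boot = 0)
  s1 <- os[["1"]]
  expect_lt(abs(s1$frequencies[which.max(s1$spectrum)] - 2), 0.5)

  # memoryless (geometric-interval) onsets: flat spectrum, no strong peak
  set.seed(64)
  pathp <- ifelse(runif(120000) < 0.01, 1L, 2L)
  osp <- onset_spectrum(pathp, 250, n_boot = 100, block_seconds = 5,
                        level = 0.99)
  sp <- osp[["1"]]
  band <- sp$spectrum >= sp$lower & sp$spectrum <= sp$upper
  expect_gt(mean(band), 0.95)
  expect_lt(max(sp$spectrum) / stats::median(sp$spectrum), 3)

  # doubling the onset rate roughly doubles the broadband level
  set.seed(65)
  path2 <- ifelse(runif(120000) < 0.02, 1L, 2L)
  os2 <- onset_spectrum(path2, 250, n_boot = 0)
  r <- mean(os2[["1"]]$spectrum) / mean(osp[["1"]]$spectrum)
  expect_lt(abs(r - 2), 0.3)
})

test_that("permutation test is calibrated and powerful", {
  # exchangeable null: p-values bounded below and roughly uniform
  set.seed(66)
  v0 <- matrix(rnorm(4 * 12), 4, 12)
  p0 <- permutation_test_across_states(v0, n_perm = 500, seed = 1)
  expect_true(all(p0 >= 1 / 501))
  # one state shifted far above the rest: minimal p-value
  v1 <- matrix(rnorm(4 * 20), 4, 20)
  v1[3, ] <- v1[3, ] + 10
  p1 <- permutation_test_across_states(v1, n_perm = 1000, seed = 2)
  expect_lte(p1[3], 0.001)
  expect_warning(permutation_test_across_states(v0, n_perm = 50, seed = 1),
                 "unreliable")
})

test_that("type-I error stays near the nominal level under the null", {
  set.seed(67)
  rej <- 0; tot <- 0
  for (i in 1:300) {
    v <- matrix(rnorm(4 * 10), 4, 10)
    p <- permutation_test_across_states(v, n_perm = 200, seed = i)
    rej <- rej + sum(p <= 0.05)
    tot <- tot + 4
  }
  expect_lte(rej / tot, 0.07)
})

test_that("riemannian distance satisfies metric axioms and invariances", {
  set.seed(68)
  for (r in 1:20) {
    A <- random_spd(5); B <- random_spd(5)
    dAB <- riemannian_distance(A, B)
    expect_equal(riemannian_distance(A, A), 0, tolerance = 1e-6)
    expect_equal(dAB, riemannian_distance(B, A), tolerance = 1e-8)
    expect_gt(dAB, 0)
    # affine invariance under congruence
    M <- matrix(rnorm(25), 5)
    expect_equal(riemannian_distance(M %*% A %*% t(M), M %*% B %*% t(M)),
                 dAB, tolerance = 1e-8)
  }
  # triangle inequality, spot-checked
  for (r in 1:20) {
    A <- random_spd(4); B <- random_spd(4); C <- random_spd(4)
    expect_lte(riemannian_distance(A, C),
               riemannian_distance(A, B) + riemannian_distance(B, C) + 1e-10)
  }
  # commuting (diagonal) closed form
  a <- c(0.5, 2, 7); b <- c(1.5, 2, 4)
  expect_equal(riemannian_distance(diag(a), diag(b)),
               sqrt(sum(log(b / a)^2)), tolerance = 1e-12)
  expect_error(riemannian_distance(diag(c(1, -1)), diag(2)), "positive definite")
  # literal (non-metric) variant: d(C, C) generally nonzero
  A <- random_spd(3)
  expect_gt(Mod(riemannian_distance(A, A, literal = TRUE)), 0)
})

test_that("distance decomposition isolates power and coupling differences", {
  n_ch <- 2; n_lag <- 3; d <- n_ch * n_lag
  base <- random_spd(d, seed = 70)
  layout <- list(n_channels = n_ch, n_lags = n_lag)
  blocks <- function(C) {
    C
  }
  # states differing only in the cross-channel blocks
  C1 <- base
  C2 <- base
  C2[1:3, 4:6] <- 0.5 * C2[1:3, 4:6]
  C2[4:6, 1:3] <- t(C2[1:3, 4:6])
  covs <- list(C1, C2)
  attr(covs, "lag_layout") <- layout
  D_pow <- state_distance_decomposition(covs, "power_only")
  D_full <- state_distance_decomposition(covs, "full")
  expect_lte(D_pow[1, 2], 1e-6)
  expect_gt(D_full[1, 2], 0.01)
  # states differing only by per-channel variance scaling
  s <- rep(c(2, 0.5), each = n_lag)
  C3 <- base * tcrossprod(s)
  covs2 <- list(base, C3)
  attr(covs2, "lag_layout") <- layout
  D_coh <- state_distance_decomposition(covs2, "coherence_only")
  D_pow2 <- state_distance_decomposition(covs2, "power_only")
  expect_lte(D_coh[1, 2], 1e-6)
  expect_gt(D_pow2[1, 2], 0.01)
  # full mode equals the plain pairwise distance
  expect_equal(D_full[1, 2], riemannian_distance(C1, C2), tolerance = 1e-6)
})

test_that("state autocovariances carry the block layout and feed distances", {
  sim <- chain_coupled_sim(71, n_subjects = 2L, duration = 8,
                           flip_probability = 0)
  recs <- standardize(sim$recordings)
  w <- lag_window(-3:3, 250)
  gam <- onehot_gamma(sim$ground_truth$paths, 2)
  covs <- state_autocovariances(recs, gam, w)
  expect_length(covs, 2)
  expect_equal(dim(covs[[1]]), c(42, 42))
  expect_equal(covs[[1]], t(covs[[1]]), tolerance = 1e-10)
  lay <- attr(covs, "lag_layout")
  expect_equal(lay$n_channels, 6)
  D <- state_distance_decomposition(covs, "full")
  expect_gt(D[1, 2], 0)
  expect_equal(diag(D), c(0, 0))
})
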