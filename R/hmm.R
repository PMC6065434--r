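#' Options controlling HMM inference
#'
#' @param K Number of states.
#' @param max_iterations Maximum variational-Bayes cycles (full-batch), or
#'   minibatch steps (stochastic).
#' @param tolerance Relative free-energy change below which iteration stops.
#' @param seed Optional integer seed used for initialization (and minibatch
#'   order under stochastic inference).
#' @param stochastic Use stochastic (minibatch, natural-gradient) updates.
#' @param batch_size Subjects per minibatch when `stochastic = TRUE`.
#' @param forget_delay,forget_rate Robbins-Monro step-size schedule
#'   `rho_i = (i + forget_delay)^(-forget_rate)`.
#' @param n_starts Number of random initializations; each is run for
#'   `start_iterations` cycles and the one with the lowest free energy is
#'   continued.
#' @param start_iterations VB cycles used to score each initialization.
#' @return A `fit_options` list.
#' @export
fit_options <- function(K, max_iterations = 100L, tolerance = 1e-6,
                        seed = NULL, stochastic = FALSE, batch_size = 2L,
                        forget_delay = 2, forget_rate = 0.7,
                        n_starts = 3L, start_iterations = 3L) {
  stopifnot(K >= 1L, tolerance > 0, max_iterations >= 1L, n_starts >= 1L)
  structure(list(K = as.integer(K), max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, seed = seed, stochastic = stochastic,
                 batch_size = as.integer(batch_size),
                 forget_delay = forget_delay, forget_rate = forget_rate,
                 n_starts = as.integer(n_starts),
                 start_iterations = as.integer(start_iterations)),
            class = "fit_options")
}

#' Default priors for the variational HMM
#'
#' Transition-matrix rows and the initial distribution get flat Dirichlet(1)
#' priors. Each state's covariance gets an inverse-Wishart prior with
#' `dof = d + 2` and scale `0.1 * global covariance * (d + 2)`, which is
#' weakly informative but matched to the overall scale of the data.
#'
#' @param Y Data matrix (rows = samples) used only for its global covariance.
#' @param K Number of states.
#' @return List with `alpha_trans`, `alpha_init`, `S0`, `nu0`.
#' @export
hmm_priors <- function(Y, K) {
  d <- ncol(Y)
  S_global <- crossprod(Y) / nrow(Y)  # zero-mean observation model
  list(alpha_trans = matrix(1, K, K), alpha_init = rep(1, K),
       S0 = 0.1 * S_global * (d + 2), nu0 = d + 2)
}

#' Initialize the HMM posterior from random data segments
#'
#' Seeds the K covariance posteriors from the scatter of K distinct random
#' contiguous segments of the data, which is deterministic given the seed.
#'
#' @param Y Data matrix.
#' @param options A `fit_options`.
#' @param priors Priors as from [hmm_priors()]; computed if missing.
#' @param segment_length Length of each seeding segment; default
#'   `max(2 d + 2, 250)` capped at `floor(T / K)`.
#' @return An `hmm_posterior` object.
#' @export
hmm_init <- function(Y, options, priors = NULL, segment_length = NULL) {
  Y <- as.matrix(Y)
  K <- options$K
  d <- ncol(Y)
  T <- nrow(Y)
  if (is.null(priors)) priors <- hmm_priors(Y, K)
  if (is.null(segment_length))
    segment_length <- max(2L * d + 2L, min(250L, floor(T / K)))
  n_segments <- floor(T / segment_length)
  if (K > n_segments)
    stop(sprintf("K = %d exceeds the %d segments available for initialization",
                 K, n_segments))
  if (!is.null(options$seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(options$seed)
  }
  picks <- if (K == 1L) 1L else sample.int(n_segments, K)
  S <- vector("list", K)
  nu <- numeric(K)
  for (k in seq_len(K)) {
    idx <- ((picks[k] - 1L) * segment_length + 1L):(picks[k] * segment_length)
    S[[k]] <- priors$S0 + crossprod(Y[idx, , drop = FALSE])
    nu[k] <- priors$nu0 + segment_length
  }
  new_hmm_posterior(K = K,
                    transition_posterior = priors$alpha_trans + diag(1, K),
                    initial_posterior = priors$alpha_init,
                    state_scale = S, state_dof = nu,
                    priors = priors, free_energy_trace = numeric(0))
}

new_hmm_posterior <- function(K, transition_posterior, initial_posterior,
                              state_scale, state_dof, priors,
                              free_energy_trace) {
  structure(list(K = K, transition_posterior = transition_posterior,
                 initial_posterior = initial_posterior,
                 state_scale = state_scale, state_dof = state_dof,
                 priors = priors, free_energy_trace = free_energy_trace),
            class = "hmm_posterior")
}

#' @export
print.hmm_posterior <- function(x, ...) {
  d <- nrow(x$state_scale[[1L]])
  cat(sprintf("<hmm_posterior> K = %d states over %d dimensions\n", x$K, d))
  if (length(x$free_energy_trace))
    cat(sprintf("  free energy: %.2f after %d iterations\n",
                utils::tail(x$free_energy_trace, 1L),
                length(x$free_energy_trace)))
  cat("  expected transition matrix:\n")
  print(round(expected_transition_matrix(x), 3))
  invisible(x)
}

#' Expected transition matrix under the Dirichlet posterior
#' @param posterior An `hmm_posterior`.
#' @return K x K row-stochastic matrix.
#' @export
expected_transition_matrix <- function(posterior) {
  A <- posterior$transition_posterior
  sweep(A, 1L, rowSums(A), "/")
}

# E[log det Lambda] and nu * S^{-1} machinery for each state
state_loglik_terms <- function(posterior) {
  K <- posterior$K
  d <- nrow(posterior$state_scale[[1L]])
  lapply(seq_len(K), function(k) {
    S <- posterior$state_scale[[k]]
    nu <- posterior$state_dof[k]
    U <- chol(S)
    Ui <- backsolve(U, diag(d))
    logdetS <- 2 * sum(log(diag(U)))
    elogdet <- sum(digamma((nu + 1 - seq_len(d)) / 2)) + d * log(2) - logdetS
    list(Ui = Ui, nu = nu, elogdet = elogdet)
  })
}

# time x K matrix of expected Gaussian log-densities (zero mean)
expected_loglik_matrix <- function(Y, posterior) {
  d <- ncol(Y)
  terms <- state_loglik_terms(posterior)
  logB <- matrix(0, nrow(Y), posterior$K)
  for (k in seq_len(posterior$K)) {
    tk <- terms[[k]]
    q <- rowSums((Y %*% tk$Ui)^2) * tk$nu
    logB[, k] <- -0.5 * d * log(2 * pi) + 0.5 * tk$elogdet - 0.5 * q
  }
  logB
}

elog_dirichlet <- function(alpha) digamma(alpha) - digamma(sum(alpha))

# scaled forward-backward for one sequence given logB and expected-log params
forward_backward <- function(logB, elog_A, elog_pi, keep_xi = FALSE) {
  T <- nrow(logB)
  K <- ncol(logB)
  Atil <- exp(elog_A)
  pitil <- exp(elog_pi)
  shift <- apply(logB, 1L, max)
  B <- exp(logB - shift)
  alpha <- matrix(0, T, K)
  cvec <- numeric(T)
  a <- pitil * B[1L, ]
  cvec[1L] <- sum(a)
  alpha[1L, ] <- a / cvec[1L]
  if (T > 1L) for (t in 2L:T) {
    a <- (alpha[t - 1L, ] %*% Atil)[1L, ] * B[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, T, K)
  beta[T, ] <- 1
  if (T > 1L) for (t in (T - 1L):1L) {
    beta[t, ] <- (Atil %*% (B[t + 1L, ] * beta[t + 1L, ]))[, 1L] / cvec[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, K, K)
  xi <- if (keep_xi && T > 1L) array(0, dim = c(T - 1L, K, K)) else NULL
  if (T > 1L) {
    if (keep_xi) {
      for (t in seq_len(T - 1L)) {
        x <- (alpha[t, ] %o% (B[t + 1L, ] * beta[t + 1L, ])) * Atil
        x <- x / sum(x)
        xi_sum <- xi_sum + x
        xi[t, , ] <- x
      }
    } else {
      # each xi_t normalises by c_{t+1} under the scaled recursions, so the
      # sum over t collapses to a single cross-product
      W2 <- B[2L:T, , drop = FALSE] * beta[2L:T, , drop = FALSE] /
        cvec[2L:T]
      xi_sum <- Atil * crossprod(alpha[1L:(T - 1L), , drop = FALSE], W2)
    }
  }
  list(gamma = gamma, xi_sum = xi_sum, xi = xi,
       loglik = sum(log(cvec)) + sum(shift))
}

#' Variational E-step: posterior state time courses
#'
#' Runs scaled forward-backward recursions per subject on the expected
#' Gaussian log-likelihoods (under the inverse-Wishart covariance posteriors)
#' and the expected log transition/initial probabilities (under the Dirichlet
#' posteriors).
#'
#' @param Y Data matrix (concatenated subjects) or an `embedded_dataset`.
#' @param posterior An `hmm_posterior`.
#' @param boundaries Optional data.frame with `start`/`end` row ranges per
#'   subject; a single sequence is assumed if omitted.
#' @param keep_xi Return the full time-resolved pairwise posteriors (memory
#'   heavy; used by tests).
#' @return A `state_time_courses` object: list with per-subject `gamma`,
#'   `xi_sum`, optional `xi`, per-subject initial-state posteriors `gamma1`,
#'   and `loglik` (the data term of the evidence lower bound).
#' @export
hmm_e_step <- function(Y, posterior, boundaries = NULL, keep_xi = FALSE) {
  if (inherits(Y, "embedded_dataset")) {
    boundaries <- Y$boundaries
    Y <- Y$reduced
  }
  Y <- as.matrix(Y)
  if (is.null(boundaries))
    boundaries <- data.frame(subject = "s1", start = 1L, end = nrow(Y))
  logB <- expected_loglik_matrix(Y, posterior)
  elog_A <- t(apply(posterior$transition_posterior, 1L, elog_dirichlet))
  if (posterior$K == 1L) elog_A <- matrix(0, 1L, 1L)
  elog_pi <- elog_dirichlet(posterior$initial_posterior)
  out <- lapply(seq_len(nrow(boundaries)), function(i) {
    rows <- boundaries$start[i]:boundaries$end[i]
    forward_backward(logB[rows, , drop = FALSE], elog_A, elog_pi, keep_xi)
  })
  structure(list(
    gamma = lapply(out, `[[`, "gamma"),
    xi_sum = lapply(out, `[[`, "xi_sum"),
    xi = if (keep_xi) lapply(out, `[[`, "xi") else NULL,
    gamma1 = lapply(out, function(o) o$gamma[1L, ]),
    loglik = sum(vapply(out, `[[`, numeric(1L), "loglik")),
    boundaries = boundaries
  ), class = "state_time_courses")
}

#' Variational M-step: update the posterior from state time courses
#'
#' Conjugate updates: Dirichlet counts gain the expected transitions and
#' initial-state posteriors; each state's inverse-Wishart scale gains the
#' gamma-weighted scatter of the (zero-mean) data and its degrees of freedom
#' gain the state's expected occupancy.
#'
#' @param Y Data matrix or `embedded_dataset`.
#' @param stc A `state_time_courses` from [hmm_e_step()].
#' @param posterior The current `hmm_posterior` (supplies priors and K).
#' @return Updated `hmm_posterior`.
#' @export
hmm_m_step <- function(Y, stc, posterior) {
  if (inherits(Y, "embedded_dataset")) Y <- Y$reduced
  Y <- as.matrix(Y)
  K <- posterior$K
  d <- ncol(Y)
  pr <- posterior$priors
  gamma_all <- do.call(rbind, stc$gamma)
  occ <- colSums(gamma_all)
  S <- vector("list", K)
  nu <- numeric(K)
  for (k in seq_len(K)) {
    if (occ[k] < d) {
      warning(sprintf("state %d occupancy %.1f < dimension %d; using prior covariance",
                      k, occ[k], d))
      S[[k]] <- pr$S0
      nu[k] <- pr$nu0
    } else {
      Yw <- Y * sqrt(gamma_all[, k])
      S[[k]] <- pr$S0 + crossprod(Yw)
      nu[k] <- pr$nu0 + occ[k]
    }
  }
  new_hmm_posterior(
    K = K,
    transition_posterior = pr$alpha_trans + Reduce(`+`, stc$xi_sum),
    initial_posterior = pr$alpha_init + Reduce(`+`, stc$gamma1),
    state_scale = S, state_dof = nu, priors = pr,
    free_energy_trace = posterior$free_energy_trace)
}

kl_dirichlet <- function(alpha_q, alpha_p) {
  sum(lgamma(alpha_p)) - lgamma(sum(alpha_p)) -
    sum(lgamma(alpha_q)) + lgamma(sum(alpha_q)) +
    sum((alpha_q - alpha_p) * (digamma(alpha_q) - digamma(sum(alpha_q))))
}

lmvgamma <- function(a, d) {
  d * (d - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}

# KL( Wishart(nu_q, V_q) || Wishart(nu_p, V_p) ) for precision matrices,
# parameterised through the inverse-Wishart scale S = V^{-1}
kl_wishart_from_iw <- function(S_q, nu_q, S_p, nu_p) {
  d <- nrow(S_q)
  Uq <- chol(S_q)
  logdetSq <- 2 * sum(log(diag(Uq)))
  logdetSp <- 2 * sum(log(diag(chol(S_p))))
  elogdet <- sum(digamma((nu_q + 1 - seq_len(d)) / 2)) + d * log(2) - logdetSq
  # E_q[Lambda] = nu_q * S_q^{-1}; tr(S_p E[Lambda]) via triangular solves
  Uiq <- backsolve(Uq, diag(d))
  Sq_inv <- tcrossprod(Uiq)
  tr_term <- nu_q * sum(S_p * Sq_inv)
  (nu_q - nu_p) / 2 * elogdet +
    (tr_term - nu_q * d) / 2 +
    (nu_p - nu_q) * d / 2 * log(2) +
    nu_q / 2 * logdetSq - nu_p / 2 * logdetSp +
    lmvgamma(nu_p / 2, d) - lmvgamma(nu_q / 2, d)
}

#' Variational free energy (negative evidence lower bound)
#'
#' The objective minimised by VB: minus the forward-backward data term plus
#' the KL divergences of the Dirichlet and Wishart posteriors from their
#' priors. Non-increasing over full-batch VB cycles.
#'
#' @param Y Data matrix or `embedded_dataset`.
#' @param posterior An `hmm_posterior`.
#' @param stc A `state_time_courses` from [hmm_e_step()] under `posterior`.
#' @return Scalar free energy.
#' @export
hmm_free_energy <- function(Y, posterior, stc) {
  pr <- posterior$priors
  kl <- kl_dirichlet(posterior$initial_posterior, pr$alpha_init)
  for (j in seq_len(posterior$K))
    kl <- kl + kl_dirichlet(posterior$transition_posterior[j, ],
                            pr$alpha_trans[j, ])
  for (k in seq_len(posterior$K))
    kl <- kl + kl_wishart_from_iw(posterior$state_scale[[k]],
                                  posterior$state_dof[k],
                                  pr$S0, pr$nu0)
  -stc$loglik + kl
}

#' Fit the variational HMM
#'
#' Alternates E and M steps until the relative free-energy change falls below
#' tolerance. Several random initializations are each run briefly and the
#' best (lowest free energy) is continued. With `stochastic = TRUE`, updates
#' use minibatches of whole subjects blended with a Robbins-Monro step-size
#' schedule, followed by one full E-step for the reported state time courses.
#' States in the returned model are sorted by descending fractional
#' occupancy.
#'
#' @param Y Data matrix or (preferably) an `embedded_dataset`, whose subject
#'   boundaries keep the forward-backward recursions from crossing subjects.
#' @param options A `fit_options`.
#' @return List with `posterior` (including `free_energy_trace`), `stc`
#'   (state time courses with `gamma` per subject), and `viterbi` (per-subject
#'   hard paths). If `Y` is an `embedded_dataset`, gamma and Viterbi paths are
#'   padded back to each recording's original length (uniform probabilities /
#'   NA states at the trimmed edges).
#' @export
hmm_fit <- function(Y, options) {
  emb <- NULL
  boundaries <- NULL
  if (inherits(Y, "embedded_dataset")) {
    emb <- Y
    boundaries <- Y$boundaries
    Y <- Y$reduced
  }
  Y <- as.matrix(Y)
  K <- options$K
  d <- ncol(Y)
  if (nrow(Y) < 10 * K * d)
    warning("fewer than 10 * K * d samples; the fit may be unstable")
  priors <- hmm_priors(Y, K)
  seeds <- if (is.null(options$seed)) sample.int(1e6, options$n_starts)
           else options$seed + seq_len(options$n_starts) - 1L
  best <- NULL
  for (r in seq_len(options$n_starts)) {
    opt_r <- options
    opt_r$seed <- seeds[r]
    post <- hmm_init(Y, opt_r, priors)
    fe <- Inf
    for (it in seq_len(options$start_iterations)) {
      stc <- hmm_e_step(Y, post, boundaries)
      fe <- hmm_free_energy(Y, post, stc)
      post$free_energy_trace <- c(post$free_energy_trace, fe)
      post <- hmm_m_step(Y, stc, post)
    }
    if (is.null(best) || fe < best$fe) best <- list(post = post, fe = fe)
  }
  post <- best$post
  if (options$stochastic) {
    post <- stochastic_vb(Y, post, boundaries, options)
  }
  fe_prev <- utils::tail(post$free_energy_trace, 1L)
  for (it in seq_len(options$max_iterations)) {
    stc <- hmm_e_step(Y, post, boundaries)
    fe <- hmm_free_energy(Y, post, stc)
    if (!is.finite(fe))
      stop(sprintf("non-finite free energy at iteration %d", it))
    post$free_energy_trace <- c(post$free_energy_trace, fe)
    done <- is.finite(fe_prev) &&
      abs(fe - fe_prev) <= options$tolerance * abs(fe_prev)
    fe_prev <- fe
    post <- hmm_m_step(Y, stc, post)
    if (done) break
  }
  stc <- hmm_e_step(Y, post, boundaries)
  ord <- order(colSums(do.call(rbind, stc$gamma)), decreasing = TRUE)
  post <- reorder_states(post, ord)
  stc$gamma <- lapply(stc$gamma, function(g) g[, ord, drop = FALSE])
  stc$gamma1 <- lapply(stc$gamma1, function(g) g[ord])
  stc$xi_sum <- lapply(stc$xi_sum, function(x) x[ord, ord, drop = FALSE])
  vit <- viterbi_decode(Y, post, boundaries)
  if (!is.null(emb)) {
    stc$gamma <- pad_gamma(stc$gamma, emb)
    vit <- pad_paths(vit, emb)
  }
  list(posterior = post, stc = stc, viterbi = vit)
}

reorder_states <- function(post, ord) {
  post$transition_posterior <- post$transition_posterior[ord, ord, drop = FALSE]
  post$initial_posterior <- post$initial_posterior[ord]
  post$state_scale <- post$state_scale[ord]
  post$state_dof <- post$state_dof[ord]
  pr <- post$priors
  pr$alpha_trans <- pr$alpha_trans[ord, ord, drop = FALSE]
  pr$alpha_init <- pr$alpha_init[ord]
  post$priors <- pr
  post
}

pad_gamma <- function(gammas, emb) {
  w <- emb$trim
  K <- ncol(gammas[[1L]])
  lapply(gammas, function(g) {
    pad <- matrix(1 / K, w, K)
    rbind(pad, g, pad)
  })
}

pad_paths <- function(paths, emb) {
  w <- emb$trim
  lapply(paths, function(p) c(rep(NA_integer_, w), p, rep(NA_integer_, w)))
}

# stochastic natural-gradient updates on minibatches of whole subjects
stochastic_vb <- function(Y, post, boundaries, options) {
  if (is.null(boundaries))
    boundaries <- data.frame(subject = "s1", start = 1L, end = nrow(Y))
  nsub <- nrow(boundaries)
  B <- min(options$batch_size, nsub)
  pr <- post$priors
  if (!is.null(options$seed)) set.seed(options$seed + 101L)
  for (i in seq_len(options$max_iterations)) {
    rho_i <- (i + options$forget_delay)^(-options$forget_rate)
    pick <- sample.int(nsub, B)
    bsub <- boundaries[pick, , drop = FALSE]
    rows <- unlist(lapply(seq_len(B), function(j) bsub$start[j]:bsub$end[j]))
    bloc <- data.frame(subject = bsub$subject,
                       start = cumsum(c(1L, utils::head(bsub$end - bsub$start + 1L, -1L))),
                       end = cumsum(bsub$end - bsub$start + 1L))
    stc_b <- hmm_e_step(Y[rows, , drop = FALSE], post, bloc)
    scale_f <- nsub / B
    gamma_b <- do.call(rbind, stc_b$gamma)
    occ <- colSums(gamma_b) * scale_f
    hat_trans <- pr$alpha_trans + Reduce(`+`, stc_b$xi_sum) * scale_f
    hat_init <- pr$alpha_init + Reduce(`+`, stc_b$gamma1) * scale_f
    Yb <- Y[rows, , drop = FALSE]
    for (k in seq_len(post$K)) {
      scat <- crossprod(Yb * sqrt(gamma_b[, k])) * scale_f
      post$state_scale[[k]] <- (1 - rho_i) * post$state_scale[[k]] +
        rho_i * (pr$S0 + scat)
      post$state_dof[k] <- (1 - rho_i) * post$state_dof[k] +
        rho_i * (pr$nu0 + occ[k])
    }
    post$transition_posterior <- (1 - rho_i) * post$transition_posterior +
      rho_i * hat_trans
    post$initial_posterior <- (1 - rho_i) * post$initial_posterior +
      rho_i * hat_init
  }
  post
}

#' Viterbi decoding of the most probable state path
#'
#' Maximises the joint path probability under the expected-log parameters of
#' the fitted posterior. Ties are broken toward the lower state index.
#'
#' @param Y Data matrix or `embedded_dataset`.
#' @param posterior A fitted `hmm_posterior`.
#' @param boundaries Optional per-subject row ranges (taken from the
#'   `embedded_dataset` if one is supplied).
#' @return List of integer paths, one per subject.
#' @export
viterbi_decode <- function(Y, posterior, boundaries = NULL) {
  if (inherits(Y, "embedded_dataset")) {
    boundaries <- Y$boundaries
    Y <- Y$reduced
  }
  Y <- as.matrix(Y)
  if (is.null(boundaries))
    boundaries <- data.frame(subject = "s1", start = 1L, end = nrow(Y))
  logB <- expected_loglik_matrix(Y, posterior)
  elog_A <- t(apply(posterior$transition_posterior, 1L, elog_dirichlet))
  if (posterior$K == 1L) elog_A <- matrix(0, 1L, 1L)
  elog_pi <- elog_dirichlet(posterior$initial_posterior)
  lapply(seq_len(nrow(boundaries)), function(i) {
    lb <- logB[boundaries$start[i]:boundaries$end[i], , drop = FALSE]
    viterbi_one(lb, elog_A, elog_pi)
  })
}

viterbi_one <- function(logB, elog_A, elog_pi) {
  T <- nrow(logB)
  K <- ncol(logB)
  delta <- elog_pi + logB[1L, ]
  back <- matrix(0L, T, K)
  if (T > 1L) for (t in 2L:T) {
    cand <- delta + elog_A  # K x K: cand[j, k] = delta_j + log A_jk
    best_j <- apply(cand, 2L, which.max)  # first max = lowest index on ties
    delta <- cand[cbind(best_j, seq_len(K))] + logB[t, ]
    back[t, ] <- best_j
  }
  path <- integer(T)
  path[T] <- which.max(delta)
  if (T > 1L) for (t in (T - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
  path
}

#' Match estimated state labels to reference labels
#'
#' Finds the permutation of estimated labels maximising agreement with a
#' reference labelling (all K! permutations are scored; K is small in
#' practice). NA entries (e.g. padded edges) are ignored.
#'
#' @param estimated,reference Integer vectors of equal length with labels in
#'   1..K.
#' @param K Number of states; inferred from the data if missing.
#' @return List with `permutation` (index k of `estimated` maps to
#'   `permutation[k]`), `accuracy`, and `relabelled`.
#' @export
match_state_labels <- function(estimated, reference, K = NULL) {
  keep <- !is.na(estimated) & !is.na(reference)
  est <- estimated[keep]
  ref <- reference[keep]
  if (is.null(K)) K <- max(est, ref)
  if (K > 8L) stop("permutation matching is limited to K <= 8")
  overlap <- matrix(0, K, K)
  for (k in seq_len(K)) for (l in seq_len(K))
    overlap[k, l] <- sum(est == k & ref == l)
  perms <- all_permutations(K)
  scores <- vapply(perms, function(p) sum(overlap[cbind(seq_len(K), p)]),
                   numeric(1L))
  best <- perms[[which.max(scores)]]
  relab <- estimated
  relab[!is.na(estimated)] <- best[estimated[!is.na(estimated)]]
  list(permutation = best, accuracy = max(scores) / length(est),
       relabelled = relab)
}

all_permutations <- function(K) {
  if (K == 1L) return(list(1L))
  out <- list()
  for (sub in all_permutations(K - 1L)) {
    for (pos in seq_len(K)) {
      out[[length(out) + 1L]] <- append(sub, K, after = pos - 1L)
    }
  }
  out
}
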