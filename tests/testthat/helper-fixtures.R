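# Shared fixtures: tiny hand-checkable models and brute-force oracles.

# A two-state, two-event model with a single binary indicator whose emission
# probabilities for the observed sequence y = (0, 0) are
#   event 1: b_1 = (.7, .2),  event 2: b_2 = (.5, .3)
# with pi = (.6, .4) and A = ((.9, .1), (.2, .8)).
worked_example <- function() {
  spec <- indicator_spec("resp", "nominal", n_categories = 2L)
  logits <- array(0, dim = c(2, 2, 1))
  logits[1, 1, 1] <- log(0.3 / 0.7)   # P(y=0 | item 1, state 1) = .7
  logits[1, 2, 1] <- log(0.8 / 0.2)   # P(y=0 | item 1, state 2) = .2
  logits[2, 1, 1] <- log(0.5 / 0.5)   # P(y=0 | item 2, state 1) = .5
  logits[2, 2, 1] <- log(0.7 / 0.3)   # P(y=0 | item 2, state 2) = .3
  params <- lmm_parameters(
    S = 2, J = 2, specs = list(spec), invariance = "MNI",
    init_logits = logits_from_probs(c(0.6, 0.4)),
    transition_logits = rbind(logits_from_probs(c(0.9, 0.1)),
                              logits_from_probs(c(0.2, 0.8))),
    emissions = list(list(logits = logits)))
  y <- matrix(0, nrow = 2, ncol = 1)   # one subject observing (0, 0)
  list(params = params, y = y)
}

# Random MNI model with one discrete and one continuous indicator.
random_params <- function(S, J, M = 3L) {
  specs <- list(indicator_spec("cat", "nominal", n_categories = M),
                indicator_spec("cont", "continuous"))
  logits <- array(rnorm(J * S * (M - 1), 0, 1), dim = c(J, S, M - 1L))
  mu <- matrix(rnorm(J * S, 0, 2), J, S)
  log_sigma <- matrix(log(runif(J * S, 0.5, 1.5)), J, S)
  pi <- rgamma(S, 2); pi <- pi / sum(pi)
  A <- matrix(rgamma(S * S, 2), S, S); A <- A / rowSums(A)
  lmm_parameters(S, J, specs, "MNI",
                 logits_from_probs(pi), t(apply(A, 1, logits_from_probs)),
                 list(list(logits = logits),
                      list(mu = mu, log_sigma = log_sigma)))
}

random_observations <- function(params) {
  J <- params$J
  M <- params$specs[[1]]$n_categories
  cbind(sample(0:(M - 1), J, replace = TRUE), rnorm(J, 0, 2))
}

# Brute-force oracles: enumerate all S^J latent paths.
enumerate_paths <- function(S, J) {
  as.matrix(expand.grid(rep(list(seq_len(S)), J)))
}

enumerate_loglik <- function(y, params) {
  S <- params$S; J <- params$J
  paths <- enumerate_paths(S, J)
  lik <- 0
  for (r in seq_len(nrow(paths))) {
    lik <- lik + exp(path_logjoint(paths[r, ], y, params))
  }
  log(lik)
}

path_logjoint <- function(path, y, params) {
  lp <- log(init_probs(params))[path[1]]
  A <- transition_matrix(params)
  J <- params$J
  if (J > 1) for (j in 2:J) lp <- lp + log(A[path[j - 1], path[j]])
  for (j in seq_len(J)) lp <- lp + joint_emission_logprob(y[j, ], j, path[j], params)
  lp
}

enumerate_viterbi <- function(y, params) {
  paths <- enumerate_paths(params$S, params$J)
  lp <- apply(paths, 1, path_logjoint, y = y, params = params)
  best <- which(lp == max(lp))
  # ties toward the lexicographically smallest path (lowest state indices)
  if (length(best) > 1) {
    ord <- do.call(order, as.data.frame(paths[best, , drop = FALSE]))
    best <- best[ord[1]]
  }
  list(states = unname(paths[best, ]), log_joint = max(lp))
}

# posterior of state s at event j by direct path enumeration
enumerate_gamma <- function(y, params, j, s) {
  paths <- enumerate_paths(params$S, params$J)
  lp <- apply(paths, 1, path_logjoint, y = y, params = params)
  sum(exp(lp[paths[, j] == s])) / sum(exp(lp))
}

# small simulated dataset for integration-style tests
small_sim <- function(S = 3, N = 150, J = 8, delta = 1.0, seed = 99,
                      generator = "MNI", ...) {
  simulate_lmm(simulation_design(S = S, N = N, J = J, delta = delta,
                                 generator = generator, seed = seed, ...))
}
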