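state_roles_for <- function(S) {
  if (S == 3) c("normal", "noneffortful", "plodding")
  else if (S == 5) c("normal", "noneffortful", "struggling", "efficient", "plodding")
  else stop("state roles are defined for S = 3 or S = 5")
}

default_hyper <- function() {
  list(mu = 4.0,          # normal-state mean of log response time (log-seconds)
       sigma = 0.5,       # state- and item-invariant log-time SD
       lambda = 5,        # normal-state action-count rate
       ordinal_range = c(-1.5, 1.5),  # uniform range of adjacent-category logits
       # half-width of per-item effects on mu / log-lambda under the MNI
       # generator, so noninvariant data differ per item in every channel
       # (the ordinal parameters are drawn per item in any case)
       item_range = 0.5)
}

#' Define one simulation design cell
#'
#' One cell of the Monte Carlo experiments: a state dimensionality with its
#' role labels, an initial-state scenario (balanced, or skewed with mass
#' `1 - .1 (S - 1)` on the normal state), a transition scenario (stayer
#' probability .9 stable / .7 unstable, off-diagonals equal), the between-state
#' emission shift `delta`, the sample size, assessment length, and the
#' generating measurement model (MNI draws per-item emission parameters, MI a
#' single pooled set).
#'
#' @param S Number of latent states, 3 or 5.
#' @param init_scenario `"balanced"` or `"skewed"`.
#' @param transition_scenario `"stable"` (stayer .9) or `"unstable"` (.7).
#' @param delta Emission shift between states: .5 (moderate) or 1.0 (large),
#'   though any positive value is accepted.
#' @param N Number of subjects.
#' @param J Number of measurement events.
#' @param generator Generating measurement model, `"MNI"` or `"MI"`.
#' @param seed Optional integer seed for the cell.
#' @param hyper Normal-state hyperparameters; see Details of the package
#'   vignette. Partial lists are completed with the defaults.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(S = 3, init_scenario = c("balanced", "skewed"),
                              transition_scenario = c("stable", "unstable"),
                              delta = 1.0, N = 500, J = 20,
                              generator = c("MNI", "MI"), seed = NULL,
                              hyper = list()) {
  init_scenario <- match.arg(init_scenario)
  transition_scenario <- match.arg(transition_scenario)
  generator <- match.arg(generator)
  stopifnot(delta > 0, N >= 1, J >= 1)
  roles <- state_roles_for(S)
  hyper <- modifyList(default_hyper(), hyper)
  structure(list(S = as.integer(S), init_scenario = init_scenario,
                 transition_scenario = transition_scenario, delta = delta,
                 N = as.integer(N), J = as.integer(J),
                 generator = generator, state_roles = roles,
                 seed = seed, hyper = hyper),
            class = "simulation_design")
}

design_init_probs <- function(design) {
  S <- design$S
  if (design$init_scenario == "balanced") rep(1 / S, S)
  else c(1 - 0.1 * (S - 1), rep(0.1, S - 1))
}

design_transition_matrix <- function(design) {
  S <- design$S
  stay <- if (design$transition_scenario == "stable") 0.9 else 0.7
  A <- matrix((1 - stay) / (S - 1), S, S)
  diag(A) <- stay
  A
}

default_n_levels <- function(S) if (S == 3) c(250, 500, 1000) else c(500, 1000, 2000)

#' Build the factorial design grid of a simulation study
#'
#' Study `"I"` fully crosses S (3 and 5, or a single supplied value), the
#' initial-state and transition scenarios, the emission shift delta (.5, 1.0)
#' and three sample-size levels (250/500/1000 at S = 3; 500/1000/2000 at
#' S = 5), with the MNI generator throughout. Study `"II"` fixes S = 3 and
#' additionally crosses the generating measurement model (MI vs MNI).
#' Singleton overrides pin any factor to one value.
#'
#' @param study `"I"` or `"II"`.
#' @param S Restrict Study I to one state dimensionality (3 or 5); Study II
#'   default is 3.
#' @param N Override the sample-size levels.
#' @param delta,init_scenario,transition_scenario,generator Optional overrides
#'   of the factor levels.
#' @param J Number of measurement events for every cell.
#' @param hyper Hyperparameter overrides passed to every cell.
#' @return A list of [simulation_design()] objects.
#' @export
make_design_grid <- function(study = c("I", "II"), S = NULL, N = NULL,
                             delta = c(0.5, 1.0),
                             init_scenario = c("balanced", "skewed"),
                             transition_scenario = c("stable", "unstable"),
                             generator = NULL, J = 20, hyper = list()) {
  study <- match.arg(study)
  S_levels <- if (study == "II") (if (is.null(S)) 3L else S) else (if (is.null(S)) c(3L, 5L) else S)
  gen_levels <- if (study == "II") (if (is.null(generator)) c("MI", "MNI") else generator)
                else (if (is.null(generator)) "MNI" else generator)
  designs <- list()
  for (s in S_levels) {
    n_levels <- if (is.null(N)) default_n_levels(s) else N
    grid <- expand.grid(generator = gen_levels, init_scenario = init_scenario,
                        transition_scenario = transition_scenario,
                        delta = delta, N = n_levels,
                        stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grid))) {
      designs[[length(designs) + 1L]] <- simulation_design(
        S = s, init_scenario = grid$init_scenario[r],
        transition_scenario = grid$transition_scenario[r],
        delta = grid$delta[r], N = grid$N[r], J = J,
        generator = grid$generator[r], hyper = hyper)
    }
  }
  designs
}

# reorder a category-probability vector to match a state's accuracy role
reorder_probs_for_role <- function(p, role) {
  M <- length(p)
  switch(role,
    normal = ,                                  # normal working mode scores well
    efficient = sort(p),                        # mass on high categories
    noneffortful = ,
    struggling = sort(p, decreasing = TRUE),    # mass on low categories
    plodding = {                                # unimodal around the middle
      out <- numeric(M)
      mid <- ceiling(M / 2) + 1L      # peak category (0-based index mid - 1)
      ord <- order(abs(seq_len(M) - mid), seq_len(M) - mid)
      out[ord] <- sort(p, decreasing = TRUE)
      out
    },
    stop("unknown state role: ", role))
}

#' Generate emission (and structural) parameters for a design cell
#'
#' The normal state's continuous and count parameters sit at the hyperparameter
#' values; other states shift `mu` and `log(lambda)` by `+/- delta` according
#' to their role (noneffortful: faster and fewer actions; plodding/struggling:
#' slower and more actions; efficient: faster). Adjacent-category logits of the
#' ordinal indicator are drawn uniformly -- per item under the MNI generator,
#' once per state under MI -- and the implied category probabilities are
#' reordered to match each role's accuracy profile. Under the MNI generator,
#' uniform per-item effects of half-width `hyper$item_range` additionally
#' perturb `mu` and `log(lambda)`, so noninvariant data differ per item in
#' every channel.
#'
#' @param design A [simulation_design()].
#' @return An [lmm_parameters()] object (the generating truth). Indicators are
#'   `score` (ordinal, 4 categories), `log_time` (continuous), `actions`
#'   (count).
#' @export
generate_emission_parameters <- function(design) {
  S <- design$S; J <- design$J
  roles <- design$state_roles
  h <- design$hyper
  d <- design$delta
  mni <- design$generator == "MNI"
  Jeff <- if (mni) J else 1L
  time_shift <- unname(vapply(roles, function(r) switch(r,
    normal = 0, noneffortful = -d, plodding = d, struggling = d, efficient = -d),
    numeric(1)))
  count_shift <- unname(vapply(roles, function(r) switch(r,
    normal = 0, noneffortful = -d, plodding = d, struggling = d, efficient = 0),
    numeric(1)))
  specs <- list(indicator_spec("score", "ordinal", n_categories = 4L),
                indicator_spec("log_time", "continuous"),
                indicator_spec("actions", "count"))
  M <- 4L
  # ordinal adjacent logits, reordered per role on the probability scale
  logits <- array(0, dim = c(Jeff, S, M - 1L))
  for (s in seq_len(S)) {
    if (mni) {
      for (j in seq_len(Jeff)) {
        eta <- runif(M - 1L, h$ordinal_range[1], h$ordinal_range[2])
        p <- reorder_probs_for_role(adjacent_emission_probs(eta), roles[s])
        logits[j, s, ] <- adjacent_logits_from_probs(p)
      }
    } else {
      eta <- runif(M - 1L, h$ordinal_range[1], h$ordinal_range[2])
      p <- reorder_probs_for_role(adjacent_emission_probs(eta), roles[s])
      logits[1, s, ] <- adjacent_logits_from_probs(p)
    }
  }
  item_mu <- if (mni && h$item_range > 0) runif(Jeff, -h$item_range, h$item_range) else rep(0, Jeff)
  item_lam <- if (mni && h$item_range > 0) runif(Jeff, -h$item_range, h$item_range) else rep(0, Jeff)
  mu <- outer(item_mu, time_shift, `+`) + h$mu
  log_sigma <- matrix(log(h$sigma), Jeff, S)
  log_lambda <- outer(item_lam, count_shift, `+`) + log(h$lambda)
  pi <- design_init_probs(design)
  A <- design_transition_matrix(design)
  lmm_parameters(S, J, specs, invariance = if (mni) "MNI" else "MI",
                 logits_from_probs(pi), t(apply(A, 1, logits_from_probs)),
                 list(list(logits = logits),
                      list(mu = mu, log_sigma = log_sigma),
                      list(log_lambda = log_lambda)))
}

#' Draw latent state sequences
#'
#' Rows are independent first-order Markov chains under the structural
#' parameters: initial states from `pi`, subsequent states from the rows of
#' the transition matrix.
#'
#' @param params An [lmm_parameters()] object.
#' @param N Number of subjects (chains).
#' @return N x J integer matrix of state labels.
#' @export
draw_state_sequences <- function(params, N) {
  S <- params$S; J <- params$J
  pi <- init_probs(params)
  A <- transition_matrix(params)
  states <- matrix(0L, N, J)
  states[, 1] <- sample.int(S, N, replace = TRUE, prob = pi)
  if (J > 1) for (j in 2:J) {
    for (s in seq_len(S)) {
      idx <- which(states[, j - 1] == s)
      if (length(idx))
        states[idx, j] <- sample.int(S, length(idx), replace = TRUE, prob = A[s, ])
    }
  }
  states
}

#' Generate indicator data given state sequences
#'
#' Each subject-event cell is drawn from the state- and item-specific emission
#' distribution of every indicator.
#'
#' @param states N x J integer state matrix.
#' @param params The generating [lmm_parameters()].
#' @return An [indicator_dataset()].
#' @export
generate_indicator_data <- function(states, params) {
  N <- nrow(states); J <- ncol(states); K <- length(params$specs)
  stopifnot(J == params$J)
  mi <- params$invariance == "MI"
  values <- array(0, dim = c(N, J, K))
  for (k in seq_len(K)) {
    spec <- params$specs[[k]]; em <- params$emissions[[k]]
    for (j in seq_len(J)) {
      jj <- if (mi) 1L else j
      for (s in seq_len(params$S)) {
        idx <- which(states[, j] == s)
        if (!length(idx)) next
        values[idx, j, k] <- switch(spec$family,
          nominal = sample.int(spec$n_categories, length(idx), replace = TRUE,
                               prob = categorical_emission_probs(em$logits[jj, s, ])) - 1L,
          ordinal = sample.int(spec$n_categories, length(idx), replace = TRUE,
                               prob = adjacent_emission_probs(em$logits[jj, s, ])) - 1L,
          continuous = rnorm(length(idx), em$mu[jj, s], exp(em$log_sigma[jj, s])),
          count = rpois(length(idx), exp(em$log_lambda[jj, s])))
      }
    }
  }
  indicator_dataset(values, params$specs)
}

#' Simulate one complete dataset from a design cell
#'
#' Runs the full generating pipeline for one cell: parameter generation, state
#' sequences, indicator data. With a fixed seed the output is bit-reproducible.
#'
#' @param design A [simulation_design()].
#' @return A list of class `lmm_simulation`: `design`, `params` (generating
#'   truth), `states` (N x J), `data` ([indicator_dataset()]).
#' @export
simulate_lmm <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  if (!is.null(design$seed)) set.seed(design$seed %% 2147483647L)
  params <- generate_emission_parameters(design)
  states <- draw_state_sequences(params, design$N)
  data <- generate_indicator_data(states, params)
  structure(list(design = design, params = params, states = states, data = data),
            class = "lmm_simulation")
}
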