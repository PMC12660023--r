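#' Construct a latent Markov model parameter set
#'
#' Parameters are stored on an unconstrained scale -- multinomial logits with
#' state 1 (and category 0) as the fixed reference, `log(sigma)` and
#' `log(lambda)` for the positive emission parameters -- so every derived
#' probability vector satisfies its constraints by construction.
#'
#' Emission parameter arrays carry an item dimension of length J under
#' measurement noninvariance (`invariance = "MNI"`) and of length 1 under the
#' measurement-invariant constraint (`"MI"`), in which case the single set is
#' shared by all items.
#'
#' @param S Number of latent states.
#' @param J Number of measurement events (items).
#' @param specs List of [indicator_spec()] objects.
#' @param invariance `"MNI"` (per-item emission parameters) or `"MI"` (pooled).
#' @param init_logits Length-S vector, first entry 0.
#' @param transition_logits S x S matrix, first column 0 (row-wise reference).
#' @param emissions List of per-indicator parameter blocks: discrete families
#'   use `list(logits = array(Jeff x S x (M-1)))`, continuous
#'   `list(mu, log_sigma)` (each Jeff x S), count `list(log_lambda)` (Jeff x S),
#'   where `Jeff` is `J` under MNI and 1 under MI.
#' @return An object of class `lmm_parameters`.
#' @seealso [init_probs()], [transition_matrix()], [natural_parameter_table()]
#' @export
lmm_parameters <- function(S, J, specs, invariance = c("MNI", "MI"),
                           init_logits, transition_logits, emissions) {
  invariance <- match.arg(invariance)
  S <- as.integer(S); J <- as.integer(J)
  stopifnot(S >= 1, J >= 1)
  if (inherits(specs, "indicator_spec")) specs <- list(specs)
  K <- length(specs)
  init_logits <- as.numeric(init_logits)
  transition_logits <- as.matrix(transition_logits)
  if (length(init_logits) != S) stop("init_logits must have length S")
  if (!all(dim(transition_logits) == c(S, S))) stop("transition_logits must be S x S")
  if (init_logits[1] != 0 || any(transition_logits[, 1] != 0))
    stop("reference-state logits (state 1) must be exactly zero")
  if (any(!is.finite(init_logits)) || any(!is.finite(transition_logits)))
    stop("structural logits must be finite")
  Jeff <- if (invariance == "MI") 1L else J
  if (length(emissions) != K) stop("one emission block per indicator is required")
  for (k in seq_len(K)) {
    spec <- specs[[k]]; em <- emissions[[k]]
    if (is_discrete(spec)) {
      d <- dim(em$logits)
      if (is.null(d) || !all(d == c(Jeff, S, spec$n_categories - 1L)))
        stop("indicator '", spec$name, "': logits must be a ", Jeff, " x ", S,
             " x ", spec$n_categories - 1L, " array")
    } else if (spec$family == "continuous") {
      if (!all(dim(em$mu) == c(Jeff, S)) || !all(dim(em$log_sigma) == c(Jeff, S)))
        stop("indicator '", spec$name, "': mu and log_sigma must be ", Jeff, " x ", S)
    } else {
      if (!all(dim(em$log_lambda) == c(Jeff, S)))
        stop("indicator '", spec$name, "': log_lambda must be ", Jeff, " x ", S)
    }
  }
  structure(list(S = S, J = J, specs = specs, invariance = invariance,
                 init_logits = init_logits, transition_logits = transition_logits,
                 emissions = emissions),
            class = "lmm_parameters")
}

#' Initial-state probability vector
#' @param params An [lmm_parameters()] object.
#' @return Length-S probability vector.
#' @export
init_probs <- function(params) probs_from_logits(params$init_logits)

#' Transition probability matrix
#' @param params An [lmm_parameters()] object.
#' @return S x S row-stochastic matrix.
#' @export
transition_matrix <- function(params) {
  t(apply(params$transition_logits, 1, probs_from_logits))
}

#' @export
print.lmm_parameters <- function(x, ...) {
  cat("lmm_parameters: S =", x$S, ", J =", x$J, ", K =", length(x$specs),
      ", invariance =", x$invariance, "\n")
  cat("  pi:", round(init_probs(x), 3), "\n")
  cat("  A diag:", round(diag(transition_matrix(x)), 3), "\n")
  invisible(x)
}

# number of items the emission arrays actually carry
item_dim <- function(params) if (params$invariance == "MI") 1L else params$J

#' Number of free parameters (model degrees of freedom)
#'
#' Structural: (S - 1) initial logits plus S(S - 1) transition logits. Per
#' indicator and per stored item: (M - 1) logits for discrete families, two
#' parameters (location, scale) for continuous, one rate for count.
#'
#' @param params An [lmm_parameters()] object.
#' @return Integer parameter count.
#' @export
n_parameters <- function(params) {
  S <- params$S; Jeff <- item_dim(params)
  df <- (S - 1L) + S * (S - 1L)
  for (spec in params$specs) {
    df <- df + switch(spec$family,
      nominal = ,
      ordinal = Jeff * S * (spec$n_categories - 1L),
      continuous = 2L * Jeff * S,
      count = Jeff * S)
  }
  as.integer(df)
}

#' Natural-scale parameter table
#'
#' Flattens a parameter object to a tidy table on the scales the model is
#' usually reported on: initial-state probabilities, transition probabilities,
#' per-category emission probabilities for discrete indicators, and mu / sigma /
#' lambda for the continuous and count indicators. For transition rows, `state`
#' is the origin and `category` the destination state.
#'
#' @param params An [lmm_parameters()] object.
#' @param J_out Broadcast MI (pooled) emission parameters over this many items,
#'   so MI and MNI objects can be compared row by row. Defaults to the stored
#'   item dimension.
#' @return A data.frame with columns `domain`, `indicator`, `item`, `state`,
#'   `category`, `value`.
#' @export
natural_parameter_table <- function(params, J_out = NULL) {
  S <- params$S
  Jeff <- item_dim(params)
  if (is.null(J_out)) J_out <- Jeff
  if (Jeff != 1L && J_out != Jeff)
    stop("cannot broadcast per-item parameters to a different item count")
  rows <- list()
  pi <- init_probs(params)
  rows[[length(rows) + 1L]] <- data.frame(
    domain = "init", indicator = "", item = 0L, state = seq_len(S),
    category = NA_integer_, value = pi)
  A <- transition_matrix(params)
  rows[[length(rows) + 1L]] <- data.frame(
    domain = "transition", indicator = "", item = 0L,
    state = rep(seq_len(S), times = S), category = rep(seq_len(S), each = S),
    value = as.vector(A))
  items <- seq_len(J_out)
  for (k in seq_along(params$specs)) {
    spec <- params$specs[[k]]; em <- params$emissions[[k]]
    jj_of <- function(j) if (Jeff == 1L) 1L else j
    if (is_discrete(spec)) {
      M <- spec$n_categories
      for (j in items) for (s in seq_len(S)) {
        pr <- if (spec$family == "nominal")
          categorical_emission_probs(em$logits[jj_of(j), s, ])
        else adjacent_emission_probs(em$logits[jj_of(j), s, ])
        rows[[length(rows) + 1L]] <- data.frame(
          domain = "category_prob", indicator = spec$name, item = j, state = s,
          category = 0:(M - 1L), value = pr)
      }
    } else if (spec$family == "continuous") {
      for (j in items) {
        jj <- jj_of(j)
        rows[[length(rows) + 1L]] <- data.frame(
          domain = "mu", indicator = spec$name, item = j, state = seq_len(S),
          category = NA_integer_, value = em$mu[jj, ])
        rows[[length(rows) + 1L]] <- data.frame(
          domain = "sigma", indicator = spec$name, item = j, state = seq_len(S),
          category = NA_integer_, value = exp(em$log_sigma[jj, ]))
      }
    } else {
      for (j in items) {
        jj <- jj_of(j)
        rows[[length(rows) + 1L]] <- data.frame(
          domain = "lambda", indicator = spec$name, item = j, state = seq_len(S),
          category = NA_integer_, value = exp(em$log_lambda[jj, ]))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# fast natural-scale vector used for the EM parameter-change criterion
natural_parameter_vector <- function(params) {
  tab <- c(init_probs(params), as.vector(transition_matrix(params)))
  for (k in seq_along(params$specs)) {
    spec <- params$specs[[k]]; em <- params$emissions[[k]]
    if (is_discrete(spec)) {
      tab <- c(tab, as.vector(category_prob_matrix(em$logits, spec$family)))
    } else if (spec$family == "continuous") {
      tab <- c(tab, as.vector(em$mu), as.vector(exp(em$log_sigma)))
    } else {
      tab <- c(tab, as.vector(exp(em$log_lambda)))
    }
  }
  tab
}

#' Relabel latent states
#'
#' Reorders the states of a parameter object so that new state `k` is old state
#' `perm[k]`; used to undo label switching after [align_state_labels()].
#'
#' @param params An [lmm_parameters()] object.
#' @param perm Integer permutation of `1:S`.
#' @return The relabeled `lmm_parameters` object.
#' @export
permute_states <- function(params, perm) {
  S <- params$S
  stopifnot(length(perm) == S, all(sort(perm) == seq_len(S)))
  pi <- init_probs(params)[perm]
  A <- transition_matrix(params)[perm, perm, drop = FALSE]
  emissions <- params$emissions
  for (k in seq_along(emissions)) {
    spec <- params$specs[[k]]
    if (is_discrete(spec)) {
      emissions[[k]]$logits <- emissions[[k]]$logits[, perm, , drop = FALSE]
    } else if (spec$family == "continuous") {
      emissions[[k]]$mu <- emissions[[k]]$mu[, perm, drop = FALSE]
      emissions[[k]]$log_sigma <- emissions[[k]]$log_sigma[, perm, drop = FALSE]
    } else {
      emissions[[k]]$log_lambda <- emissions[[k]]$log_lambda[, perm, drop = FALSE]
    }
  }
  lmm_parameters(S, params$J, params$specs, params$invariance,
                 logits_from_probs(pi),
                 t(apply(A, 1, logits_from_probs)),
                 emissions)
}
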