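#' Scaled forward recursion for one subject
#'
#' Computes the scaled forward table `alpha[j, s]`, the per-event normalizers,
#' and the observed-data log-likelihood of a single subject's indicator
#' sequence. Each event's emission column is rescaled before normalization, so
#' the recursion is safe against underflow; the log-likelihood is recovered as
#' the sum of the log scale factors.
#'
#' @param data_i A J x K matrix of one subject's observations (or a one-subject
#'   [indicator_dataset()]).
#' @param params An [lmm_parameters()] object.
#' @return A list with `alpha` (J x S, rows summing to 1), `scale` (length J
#'   normalizers) and `loglik`.
#' @export
forward_pass <- function(data_i, params) {
  fb <- forward_backward(data_i, params)
  list(alpha = fb$alpha[1, , , drop = TRUE], scale = exp(fb$log_scale[1, ]),
       loglik = fb$loglik)
}

#' Scaled backward recursion for one subject
#'
#' Backward table scaled by the forward normalizers, so that
#' `sum_s alpha[j, s] * beta[j, s] = 1` at every event.
#'
#' @inheritParams forward_pass
#' @return J x S matrix `beta` with `beta[J, ] = 1`.
#' @export
backward_pass <- function(data_i, params) {
  fb <- forward_backward(data_i, params)
  fb$beta[1, , , drop = TRUE]
}

#' Posterior state probabilities for one subject
#'
#' Marginal posteriors `gamma[j, s]` of occupying state s at event j, and
#' pairwise posteriors `xi[j, s, s']` of transitioning from s at j to s' at
#' j + 1, given the full observation sequence.
#'
#' @inheritParams forward_pass
#' @return A list with `gamma` (J x S), `xi` ((J-1) x S x S) and `loglik`.
#' @export
posterior_marginals <- function(data_i, params) {
  fb <- forward_backward(data_i, params)
  xi <- if (params$J > 1) array(fb$xi[1, , , ], dim = dim(fb$xi)[-1]) else NULL
  list(gamma = fb$gamma[1, , , drop = TRUE], xi = xi, loglik = fb$loglik)
}

# Batch forward-backward over all subjects (compiled core). With full = TRUE
# returns scaled alpha/beta, gamma, the full xi table and per-event log
# normalizers; with full = FALSE only gamma, the summed xi matrix and the
# log-likelihood (the EM path).
forward_backward <- function(data, params, logb = NULL, full = TRUE) {
  if (is.null(logb)) logb <- emission_logprob_array(data, params)
  d <- dim(logb)
  out <- .fb_cpp(logb, d[1], d[2], d[3],
                 init_probs(params), transition_matrix(params), full)
  out$loglik_by_subject <- out$loglik
  out$loglik <- sum(out$loglik)
  out
}

#' Complete-data log-likelihood
#'
#' Joint log-probability of observed indicator sequences and given latent state
#' sequences: initial-state, transition, and emission terms summed over
#' subjects. A transition (or initial state) of probability zero under the
#' given sequences yields `-Inf` with a warning.
#'
#' @param states N x J integer matrix of state sequences (a vector for one
#'   subject).
#' @param data An [indicator_dataset()] (or J x K matrix for one subject).
#' @param params An [lmm_parameters()] object.
#' @return Scalar log-likelihood.
#' @export
complete_data_loglik <- function(states, data, params) {
  values <- as_values_array(data)
  N <- dim(values)[1]; J <- dim(values)[2]
  if (is.vector(states)) states <- matrix(states, nrow = 1)
  stopifnot(nrow(states) == N, ncol(states) == J)
  if (any(states < 1) || any(states > params$S)) stop("state labels out of range")
  lpi <- log(init_probs(params))
  lA <- log(transition_matrix(params))
  logb <- emission_logprob_array(values, params)
  total <- 0
  for (i in seq_len(N)) {
    ll <- lpi[states[i, 1]] + logb[i, 1, states[i, 1]]
    if (J > 1) for (j in 2:J) {
      ll <- ll + lA[states[i, j - 1], states[i, j]] + logb[i, j, states[i, j]]
    }
    total <- total + ll
  }
  if (!is.finite(total)) warning("a given state path has zero probability; log-likelihood is -Inf")
  total
}

#' Observed-data log-likelihood
#'
#' Marginal log-likelihood of the indicator data with the latent states summed
#' out, computed by the scaled forward recursion.
#'
#' @inheritParams complete_data_loglik
#' @return Scalar log-likelihood.
#' @export
observed_loglik <- function(data, params) {
  forward_backward(data, params, full = FALSE)$loglik
}
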