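#' Viterbi decoding of latent state sequences
#'
#' Exact maximum a posteriori state sequences: for each subject the max-product
#' recursion in log space returns the jointly most probable path through all
#' S^J candidate sequences, with ties broken toward the lowest state index.
#'
#' @param data An [indicator_dataset()], or a J x K matrix for one subject.
#' @param params An [lmm_parameters()] object.
#' @return For a dataset: a list with `states` (N x J integer matrix) and
#'   `log_joint` (length-N vector of maximized joint log-probabilities). For a
#'   single subject: a list of class `state_sequence` with `states` (length-J
#'   vector) and `log_joint`.
#' @export
viterbi_decode <- function(data, params) {
  single <- !inherits(data, "indicator_dataset") && is.matrix(data)
  logb <- emission_logprob_array(data, params)
  d <- dim(logb)
  lpi <- log(init_probs(params))
  lA <- log(transition_matrix(params))
  out <- .viterbi_cpp(logb, d[1], d[2], d[3], lpi, lA)
  if (single) {
    structure(list(states = as.integer(out$states[1, ]),
                   log_joint = out$log_joint[1]),
              class = "state_sequence")
  } else {
    list(states = out$states, log_joint = out$log_joint)
  }
}

#' Per-event posterior state assignment (diagnostic)
#'
#' Event-wise argmax of the marginal posteriors gamma. This is not the
#' maximum a posteriori sequence estimator -- the jointly most probable path is
#' given by [viterbi_decode()] -- and may even select locally plausible but
#' jointly impossible sequences; it is exposed only as a diagnostic.
#'
#' @inheritParams viterbi_decode
#' @return A list with `states` (N x J matrix of per-event argmax labels) and
#'   `gamma` (N x J x S posterior array).
#' @export
posterior_states <- function(data, params) {
  fb <- forward_backward(data, params, full = FALSE)
  d <- dim(fb$gamma)
  states <- matrix(0L, d[1], d[2])
  for (j in seq_len(d[2])) {
    g <- matrix(fb$gamma[, j, ], nrow = d[1])
    states[, j] <- max.col(g, ties.method = "first")
  }
  list(states = states, gamma = fb$gamma)
}

#' Write decoded sequences to long-format CSV
#'
#' One row per subject-event with the Viterbi state and the posterior state
#' probabilities `gamma_1..gamma_S`.
#'
#' @param path Output file path.
#' @inheritParams viterbi_decode
#' @return The written data.frame, invisibly.
#' @export
write_decoded_csv <- function(path, data, params) {
  dec <- viterbi_decode(data, params)
  fb <- forward_backward(data, params, full = FALSE)
  N <- nrow(dec$states); J <- ncol(dec$states); S <- params$S
  out <- data.frame(subject = rep(seq_len(N), each = J),
                    event = rep(seq_len(J), times = N),
                    state = as.vector(t(dec$states)))
  for (s in seq_len(S)) {
    g <- matrix(fb$gamma[, , s], nrow = N)
    out[[paste0("gamma_", s)]] <- as.vector(t(g))
  }
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
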