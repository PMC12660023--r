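#' Category probabilities of a baseline-category multinomial logit
#'
#' Category 0 is the fixed reference with logit zero; the remaining `M - 1`
#' logits give the log odds of each category against category 0. The softmax is
#' computed with max-subtraction so extreme logits cannot overflow.
#'
#' @param logits Numeric vector of length `M - 1` (finite).
#' @return Probability vector of length `M` summing to one.
#' @examples
#' categorical_emission_probs(c(0, 0, 0))        # uniform over 4 categories
#' categorical_emission_probs(log(c(3, 3, 3)))   # (.1, .3, .3, .3)
#' @export
categorical_emission_probs <- function(logits) {
  if (!is.numeric(logits) || length(logits) < 1L || any(!is.finite(logits)))
    stop("logits must be a non-empty finite numeric vector")
  full <- c(0, logits)
  e <- exp(full - max(full))
  e / sum(e)
}

#' Category probabilities of an adjacent-categories logit model
#'
#' The m-th logit is the log odds between neighbouring categories,
#' `eta_m = log P(m) - log P(m - 1)`, so the baseline-category logits are the
#' cumulative sums of `eta`.
#'
#' @param adjacent_logits Numeric vector `eta_1 .. eta_{M-1}` (finite).
#' @return Probability vector of length `M` summing to one.
#' @examples
#' adjacent_emission_probs(log(c(2, 2, 2)))  # (1, 2, 4, 8) / 15
#' @export
adjacent_emission_probs <- function(adjacent_logits) {
  if (!is.numeric(adjacent_logits) || length(adjacent_logits) < 1L ||
      any(!is.finite(adjacent_logits)))
    stop("adjacent logits must be a non-empty finite numeric vector")
  categorical_emission_probs(cumsum(adjacent_logits))
}

#' Gaussian log-density of a continuous indicator
#'
#' @param y Observed value(s).
#' @param mu Location parameter.
#' @param sigma Scale parameter, strictly positive.
#' @return Log-density value(s).
#' @export
gaussian_logdensity <- function(y, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  dnorm(y, mean = mu, sd = sigma, log = TRUE)
}

#' Poisson log-mass of a count indicator
#'
#' @param y Non-negative integer count(s).
#' @param lambda Rate parameter, strictly positive.
#' @return Log-probability value(s).
#' @export
poisson_logpmf <- function(y, lambda) {
  if (any(lambda <= 0)) stop("lambda must be strictly positive")
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  dpois(y, lambda = lambda, log = TRUE)
}

#' Probabilities from reference-constrained multinomial logits
#'
#' Inverse-softmax parameterization used by the structural models: the logit of
#' the reference level (the first entry) is fixed at zero and the remaining
#' entries are free. The map is invertible up to that constraint (see
#' [logits_from_probs()]).
#'
#' @param logits Numeric vector whose first entry is the (zero) reference.
#' @return Probability vector of the same length.
#' @export
probs_from_logits <- function(logits) {
  if (any(!is.finite(logits))) stop("logits must be finite")
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Reference-constrained logits from a probability vector
#'
#' @param probs Probability vector with strictly positive entries.
#' @param floor Probabilities are clamped below at this value before taking
#'   logs, so degenerate M-step outputs stay representable.
#' @return Logit vector with first entry exactly zero.
#' @export
logits_from_probs <- function(probs, floor = 1e-12) {
  p <- pmax(probs, floor)
  l <- log(p) - log(p[1])
  l[1] <- 0
  l
}

# adjacent-categories logits from a category probability vector
adjacent_logits_from_probs <- function(probs, floor = 1e-12) {
  p <- pmax(probs, floor)
  diff(log(p))
}

#' Joint emission log-probability of one measurement event
#'
#' Sums the family-appropriate log density/mass over the K indicators observed
#' at one event, under local independence given the latent state. Under the
#' measurement-invariant (MI) constraint the same emission parameters are used
#' for every item, so the result does not depend on `item`.
#'
#' @param y_event Length-K vector of indicator values at one event, ordered as
#'   `params$specs`.
#' @param item Measurement-event index in `1..J`.
#' @param state Latent-state index in `1..S`.
#' @param params An [lmm_parameters()] object.
#' @return Scalar log-probability.
#' @export
joint_emission_logprob <- function(y_event, item, state, params) {
  stopifnot(item >= 1, item <= params$J, state >= 1, state <= params$S)
  K <- length(params$specs)
  if (length(y_event) != K) stop("y_event must have one value per indicator")
  jj <- if (params$invariance == "MI") 1L else as.integer(item)
  out <- 0
  for (k in seq_len(K)) {
    spec <- params$specs[[k]]
    em <- params$emissions[[k]]
    y <- y_event[k]
    out <- out + switch(spec$family,
      nominal = {
        check_category(y, spec)
        log(categorical_emission_probs(em$logits[jj, state, ]))[y + 1]
      },
      ordinal = {
        check_category(y, spec)
        log(adjacent_emission_probs(em$logits[jj, state, ]))[y + 1]
      },
      continuous = gaussian_logdensity(y, em$mu[jj, state], exp(em$log_sigma[jj, state])),
      count = poisson_logpmf(y, exp(em$log_lambda[jj, state]))
    )
  }
  out
}

check_category <- function(y, spec) {
  if (y != round(y) || y < 0 || y > spec$n_categories - 1)
    stop("value ", y, " out of range for discrete indicator '", spec$name, "'")
  invisible(TRUE)
}

# category probabilities for every (item, state) block of a discrete
# indicator: returns a (Jeff * S) x M matrix, rows in column-major (j, s) order
category_prob_matrix <- function(logits, family) {
  d <- dim(logits)
  B <- matrix(logits, nrow = d[1] * d[2], ncol = d[3])
  if (family == "ordinal" && d[3] > 1) {
    # row-wise cumulative sums as one matrix product
    U <- upper.tri(diag(d[3]), diag = TRUE) * 1
    B <- B %*% U
  }
  full <- cbind(0, B)
  mx <- full[, 1]
  for (m in seq_len(ncol(full))[-1]) mx <- pmax(mx, full[, m])
  e <- exp(full - mx)
  e / rowSums(e)
}

# per-dataset quantities that do not change across EM iterations
emission_cache <- function(values, specs = NULL) {
  N <- dim(values)[1]; J <- dim(values)[2]; K <- dim(values)[3]
  cache <- vector("list", K)
  for (k in seq_len(K)) {
    y <- matrix(values[, , k], nrow = N)
    yvec <- as.vector(y)
    cache[[k]] <- list(y = y, yvec = yvec, yint = as.integer(yvec),
                       lgam = lgamma(yvec + 1))
  }
  cache
}

# N x J x S array of per-event emission log-probabilities for a whole dataset.
# The workhorse behind the forward-backward and Viterbi recursions; `cache`
# (from emission_cache) avoids recomputing data-only terms inside EM.
emission_logprob_array <- function(data, params, cache = NULL) {
  values <- as_values_array(data)
  N <- dim(values)[1]; J <- dim(values)[2]; K <- dim(values)[3]
  S <- params$S
  if (J != params$J) stop("dataset has ", J, " events but parameters expect ", params$J)
  if (K != length(params$specs)) stop("indicator count mismatch")
  if (is.null(cache)) cache <- emission_cache(values)
  blocks <- vector("list", K)
  for (k in seq_len(K)) {
    spec <- params$specs[[k]]
    em <- params$emissions[[k]]
    blocks[[k]] <- if (is_discrete(spec)) {
      list(type = 1L, jeff = dim(em$logits)[1], y = as.numeric(cache[[k]]$yint),
           logP = log(category_prob_matrix(em$logits, spec$family)))
    } else if (spec$family == "continuous") {
      list(type = 2L, jeff = nrow(em$mu), y = cache[[k]]$yvec,
           mu = em$mu, sigma = exp(em$log_sigma))
    } else {
      list(type = 3L, jeff = nrow(em$log_lambda), y = cache[[k]]$yvec,
           log_lambda = em$log_lambda, lambda = exp(em$log_lambda),
           lgam = cache[[k]]$lgam)
    }
  }
  .emission_logprob_cpp(N, J, S, blocks)
}
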