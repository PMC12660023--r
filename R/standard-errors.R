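# pack the free (unconstrained) parameters into a named vector
pack_parameters <- function(params) {
  S <- params$S
  v <- numeric(0); nm <- character(0)
  if (S > 1) {
    v <- c(v, params$init_logits[-1])
    nm <- c(nm, paste0("init_logit.", 2:S))
    for (s in seq_len(S)) {
      v <- c(v, params$transition_logits[s, -1])
      nm <- c(nm, paste0("trans_logit.", s, ".", 2:S))
    }
  }
  for (k in seq_along(params$specs)) {
    spec <- params$specs[[k]]; em <- params$emissions[[k]]
    Jeff <- item_dim(params)
    if (is_discrete(spec)) {
      M <- spec$n_categories
      for (jj in seq_len(Jeff)) for (s in seq_len(S)) {
        v <- c(v, em$logits[jj, s, ])
        nm <- c(nm, paste0(spec$name, ".logit.", jj, ".", s, ".", seq_len(M - 1)))
      }
    } else if (spec$family == "continuous") {
      v <- c(v, as.vector(em$mu), as.vector(em$log_sigma))
      nm <- c(nm,
              paste0(spec$name, ".mu.", rep(seq_len(Jeff), times = S), ".", rep(seq_len(S), each = Jeff)),
              paste0(spec$name, ".log_sigma.", rep(seq_len(Jeff), times = S), ".", rep(seq_len(S), each = Jeff)))
    } else {
      v <- c(v, as.vector(em$log_lambda))
      nm <- c(nm, paste0(spec$name, ".log_lambda.", rep(seq_len(Jeff), times = S), ".", rep(seq_len(S), each = Jeff)))
    }
  }
  setNames(v, nm)
}

unpack_parameters <- function(v, template) {
  S <- template$S
  pos <- 0L
  take <- function(n) {
    out <- v[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  init_logits <- template$init_logits
  transition_logits <- template$transition_logits
  if (S > 1) {
    init_logits <- c(0, take(S - 1))
    for (s in seq_len(S)) transition_logits[s, ] <- c(0, take(S - 1))
  }
  emissions <- template$emissions
  Jeff <- item_dim(template)
  for (k in seq_along(template$specs)) {
    spec <- template$specs[[k]]
    if (is_discrete(spec)) {
      M <- spec$n_categories
      for (jj in seq_len(Jeff)) for (s in seq_len(S))
        emissions[[k]]$logits[jj, s, ] <- take(M - 1)
    } else if (spec$family == "continuous") {
      emissions[[k]]$mu <- matrix(take(Jeff * S), Jeff, S)
      emissions[[k]]$log_sigma <- matrix(take(Jeff * S), Jeff, S)
    } else {
      emissions[[k]]$log_lambda <- matrix(take(Jeff * S), Jeff, S)
    }
  }
  lmm_parameters(S, template$J, template$specs, template$invariance,
                 init_logits, transition_logits, emissions)
}

#' Standard errors from the numerical Hessian
#'
#' Central-difference Hessian of the observed-data log-likelihood on the
#' unconstrained parameterization (reference-constrained logits, log-sigma,
#' log-lambda); standard errors are the square roots of the diagonal of the
#' inverse negative Hessian. A Hessian that is not negative definite is
#' repaired by clipping its eigenvalues with a warning; coordinates whose
#' repaired variance is not positive are reported as `NA`.
#'
#' The cost grows quadratically in the number of free parameters, so this is
#' intended for the converged fit of a model of moderate size.
#'
#' @param params Converged [lmm_parameters()] (or an `lmm_fit`, whose
#'   parameters are used).
#' @param data The [indicator_dataset()] the model was fit to.
#' @return A data.frame with columns `parameter`, `estimate`, `se`, where
#'   `parameter` names the unconstrained coordinate.
#' @export
standard_errors <- function(params, data) {
  if (inherits(params, "lmm_fit")) params <- params$params
  v0 <- pack_parameters(params)
  f <- function(v) observed_loglik(data, unpack_parameters(v, params))
  H <- pracma::hessian(f, as.numeric(v0))
  negH <- -(H + t(H)) / 2
  ev <- eigen(negH, symmetric = TRUE)
  tolv <- max(abs(ev$values)) * 1e-10
  if (any(ev$values <= tolv)) {
    warning("negative Hessian is not positive definite; eigenvalues clipped for the repair")
    vals <- pmax(ev$values, tolv)
  } else {
    vals <- ev$values
  }
  cov <- ev$vectors %*% diag(1 / vals, length(vals)) %*% t(ev$vectors)
  var <- diag(cov)
  se <- ifelse(var > 0, sqrt(var), NA_real_)
  data.frame(parameter = names(v0), estimate = as.numeric(v0), se = se)
}
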