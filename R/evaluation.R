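permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutations_of(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# natural-scale comparison vector: estimated table broadcast to the truth's
# item dimension and ordered canonically
comparison_table <- function(params, J_out) {
  tab <- natural_parameter_table(params, J_out = J_out)
  tab[order(tab$domain, tab$indicator, tab$item, tab$state,
            ifelse(is.na(tab$category), -1L, tab$category)), , drop = FALSE]
}

#' Align estimated state labels to the generating truth
#'
#' Latent-state labels are arbitrary up to permutation (label switching). This
#' searches all S! permutations and selects the one minimizing the summed
#' squared distance between the estimated and generating parameter vectors,
#' concatenated across all domains on their natural scales (probabilities,
#' mu, sigma, lambda). MI estimates are broadcast over items before comparison
#' with per-item truth.
#'
#' @param estimated Estimated [lmm_parameters()] (or an `lmm_fit`).
#' @param truth Generating [lmm_parameters()].
#' @return A list with `perm` (integer vector: estimated state `perm[k]`
#'   corresponds to true state `k`), `aligned` (the relabeled estimate), and
#'   `distance` (the minimized squared distance).
#' @export
align_state_labels <- function(estimated, truth) {
  if (inherits(estimated, "lmm_fit")) estimated <- estimated$params
  S <- truth$S
  stopifnot(estimated$S == S, estimated$J == truth$J)
  J_out <- max(item_dim(truth), item_dim(estimated))
  truth_vec <- comparison_table(truth, J_out)$value
  # relabeling a parameter object only permutes rows of its natural table, so
  # each candidate permutation is evaluated by an index lookup on one table
  # rather than by rebuilding the object
  tab <- comparison_table(estimated, J_out)
  cat0 <- ifelse(is.na(tab$category), -1L, tab$category)
  keys <- paste(tab$domain, tab$indicator, tab$item, tab$state, cat0, sep = "\r")
  lookup <- setNames(seq_along(keys), keys)
  best <- NULL
  for (p in permutations_of(S)) {
    state_p <- p[tab$state]
    cat_p <- ifelse(tab$domain == "transition", p[tab$category], cat0)
    idx <- lookup[paste(tab$domain, tab$indicator, tab$item, state_p, cat_p, sep = "\r")]
    d <- sum((tab$value[idx] - truth_vec)^2)
    if (is.null(best) || d < best$distance) best <- list(perm = p, distance = d)
  }
  best$aligned <- if (identical(best$perm, seq_len(S))) estimated
                  else permute_states(estimated, best$perm)
  best[c("perm", "aligned", "distance")]
}

#' Bias, absolute bias and RMSE of aligned estimates
#'
#' Summarizes estimation error against the generating truth per congeneric
#' parameter domain: initial-state probabilities (reference state 1 excluded),
#' transition probabilities (reference destination state 1 excluded), ordinal
#' category probabilities (reference category 0 excluded), and the location,
#' scale and rate parameters. Errors pool over items, states, categories and
#' replications within each domain.
#'
#' @param estimates A single aligned [lmm_parameters()] or a list of them (one
#'   per replication).
#' @param truth Generating [lmm_parameters()].
#' @return A data.frame of class `evaluation_report` with columns `domain`,
#'   `bias`, `abs_bias`, `rmse`, `n`.
#' @export
bias_rmse_summary <- function(estimates, truth) {
  if (inherits(estimates, "lmm_parameters")) estimates <- list(estimates)
  J_out <- item_dim(truth)
  for (est in estimates) J_out <- max(J_out, item_dim(est))
  truth_tab <- comparison_table(truth, J_out)
  keep <- !(truth_tab$domain == "init" & truth_tab$state == 1) &
          !(truth_tab$domain == "transition" & truth_tab$category == 1) &
          !(truth_tab$domain == "category_prob" & truth_tab$category == 0)
  errs <- lapply(estimates, function(est) {
    tab <- comparison_table(est, J_out)
    if (nrow(tab) != nrow(truth_tab)) stop("estimate and truth tables do not conform")
    (tab$value - truth_tab$value)[keep]
  })
  e <- do.call(cbind, errs)
  dom <- truth_tab$domain[keep]
  doms <- unique(dom)
  out <- data.frame(domain = doms,
                    bias = NA_real_, abs_bias = NA_real_, rmse = NA_real_,
                    n = NA_integer_)
  for (r in seq_along(doms)) {
    ed <- e[dom == doms[r], , drop = FALSE]
    out$bias[r] <- mean(ed)
    out$abs_bias[r] <- mean(abs(ed))
    out$rmse[r] <- sqrt(mean(ed^2))
    out$n[r] <- length(ed)
  }
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' State match rate
#'
#' Fraction of subject-event cells whose decoded state equals the true state,
#' after mapping the decoded labels through the alignment permutation.
#'
#' @param decoded N x J matrix of decoded state labels.
#' @param truth N x J matrix of true state labels.
#' @param perm Alignment permutation from [align_state_labels()] (estimated
#'   state `perm[k]` corresponds to true state `k`); identity by default.
#' @return Match rate in `[0, 1]`.
#' @export
state_match_rate <- function(decoded, truth, perm = NULL) {
  stopifnot(all(dim(decoded) == dim(truth)))
  if (is.null(perm)) perm <- seq_len(max(truth, decoded))
  relabel <- integer(length(perm))
  relabel[perm] <- seq_along(perm)   # estimated label -> true label
  mean(relabel[decoded] == truth)
}

#' Information criteria for a fitted model
#'
#' AIC, corrected AIC (AICc), BIC and adjusted BIC. The sample size `n` is the
#' number of subjects (independent chains), not subject-events. The corrected
#' AIC is undefined when `n <= df + 1` and reported as `NA` with a warning.
#'
#' @param loglik Maximized observed-data log-likelihood.
#' @param df Number of free parameters.
#' @param n_subjects Number of subjects.
#' @return Named vector with `AIC`, `CAIC`, `BIC`, `ABIC`.
#' @export
information_criteria <- function(loglik, df, n_subjects) {
  stopifnot(df >= 1, n_subjects >= 1)
  aic <- -2 * loglik + 2 * df
  caic <- if (n_subjects > df + 1) aic + 2 * df * (df + 1) / (n_subjects - df - 1)
          else { warning("corrected AIC undefined for n <= df + 1"); NA_real_ }
  bic <- -2 * loglik + df * log(n_subjects)
  abic <- -2 * loglik + df * log((n_subjects + 2) / 24)
  c(AIC = aic, CAIC = caic, BIC = bic, ABIC = abic)
}

# deterministic per-cell, per-replication seed derived from a base seed
cell_seed <- function(base_seed, cell, rep, model = 0L) {
  (as.integer(base_seed) + 7919L * as.integer(cell) + 104729L * as.integer(rep) +
     17L * as.integer(model)) %% 2147483647L
}

#' Run one simulation cell: generate, fit, align, decode, score
#'
#' Generates `reps` datasets from the design cell, fits each requested model
#' by EM, aligns the state labels to the generating truth, decodes the state
#' sequences by Viterbi, and summarizes parameter recovery and state recovery.
#'
#' @param design A [simulation_design()].
#' @param reps Number of replications.
#' @param models Character vector of model variants to fit (`"MNI"`, `"MI"`).
#' @param config An [em_config()] (its seed is combined with the replication
#'   index to seed both data generation and the EM starts).
#' @return A data.frame with one row per (replication, model): design factors,
#'   `model`, `loglik`, `match_rate`, domain-averaged `rmse`, `abs_bias`,
#'   `bias`, and `converged`.
#' @export
run_study_cell <- function(design, reps = 1L, models = "MNI",
                           config = em_config()) {
  base_seed <- if (is.null(config$seed)) 1L else config$seed
  rows <- list()
  for (r in seq_len(reps)) {
    d <- design
    d$seed <- cell_seed(base_seed, 0L, r)
    sim <- simulate_lmm(d)
    for (m in models) {
      cfg <- config
      cfg$seed <- cell_seed(base_seed, 0L, r, model = match(m, c("MNI", "MI")))
      fit <- em_fit(sim$data, S = design$S, invariance = m, config = cfg)
      al <- align_state_labels(fit$params, sim$params)
      dec <- viterbi_decode(sim$data, fit$params)
      rate <- state_match_rate(dec$states, sim$states, al$perm)
      rep_tab <- bias_rmse_summary(al$aligned, sim$params)
      rows[[length(rows) + 1L]] <- data.frame(
        S = design$S, init_scenario = design$init_scenario,
        transition_scenario = design$transition_scenario,
        delta = design$delta, N = design$N, J = design$J,
        generator = design$generator, model = m, rep = r,
        loglik = fit$loglik, converged = fit$converged,
        match_rate = rate,
        rmse = mean(rep_tab$rmse), abs_bias = mean(rep_tab$abs_bias),
        bias = mean(rep_tab$bias))
    }
  }
  do.call(rbind, rows)
}

#' Run a full simulation study
#'
#' Maps [run_study_cell()] over a design grid and binds the per-replication
#' rows. `rmse`, `abs_bias` and `bias` are domain-averaged (the mean over the
#' six congeneric parameter domains).
#'
#' @param designs A list of [simulation_design()] cells (see
#'   [make_design_grid()]).
#' @param reps Replications per cell.
#' @param models Model variants to fit to every dataset.
#' @param config An [em_config()].
#' @param seed Base seed; per-cell seeds are derived deterministically.
#' @param verbose Print one line per completed cell?
#' @return A data.frame with one row per (cell, replication, model).
#' @export
run_study <- function(designs, reps = 1L, models = "MNI",
                      config = em_config(), seed = 1L, verbose = FALSE) {
  rows <- list()
  for (ci in seq_along(designs)) {
    cfg <- config
    cfg$seed <- cell_seed(seed, ci, 0L)
    res <- run_study_cell(designs[[ci]], reps = reps, models = models, config = cfg)
    res$cell <- ci
    rows[[ci]] <- res
    if (verbose)
      cat(sprintf("cell %d/%d (S=%d %s/%s delta=%.1f N=%d %s): match %s\n",
                  ci, length(designs), designs[[ci]]$S,
                  designs[[ci]]$init_scenario, designs[[ci]]$transition_scenario,
                  designs[[ci]]$delta, designs[[ci]]$N, designs[[ci]]$generator,
                  paste(round(res$match_rate, 3), collapse = "/")))
  }
  do.call(rbind, rows)
}

#' Cross-fit experiment: consequences of over- and underfitting
#'
#' For every cell of a Study II grid, fits both the MI and the MNI model to
#' each generated dataset and contrasts the ill-fitting model with the
#' normal-fitting one (the model matching the generator): the increase in
#' domain-averaged absolute bias and the decrease in Viterbi state recovery.
#'
#' @param designs Study II design grid (see `make_design_grid("II")`).
#' @inheritParams run_study
#' @return A list with `runs` (per-replication rows for both fitted models)
#'   and `deltas` (one row per cell and replication: `d_abs_bias` = ill-fit
#'   minus normal-fit absolute bias, `d_match` = normal-fit minus ill-fit
#'   match rate).
#' @export
crossfit_experiment <- function(designs, reps = 1L, config = em_config(),
                                seed = 1L, verbose = FALSE) {
  runs <- run_study(designs, reps = reps, models = c("MNI", "MI"),
                    config = config, seed = seed, verbose = verbose)
  key <- c("cell", "rep")
  deltas <- list()
  for (cl in unique(runs$cell)) for (r in unique(runs$rep)) {
    sub <- runs[runs$cell == cl & runs$rep == r, ]
    if (nrow(sub) != 2) next
    normal <- sub[sub$model == sub$generator[1], ]
    ill <- sub[sub$model != sub$generator[1], ]
    deltas[[length(deltas) + 1L]] <- data.frame(
      cell = cl, rep = r, generator = sub$generator[1],
      S = sub$S[1], init_scenario = sub$init_scenario[1],
      transition_scenario = sub$transition_scenario[1],
      delta = sub$delta[1], N = sub$N[1],
      d_abs_bias = ill$abs_bias - normal$abs_bias,
      d_match = normal$match_rate - ill$match_rate,
      normal_abs_bias = normal$abs_bias, ill_abs_bias = ill$abs_bias,
      normal_match = normal$match_rate, ill_match = ill$match_rate)
  }
  list(runs = runs, deltas = do.call(rbind, deltas))
}
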