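#' Read a long-format indicator dataset from CSV
#'
#' Expects columns `subject_id`, `event_index` (1-based, contiguous `1..J`
#' within every subject), and one column per declared indicator. Subjects with
#' missing or non-contiguous events, and discrete values outside their declared
#' category range, are rejected with the offending row named.
#'
#' @param path CSV file path.
#' @param specs List of [indicator_spec()] declaring the indicator columns.
#' @return An [indicator_dataset()].
#' @export
read_dataset <- function(path, specs) {
  if (inherits(specs, "indicator_spec")) specs <- list(specs)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "event_index", vapply(specs, function(s) s$name, character(1)))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  subjects <- unique(df$subject_id)
  J <- max(df$event_index)
  N <- length(subjects)
  K <- length(specs)
  values <- array(NA_real_, dim = c(N, J, K))
  for (i in seq_len(N)) {
    sub <- df[df$subject_id == subjects[i], ]
    sub <- sub[order(sub$event_index), ]
    if (nrow(sub) != J || !identical(as.integer(sub$event_index), seq_len(J)))
      stop("subject '", subjects[i], "': events must be contiguous 1..", J)
    for (k in seq_len(K)) {
      y <- sub[[specs[[k]]$name]]
      spec <- specs[[k]]
      if (is_discrete(spec) &&
          (any(y != round(y)) || any(y < 0) || any(y > spec$n_categories - 1))) {
        bad <- which(y < 0 | y > spec$n_categories - 1 | y != round(y))[1]
        stop("subject '", subjects[i], "', event ", bad, ": value ", y[bad],
             " out of range for indicator '", spec$name, "'")
      }
      values[i, , k] <- y
    }
  }
  ds <- indicator_dataset(values, specs)
  attr(ds, "subject_ids") <- subjects
  ds
}

#' Write an indicator dataset to long-format CSV
#'
#' Inverse of [read_dataset()]: round-trips exactly (up to numeric printing
#' precision of continuous indicators).
#'
#' @param data An [indicator_dataset()].
#' @param path Output CSV path.
#' @return The written data.frame, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "indicator_dataset"))
  N <- data$n_subjects; J <- data$n_events
  ids <- attr(data, "subject_ids")
  if (is.null(ids)) ids <- seq_len(N)
  out <- data.frame(subject_id = rep(ids, each = J),
                    event_index = rep(seq_len(J), times = N))
  for (k in seq_len(data$n_indicators)) {
    out[[data$specs[[k]]$name]] <- as.vector(t(matrix(data$values[, , k], nrow = N)))
  }
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Serialize model parameters to a flat CSV
#'
#' Writes the unconstrained parameter values plus the model metadata needed to
#' rebuild the object, in a flat table with columns `block`, `indicator`,
#' `item`, `state`, `category`, `value`. [read_lmm_parameters()] round-trips
#' exactly.
#'
#' @param params An [lmm_parameters()] object.
#' @param path Output CSV path.
#' @return The written data.frame, invisibly.
#' @export
write_lmm_parameters <- function(params, path) {
  rows <- list(
    data.frame(block = "meta", indicator = "S", item = 0L, state = 0L,
               category = NA_integer_, value = params$S),
    data.frame(block = "meta", indicator = "J", item = 0L, state = 0L,
               category = NA_integer_, value = params$J),
    data.frame(block = "meta", indicator = "invariance", item = 0L, state = 0L,
               category = NA_integer_, value = as.numeric(params$invariance == "MI")))
  for (k in seq_along(params$specs)) {
    spec <- params$specs[[k]]
    fam_code <- match(spec$family, c("nominal", "ordinal", "continuous", "count"))
    rows[[length(rows) + 1L]] <- data.frame(
      block = "spec", indicator = spec$name, item = k, state = fam_code,
      category = if (is_discrete(spec)) spec$n_categories else NA_integer_,
      value = NA_real_)
  }
  S <- params$S
  rows[[length(rows) + 1L]] <- data.frame(
    block = "init_logit", indicator = "", item = 0L, state = seq_len(S),
    category = NA_integer_, value = params$init_logits)
  rows[[length(rows) + 1L]] <- data.frame(
    block = "transition_logit", indicator = "", item = 0L,
    state = rep(seq_len(S), times = S), category = rep(seq_len(S), each = S),
    value = as.vector(params$transition_logits))
  Jeff <- item_dim(params)
  for (k in seq_along(params$specs)) {
    spec <- params$specs[[k]]; em <- params$emissions[[k]]
    if (is_discrete(spec)) {
      M <- spec$n_categories
      for (jj in seq_len(Jeff)) for (s in seq_len(S))
        rows[[length(rows) + 1L]] <- data.frame(
          block = "logit", indicator = spec$name, item = jj, state = s,
          category = seq_len(M - 1L), value = em$logits[jj, s, ])
    } else if (spec$family == "continuous") {
      for (jj in seq_len(Jeff)) {
        rows[[length(rows) + 1L]] <- data.frame(
          block = "mu", indicator = spec$name, item = jj, state = seq_len(S),
          category = NA_integer_, value = em$mu[jj, ])
        rows[[length(rows) + 1L]] <- data.frame(
          block = "log_sigma", indicator = spec$name, item = jj, state = seq_len(S),
          category = NA_integer_, value = em$log_sigma[jj, ])
      }
    } else {
      for (jj in seq_len(Jeff))
        rows[[length(rows) + 1L]] <- data.frame(
          block = "log_lambda", indicator = spec$name, item = jj, state = seq_len(S),
          category = NA_integer_, value = em$log_lambda[jj, ])
    }
  }
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read model parameters from the flat CSV written by [write_lmm_parameters()]
#'
#' @param path CSV file path.
#' @return An [lmm_parameters()] object.
#' @export
read_lmm_parameters <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  meta <- df[df$block == "meta", ]
  S <- as.integer(meta$value[meta$indicator == "S"])
  J <- as.integer(meta$value[meta$indicator == "J"])
  invariance <- if (meta$value[meta$indicator == "invariance"] == 1) "MI" else "MNI"
  spec_rows <- df[df$block == "spec", ]
  spec_rows <- spec_rows[order(spec_rows$item), ]
  fams <- c("nominal", "ordinal", "continuous", "count")
  specs <- lapply(seq_len(nrow(spec_rows)), function(r)
    indicator_spec(spec_rows$indicator[r], fams[spec_rows$state[r]],
                   n_categories = if (!is.na(spec_rows$category[r])) spec_rows$category[r] else NULL))
  init_logits <- df$value[df$block == "init_logit"][order(df$state[df$block == "init_logit"])]
  tr <- df[df$block == "transition_logit", ]
  transition_logits <- matrix(0, S, S)
  transition_logits[cbind(tr$state, tr$category)] <- tr$value
  Jeff <- if (invariance == "MI") 1L else J
  emissions <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    sub <- df[df$indicator == spec$name & df$block != "spec", ]
    if (is_discrete(spec)) {
      M <- spec$n_categories
      logits <- array(0, dim = c(Jeff, S, M - 1L))
      lg <- sub[sub$block == "logit", ]
      logits[cbind(lg$item, lg$state, lg$category)] <- lg$value
      emissions[[k]] <- list(logits = logits)
    } else if (spec$family == "continuous") {
      mu <- matrix(0, Jeff, S); ls <- matrix(0, Jeff, S)
      mr <- sub[sub$block == "mu", ]; sr <- sub[sub$block == "log_sigma", ]
      mu[cbind(mr$item, mr$state)] <- mr$value
      ls[cbind(sr$item, sr$state)] <- sr$value
      emissions[[k]] <- list(mu = mu, log_sigma = ls)
    } else {
      ll <- matrix(0, Jeff, S)
      lr <- sub[sub$block == "log_lambda", ]
      ll[cbind(lr$item, lr$state)] <- lr$value
      emissions[[k]] <- list(log_lambda = ll)
    }
  }
  lmm_parameters(S, J, specs, invariance, init_logits, transition_logits, emissions)
}

#' Write a fit summary to JSON
#'
#' Scalars and diagnostics only (log-likelihood, iteration trace, information
#' criteria, convergence); the parameter table itself travels as CSV via
#' [write_lmm_parameters()].
#'
#' @param fit An `lmm_fit` from [em_fit()].
#' @param path Output JSON path.
#' @return The summary list, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(S = fit$params$S, J = fit$params$J,
              invariance = fit$params$invariance,
              loglik = fit$loglik, df = fit$df,
              n_subjects = fit$n_subjects,
              n_iter = fit$n_iter, converged = fit$converged,
              ics = as.list(fit$ics),
              loglik_trace = fit$loglik_trace,
              seed = fit$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
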