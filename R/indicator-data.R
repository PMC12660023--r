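#' Declare an indicator variable
#'
#' An indicator is one of the K channels observed at every measurement event
#' (e.g., a response score, a log response time, an action count). Discrete
#' families code their values as integers `0 .. n_categories - 1`.
#'
#' @param name Indicator name (column name in long-format files).
#' @param family One of `"nominal"`, `"ordinal"`, `"continuous"`, `"count"`.
#' @param n_categories Number of categories `M >= 2`; required for (and only
#'   allowed with) the discrete families.
#' @return An object of class `indicator_spec`.
#' @examples
#' indicator_spec("score", "ordinal", n_categories = 4)
#' indicator_spec("log_time", "continuous")
#' @export
indicator_spec <- function(name, family = c("nominal", "ordinal", "continuous", "count"),
                           n_categories = NULL) {
  family <- match.arg(family)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  discrete <- family %in% c("nominal", "ordinal")
  if (discrete) {
    if (is.null(n_categories) || n_categories < 2)
      stop("indicator '", name, "': discrete families need n_categories >= 2")
    n_categories <- as.integer(n_categories)
  } else if (!is.null(n_categories)) {
    stop("indicator '", name, "': n_categories is only meaningful for discrete families")
  }
  structure(list(name = name, family = family, n_categories = n_categories),
            class = "indicator_spec")
}

is_discrete <- function(spec) spec$family %in% c("nominal", "ordinal")

#' Assemble a rectangular indicator dataset
#'
#' Holds the N x J x K observation array: N subjects, J measurement events
#' administered to everyone in the same order, K indicators per event. No
#' missing cells are allowed and discrete values must lie inside their declared
#' category range.
#'
#' @param values Numeric N x J x K array (the third dimension ordered as
#'   `specs`).
#' @param specs List of [indicator_spec()] objects, length K.
#' @return An object of class `indicator_dataset` with elements `values`,
#'   `specs`, `n_subjects`, `n_events`, `n_indicators`.
#' @export
indicator_dataset <- function(values, specs) {
  if (inherits(specs, "indicator_spec")) specs <- list(specs)
  stopifnot(is.array(values), length(dim(values)) == 3L)
  K <- length(specs)
  if (dim(values)[3] != K)
    stop("third array dimension (", dim(values)[3], ") must equal the number of indicator specs (", K, ")")
  if (anyNA(values)) stop("indicator datasets may not contain missing cells")
  for (k in seq_len(K)) {
    spec <- specs[[k]]
    yk <- values[, , k]
    if (is_discrete(spec)) {
      if (any(yk != round(yk)) || any(yk < 0) || any(yk > spec$n_categories - 1))
        stop("indicator '", spec$name, "': values must be integers in 0..",
             spec$n_categories - 1)
    } else if (spec$family == "count") {
      if (any(yk != round(yk)) || any(yk < 0))
        stop("indicator '", spec$name, "': counts must be non-negative integers")
    }
  }
  structure(list(values = values, specs = specs,
                 n_subjects = dim(values)[1], n_events = dim(values)[2],
                 n_indicators = K),
            class = "indicator_dataset")
}

#' @export
print.indicator_dataset <- function(x, ...) {
  fams <- vapply(x$specs, function(s) s$family, character(1))
  cat("indicator_dataset: ", x$n_subjects, " subjects x ", x$n_events,
      " events x ", x$n_indicators, " indicators (",
      paste(fams, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# Coerce a single-subject J x K matrix (or an indicator_dataset) to the
# internal array form.
as_values_array <- function(data, specs = NULL) {
  if (inherits(data, "indicator_dataset")) return(data$values)
  if (is.array(data) && length(dim(data)) == 3L) return(data)
  if (is.matrix(data)) {
    arr <- array(data, dim = c(1L, nrow(data), ncol(data)))
    return(arr)
  }
  stop("expected an indicator_dataset or a J x K matrix of one subject's observations")
}
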