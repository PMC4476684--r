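#' Construct a discrete dataset for decision-path modelling
#'
#' Wraps a data frame of predictor variables and a binary (or, more
#' generally, K-valued) target into the container every learner in the
#' package consumes. Discrete predictors are stored as factors whose level
#' sets define the variable domains; numeric columns are kept as continuous
#' variables and must be discretized (see [apply_cuts()]) before any learner
#' will accept them. Rows whose target value is missing cannot contribute to
#' any score and are dropped at construction, with the dropped count kept in
#' the `n_dropped_missing_target` attribute.
#'
#' @param x A data frame. Character and logical columns become factors with
#'   sorted unique observed values as their domain; existing factors keep
#'   their level sets (so a domain may include values unobserved in `x`);
#'   numeric columns remain continuous.
#' @param target Name of the target column in `x`.
#' @param positive The target value treated as the positive outcome (the
#'   class whose probability predictions report). Defaults to the last
#'   target level, so with levels `c("no", "yes")` the positive value is
#'   `"yes"`.
#' @return An object of class `discrete_dataset`: a list with elements
#'   `data` (the cleaned data frame), `target`, `positive`, and attribute
#'   bookkeeping.
#' @examples
#' d <- data.frame(sex = c("f", "m", "f", "m"),
#'                 outcome = c("no", "no", "yes", "no"))
#' ds <- discrete_dataset(d, target = "outcome")
#' class_counts(ds)
#' @export
discrete_dataset <- function(x, target, positive = NULL) {
  stopifnot(is.data.frame(x))
  if (!target %in% names(x)) {
    stop("target column '", target, "' not found in data", call. = FALSE)
  }
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  for (nm in names(df)) {
    col <- df[[nm]]
    if (is.factor(col)) next
    if (is.numeric(col) && nm != target) next
    if (is.logical(col)) col <- as.character(col)
    if (is.numeric(col)) col <- as.character(col)
    df[[nm]] <- factor(col, levels = sort(unique(col[!is.na(col)])))
  }
  dropped <- sum(is.na(df[[target]]))
  if (dropped > 0) df <- df[!is.na(df[[target]]), , drop = FALSE]
  rownames(df) <- NULL
  lev <- levels(df[[target]])
  if (nrow(df) > 0 || length(lev) > 0) {
    if (length(lev) < 2) {
      stop("target must have at least two values in its domain", call. = FALSE)
    }
  }
  positive <- positive %||% lev[length(lev)]
  if (length(lev) > 0 && !positive %in% lev) {
    stop("positive value '", positive, "' is not a target level", call. = FALSE)
  }
  structure(
    list(data = df, target = target, positive = positive,
         n_dropped_missing_target = dropped),
    class = "discrete_dataset"
  )
}

#' @export
print.discrete_dataset <- function(x, ...) {
  p <- dataset_variables(x)
  cont <- continuous_variables(x)
  cat("<discrete_dataset> ", nrow(x$data), " individuals, ",
      length(p), " predictors (", length(cont), " continuous), target '",
      x$target, "' (positive = '", x$positive, "')\n", sep = "")
  cc <- class_counts(x)
  cat("  class counts:", paste(names(cc), cc, sep = "=", collapse = ", "), "\n")
  if (x$n_dropped_missing_target > 0) {
    cat("  dropped", x$n_dropped_missing_target, "rows with missing target\n")
  }
  invisible(x)
}

#' Predictor variable names of a dataset
#' @param data A [discrete_dataset()].
#' @return Character vector of predictor names (the target is excluded).
#' @export
dataset_variables <- function(data) {
  setdiff(names(data$data), data$target)
}

#' Names of the continuous (not yet discretized) predictors
#' @inheritParams dataset_variables
#' @export
continuous_variables <- function(data) {
  vars <- dataset_variables(data)
  vars[vapply(data$data[vars], is.numeric, TRUE)]
}

#' Number of individuals in a dataset
#' @inheritParams dataset_variables
#' @export
n_individuals <- function(data) nrow(data$data)

#' Per-class counts of the target variable
#'
#' Tabulates the target over its domain, in domain order. Rows with missing
#' target were already excluded at construction; their number is available
#' as `data$n_dropped_missing_target`.
#'
#' @inheritParams dataset_variables
#' @return Named integer vector, one entry per target level.
#' @export
class_counts <- function(data) {
  stopifnot(inherits(data, "discrete_dataset"))
  tab <- table(data$data[[data$target]])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

validate_conjuncts <- function(data, conj) {
  vars <- dataset_variables(data)
  unknown <- setdiff(conj$variable, vars)
  if (length(unknown) > 0) {
    stop("unknown variable(s) in conjunction: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(conj))) {
    v <- conj$variable[i]
    col <- data$data[[v]]
    if (!is.factor(col)) {
      stop("variable '", v, "' is continuous; discretize it before matching",
           call. = FALSE)
    }
    if (!conj$value[i] %in% levels(col)) {
      stop("value '", conj$value[i], "' is not in the domain of '", v, "'",
           call. = FALSE)
    }
  }
  invisible(conj)
}

subset_rows <- function(data, idx) {
  out <- data
  out$data <- data$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' Retain the individuals matching a conjunction of features
#'
#' A row matches when every conjunct `V = v` is satisfied; a row with a
#' missing value for a conjunct variable does not satisfy it and is
#' excluded. The empty conjunction is vacuously true and returns the full
#' dataset. The schema (domains, target, positive value) is unchanged, so
#' the operation is idempotent and composable.
#'
#' @inheritParams dataset_variables
#' @param conjuncts A named character vector (`c(V1 = "a")`), a list of
#'   `(variable, value)` pairs, or a data frame with columns `variable` and
#'   `value`.
#' @return A `discrete_dataset` containing only the matching rows.
#' @export
filter_matching <- function(data, conjuncts) {
  stopifnot(inherits(data, "discrete_dataset"))
  conj <- as_conjuncts(conjuncts)
  validate_conjuncts(data, conj)
  keep <- rep(TRUE, nrow(data$data))
  for (i in seq_len(nrow(conj))) {
    col <- data$data[[conj$variable[i]]]
    keep <- keep & !is.na(col) & col == conj$value[i]
  }
  subset_rows(data, keep)
}

#' Partition a dataset on a single feature
#'
#' Splits `data` into the individuals satisfying `variable = value`
#' (`matched`, the candidate subgroup) and everyone else (`rest`), including
#' rows where `variable` is missing -- missingness cannot satisfy a
#' conjunct. The two parts always partition the input.
#'
#' @inheritParams filter_matching
#' @param variable A predictor name.
#' @param value A value in that predictor's domain.
#' @return A list with `discrete_dataset` elements `matched` and `rest`.
#' @export
split_by_feature <- function(data, variable, value) {
  conj <- as_conjuncts(stats::setNames(as.character(value), variable))
  validate_conjuncts(data, conj)
  col <- data$data[[variable]]
  inside <- !is.na(col) & col == value
  list(matched = subset_rows(data, inside),
       rest = subset_rows(data, !inside))
}

#' Describe one test individual
#'
#' Validates a single person's variable/value assignments against a
#' dataset's schema and returns them as a named character vector with `NA`
#' marking missing values. Variables absent from `x` are treated as missing;
#' a value for the target column is dropped (a person carries no outcome at
#' prediction time).
#'
#' @param x A named character vector or a one-row data frame.
#' @inheritParams dataset_variables
#' @return Named character vector over all predictors, `NA` where missing.
#' @export
person_instance <- function(x, data) {
  stopifnot(inherits(data, "discrete_dataset"))
  vars <- dataset_variables(data)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- vapply(names(x), function(nm) {
      v <- x[[nm]][1]
      if (is.na(v)) NA_character_ else as.character(v)
    }, "")
  }
  if (!is.character(x)) {
    nms <- names(x)
    x <- as.character(x)
    names(x) <- nms
  }
  x <- x[setdiff(names(x), data$target)]
  unknown <- setdiff(names(x), vars)
  if (length(unknown) > 0) {
    stop("unknown variable(s) in person: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- stats::setNames(rep(NA_character_, length(vars)), vars)
  out[names(x)] <- x
  for (v in vars) {
    if (is.na(out[[v]])) next
    col <- data$data[[v]]
    if (!is.factor(col)) next  # continuous values checked at discretization
    if (!out[[v]] %in% levels(col)) {
      stop("person value '", out[[v]], "' is not in the domain of '", v, "'",
           call. = FALSE)
    }
  }
  out
}

# Integer encoding used by the C++ engines: predictors as a matrix of
# 1-based domain codes (NA = missing), target as 1-based codes.
encode_dataset <- function(data) {
  vars <- dataset_variables(data)
  cont <- continuous_variables(data)
  if (length(cont) > 0) {
    stop("continuous predictor(s) must be discretized before model fitting: ",
         paste(cont, collapse = ", "), call. = FALSE)
  }
  n <- nrow(data$data)
  X <- matrix(NA_integer_, nrow = n, ncol = length(vars),
              dimnames = list(NULL, vars))
  for (j in seq_along(vars)) X[, j] <- as.integer(data$data[[vars[j]]])
  ylev <- levels(data$data[[data$target]])
  list(X = X, y = as.integer(data$data[[data$target]]),
       vars = vars,
       levels = lapply(data$data[vars], levels),
       nlev = vapply(data$data[vars], nlevels, 0L),
       ylev = ylev, K = length(ylev),
       positive = match(data$positive, ylev))
}

encode_person <- function(person, enc) {
  codes <- rep(NA_integer_, length(enc$vars))
  for (j in seq_along(enc$vars)) {
    v <- person[[enc$vars[j]]]
    if (!is.na(v)) codes[j] <- match(v, enc$levels[[j]])
  }
  codes
}
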