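# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user
# simulations.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalise the many ways a conjunction can be supplied (named character
# vector, list of pairs, two-column data frame) into a canonical data frame
# with character columns `variable` and `value`. An empty conjunction is the
# vacuously true path.
as_conjuncts <- function(x) {
  if (is.null(x) || length(x) == 0) {
    return(data.frame(variable = character(), value = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("variable", "value") %in% names(x)))
    out <- data.frame(variable = as.character(x$variable),
                      value = as.character(x$value),
                      stringsAsFactors = FALSE)
  } else if (is.character(x) && !is.null(names(x))) {
    out <- data.frame(variable = names(x), value = unname(x),
                      stringsAsFactors = FALSE)
  } else if (is.list(x)) {
    out <- data.frame(variable = vapply(x, function(p) as.character(p[[1]]), ""),
                      value = vapply(x, function(p) as.character(p[[2]]), ""),
                      stringsAsFactors = FALSE)
  } else {
    stop("cannot interpret `conjuncts`; supply a named character vector, ",
         "a list of (variable, value) pairs, or a data frame", call. = FALSE)
  }
  if (anyDuplicated(out$variable)) {
    stop("duplicated variable in conjunction: ",
         paste(unique(out$variable[duplicated(out$variable)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

conjuncts_to_string <- function(conj, sorted = TRUE) {
  if (nrow(conj) == 0) return("TRUE")
  s <- paste0(conj$variable, "=", conj$value)
  if (sorted) s <- sort(s)
  paste(s, collapse = " & ")
}
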