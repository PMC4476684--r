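criterion_code <- function(criterion) {
  match(criterion, c("bay", "ig", "auc")) - 1L
}

#' Grow a personalized decision path
#'
#' Greedy forward-stepping search guided by the test individual: starting
#' from the empty path, at every step each predictor not yet on the path and
#' observed (non-missing) in the person is scored by splitting the current
#' matching subgroup on the person's value of that predictor; the
#' best-scoring feature is appended, and the subgroup is restricted to the
#' rows matching it. Growth stops when no candidate remains, when every
#' remaining candidate's matching subsample would be empty (the search
#' would be stranded with no training individuals), or when the remaining
#' individuals all share the same target value. Score ties are broken
#' toward the variable earliest in schema order.
#'
#' Two scores play distinct roles. Candidate *selection* within a step uses
#' the two-sample criterion on the current matching subgroup, so all
#' candidates are judged on the same individuals. The score *recorded* in
#' the trace for each added feature -- the quantity pruning compares -- is
#' the same criterion evaluated at the path level on the full training
#' cohort, partitioned into individuals matching the extended path and
#' everyone else. Recorded scores therefore condition on the same N
#' individuals at every depth, which makes the argmax pruning rule
#' meaningful: a raw subgroup-level log marginal shrinks in magnitude with
#' the subgroup and would almost always peak at the deepest step,
#' silently disabling pruning.
#'
#' @param train A [discrete_dataset()] with all-discrete predictors.
#' @param person A [person_instance()], named character vector, or one-row
#'   data frame of the test individual's values (`NA` = missing).
#' @param criterion `"bay"` (two-sample Bayesian score), `"ig"`
#'   (information gain) or `"auc"` (pooled leave-one-out AUC; binary
#'   targets only).
#' @param config A [scoring_config()].
#' @return A `growth_trace`: a data frame with columns `step`, `variable`,
#'   `value`, `score`, carrying the criterion, the class counts of the
#'   matching subgroup after each step (`step_counts`) and at the root
#'   (`root_counts`) as attributes.
#' @export
grow_path <- function(train, person, criterion = c("bay", "ig", "auc"),
                      config = scoring_config()) {
  stopifnot(inherits(train, "discrete_dataset"))
  criterion <- match.arg(criterion)
  if (n_individuals(train) == 0) {
    stop("training dataset is empty", call. = FALSE)
  }
  enc <- encode_dataset(train)
  if (criterion == "auc" && enc$K != 2) {
    stop("the AUC criterion supports binary targets only", call. = FALSE)
  }
  person <- person_instance(person, train)
  codes <- encode_person(person, enc)
  res <- cpp_grow_path(enc$X, enc$y, enc$K, codes, config$pess,
                       criterion_code(criterion), enc$positive)
  vars <- enc$vars[res$vars]
  trace <- data.frame(
    step = seq_along(vars),
    variable = vars,
    value = unname(person[vars]),
    score = res$scores,
    stringsAsFactors = FALSE
  )
  sc <- res$step_counts
  rownames(sc) <- enc$ylev
  rc <- res$root_counts
  names(rc) <- enc$ylev
  structure(trace, criterion = criterion, step_counts = sc, root_counts = rc,
            config = config, class = c("growth_trace", "data.frame"))
}

#' Prune a grown path at its best-scoring step
#'
#' Bottom-up pruning keeps the prefix of the grown path ending at the step
#' whose recorded criterion score is maximal, so the final retained feature
#' is the one with the highest score seen during growth. Ties are broken
#' toward the shortest qualifying prefix (the simpler model). An empty
#' trace yields the empty path; when at least one feature was added the
#' pruned path always keeps at least one.
#'
#' @param trace A `growth_trace` from [grow_path()].
#' @return Data frame of conjuncts (`variable`, `value`).
#' @export
prune_path <- function(trace) {
  stopifnot(inherits(trace, "growth_trace"))
  if (nrow(trace) == 0) {
    return(data.frame(variable = character(), value = character(),
                      stringsAsFactors = FALSE))
  }
  j <- which.max(trace$score)  # first maximum = shortest prefix on ties
  out <- as.data.frame(trace)[seq_len(j), c("variable", "value")]
  rownames(out) <- NULL
  out
}

#' Fit a decision-path model for one test individual
#'
#' Grows a path with [grow_path()], prunes it with [prune_path()], and
#' estimates the smoothed outcome distribution [bdeu_theta()] from the
#' training individuals matching the pruned path. A person with no observed
#' predictors yields the empty path and the smoothed training prevalence.
#'
#' @inheritParams grow_path
#' @return An object of class `decision_path` with elements `path`
#'   (conjunct data frame), `theta` (named probability vector),
#'   `support_counts`, `trace`, `criterion`, `config`, `target`, `positive`.
#' @examples
#' ds <- gen_path_process(n = 200, seed = 7)
#' person <- person_instance(ds$data[1, ], ds)
#' m <- fit_decision_path(ds, person)
#' predict(m)
#' export_rule(m)
#' @export
fit_decision_path <- function(train, person, criterion = c("bay", "ig", "auc"),
                              config = scoring_config()) {
  criterion <- match.arg(criterion)
  trace <- grow_path(train, person, criterion, config)
  path <- prune_path(trace)
  j <- nrow(path)
  counts <- if (j == 0) {
    attr(trace, "root_counts")
  } else {
    sc <- attr(trace, "step_counts")[, j]
    stats::setNames(as.integer(sc), rownames(attr(trace, "step_counts")))
  }
  structure(
    list(path = path,
         theta = bdeu_theta(counts, config),
         support_counts = counts,
         trace = trace,
         criterion = criterion,
         config = config,
         target = train$target,
         positive = train$positive),
    class = "decision_path"
  )
}

#' Predicted probability of the positive outcome
#'
#' Returns `theta_p` for the model's positive target value. Thresholding at
#' 0.5 (or any other operating point) for a hard class label is left to the
#' caller.
#'
#' @param object A fitted `decision_path`.
#' @param ... Unused.
#' @export
predict.decision_path <- function(object, ...) {
  unname(object$theta[object$positive])
}

#' @export
print.decision_path <- function(x, ...) {
  cat("<decision_path> criterion =", x$criterion, "\n")
  cat(" ", export_rule(x), "\n")
  invisible(x)
}

#' Render a decision-path model as an IF-THEN rule
#'
#' Deterministic single-rule rendering in growth order, e.g.
#' `IF age=(65,Inf] AND bp=high THEN P(death=yes)=0.607 (n=102, counts=40/62)`.
#' The empty path renders as `IF TRUE THEN ...`.
#'
#' @param model A fitted `decision_path`.
#' @param digits Decimal places for the probability.
#' @return A single character string.
#' @export
export_rule <- function(model, digits = 3) {
  stopifnot(inherits(model, "decision_path"))
  lhs <- if (nrow(model$path) == 0) {
    "TRUE"
  } else {
    paste(paste0(model$path$variable, "=", model$path$value), collapse = " AND ")
  }
  prob <- unname(model$theta[model$positive])
  sprintf("IF %s THEN P(%s=%s)=%s (n=%d, counts=%s)",
          lhs, model$target, model$positive,
          formatC(prob, digits = digits, format = "f"),
          sum(model$support_counts),
          paste(model$support_counts, collapse = "/"))
}

# Minimal-overhead fit used inside cross-validation: returns the positive
# probability and the canonical conjunct-set string of the pruned path.
dp_fit_fast <- function(enc, codes, crit_code, pess) {
  res <- cpp_grow_path(enc$X, enc$y, enc$K, codes, pess, crit_code,
                       enc$positive)
  if (length(res$scores) == 0) {
    counts <- res$root_counts
    path_str <- "TRUE"
  } else {
    j <- which.max(res$scores)
    counts <- res$step_counts[, j]
    v <- res$vars[seq_len(j)]
    path_str <- paste(sort(paste0(enc$vars[v],
                                  "=",
                                  vapply(seq_len(j), function(i) {
                                    enc$levels[[v[i]]][codes[v[i]]]
                                  }, ""))),
                      collapse = " & ")
  }
  prob <- (pess / enc$K + counts[enc$positive]) / (pess + sum(counts))
  list(prob = unname(prob), path = path_str)
}
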