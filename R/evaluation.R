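#' Stratified fold assignment
#'
#' Partitions the individuals into `k` near-equal folds preserving the
#' class mix: within each target class the rows are shuffled and dealt
#' round-robin, so per-fold class counts differ from perfect stratification
#' by at most one. Deterministic given `seed`; the caller's RNG state is
#' untouched.
#'
#' @inheritParams dataset_variables
#' @param k Number of folds (`>= 2`, and at most the smaller class count --
#'   beyond that a fold would necessarily lose a class).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per row.
#' @export
stratified_folds <- function(data, k, seed = 1) {
  stopifnot(inherits(data, "discrete_dataset"))
  counts <- class_counts(data)
  if (length(counts[counts > 0]) < 2) {
    stop("both classes must be present to stratify", call. = FALSE)
  }
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > min(counts[counts > 0])) {
    stop("k = ", k, " exceeds the smaller class count (",
         min(counts[counts > 0]), ")", call. = FALSE)
  }
  y <- data$data[[data$target]]
  fold <- integer(length(y))
  local_seed(seed, {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      if (length(idx) == 0) next
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Run the cross-validation benchmark
#'
#' The full evaluation protocol: stratified `k`-fold cross-validation in
#' which, for every fold, continuous predictors are discretized on the
#' training folds only (per-fold scope; `"global"` discretizes once on the
#' full data, for sensitivity analysis), the population tree is fitted once
#' per fold, and each decision-path method derives one personalized model
#' per test individual. Every individual is predicted exactly once per
#' method. Should a model fitting fail for an individual, the smoothed
#' training prevalence is recorded as a fallback and counted.
#'
#' @inheritParams stratified_folds
#' @param methods Any of `"dp-bay"`, `"dp-ig"`, `"dp-auc"`, `"tree"`.
#' @param k Number of folds (default 20, the protocol standard). If `k`
#'   exceeds the smaller class count it is capped there, with a message.
#' @param seed Integer seed for the fold assignment.
#' @param config A [scoring_config()].
#' @param threshold Probability threshold for the hard class label.
#' @param discretize_scope `"per-fold"` (no leakage) or `"global"`.
#' @return A data frame of prediction records with columns `id`, `method`,
#'   `fold`, `prob`, `outcome` (logical, TRUE = positive), `label`
#'   (thresholded prediction). Attributes: `paths` (per-method character
#'   vectors of canonical conjunct-set strings, aligned with `id` order),
#'   `fit_counts`, `fallbacks`, `k`, `positive`.
#' @export
run_cross_validation <- function(data,
                                 methods = c("dp-bay", "dp-ig", "dp-auc", "tree"),
                                 k = 20, seed = 1,
                                 config = scoring_config(),
                                 threshold = 0.5,
                                 discretize_scope = c("per-fold", "global")) {
  stopifnot(inherits(data, "discrete_dataset"))
  discretize_scope <- match.arg(discretize_scope)
  methods <- match.arg(methods, several.ok = TRUE)
  counts <- class_counts(data)
  k_eff <- min(k, min(counts[counts > 0]))
  if (k_eff < k) {
    message("capping k at the smaller class count: ", k_eff)
  }
  if (k_eff < 2) stop("too few individuals in a class to cross-validate",
                      call. = FALSE)
  if (discretize_scope == "global" && length(continuous_variables(data)) > 0) {
    data <- apply_cuts(data, learn_cuts(data))
  }
  fold <- stratified_folds(data, k_eff, seed)
  n <- n_individuals(data)
  dp_methods <- setdiff(methods, "tree")
  crit_of <- c("dp-bay" = "bay", "dp-ig" = "ig", "dp-auc" = "auc")

  prob <- matrix(NA_real_, nrow = n, ncol = length(methods),
                 dimnames = list(NULL, methods))
  paths <- matrix(NA_character_, nrow = n, ncol = length(methods),
                  dimnames = list(NULL, methods))
  fallbacks <- stats::setNames(integer(length(methods)), methods)
  fit_counts <- stats::setNames(integer(length(methods)), methods)

  y_pos <- data$data[[data$target]] == data$positive

  for (f in seq_len(k_eff)) {
    test_idx <- which(fold == f)
    train <- subset_rows(data, fold != f)
    test <- subset_rows(data, fold == f)
    if (discretize_scope == "per-fold" &&
        length(continuous_variables(train)) > 0) {
      cuts <- learn_cuts(train)
      train <- apply_cuts(train, cuts)
      test <- apply_cuts(test, cuts)
    }
    enc <- encode_dataset(train)
    prior_prob <- unname(
      (config$pess / enc$K + sum(enc$y == enc$positive)) /
        (config$pess + length(enc$y)))

    test_codes <- matrix(NA_integer_, nrow = length(test_idx),
                         ncol = length(enc$vars))
    for (j in seq_along(enc$vars)) {
      test_codes[, j] <- match(as.character(test$data[[enc$vars[j]]]),
                               enc$levels[[j]])
    }

    if ("tree" %in% methods) {
      tr <- fit_population_tree(train, config)
      fit_counts[["tree"]] <- fit_counts[["tree"]] + 1L
      res <- tree_predict_codes(tr, test_codes)
      prob[test_idx, "tree"] <- res$prob
      paths[test_idx, "tree"] <- res$path
    }
    for (m in dp_methods) {
      cc <- criterion_code(crit_of[[m]])
      for (i in seq_along(test_idx)) {
        fit <- tryCatch(
          dp_fit_fast(enc, test_codes[i, ], cc, config$pess),
          error = function(e) NULL
        )
        if (is.null(fit)) {
          fallbacks[[m]] <- fallbacks[[m]] + 1L
          fit <- list(prob = prior_prob, path = "TRUE")
        }
        fit_counts[[m]] <- fit_counts[[m]] + 1L
        prob[test_idx[i], m] <- fit$prob
        paths[test_idx[i], m] <- fit$path
      }
    }
  }

  records <- data.frame(
    id = rep(seq_len(n), times = length(methods)),
    method = rep(methods, each = n),
    fold = rep(fold, times = length(methods)),
    prob = as.vector(prob),
    outcome = rep(y_pos, times = length(methods)),
    stringsAsFactors = FALSE
  )
  records$label <- records$prob >= threshold
  structure(records,
            paths = lapply(stats::setNames(methods, methods),
                           function(m) paths[, m]),
            fit_counts = fit_counts, fallbacks = fallbacks,
            k = k_eff, positive = data$positive,
            class = c("cv_records", "data.frame"))
}

records_for <- function(records, method = NULL) {
  if (!is.null(method)) {
    stopifnot(method %in% unique(records$method))
    records <- records[records$method == method, , drop = FALSE]
  }
  records
}

#' Brier score, 1 - BS, and Brier skill score
#'
#' `BS` is the mean squared difference between the predicted probability and
#' the binary outcome (1 = positive); `1 - BS` is its positively oriented
#' twin; the skill score `BSS = 1 - BS / BS_ref` compares against a
#' reference that predicts the outcome prevalence for everyone, so the
#' reference itself scores exactly 0 and positive values mean better than
#' prevalence.
#'
#' @param predicted Predicted probabilities.
#' @param outcome Logical (TRUE = positive) or 0/1 outcomes.
#' @param reference Reference probability; defaults to the prevalence of
#'   `outcome`.
#' @return List with `bs`, `one_minus_bs`, `bss`.
#' @export
brier_metrics <- function(predicted, outcome, reference = NULL) {
  if (is.logical(outcome)) outcome <- as.numeric(outcome)
  stopifnot(length(predicted) == length(outcome), length(predicted) > 0)
  reference <- reference %||% mean(outcome)
  bs <- mean((predicted - outcome)^2)
  bs_ref <- mean((reference - outcome)^2)
  list(bs = bs, one_minus_bs = 1 - bs, bss = 1 - bs / bs_ref)
}

#' Cross-validated AUC with a t-based confidence interval
#'
#' The AUC is computed within each fold ([mann_whitney_auc()]) and
#' summarized as the across-fold mean with a t-based 95% confidence
#' interval; folds containing a single outcome class are skipped and
#' counted. The AUC of all predictions pooled across folds is reported
#' alongside.
#'
#' @param records A [run_cross_validation()] result (or compatible data
#'   frame with `prob`, `outcome`, `fold`).
#' @param method Optional method name to filter on.
#' @param level Confidence level.
#' @return List with `auc_mean`, `ci` (length 2), `auc_pooled`, `fold_aucs`,
#'   `n_folds_skipped`.
#' @export
auc_with_ci <- function(records, method = NULL, level = 0.95) {
  r <- records_for(records, method)
  folds <- sort(unique(r$fold))
  aucs <- rep(NA_real_, length(folds))
  for (i in seq_along(folds)) {
    rf <- r[r$fold == folds[i], ]
    aucs[i] <- tryCatch(mann_whitney_auc(rf$prob, rf$outcome),
                        undefined_auc = function(e) NA_real_)
  }
  skipped <- sum(is.na(aucs))
  if (skipped > 0) {
    message(skipped, " fold(s) with a single outcome class skipped")
  }
  aucs <- aucs[!is.na(aucs)]
  m <- mean(aucs)
  ci <- if (length(aucs) > 1 && stats::sd(aucs) > 0) {
    half <- stats::qt(1 - (1 - level) / 2, df = length(aucs) - 1) *
      stats::sd(aucs) / sqrt(length(aucs))
    c(m - half, m + half)
  } else {
    c(m, m)
  }
  list(auc_mean = m, ci = ci,
       auc_pooled = mann_whitney_auc(r$prob, r$outcome),
       fold_aucs = aucs, n_folds_skipped = skipped)
}

#' Two-sided paired-samples t-test
#'
#' Classic paired t on per-dataset metric pairs: reports the mean
#' difference `A - B`, the t statistic, `df = n - 1`, and the two-sided p
#' value. When every difference is identical the t statistic is undefined;
#' by convention p is reported as exactly 1 when the common difference is
#' zero and 0 otherwise (with a message).
#'
#' @param a,b Paired metric values (e.g. per-dataset AUCs of two methods).
#' @return List with `mean_diff`, `t`, `df`, `p`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2, !anyNA(a), !anyNA(b))
  d <- a - b
  if (stats::sd(d) == 0) {
    message("zero variance of paired differences; edge-convention p value")
    return(list(mean_diff = mean(d),
                t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = length(d) - 1,
                p = if (mean(d) == 0) 1 else 0))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

#' Proportion of individuals on which two methods disagree
#'
#' `mode = "prediction"`: the fraction of individuals whose thresholded
#' class labels differ between the two methods. `mode = "path"`: the
#' fraction whose personalized conjunct set is not identical (as a set) to
#' the routing path in the comparator -- both interpretations of
#' "the model is different" are available because a path can differ while
#' the prediction agrees.
#'
#' @inheritParams auc_with_ci
#' @param method_a,method_b Method names present in `records`.
#' @param mode `"prediction"` or `"path"`.
#' @return Proportion in `[0, 1]`.
#' @export
disagreement_proportion <- function(records, method_a, method_b = "tree",
                                    mode = c("prediction", "path")) {
  mode <- match.arg(mode)
  ra <- records_for(records, method_a)
  rb <- records_for(records, method_b)
  if (!identical(ra$id, rb$id)) {
    ra <- ra[order(ra$id), ]
    rb <- rb[order(rb$id), ]
    if (!identical(ra$id, rb$id)) {
      stop("records of the two methods are not aligned by individual",
           call. = FALSE)
    }
  }
  if (mode == "prediction") {
    mean(ra$label != rb$label)
  } else {
    paths <- attr(records, "paths")
    if (is.null(paths)) {
      stop("path-mode disagreement needs the `paths` attribute from ",
           "run_cross_validation()", call. = FALSE)
    }
    mean(paths[[method_a]][ra$id] != paths[[method_b]][rb$id])
  }
}

#' Per-method metric summary of a cross-validation run
#'
#' One row per method: pooled and across-fold mean AUC with CI, `1 - BS`,
#' and BSS -- the layout of a benchmark results table.
#'
#' @inheritParams auc_with_ci
#' @return Data frame with one row per method.
#' @export
summarize_cv <- function(records) {
  methods <- unique(records$method)
  rows <- lapply(methods, function(m) {
    r <- records_for(records, m)
    a <- suppressMessages(auc_with_ci(records, m))
    b <- brier_metrics(r$prob, r$outcome)
    data.frame(method = m,
               auc = a$auc_pooled,
               auc_fold_mean = a$auc_mean,
               ci_lo = a$ci[1], ci_hi = a$ci[2],
               one_minus_bs = b$one_minus_bs,
               bss = b$bss,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
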