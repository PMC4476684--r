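#' Scoring configuration: the prior equivalent sample size
#'
#' All probability estimates and Bayesian split scores in the package are
#' governed by a single Dirichlet prior whose total mass `pess` (prior
#' equivalent sample size, the alpha of the BDeu estimator) is spread
#' uniformly over the K target values: `alpha_k = pess / K` for parameter
#' estimation, and per-sample Dirichlet parameters `alpha_jk = pess / K`,
#' `alpha_j = pess` in the two-sample split score. Larger `pess` pulls
#' estimates harder toward the uniform distribution. The default `pess = 1`
#' reproduces the non-informative setting used throughout the package's
#' evaluation protocol (for a binary target, `alpha_jk = 1/2`, `alpha_j = 1`).
#'
#' @param pess Positive real; total prior mass.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(pess = 1) {
  if (!is.numeric(pess) || length(pess) != 1 || !is.finite(pess) || pess <= 0) {
    stop("pess must be a single positive number", call. = FALSE)
  }
  structure(list(pess = as.numeric(pess)), class = "scoring_config")
}

check_counts <- function(counts) {
  if (!is.numeric(counts) || length(counts) < 2 || any(!is.finite(counts)) ||
      any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers over at least two classes",
         call. = FALSE)
  }
  as.numeric(counts)
}

#' BDeu-smoothed class probabilities
#'
#' The posterior-mean estimate `theta_k = (alpha_k + N_k) / (alpha + N)`
#' with uniform prior mass `alpha_k = pess / K`. With `pess > 0` every
#' probability is strictly inside (0, 1), so the estimate never commits to
#' impossibility even for empty or pure subgroups: zero counts give the
#' uniform prior back.
#'
#' @param counts Nonnegative integer vector of per-class counts.
#' @param config A [scoring_config()].
#' @return Numeric probability vector summing to 1, named like `counts`.
#' @examples
#' bdeu_theta(c(no = 40, yes = 62))          # ~0.393 / 0.607
#' bdeu_theta(c(no = 28, yes = 3))           # ~0.891 / 0.109
#' @export
bdeu_theta <- function(counts, config = scoring_config()) {
  cc <- check_counts(counts)
  K <- length(cc)
  theta <- (config$pess / K + cc) / (config$pess + sum(cc))
  names(theta) <- names(counts)
  theta
}

#' Two-sample Bayesian split score
#'
#' The log marginal likelihood of the target values in the two subsamples a
#' candidate feature induces -- the individuals matching the extended path
#' (`counts_in`) and the remainder of the current subgroup (`counts_out`) --
#' under independent Dirichlet-multinomial models with per-sample prior
#' parameters `alpha_jk = pess / K`:
#' \deqn{\sum_{j=1,2}\Big[\log\Gamma(\alpha_j) - \log\Gamma(N_j+\alpha_j) +
#'   \sum_k \big(\log\Gamma(N_{jk}+\alpha_{jk}) -
#'   \log\Gamma(\alpha_{jk})\big)\Big].}
#' Both candidate subsamples always enter, so every candidate variable is
#' evaluated on the same set of individuals regardless of how many it
#' matches. Computed entirely in log-gamma space; symmetric in its two
#' samples; empty samples contribute 0 (an empty dataset has marginal
#' likelihood 1).
#'
#' @param counts_in,counts_out Per-class counts of the two subsamples.
#' @inheritParams bdeu_theta
#' @return A single number (log marginal likelihood; always <= 0).
#' @export
bayes_score <- function(counts_in, counts_out, config = scoring_config()) {
  cin <- check_counts(counts_in)
  cout <- check_counts(counts_out)
  if (length(cin) != length(cout)) {
    stop("the two count vectors must cover the same classes", call. = FALSE)
  }
  K <- length(cin)
  ajk <- config$pess / K
  aj <- config$pess
  one <- function(cnt) {
    lgamma(aj) - lgamma(sum(cnt) + aj) + sum(lgamma(cnt + ajk) - lgamma(ajk))
  }
  one(cin) + one(cout)
}

# Single-sample Dirichlet-multinomial log marginal; the m-sample
# generalization of bayes_score, used by population-tree pruning.
dirichlet_marginal <- function(counts, config = scoring_config()) {
  cc <- check_counts(counts)
  K <- length(cc)
  ajk <- config$pess / K
  lgamma(config$pess) - lgamma(sum(cc) + config$pess) +
    sum(lgamma(cc + ajk) - lgamma(ajk))
}

#' Entropy of a class-count vector, in bits
#'
#' `-sum p_k log2 p_k` with `p_k = N_k / N`; the empty count vector has
#' entropy 0 by convention, as does any pure one (`0 log 0 = 0`).
#'
#' @inheritParams bdeu_theta
#' @export
entropy_bits <- function(counts) {
  cc <- check_counts(counts)
  n <- sum(cc)
  if (n == 0) return(0)
  p <- cc[cc > 0] / n
  -sum(p * log2(p))
}

#' Information gain of a binary partition
#'
#' Parent entropy minus the size-weighted entropies of the two subsamples.
#' Always in `[0, H(parent)]`. The subsample counts must sum to the parent
#' counts elementwise (i.e. form a partition).
#'
#' @param counts_parent,counts_in,counts_out Per-class counts.
#' @return Information gain in bits.
#' @export
info_gain <- function(counts_parent, counts_in, counts_out) {
  cp <- check_counts(counts_parent)
  cin <- check_counts(counts_in)
  cout <- check_counts(counts_out)
  if (length(cin) != length(cp) || length(cout) != length(cp) ||
      any(cin + cout != cp)) {
    stop("counts_in + counts_out must equal counts_parent: the split must ",
         "partition the parent sample", call. = FALSE)
  }
  n <- sum(cp)
  if (n == 0) return(0)
  entropy_bits(cp) -
    sum(cin) / n * entropy_bits(cin) -
    sum(cout) / n * entropy_bits(cout)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' The probability that a randomly chosen positive scores higher than a
#' randomly chosen negative, with half credit for ties:
#' `(#concordant + 0.5 #tied) / (#pos * #neg)`. Invariant to any strictly
#' increasing transform of the scores.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (TRUE = positive), or a 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @export
mann_whitney_auc <- function(scores, labels) {
  if (is.numeric(labels)) labels <- labels != 0
  stopifnot(is.logical(labels), length(scores) == length(labels),
            !anyNA(scores), !anyNA(labels))
  npos <- sum(labels)
  nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) {
    stop(structure(
      class = c("undefined_auc", "error", "condition"),
      list(message = "AUC undefined: both a positive and a negative label are required",
           call = sys.call())
    ))
  }
  r <- rank(scores)  # midranks give the tied pairs half credit
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Leave-one-out smoothed predictions within a subgroup
#'
#' For each individual in the subgroup, the BDeu probability of the positive
#' target value estimated from the remaining individuals: row `i` of class
#' `k` receives `(alpha_p + N_p - [k = p]) / (alpha + N - 1)`. A singleton
#' subgroup therefore gets the prior `alpha_p / alpha` back (0.5 at
#' `pess = 1` on a binary target).
#'
#' @inheritParams filter_matching
#' @inheritParams bdeu_theta
#' @return Numeric vector of positive-class probabilities, one per row.
#' @export
loocv_predictions <- function(data, config = scoring_config()) {
  stopifnot(inherits(data, "discrete_dataset"))
  n <- n_individuals(data)
  if (n == 0) stop("subgroup is empty", call. = FALSE)
  counts <- class_counts(data)
  K <- length(counts)
  p_idx <- match(data$positive, names(counts))
  y <- data$data[[data$target]]
  np <- counts[p_idx]
  denom <- config$pess + n - 1
  alpha_p <- config$pess / K
  ifelse(as.integer(y) == p_idx,
         (alpha_p + np - 1) / denom,
         (alpha_p + np) / denom)
}

#' Leave-one-out AUC split criterion
#'
#' Scores the candidate split `variable = value` of a subgroup `D` the way
#' the AUC-driven decision-path learner does: split `D` into the matching
#' individuals and the rest, compute [loocv_predictions()] separately within
#' each part (an empty part contributes nothing), pool all `|D|` predictions
#' with their true labels, and return the Mann-Whitney AUC. If the pooled
#' labels contain a single class the score falls back to 0.5 with a message.
#'
#' @inheritParams split_by_feature
#' @inheritParams bdeu_theta
#' @return AUC in `[0, 1]`.
#' @export
auc_criterion_score <- function(data, variable, value,
                                config = scoring_config()) {
  parts <- split_by_feature(data, variable, value)
  preds <- numeric(0)
  labs <- logical(0)
  for (part in parts) {
    if (n_individuals(part) == 0) next
    preds <- c(preds, loocv_predictions(part, config))
    labs <- c(labs, part$data[[part$target]] == part$positive)
  }
  tryCatch(
    mann_whitney_auc(preds, labs),
    undefined_auc = function(e) {
      message("AUC undefined for this split (single-class subgroup); scoring 0.5")
      0.5
    }
  )
}
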