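# Independent brute-force oracles.  These deliberately re-derive every
# quantity from first principles with naive loops and data-frame subsetting,
# sharing no code with the package internals they check.

# Dirichlet-multinomial marginal likelihood of one sample, computed as the
# direct product Gamma(a_j)/Gamma(N_j+a_j) * prod_k Gamma(N_jk+a_jk)/Gamma(a_jk)
# using rising factorials (exact for integer counts, no lgamma).
oracle_dm_marginal <- function(counts, ajk) {
  aj <- ajk * length(counts)
  num <- 1
  for (ck in counts) {
    if (ck > 0) num <- num * prod(ajk + 0:(ck - 1))
  }
  den <- if (sum(counts) == 0) 1 else prod(aj + 0:(sum(counts) - 1))
  num / den
}

oracle_bayes_score <- function(counts_in, counts_out, pess = 1) {
  ajk <- pess / length(counts_in)
  log(oracle_dm_marginal(counts_in, ajk) * oracle_dm_marginal(counts_out, ajk))
}

oracle_entropy <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# AUC by explicit enumeration of every positive/negative pair.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels]
  sn <- scores[!labels]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Leave-one-out smoothed positive-class predictions for a data-frame
# subgroup, by materializing each held-out count table.
oracle_loocv <- function(df, target, ylev, positive, pess = 1) {
  K <- length(ylev)
  pidx <- match(positive, ylev)
  n <- nrow(df)
  vapply(seq_len(n), function(i) {
    cc <- as.vector(table(factor(df[[target]][-i], levels = ylev)))
    (pess / K + cc[pidx]) / (pess + (n - 1))
  }, 0)
}

# Brute-force greedy growth + pruning re-implementation over plain data
# frames: candidate selection by the two-sample criterion on the current
# matching subgroup (skipping candidates with an empty matching part),
# earliest-variable tie-breaks, the three stopping rules, and a recorded
# path-level score computed on the full cohort partitioned into path
# matches vs the rest.  Returns the growth trace and the pruned prefix.
oracle_grow <- function(ds, person, criterion, pess = 1) {
  data <- ds$data
  target <- ds$target
  ylev <- levels(data[[target]])
  K <- length(ylev)
  positive <- ds$positive
  vars <- setdiff(names(data), target)
  counts_of <- function(d) as.vector(table(factor(d[[target]], levels = ylev)))

  subgroup_score <- function(din, dout, dcur) {
    cin <- counts_of(din)
    cout <- counts_of(dout)
    if (criterion == "bay") {
      oracle_bayes_score(cin, cout, pess)
    } else if (criterion == "ig") {
      oracle_entropy(counts_of(dcur)) -
        nrow(din) / nrow(dcur) * oracle_entropy(cin) -
        nrow(dout) / nrow(dcur) * oracle_entropy(cout)
    } else {
      preds <- labs <- NULL
      for (d in list(din, dout)) {
        if (nrow(d) == 0) next
        preds <- c(preds, oracle_loocv(d, target, ylev, positive, pess))
        labs <- c(labs, d[[target]] == positive)
      }
      if (all(labs) || !any(labs)) 0.5 else oracle_auc(preds, labs)
    }
  }

  cur <- data
  trace_var <- character(0)
  trace_score <- numeric(0)
  S <- character(0)
  repeat {
    cc <- counts_of(cur)
    if (nrow(cur) == 0 || sum(cc > 0) <= 1) break
    cand <- vars[!(vars %in% S) & !is.na(person[vars])]
    best <- NULL
    best_s <- NA_real_
    for (v in cand) {
      inmask <- !is.na(cur[[v]]) & cur[[v]] == person[[v]]
      if (sum(inmask) == 0) next
      sc <- subgroup_score(cur[inmask, , drop = FALSE],
                           cur[!inmask, , drop = FALSE], cur)
      if (is.null(best) || sc > best_s) {
        best <- v
        best_s <- sc
      }
    }
    if (is.null(best)) break
    S <- c(S, best)
    inmask <- !is.na(cur[[best]]) & cur[[best]] == person[[best]]
    cur <- cur[inmask, , drop = FALSE]
    match_all <- rep(TRUE, nrow(data))
    for (v in S) {
      match_all <- match_all & !is.na(data[[v]]) & data[[v]] == person[[v]]
    }
    rec <- subgroup_score(data[match_all, , drop = FALSE],
                          data[!match_all, , drop = FALSE], data)
    trace_var <- c(trace_var, best)
    trace_score <- c(trace_score, rec)
  }
  pruned_len <- if (length(trace_score) == 0) 0L else which.max(trace_score)
  list(vars = trace_var, scores = trace_score, pruned_len = pruned_len)
}

# Random tiny dataset for oracle-equivalence checks: <= 4 predictors of
# domain size 2-3, <= 12 rows, occasional missing predictor values.
random_tiny_dataset <- function(max_vars = 4, max_rows = 12,
                                missing_rate = 0.1) {
  p <- sample(1:max_vars, 1)
  n <- sample(3:max_rows, 1)
  df <- data.frame(row.names = seq_len(n))
  for (j in seq_len(p)) {
    m <- sample(2:3, 1)
    vals <- letters[sample.int(m, n, replace = TRUE)]
    vals[runif(n) < missing_rate] <- NA
    df[[paste0("V", j)]] <- factor(vals, levels = letters[1:m])
  }
  df$y <- factor(sample(c("no", "yes"), n, replace = TRUE),
                 levels = c("no", "yes"))
  discrete_dataset(df, target = "y", positive = "yes")
}

random_person_for <- function(ds, missing_rate = 0.2) {
  vars <- dataset_variables(ds)
  out <- stats::setNames(rep(NA_character_, length(vars)), vars)
  for (v in vars) {
    if (runif(1) >= missing_rate) {
      out[[v]] <- sample(levels(ds$data[[v]]), 1)
    }
  }
  out
}

# Parse an exported IF-THEN rule back into conjuncts and probability.
parse_rule <- function(rule) {
  m <- regmatches(rule,
                  regexec("^IF (.*) THEN P\\(([^=]+)=([^)]+)\\)=([0-9.]+) \\(n=([0-9]+), counts=([0-9/]+)\\)$",
                          rule))[[1]]
  stopifnot(length(m) == 7)
  conj <- if (m[2] == "TRUE") {
    data.frame(variable = character(), value = character(),
               stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(strsplit(m[2], " AND ", fixed = TRUE)[[1]], "=",
                      fixed = TRUE)
    data.frame(variable = vapply(parts, `[`, "", 1),
               value = vapply(parts, `[`, "", 2),
               stringsAsFactors = FALSE)
  }
  list(conjuncts = conj, prob = as.numeric(m[5]),
       counts = as.integer(strsplit(m[7], "/", fixed = TRUE)[[1]]))
}
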