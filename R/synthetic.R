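# Seeded synthetic cohorts with the statistical structure the learners
# assume: a small set of genuinely predictive discrete variables among
# noise, a binary outcome at a controlled prevalence, and (optionally)
# missing values injected completely at random.

inject_mcar <- function(df, vars, rate) {
  if (rate <= 0 || length(vars) == 0) return(df)
  for (v in vars) {
    col <- df[[v]]
    miss <- runif(length(col)) < rate
    col[miss] <- NA
    df[[v]] <- col
  }
  df
}

#' Generate a path-structured discrete cohort with known ground truth
#'
#' Draws `s = log2(length(signal_probs))` binary signal variables, sets the
#' binary outcome from the conditional table `P(T = yes | signal pattern)`,
#' and adds `n_noise` discrete noise variables independent of the outcome
#' (domain sizes 2-4, echoing discretized clinical variables). Missingness,
#' when requested, is injected completely at random into every predictor.
#' The ground truth -- signal variable names, each row's true outcome
#' probability, and the Bayes-optimal AUC obtained by rank-scoring the rows
#' with those true probabilities -- is attached so parameter-recovery tests
#' need no external reference.
#'
#' @param n Number of individuals.
#' @param signal_probs Numeric vector of length `2^s`: `P(T = yes)` for each
#'   signal pattern (patterns ordered by binary code, first variable =
#'   lowest bit). The default is a single strong binary signal,
#'   `P(T = yes | V = 0) = 0.1`, `P(T = yes | V = 1) = 0.9`.
#' @param n_noise Number of noise variables.
#' @param noise_levels Optional integer vector of domain sizes for the noise
#'   variables; defaults to sizes drawn from 2-4.
#' @param signal_var_p Probability that a signal variable equals `"1"`.
#' @param prevalence Optional target prevalence; only supported for a single
#'   signal variable, where `P(V = 1)` is solved to reach it. An
#'   unreachable prevalence (outside the range of `signal_probs`) is an
#'   error.
#' @param missing_rate MCAR missingness rate applied to every predictor.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A [discrete_dataset()] (target `outcome`, positive `"yes"`) with
#'   a `ground_truth` attribute: list of `signal`, `bayes_prob`,
#'   `bayes_auc`.
#' @export
gen_path_process <- function(n = 2000, signal_probs = c(0.1, 0.9),
                             n_noise = 20, noise_levels = NULL,
                             signal_var_p = 0.5, prevalence = NULL,
                             missing_rate = 0, seed = 1) {
  s <- log2(length(signal_probs))
  if (s != round(s) || s < 1) {
    stop("signal_probs must have length 2^s for s >= 1 signal variables",
         call. = FALSE)
  }
  s <- as.integer(s)
  if (any(signal_probs < 0 | signal_probs > 1)) {
    stop("signal_probs must be probabilities", call. = FALSE)
  }
  if (!is.null(prevalence)) {
    if (s > 1) {
      stop("explicit prevalence is only supported for one signal variable; ",
           "encode it through signal_probs instead", call. = FALSE)
    }
    lo <- min(signal_probs)
    hi <- max(signal_probs)
    if (prevalence < lo || prevalence > hi) {
      stop("prevalence ", prevalence, " unreachable: signal_probs span [",
           lo, ", ", hi, "]", call. = FALSE)
    }
    if (signal_probs[2] != signal_probs[1]) {
      signal_var_p <- (prevalence - signal_probs[1]) /
        (signal_probs[2] - signal_probs[1])
    }
  }
  local_seed(seed, {
    sig <- matrix(rbinom(n * s, 1, signal_var_p), nrow = n)
    pattern <- as.vector(sig %*% 2^(seq_len(s) - 1))
    p1 <- signal_probs[pattern + 1]
    yv <- rbinom(n, 1, p1)
    if (is.null(noise_levels)) {
      noise_levels <- sample(2:4, n_noise, replace = TRUE)
    }
    stopifnot(length(noise_levels) == n_noise)
    df <- as.data.frame(
      lapply(seq_len(s), function(j) as.character(sig[, j])),
      col.names = paste0("S", seq_len(s))
    )
    for (j in seq_len(n_noise)) {
      df[[paste0("X", j)]] <- as.character(
        sample.int(noise_levels[j], n, replace = TRUE) - 1L)
    }
    df <- inject_mcar(df, names(df), missing_rate)
    df$outcome <- ifelse(yv == 1, "yes", "no")
    ds <- discrete_dataset(df, target = "outcome", positive = "yes")
    attr(ds, "ground_truth") <- list(
      signal = paste0("S", seq_len(s)),
      bayes_prob = p1,
      bayes_auc = mann_whitney_auc(p1, yv == 1)
    )
    ds
  })
}

#' Two-class Gaussian mixture, for discretization tests
#'
#' Balanced two-class sample with class-conditional means `means[1]`,
#' `means[2]` and common standard deviation `sd` -- the canonical input for
#' checking that MDL discretization places one cut at the class boundary
#' (well-separated means) and none under the null (equal means).
#'
#' @param n Sample size (split as evenly as possible between classes).
#' @param means Length-2 class means.
#' @param sd Common standard deviation (> 0).
#' @param seed Integer seed.
#' @return List with `values` (numeric) and `labels` (factor `neg`/`pos`).
#' @export
gen_continuous_mixture <- function(n = 500, means = c(-3, 3), sd = 1,
                                   seed = 1) {
  stopifnot(length(means) == 2, sd > 0)
  local_seed(seed, {
    lab <- rep(c("neg", "pos"), length.out = n)
    vals <- rnorm(n, mean = ifelse(lab == "pos", means[2], means[1]), sd = sd)
    list(values = vals, labels = factor(lab, levels = c("neg", "pos")))
  })
}

benchmark_shapes <- function() {
  data.frame(
    name = c("pneumonia", "sepsis-d", "sepsis-s", "heart-failure-d",
             "heart-failure-c", "hit", "alzheimer"),
    n = c(2287, 1673, 1673, 11178, 11178, 549, 1411),
    n_cont = c(38, 7, 7, 11, 11, 50, 0),
    n_disc = c(120, 14, 14, 10, 10, 9, 100),
    prevalence = c(0.114, 0.113, 0.286, 0.045, 0.112, 0.138, 0.610),
    stringsAsFactors = FALSE
  )
}

# One synthetic benchmark cohort: a handful of binary discrete signal
# variables plus (when the shape has continuous predictors) one continuous
# signal variable act on the outcome through a logistic model whose
# intercept is solved so the expected prevalence matches the target; all
# remaining predictors are noise.  MCAR missingness (5%) on every third
# predictor.  Assumes the RNG is already seeded by the caller.
gen_benchmark_dataset <- function(n, n_cont, n_disc, prevalence) {
  n_sig_d <- min(3L, n_disc)
  beta_d <- c(1.2, 1.0, 0.8)[seq_len(n_sig_d)]
  n_sig_c <- if (n_cont > 0) 1L else 0L
  beta_c <- 0.8

  sig_d <- matrix(rbinom(n * n_sig_d, 1, 0.5), nrow = n)
  lp <- as.vector(sig_d %*% beta_d)
  sig_c <- NULL
  if (n_sig_c == 1) {
    sig_c <- rnorm(n)
    lp <- lp + beta_c * sig_c
  }
  b0 <- uniroot(function(b) mean(plogis(b + lp)) - prevalence,
                c(-30, 30))$root
  pr <- plogis(b0 + lp)
  yv <- rbinom(n, 1, pr)

  df <- as.data.frame(
    lapply(seq_len(n_sig_d), function(j) as.character(sig_d[, j])),
    col.names = paste0("sig", seq_len(n_sig_d))
  )
  if (n_sig_c == 1) df$csig1 <- sig_c
  for (j in seq_len(n_disc - n_sig_d)) {
    lev <- sample(2:4, 1)
    df[[paste0("d", j)]] <- as.character(sample.int(lev, n, replace = TRUE) - 1L)
  }
  for (j in seq_len(n_cont - n_sig_c)) {
    df[[paste0("c", j)]] <- rnorm(n)
  }
  preds <- names(df)
  df <- inject_mcar(df, preds[seq_along(preds) %% 3 == 0], 0.05)
  df$outcome <- ifelse(yv == 1, "yes", "no")
  ds <- discrete_dataset(df, target = "outcome", positive = "yes")
  attr(ds, "ground_truth") <- list(
    signal = c(paste0("sig", seq_len(n_sig_d)),
               if (n_sig_c == 1) "csig1"),
    bayes_prob = pr,
    bayes_auc = mann_whitney_auc(pr, yv == 1)
  )
  ds
}

#' Synthetic benchmark suite of clinically shaped cohorts
#'
#' Seven seeded synthetic datasets whose (predictor count, sample size,
#' prevalence) triples mirror a representative spread of clinical and
#' genomic prediction problems -- from a rare-outcome administrative
#' cohort (4.5% prevalence, ~11k individuals, scaled) to a balanced
#' genotype panel of 100 discrete predictors at 61% prevalence -- each with
#' planted signal, continuous noise requiring discretization, and MCAR
#' missingness. All cohorts are synthetic; the clinical names label the
#' shape being emulated, not real patient data.
#'
#' @param seed Integer seed.
#' @param scale Sample-size scale factor; the default 1/10 keeps the full
#'   suite evaluable on a desk machine.
#' @return Named list of [discrete_dataset()]s, each with a `ground_truth`
#'   attribute.
#' @export
make_benchmark_suite <- function(seed = 1, scale = 0.1) {
  shapes <- benchmark_shapes()
  local_seed(seed, {
    out <- lapply(seq_len(nrow(shapes)), function(i) {
      gen_benchmark_dataset(
        n = max(40L, as.integer(round(shapes$n[i] * scale))),
        n_cont = shapes$n_cont[i],
        n_disc = shapes$n_disc[i],
        prevalence = shapes$prevalence[i]
      )
    })
    names(out) <- shapes$name
    out
  })
}
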