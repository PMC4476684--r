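#' Best entropy cut of a continuous variable
#'
#' Evaluates every candidate threshold (midpoints between adjacent distinct
#' sorted values) of `values` and returns the one whose induced binary
#' partition maximizes the information gain of `labels`, together with the
#' statistics the MDL acceptance rule needs. Boundary-point theory
#' guarantees the optimum sits between adjacent values of differing class
#' composition; scanning all midpoints returns the identical maximum. Ties
#' go to the lowest threshold. Pairs with a missing value or label are
#' ignored.
#'
#' @param values Numeric vector.
#' @param labels Class labels aligned with `values`.
#' @return `NULL` when no cut exists (all labels equal, or fewer than two
#'   distinct values); otherwise a list with `cut`, `gain`, and the node /
#'   child statistics `n`, `k`, `k1`, `k2`, `h`, `h1`, `h2`.
#' @export
mdl_best_cut <- function(values, labels) {
  ok <- !is.na(values) & !is.na(labels)
  v <- values[ok]
  l <- factor(labels[ok])
  if (any(!is.finite(v))) stop("values must be finite", call. = FALSE)
  l <- droplevels(l)
  if (nlevels(l) < 2 || length(unique(v)) < 2) return(NULL)
  ord <- order(v)
  v <- v[ord]
  l <- l[ord]
  K <- nlevels(l)
  # class counts aggregated over distinct values, then cumulated
  dv <- unique(v)
  m <- length(dv)
  grp <- match(v, dv)
  cnt <- matrix(0, nrow = m, ncol = K)
  for (k in seq_len(K)) cnt[, k] <- tabulate(grp[as.integer(l) == k], nbins = m)
  cum <- apply(cnt, 2, cumsum)
  if (m == 2) cum <- matrix(cum, nrow = m)
  total <- cum[m, ]
  n <- sum(total)
  h <- entropy_bits(total)
  ent_rows <- function(mat) {
    ns <- rowSums(mat)
    e <- numeric(nrow(mat))
    for (k in seq_len(ncol(mat))) {
      p <- ifelse(ns > 0, mat[, k] / ns, 0)
      e <- e - ifelse(p > 0, p * log2(p), 0)
    }
    e
  }
  left <- cum[seq_len(m - 1), , drop = FALSE]
  right <- matrix(total, nrow = m - 1, ncol = K, byrow = TRUE) - left
  nl <- rowSums(left)
  gains <- h - nl / n * ent_rows(left) - (n - nl) / n * ent_rows(right)
  best <- which.max(gains)
  list(cut = (dv[best] + dv[best + 1]) / 2,
       gain = gains[best],
       n = n,
       k = K,
       k1 = sum(left[best, ] > 0),
       k2 = sum(right[best, ] > 0),
       h = h,
       h1 = ent_rows(left[best, , drop = FALSE]),
       h2 = ent_rows(right[best, , drop = FALSE]))
}

#' MDL acceptance rule for a candidate cut
#'
#' The minimum-description-length criterion of entropy-based recursive
#' discretization: a cut is accepted iff
#' `gain > log2(n - 1)/n + (log2(3^k - 2) - (k*h - k1*h1 - k2*h2)) / n`,
#' where `k`, `k1`, `k2` are the numbers of classes present in the node and
#' its two children and `h`, `h1`, `h2` their entropies in bits.
#'
#' @param gain Information gain of the cut, in bits.
#' @param n Number of (non-missing) individuals at the node.
#' @param k,k1,k2 Class counts present in the node and the two children.
#' @param h,h1,h2 Entropies (bits) of the node and the two children.
#' @return `TRUE` if the cut passes the MDL test.
#' @export
mdl_accepts <- function(gain, n, k, k1, k2, h, h1, h2) {
  stopifnot(n >= 2)
  delta <- log2(3^k - 2) - (k * h - k1 * h1 - k2 * h2)
  gain > log2(n - 1) / n + delta / n
}

#' Recursive MDL entropy discretization of one variable
#'
#' Entropy-based recursive binary discretization: the best cut
#' ([mdl_best_cut()]) is applied whenever it passes the MDL test
#' ([mdl_accepts()]), then each half is discretized recursively until no
#' accepted cut remains. Thresholds come back strictly increasing; an empty
#' result means the variable carries no MDL-detectable class signal and
#' will become a single constant bin.
#'
#' @inheritParams mdl_best_cut
#' @return Numeric vector of thresholds (possibly empty), defining the
#'   half-open bins `(-Inf, c1], (c1, c2], ..., (cm, Inf)`.
#' @export
discretize_mdl <- function(values, labels) {
  ok <- !is.na(values) & !is.na(labels)
  rec <- function(v, l) {
    bc <- mdl_best_cut(v, l)
    if (is.null(bc)) return(numeric(0))
    if (!mdl_accepts(bc$gain, bc$n, bc$k, bc$k1, bc$k2, bc$h, bc$h1, bc$h2)) {
      return(numeric(0))
    }
    lower <- v <= bc$cut
    c(rec(v[lower], l[lower]), bc$cut, rec(v[!lower], l[!lower]))
  }
  rec(values[ok], labels[ok])
}

#' Learn MDL cut points for every continuous predictor
#'
#' @inheritParams dataset_variables
#' @return A named list (class `cut_point_set`) with one numeric threshold
#'   vector per continuous predictor.
#' @export
learn_cuts <- function(data) {
  stopifnot(inherits(data, "discrete_dataset"))
  vars <- continuous_variables(data)
  y <- data$data[[data$target]]
  cuts <- lapply(vars, function(v) discretize_mdl(data$data[[v]], y))
  names(cuts) <- vars
  structure(cuts, class = "cut_point_set")
}

#' Apply cut points, turning continuous predictors into discrete bins
#'
#' Each continuous value maps to its half-open bin `(c_i, c_{i+1}]` -- a
#' value exactly equal to a threshold falls in the lower bin -- labelled
#' `"(-Inf,c1]"` etc.; missing stays missing. A variable with zero accepted
#' cuts becomes a single constant bin and is flagged in the
#' `uninformative_vars` attribute of the result (such variables can never
#' split anything).
#'
#' @inheritParams dataset_variables
#' @param cuts A `cut_point_set` from [learn_cuts()] (or a named list of
#'   thresholds).
#' @return A `discrete_dataset` with the listed variables discretized.
#' @export
apply_cuts <- function(data, cuts) {
  stopifnot(inherits(data, "discrete_dataset"))
  out <- data
  flat <- character(0)
  for (v in names(cuts)) {
    if (!v %in% names(out$data)) {
      stop("cut-point variable '", v, "' not found in data", call. = FALSE)
    }
    col <- out$data[[v]]
    if (!is.numeric(col)) {
      stop("variable '", v, "' is not continuous", call. = FALSE)
    }
    th <- cuts[[v]]
    if (length(th) == 0) {
      out$data[[v]] <- factor(ifelse(is.na(col), NA, "all"), levels = "all")
      flat <- c(flat, v)
    } else {
      out$data[[v]] <- cut(col, breaks = c(-Inf, th, Inf), right = TRUE)
    }
  }
  attr(out, "uninformative_vars") <- flat
  out
}

#' Write / read a cut-point sidecar file
#'
#' Plain-text serialization of a [learn_cuts()] result: one line per
#' variable, `name<TAB>c1,c2,...` (an empty threshold list writes an empty
#' field), so a discretization can be reapplied exactly.
#'
#' @param cuts A `cut_point_set`.
#' @param path File path.
#' @export
write_cutpoints <- function(cuts, path) {
  lines <- vapply(names(cuts), function(v) {
    paste0(v, "\t", paste(format(cuts[[v]], digits = 17), collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cutpoints
#' @export
read_cutpoints <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    th <- if (length(parts) < 2 || !nzchar(trimws(parts[2]))) {
      numeric(0)
    } else {
      as.numeric(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    }
    out[[parts[1]]] <- th
  }
  structure(out, class = "cut_point_set")
}

#' Rank discrete predictors by chi-square association with the target
#'
#' Pearson chi-square statistic (no continuity correction) of each
#' predictor-by-target contingency table, sorted in descending order --
#' the screening used to pick a manageable top slice of a very wide
#' genotype table (e.g. the 100 most outcome-associated SNPs) before path
#' learning. Rows missing the predictor are dropped pairwise; a predictor
#' with a single observed value gets statistic 0.
#'
#' @inheritParams dataset_variables
#' @param top_n How many top-ranked variables to return; a value exceeding
#'   the predictor count returns all of them (with a message).
#' @return Data frame with columns `variable`, `statistic`, `df`, ordered
#'   by decreasing statistic.
#' @export
chi2_rank <- function(data, top_n = Inf) {
  stopifnot(inherits(data, "discrete_dataset"))
  vars <- dataset_variables(data)
  cont <- continuous_variables(data)
  if (length(cont) > 0) {
    stop("chi2_rank requires discrete predictors; discretize first: ",
         paste(cont, collapse = ", "), call. = FALSE)
  }
  y <- data$data[[data$target]]
  stat <- df <- numeric(length(vars))
  for (i in seq_along(vars)) {
    x <- data$data[[vars[i]]]
    tab <- table(droplevels(x), y)
    if (nrow(tab) < 2 || ncol(tab) < 2 || sum(tab) == 0) {
      stat[i] <- 0
      df[i] <- 0
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      stat[i] <- unname(ct$statistic)
      df[i] <- unname(ct$parameter)
    }
  }
  ord <- order(stat, decreasing = TRUE)
  out <- data.frame(variable = vars[ord], statistic = stat[ord], df = df[ord],
                    stringsAsFactors = FALSE)
  if (is.finite(top_n) && top_n > nrow(out)) {
    message("top_n exceeds the number of predictors; returning all ",
            nrow(out))
  }
  head(out, n = min(top_n, nrow(out)))
}
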