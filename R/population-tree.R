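#' Fit a population decision tree
#'
#' The population comparator: one tree fitted to the whole training cohort
#' and applied unchanged to every future individual. Top-down recursive
#' multiway splitting chooses at each node the variable (not already used on
#' the path) maximizing the information gain of the induced partition, with
#' rows missing the split variable routed to the child receiving the most
#' training rows; children cover the variable's full domain, so every
#' training row reaches exactly one leaf. Splitting stops on purity,
#' exhausted variables, `max_depth`, or the `min_leaf` floor. Leaf
#' probabilities are BDeu-smoothed ([bdeu_theta()]).
#'
#' With `prune = TRUE` (default) the grown tree is collapsed bottom-up:
#' an internal node whose children are all leaves is merged whenever the
#' Dirichlet-multinomial log marginal of its pooled counts is at least the
#' sum of its children's marginals -- the multiway analogue of the
#' two-sample [bayes_score()], so uninformative splits are removed.
#'
#' @inheritParams grow_path
#' @param min_leaf Minimum number of training rows in any nonempty child of
#'   a split (1 = unconstrained).
#' @param max_depth Maximum tree depth (`Inf` = unconstrained).
#' @param prune Collapse uninformative subtrees bottom-up.
#' @return An object of class `population_tree`.
#' @examples
#' ds <- gen_path_process(n = 300, n_noise = 4, seed = 11)
#' tr <- fit_population_tree(ds)
#' tree_predict(tr, person_instance(ds$data[1, ], ds))
#' @export
fit_population_tree <- function(train, config = scoring_config(),
                                min_leaf = 1, max_depth = Inf, prune = TRUE) {
  stopifnot(inherits(train, "discrete_dataset"))
  if (n_individuals(train) == 0) {
    stop("training dataset is empty", call. = FALSE)
  }
  enc <- encode_dataset(train)
  md <- if (is.finite(max_depth)) as.integer(max_depth) else .Machine$integer.max
  res <- cpp_fit_tree(enc$X, enc$y, enc$K, enc$nlev,
                      as.integer(min_leaf), md)
  tree <- structure(
    list(parent = res$parent, depth = res$depth, var = res$var,
         missing_child = res$missing_child, counts = res$counts,
         children = res$children,
         is_leaf = is.na(res$var),
         enc = enc[c("vars", "levels", "nlev", "ylev", "K", "positive")],
         target = train$target, positive = train$positive,
         config = config, pruned = FALSE),
    class = "population_tree"
  )
  if (prune) tree <- prune_population_tree(tree)
  tree
}

# Bottom-up collapse: children (all leaves) vs merged node compared on
# Dirichlet-multinomial log marginals.  Ties collapse (simpler model).
prune_population_tree <- function(tree) {
  n <- length(tree$parent)
  is_leaf <- tree$is_leaf
  ord <- order(tree$depth, decreasing = TRUE)
  for (id in ord) {
    if (is_leaf[id]) next
    kids <- tree$children[[id]]
    if (!all(is_leaf[kids])) next
    split_ll <- sum(vapply(kids, function(k) {
      dirichlet_marginal(tree$counts[k, ], tree$config)
    }, 0))
    merged_ll <- dirichlet_marginal(tree$counts[id, ], tree$config)
    if (merged_ll >= split_ll - 1e-9) is_leaf[id] <- TRUE
  }
  tree$is_leaf <- is_leaf
  tree$pruned <- TRUE
  tree
}

#' @export
print.population_tree <- function(x, ...) {
  live <- tree_live_nodes(x)
  n_leaf <- sum(x$is_leaf[live])
  cat("<population_tree> ", length(live), " nodes (", n_leaf, " leaves), ",
      "depth ", max(x$depth[live]), if (x$pruned) ", pruned" else "",
      "\n", sep = "")
  invisible(x)
}

# Node ids reachable from the root without crossing a (possibly
# prune-created) leaf.
tree_live_nodes <- function(tree) {
  live <- integer(0)
  stack <- 1L
  while (length(stack) > 0) {
    id <- stack[[1]]
    stack <- stack[-1]
    live <- c(live, id)
    if (!tree$is_leaf[id]) stack <- c(stack, tree$children[[id]])
  }
  live
}

tree_route <- function(tree, codes) {
  id <- 1L
  path_vars <- integer(0)
  path_vals <- integer(0)
  while (!tree$is_leaf[id]) {
    v <- tree$var[id]
    code <- codes[v]
    if (is.na(code)) code <- tree$missing_child[id]
    path_vars <- c(path_vars, v)
    path_vals <- c(path_vals, code)
    id <- tree$children[[id]][code]
  }
  list(leaf = id, vars = path_vars, vals = path_vals)
}

#' Predict with a population tree
#'
#' Routes the individual from the root to a leaf -- a missing value follows
#' the designated missing-child (the child that received the most training
#' rows) -- and returns the leaf's BDeu-smoothed probability of the positive
#' target value.
#'
#' @param tree A fitted [fit_population_tree()] model.
#' @param person A [person_instance()], named character vector, or one-row
#'   data frame.
#' @return Probability of the positive outcome.
#' @export
tree_predict <- function(tree, person) {
  stopifnot(inherits(tree, "population_tree"))
  codes <- tree_person_codes(tree, person)
  r <- tree_route(tree, codes)
  theta <- bdeu_theta(tree$counts[r$leaf, ], tree$config)
  unname(theta[tree$enc$positive])
}

#' @export
predict.population_tree <- function(object, newdata, ...) {
  tree_predict(object, newdata)
}

tree_person_codes <- function(tree, person) {
  if (is.data.frame(person)) {
    stopifnot(nrow(person) == 1)
    person <- vapply(names(person), function(nm) {
      v <- person[[nm]][1]
      if (is.na(v)) NA_character_ else as.character(v)
    }, "")
  }
  codes <- rep(NA_integer_, length(tree$enc$vars))
  for (j in seq_along(tree$enc$vars)) {
    v <- person[[tree$enc$vars[j]]]
    if (!is.null(v) && !is.na(v)) {
      codes[j] <- match(v, tree$enc$levels[[j]])
      if (is.na(codes[j])) {
        stop("person value '", v, "' is not in the domain of '",
             tree$enc$vars[j], "'", call. = FALSE)
      }
    }
  }
  codes
}

#' Conjuncts along an individual's routing path
#'
#' The ordered `(variable, value)` conjuncts of the root-to-leaf path the
#' individual follows, including the branch value taken by missing-value
#' routing. A single-leaf tree yields the empty list.
#'
#' @inheritParams tree_predict
#' @return Data frame of conjuncts (`variable`, `value`).
#' @export
tree_path_for_person <- function(tree, person) {
  stopifnot(inherits(tree, "population_tree"))
  codes <- tree_person_codes(tree, person)
  r <- tree_route(tree, codes)
  data.frame(
    variable = tree$enc$vars[r$vars],
    value = vapply(seq_along(r$vars), function(i) {
      tree$enc$levels[[r$vars[i]]][r$vals[i]]
    }, ""),
    stringsAsFactors = FALSE
  )
}

# Batch prediction for cross-validation: codes matrix rows are individuals.
tree_predict_codes <- function(tree, codes_mat) {
  n <- nrow(codes_mat)
  prob <- numeric(n)
  path <- character(n)
  pess <- tree$config$pess
  K <- tree$enc$K
  for (i in seq_len(n)) {
    r <- tree_route(tree, codes_mat[i, ])
    cnt <- tree$counts[r$leaf, ]
    prob[i] <- (pess / K + cnt[tree$enc$positive]) / (pess + sum(cnt))
    path[i] <- if (length(r$vars) == 0) {
      "TRUE"
    } else {
      paste(sort(paste0(tree$enc$vars[r$vars], "=",
                        vapply(seq_along(r$vars), function(q) {
                          tree$enc$levels[[r$vars[q]]][r$vals[q]]
                        }, ""))),
            collapse = " & ")
    }
  }
  list(prob = prob, path = path)
}
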