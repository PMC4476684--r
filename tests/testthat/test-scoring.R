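test_that("BDeu smoothing matches hand arithmetic and its limits", {
  expect_equal(unname(bdeu_theta(c(0, 0))), c(0.5, 0.5))
  expect_equal(unname(bdeu_theta(c(40, 62))), c(40.5, 62.5) / 103)
  expect_equal(unname(bdeu_theta(c(28, 3))), c(28.5, 3.5) / 32)
  expect_equal(sum(bdeu_theta(c(7, 1, 4), scoring_config(2))), 1)

  # converges to empirical frequencies as N grows ...
  big <- c(30000, 70000)
  expect_equal(unname(bdeu_theta(big)), big / sum(big), tolerance = 1e-2)
  # ... and to uniform as pess grows
  expect_equal(unname(bdeu_theta(c(40, 62), scoring_config(1e8))),
               c(0.5, 0.5), tolerance = 1e-5)
  expect_error(bdeu_theta(c(-1, 2)), "nonnegative")
  expect_error(scoring_config(0), "positive")
})

test_that("two-sample Bayesian score equals the direct marginal product", {
  expect_equal(bayes_score(c(0, 0), c(0, 0)), 0)
  expect_equal(bayes_score(c(1, 0), c(0, 1)), 2 * log(0.5))
  # symmetry in the two samples
  expect_equal(bayes_score(c(3, 1), c(0, 2)), bayes_score(c(0, 2), c(3, 1)))
  # spot-check against the rising-factorial oracle on a sample of tables
  set.seed(402)
  for (rep in 1:25) {
    cin <- c(sample(0:6, 1), sample(0:6, 1))
    cout <- c(sample(0:6, 1), sample(0:6, 1))
    pess <- sample(c(0.5, 1, 2), 1)
    expect_equal(bayes_score(cin, cout, scoring_config(pess)),
                 oracle_bayes_score(cin, cout, pess), tolerance = 1e-9)
  }
  expect_error(bayes_score(c(1, -1), c(0, 0)), "nonnegative")
})

test_that("entropy and information gain match hand arithmetic", {
  expect_equal(entropy_bits(c(2, 2)), 1)
  expect_equal(entropy_bits(c(4, 0)), 0)
  expect_equal(entropy_bits(c(1, 3)), 0.811278, tolerance = 1e-6)
  expect_equal(entropy_bits(c(0, 0)), 0)

  expect_equal(info_gain(c(2, 2), c(2, 0), c(0, 2)), 1)
  expect_equal(info_gain(c(2, 2), c(1, 1), c(1, 1)), 0)
  expect_equal(info_gain(c(3, 1), c(2, 0), c(1, 1)),
               entropy_bits(c(3, 1)) - 0.5, tolerance = 1e-9)
  # symmetry and the partition pre-condition
  expect_equal(info_gain(c(3, 1), c(2, 0), c(1, 1)),
               info_gain(c(3, 1), c(1, 1), c(2, 0)))
  expect_error(info_gain(c(3, 1), c(2, 0), c(2, 1)), "partition")
})

test_that("Mann-Whitney AUC handles ties and transforms", {
  expect_equal(mann_whitney_auc(c(2, 3, 10, 20), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(mann_whitney_auc(rep(0.3, 5), c(TRUE, FALSE, TRUE, FALSE, FALSE)), 0.5)
  expect_equal(mann_whitney_auc(c(0.9, 0.8, 0.7, 0.6),
                                c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  expect_error(mann_whitney_auc(1:3, c(TRUE, TRUE, TRUE)), class = "undefined_auc")

  set.seed(403)
  for (rep in 1:10) {
    s <- rnorm(20)
    l <- sample(c(TRUE, FALSE), 20, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(l) || all(l)) next
    expect_equal(mann_whitney_auc(s, l), oracle_auc(s, l), tolerance = 1e-12)
    # monotone invariance and complement identities
    expect_equal(mann_whitney_auc(exp(s), l), mann_whitney_auc(s, l))
    expect_equal(mann_whitney_auc(s + 5, l), mann_whitney_auc(s, l))
    expect_equal(mann_whitney_auc(s, l) + mann_whitney_auc(-s, l), 1)
  }
})

test_that("leave-one-out predictions match the closed form", {
  single <- discrete_dataset(
    data.frame(V = "a", y = factor("yes", levels = c("no", "yes"))),
    target = "y", positive = "yes")
  expect_equal(loocv_predictions(single), 0.5)

  pair <- discrete_dataset(data.frame(V = c("a", "a"), y = c("no", "yes")),
                           target = "y", positive = "yes")
  expect_equal(loocv_predictions(pair), c(0.75, 0.25))

  n <- 6
  allpos <- discrete_dataset(
    data.frame(V = rep("a", n),
               y = factor(rep("yes", n), levels = c("no", "yes"))),
    target = "y", positive = "yes")
  expect_equal(loocv_predictions(allpos), rep((0.5 + n - 1) / n, n))

  # brute-force oracle on a random subgroup
  set.seed(404)
  ds <- random_tiny_dataset()
  expect_equal(loocv_predictions(ds),
               oracle_loocv(ds$data, "y", c("no", "yes"), "yes"),
               tolerance = 1e-12)
})

test_that("the LOOCV AUC criterion pools both subsamples", {
  perfect <- discrete_dataset(
    data.frame(V = c("a", "a", "b", "b"),
               y = c("yes", "yes", "no", "no")),
    target = "y", positive = "yes")
  expect_equal(auc_criterion_score(perfect, "V", "a"), 1.0)

  # degenerate split: everyone matches, score = LOOCV AUC within D alone
  const <- discrete_dataset(
    data.frame(V = factor(rep("a", 4), levels = c("a", "b")),
               y = c("yes", "yes", "no", "no")),
    target = "y", positive = "yes")
  inside <- oracle_auc(oracle_loocv(const$data, "y", c("no", "yes"), "yes"),
                       const$data$y == "yes")
  expect_equal(auc_criterion_score(const, "V", "a"), inside)

  # O(n^2) oracle on random subgroups
  set.seed(405)
  for (rep in 1:10) {
    ds <- random_tiny_dataset(missing_rate = 0)
    if (length(unique(ds$data$y)) < 2) next
    v <- dataset_variables(ds)[1]
    val <- levels(ds$data[[v]])[1]
    parts <- split_by_feature(ds, v, val)
    preds <- labs <- NULL
    for (part in parts) {
      if (n_individuals(part) == 0) next
      preds <- c(preds, oracle_loocv(part$data, "y", c("no", "yes"), "yes"))
      labs <- c(labs, part$data$y == "yes")
    }
    want <- if (all(labs) || !any(labs)) 0.5 else oracle_auc(preds, labs)
    expect_equal(suppressMessages(auc_criterion_score(ds, v, val)), want,
                 tolerance = 1e-12)
  }
})
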