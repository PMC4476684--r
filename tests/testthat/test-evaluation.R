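balanced_ds <- function(n = 100, n_pos = 20, seed = 81) {
  local({
    set.seed(seed)
    df <- data.frame(
      V1 = sample(c("a", "b"), n, replace = TRUE),
      V2 = sample(c("x", "z"), n, replace = TRUE),
      y = c(rep("yes", n_pos), rep("no", n - n_pos))
    )
    discrete_dataset(df, target = "y", positive = "yes")
  })
}

test_that("stratified folds are exact under divisibility and deterministic", {
  ds <- balanced_ds(100, 20)
  f <- stratified_folds(ds, k = 20, seed = 3)
  expect_equal(as.vector(table(f)), rep(5L, 20))         # equal fold sizes
  pos_per_fold <- tapply(ds$data$y == "yes", f, sum)
  expect_true(all(pos_per_fold == 1))                    # exact stratification
  expect_equal(sort(unique(f)), 1:20)                    # folds cover the data

  expect_identical(f, stratified_folds(ds, k = 20, seed = 3))
  expect_false(identical(f, stratified_folds(ds, k = 20, seed = 4)))

  expect_error(stratified_folds(ds, k = 1), "at least 2")
  expect_error(stratified_folds(ds, k = 21), "class count")
})

test_that("cross-validation predicts everyone once and counts fits", {
  ds <- balanced_ds(60, 24, seed = 82)
  rec <- run_cross_validation(ds, methods = c("dp-bay", "tree"), k = 6,
                              seed = 2)
  expect_equal(nrow(rec), 60 * 2)
  for (m in c("dp-bay", "tree")) {
    ids <- rec$id[rec$method == m]
    expect_equal(sort(ids), 1:60)                         # exactly once each
  }
  fits <- attr(rec, "fit_counts")
  expect_equal(unname(fits["tree"]), 6L)                  # once per fold
  expect_equal(unname(fits["dp-bay"]), 60L)               # once per individual
  expect_true(all(rec$prob > 0 & rec$prob < 1))
  # deterministic given the seed
  rec2 <- run_cross_validation(ds, methods = c("dp-bay", "tree"), k = 6,
                               seed = 2)
  expect_equal(rec$prob, rec2$prob)
})

test_that("leave-one-out sized folds produce one record per row", {
  ds <- balanced_ds(10, 5, seed = 83)
  rec <- run_cross_validation(ds, methods = "dp-ig", k = 5, seed = 1)
  expect_equal(nrow(rec), 10)
})

test_that("Brier metrics match hand arithmetic and the reference scores zero", {
  b <- brier_metrics(c(0.8, 0.3), c(TRUE, FALSE))
  expect_equal(b$bs, 0.065)
  expect_equal(b$one_minus_bs, 0.935)
  expect_equal(b$bss, 0.74)

  expect_equal(brier_metrics(c(1, 1, 0), c(1, 1, 0))$bs, 0)
  out <- rbinom(50, 1, 0.3)
  ref <- brier_metrics(rep(mean(out), 50), out)
  expect_equal(ref$bss, 0)

  # textbook-formula oracle to 1e-10
  set.seed(804)
  p <- runif(30)
  o <- rbinom(30, 1, 0.4)
  b2 <- brier_metrics(p, o)
  expect_equal(b2$bs, sum((p - o)^2) / 30, tolerance = 1e-10)
  expect_equal(b2$bss, 1 - b2$bs / mean((mean(o) - o)^2), tolerance = 1e-10)
})

test_that("fold-wise AUC summaries behave", {
  rec <- data.frame(
    id = 1:40, method = "m", fold = rep(1:4, each = 10),
    prob = rep(c(0.9, 0.1), 20),
    outcome = rep(c(TRUE, FALSE), 20)
  )
  a <- auc_with_ci(rec)
  expect_equal(a$auc_mean, 1)
  expect_equal(a$ci, c(1, 1))
  expect_equal(a$auc_pooled, 1)

  set.seed(805)
  null_rec <- data.frame(
    id = 1:2000, method = "m", fold = rep(1:20, each = 100),
    prob = runif(2000), outcome = rbinom(2000, 1, 0.3) == 1
  )
  a2 <- auc_with_ci(null_rec)
  expect_gt(a2$auc_mean, 0.45)
  expect_lt(a2$auc_mean, 0.55)
  expect_true(a2$ci[1] <= a2$auc_mean && a2$auc_mean <= a2$ci[2])
})

test_that("paired t-test matches the textbook formula and edge conventions", {
  set.seed(806)
  for (rep in 1:10) {
    a <- runif(7)
    b <- a + rnorm(7, sd = 0.05)
    got <- paired_t_test(a, b)
    d <- a - b
    t_ref <- mean(d) / (sd(d) / sqrt(7))
    expect_equal(got$t, t_ref, tolerance = 1e-10)
    expect_equal(got$mean_diff, mean(d), tolerance = 1e-12)
    expect_equal(got$df, 6)
    expect_equal(got$p, 2 * pt(-abs(t_ref), df = 6), tolerance = 1e-10)
  }
  same <- suppressMessages(paired_t_test(rep(0.5, 7), rep(0.5, 7)))
  expect_equal(same$p, 1)
  expect_equal(same$mean_diff, 0)
  shifted <- suppressMessages(paired_t_test(rep(0.6, 7), rep(0.5, 7)))
  expect_equal(shifted$p, 0)
})

test_that("disagreement proportions count differing labels or paths", {
  rec <- data.frame(
    id = rep(1:4, 2),
    method = rep(c("dp-bay", "tree"), each = 4),
    fold = 1L,
    prob = c(0.9, 0.2, 0.8, 0.4, 0.9, 0.2, 0.3, 0.4),
    outcome = rep(c(TRUE, FALSE, TRUE, FALSE), 2)
  )
  rec$label <- rec$prob >= 0.5
  attr(rec, "paths") <- list(
    "dp-bay" = c("A=1", "B=2", "A=1 & B=2", "TRUE"),
    "tree" = c("A=1", "B=2", "B=2 & A=1...no", "TRUE")
  )
  expect_equal(disagreement_proportion(rec, "dp-bay", "tree"), 0.25)
  expect_equal(disagreement_proportion(rec, "dp-bay", "tree", mode = "path"),
               0.25)

  rec$label[rec$method == "tree"] <- !rec$label[rec$method == "dp-bay"]
  expect_equal(disagreement_proportion(rec, "dp-bay", "tree"), 1)
})

test_that("path disagreement uses canonical conjunct sets end to end", {
  ds <- balanced_ds(60, 24, seed = 88)
  rec <- run_cross_validation(ds, methods = c("dp-bay", "tree"), k = 4,
                              seed = 5)
  d <- disagreement_proportion(rec, "dp-bay", "tree", mode = "path")
  expect_gte(d, 0)
  expect_lte(d, 1)
})

test_that("per-fold discretization flows through cross-validation", {
  set.seed(807)
  n <- 240
  x <- rnorm(n, mean = ifelse(rbinom(n, 1, 0.5) == 1, 2, -2))
  df <- data.frame(xc = x,
                   noise = sample(c("a", "b"), n, TRUE),
                   y = ifelse(plogis(1.5 * x) > runif(n), "yes", "no"))
  ds <- discrete_dataset(df, target = "y", positive = "yes")
  rec <- suppressMessages(
    run_cross_validation(ds, methods = "dp-bay", k = 5, seed = 6))
  a <- suppressMessages(auc_with_ci(rec))
  expect_gt(a$auc_pooled, 0.7)  # the continuous signal survives binning
})
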