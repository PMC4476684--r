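test_that("growth stops immediately on a pure training set", {
  ds <- discrete_dataset(
    data.frame(V1 = c("a", "b", "a"),
               y = factor(rep("yes", 3), levels = c("no", "yes"))),
    target = "y", positive = "yes")
  tr <- grow_path(ds, c(V1 = "a"))
  expect_equal(nrow(tr), 0)
  m <- fit_decision_path(ds, c(V1 = "a"))
  expect_equal(nrow(m$path), 0)
})

test_that("a perfectly predictive variable is selected first", {
  set.seed(501)
  n <- 120
  sig <- sample(c("0", "1"), n, replace = TRUE)
  df <- data.frame(sig = sig)
  for (j in 1:5) df[[paste0("noise", j)]] <- sample(letters[1:3], n, replace = TRUE)
  df$y <- ifelse(sig == "1", "yes", "no")
  ds <- discrete_dataset(df, target = "y", positive = "yes")
  person <- stats::setNames(as.character(df[1, 1:6]), names(df)[1:6])
  for (crit in c("bay", "ig", "auc")) {
    tr <- grow_path(ds, person, criterion = crit)
    expect_equal(tr$variable[1], "sig")
  }
})

test_that("growth and pruning match the brute-force greedy oracle", {
  set.seed(502)
  n_checked <- 0
  for (rep in 1:30) {
    ds <- random_tiny_dataset()
    person <- random_person_for(ds)
    for (crit in c("bay", "ig", "auc")) {
      got <- grow_path(ds, person, criterion = crit)
      want <- oracle_grow(ds, person, crit)
      expect_equal(got$variable, want$vars,
                   info = paste("criterion", crit, "rep", rep))
      expect_equal(got$score, want$scores, tolerance = 1e-9)
      expect_equal(nrow(prune_path(got)), want$pruned_len)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 90)
})

test_that("pruning truncates at the maximal recorded score", {
  fake_trace <- function(scores) {
    df <- data.frame(step = integer(0), variable = character(0),
                     value = character(0), score = numeric(0),
                     stringsAsFactors = FALSE)
    for (i in seq_along(scores)) {
      df[i, ] <- list(i, paste0("V", i), "a", scores[i])
    }
    structure(df, criterion = "bay",
              class = c("growth_trace", "data.frame"))
  }
  expect_equal(nrow(prune_path(fake_trace(c(-5, -4, -3)))), 3)  # increasing
  expect_equal(nrow(prune_path(fake_trace(c(-5, -3, -4.2)))), 2)
  expect_equal(nrow(prune_path(fake_trace(c(-2, -7, -2)))), 1)  # tie: shortest
  expect_equal(nrow(prune_path(fake_trace(numeric(0)))), 0)
})

test_that("fitted paths are personalized and supported", {
  set.seed(503)
  for (rep in 1:15) {
    ds <- random_tiny_dataset()
    person <- random_person_for(ds)
    m <- fit_decision_path(ds, person, criterion = sample(c("bay", "ig", "auc"), 1))
    # every conjunct equals the person's observed value; variables distinct
    if (nrow(m$path) > 0) {
      expect_equal(unname(person[m$path$variable]), m$path$value)
      expect_false(anyDuplicated(m$path$variable) > 0)
      # the pruned step's recorded score is the trace maximum
      expect_equal(m$trace$score[nrow(m$path)], max(m$trace$score))
    }
    # support never empty on nonempty data; theta strictly inside (0,1)
    expect_gt(sum(m$support_counts) + (nrow(m$path) == 0), 0)
    expect_true(all(m$theta > 0 & m$theta < 1))
    expect_equal(sum(m$theta), 1)
    # support counts agree with filtering the training data by the path
    expect_equal(unname(m$support_counts),
                 unname(class_counts(filter_matching(ds, m$path))))
  }
})

test_that("matching subgroup size is non-increasing along the grown path", {
  set.seed(504)
  ds <- gen_path_process(n = 300, n_noise = 6, missing_rate = 0.1, seed = 77)
  person <- person_instance(ds$data[3, ], ds)
  tr <- grow_path(ds, person)
  sizes <- colSums(attr(tr, "step_counts"))
  expect_true(all(diff(c(sum(attr(tr, "root_counts")), sizes)) <= 0))
  expect_true(all(sizes >= 1))
})

test_that("an all-missing person yields the smoothed prevalence", {
  ds <- gen_path_process(n = 100, n_noise = 3, seed = 5)
  vars <- dataset_variables(ds)
  person <- stats::setNames(rep(NA_character_, length(vars)), vars)
  m <- fit_decision_path(ds, person)
  expect_equal(nrow(m$path), 0)
  expect_equal(unname(m$theta), unname(bdeu_theta(class_counts(ds))))
})

test_that("prediction reports theta for the positive value", {
  ds102 <- discrete_dataset(
    data.frame(V = rep("a", 102),
               y = c(rep("no", 40), rep("yes", 62))),
    target = "y", positive = "yes")
  ds102$data$V <- factor(ds102$data$V, levels = c("a", "b"))
  m <- fit_decision_path(ds102, c(V = "a"))
  expect_equal(predict(m), 62.5 / 103, tolerance = 1e-9)
  expect_true(predict(m) >= 0.5)  # classified positive at the 0.5 threshold
})

test_that("exported rules round-trip through a parser", {
  ds <- gen_path_process(n = 400, n_noise = 5, seed = 21)
  person <- person_instance(ds$data[10, ], ds)
  m <- fit_decision_path(ds, person)
  parsed <- parse_rule(export_rule(m))
  expect_equal(parsed$conjuncts, m$path)
  expect_equal(parsed$prob, unname(round(m$theta["yes"], 3)), tolerance = 5e-4)
  expect_equal(parsed$counts, unname(as.integer(m$support_counts)))

  empty <- fit_decision_path(
    ds, stats::setNames(rep(NA_character_, length(dataset_variables(ds))),
                        dataset_variables(ds)))
  expect_match(export_rule(empty), "^IF TRUE THEN ")
  expect_equal(nrow(parse_rule(export_rule(empty))$conjuncts), 0)
})
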