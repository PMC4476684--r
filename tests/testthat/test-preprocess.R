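test_that("the best cut maximizes gain over every midpoint", {
  expect_null(mdl_best_cut(c(1, 2, 3), c("a", "a", "a")))
  bc <- mdl_best_cut(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(bc$cut, 2.5)
  expect_equal(bc$gain, 1.0)

  # exhaustive-midpoint oracle on random fixtures
  set.seed(701)
  for (rep in 1:15) {
    v <- round(rnorm(30), 1)
    l <- sample(c("p", "q"), 30, replace = TRUE)
    bc <- mdl_best_cut(v, l)
    if (is.null(bc)) next
    sv <- sort(unique(v))
    mids <- (sv[-1] + sv[-length(sv)]) / 2
    gains <- vapply(mids, function(cut) {
      left <- table(factor(l[v <= cut], levels = c("p", "q")))
      all <- table(factor(l, levels = c("p", "q")))
      oracle_entropy(as.vector(all)) -
        sum(left) / 30 * oracle_entropy(as.vector(left)) -
        (30 - sum(left)) / 30 * oracle_entropy(as.vector(all - left))
    }, 0)
    expect_equal(bc$gain, max(gains), tolerance = 1e-12)
    expect_equal(bc$cut, mids[which.max(gains)])
  }
})

test_that("the MDL rule accepts informative cuts and rejects null ones", {
  expect_false(mdl_accepts(0, 10, 2, 1, 1, 1, 0, 0))
  # perfect split of (2,2): threshold (log2 3 + log2 7 - 2)/4 ~ 0.598 < 1
  expect_true(mdl_accepts(1, 4, 2, 1, 1, 1, 0, 0))
  expect_equal(log2(3) / 4 + (log2(7) - 2) / 4, 0.5981, tolerance = 1e-4)

  # formula oracle on random inputs
  set.seed(702)
  for (rep in 1:20) {
    g <- runif(1)
    n <- sample(4:50, 1)
    h <- runif(1)
    h1 <- runif(1, 0, h)
    h2 <- runif(1, 0, h)
    want <- g > log2(n - 1) / n +
      (log2(3^2 - 2) - (2 * h - 1 * h1 - 2 * h2)) / n
    expect_equal(mdl_accepts(g, n, 2, 1, 2, h, h1, h2), want)
  }
})

test_that("recursive discretization finds the class boundary and only it", {
  mix <- gen_continuous_mixture(n = 500, means = c(-3, 3), sd = 1, seed = 31)
  cuts <- discretize_mdl(mix$values, mix$labels)
  expect_equal(length(cuts), 1)
  expect_lt(abs(cuts), 0.3)

  null_mix <- gen_continuous_mixture(n = 200, means = c(0, 0), sd = 1, seed = 32)
  expect_equal(length(discretize_mdl(null_mix$values, null_mix$labels)), 0)
})

test_that("apply_cuts honors the half-open bin convention", {
  ds <- discrete_dataset(
    data.frame(x = c(-1, 0, 0.5, 2, NA),
               y = c("no", "no", "yes", "yes", "no")),
    target = "y")
  cut_set <- structure(list(x = c(0, 1)), class = "cut_point_set")
  out <- apply_cuts(ds, cut_set)
  lv <- as.character(out$data$x)
  expect_equal(lv[2], "(-Inf,0]")   # value exactly at the threshold: lower bin
  expect_equal(lv[3], "(0,1]")
  expect_equal(lv[4], "(1, Inf]")
  expect_true(is.na(lv[5]))         # missing stays missing

  # a variable with no accepted cuts becomes a flagged constant bin
  none <- apply_cuts(ds, structure(list(x = numeric(0)),
                                   class = "cut_point_set"))
  expect_equal(levels(none$data$x), "all")
  expect_equal(attr(none, "uninformative_vars"), "x")
})

test_that("learned cuts round-trip through the plain-text sidecar", {
  set.seed(703)
  df <- data.frame(a = rnorm(200), b = rnorm(200))
  df$y <- ifelse(df$a + rnorm(200, sd = 0.3) > 0, "yes", "no")
  ds <- discrete_dataset(df, target = "y")
  cuts <- learn_cuts(ds)
  path <- tempfile()
  write_cutpoints(cuts, path)
  back <- read_cutpoints(path)
  expect_equal(names(back), names(cuts))
  for (v in names(cuts)) expect_equal(back[[v]], cuts[[v]], tolerance = 1e-12)
})

test_that("chi-square ranking matches the direct formula", {
  df <- data.frame(
    indep = rep(c("a", "b"), 10),
    assoc = rep(c("a", "b"), each = 10),
    y = rep(c("no", "yes"), each = 10)
  )
  ds <- discrete_dataset(df, target = "y")
  r <- chi2_rank(ds)
  expect_equal(r$variable, c("assoc", "indep"))
  expect_equal(r$statistic, c(20, 0))  # perfect 2x2 association: X^2 = N

  # direct-formula oracle and invariances on a random fixture
  set.seed(704)
  df2 <- data.frame(v1 = sample(letters[1:3], 80, TRUE),
                    v2 = sample(letters[1:2], 80, TRUE),
                    y = sample(c("no", "yes"), 80, TRUE))
  ds2 <- discrete_dataset(df2, target = "y")
  r2 <- chi2_rank(ds2)
  for (i in seq_len(nrow(r2))) {
    tab <- table(df2[[r2$variable[i]]], df2$y)
    exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(r2$statistic[i], sum((tab - exp_tab)^2 / exp_tab),
                 tolerance = 1e-10)
  }
  # invariant to row order
  ds2b <- discrete_dataset(df2[sample(80), ], target = "y")
  expect_equal(chi2_rank(ds2b)$statistic, r2$statistic, tolerance = 1e-10)
  # top_n larger than the predictor count returns all, with a message
  expect_message(all_r <- chi2_rank(ds2, top_n = 99), "returning all")
  expect_equal(nrow(all_r), 2)
  expect_equal(nrow(chi2_rank(ds2, top_n = 1)), 1)
})
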