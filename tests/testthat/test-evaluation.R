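test_that("Welch t-test matches the textbook formula and conventions", {
  a <- c(1.1, 2.3, 1.9, 2.8)
  b <- c(3.0, 4.1, 3.7)
  res <- two_sided_t_test(a, b)
  # hand-computed Welch statistic
  se <- sqrt(var(a) / 4 + var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 4)^2 / 3 + (var(b) / 3)^2 / 2)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  same <- two_sided_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  sep <- two_sided_t_test(c(0, 0, 0, 0), c(10, 10, 10, 10) + rnorm(4, 0, 1e-4))
  expect_lt(sep$p, 1e-6)

  expect_error(two_sided_t_test(1, c(1, 2)), class = "tcf_spec_error")
})

test_that("MCC matches the closed form and its conventions", {
  expect_equal(mcc(5, 0, 5, 0), 1)
  expect_equal(mcc(5, 5, 0, 0), 0)   # all predicted positive
  expect_equal(mcc(3, 1, 4, 2), 10 / sqrt(600))
  # antisymmetry under label flip
  for (s in 1:20) {
    set.seed(s)
    c4 <- sample(0:10, 4, replace = TRUE)
    if (sum(c4) == 0) next
    expect_equal(mcc(c4[1], c4[2], c4[3], c4[4]),
                 -mcc(c4[4], c4[3], c4[2], c4[1]), tolerance = 1e-12)
  }
})

test_that("AUC-ROC follows the rank formula with half ties", {
  expect_equal(auc_roc(c(1, 2, 3, 4), c(0, 0, 1, 1), positive = 1), 1)
  expect_equal(auc_roc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1), positive = 1), 0.5)
  expect_equal(auc_roc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0), positive = 1), 0.75)
  expect_error(auc_roc(1:3, c(1, 1, 1), positive = 1), class = "tcf_class_error")
})

test_that("AUC-ROC is invariant under monotone score transforms", {
  set.seed(88)
  for (i in 1:10) {
    s <- rnorm(30); y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    a0 <- auc_roc(s, y, positive = 1)
    expect_equal(auc_roc(exp(s), y, positive = 1), a0, tolerance = 1e-12)
    expect_equal(auc_roc(rank(s), y, positive = 1), a0, tolerance = 1e-12)
  }
})

test_that("AUC-PR step integration matches hand computations", {
  expect_equal(auc_pr(c(4, 3, 2, 1), c(1, 1, 0, 0), positive = 1), 1)
  expect_equal(auc_pr(rep(1, 10), c(rep(1, 3), rep(0, 7)), positive = 1), 0.3)
  expect_equal(auc_pr(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0), positive = 1),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_error(auc_pr(1:3, c(0, 0, 0), positive = 1), class = "tcf_class_error")
})

test_that("sensitivity and specificity come straight from the counts", {
  expect_equal(unname(sens_spec(c(1, 1, 0, 0), c(1, 1, 0, 0), positive = 1)),
               c(1, 1))
  expect_equal(unname(sens_spec(rep(1, 4), c(1, 1, 0, 0), positive = 1)),
               c(1, 0))
  # tp=3 fn=2 tn=4 fp=1
  truth <- c(rep(1, 5), rep(0, 5))
  pred <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)
  expect_equal(unname(sens_spec(pred, truth, positive = 1)), c(0.6, 0.8))
})

test_that("bootstrap intervals are seeded, ordered and degenerate-safe", {
  set.seed(10)
  s <- c(rnorm(20, 0), rnorm(20, 3)); y <- rep(c(0, 1), each = 20)
  ci1 <- bootstrap_ci(function(sc, l) auc_roc(sc, l, positive = 1),
                      s, y, n_boot = 200, seed = 5)
  ci2 <- bootstrap_ci(function(sc, l) auc_roc(sc, l, positive = 1),
                      s, y, n_boot = 200, seed = 5)
  expect_identical(ci1, ci2)
  expect_lte(ci1[["lower"]], ci1[["upper"]])

  flat <- bootstrap_ci(function(sc, l) 0.7, s, y, n_boot = 100, seed = 1)
  expect_equal(unname(flat), c(0.7, 0.7))
  expect_error(bootstrap_ci(function(sc, l) 1, s, y, n_boot = 50),
               class = "tcf_spec_error")
})

test_that("bootstrap CI width shrinks with sample size", {
  width <- function(n, seed) {
    set.seed(seed)
    s <- c(rnorm(n, 0), rnorm(n, 1.5)); y <- rep(c(0, 1), each = n)
    ci <- bootstrap_ci(function(sc, l) auc_roc(sc, l, positive = 1),
                       s, y, n_boot = 300, seed = 2)
    ci[["upper"]] - ci[["lower"]]
  }
  expect_lt(width(200, 3), width(25, 3))
})

test_that("eval_report assembles a coherent report", {
  set.seed(12)
  s <- c(rnorm(25, 0), rnorm(25, 2)); y <- rep(c("neg", "pos"), each = 25)
  rep_ <- eval_report(s, y, n_boot = 200, seed = 9)
  expect_gte(rep_$auc_roc, 0.9)
  expect_true(rep_$auc_roc_ci[["lower"]] <= rep_$auc_roc)
  expect_true(rep_$auc_roc_ci[["upper"]] >= rep_$auc_roc)
  expect_true(rep_$mcc >= -1 && rep_$mcc <= 1)
  expect_true(rep_$sensitivity >= 0 && rep_$sensitivity <= 1)
  expect_identical(rep_$n_positive, 25L)
})

test_that("group comparison flags the separated metric only", {
  set.seed(13)
  f <- cbind(informative = c(rnorm(15, 0, 0.5), rnorm(15, 3, 0.5)),
             noise = rnorm(30))
  lab <- rep(c("a", "b"), each = 15)
  tab <- compare_groups(f, lab, positive = "b")
  expect_true(tab$significant[tab$metric == "informative"])
  expect_gt(tab$auc_roc[tab$metric == "informative"], 0.9)
  expect_false(tab$significant[tab$metric == "noise"])
})
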