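test_that("Shapiro-Wilk flags non-normal data and accepts normal data", {
  expect_error(shapiro_wilk(rep(2, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  set.seed(1)
  ln <- exp(rnorm(200, sd = 1.5))
  expect_lt(shapiro_wilk(ln)$p_value, 0.001)
  # normal samples rarely reject at the 0.001 level
  set.seed(2)
  hits <- sum(vapply(1:200, function(i) {
    shapiro_wilk(rnorm(50))$p_value > 0.001
  }, logical(1)))
  expect_gte(hits, 198)
})

test_that("Spearman rho matches the rank-then-Pearson oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman(x, x^3)$statistic, 1)
  expect_equal(spearman(x, -x)$statistic, -1)
  set.seed(3)
  for (i in 1:100) {
    a <- rnorm(25)
    b <- rnorm(25) + 0.5 * a
    oracle <- stats::cor(rank(a), rank(b))
    expect_equal(spearman(a, b)$statistic, oracle, tolerance = 1e-12)
  }
  expect_error(spearman(1:5, 1:4), "equal length")
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("Kruskal-Wallis H matches the hand rank-sum formula", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(res$statistic, 7.2, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pchisq(7.2, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # permuting the groups leaves H unchanged
  res2 <- kruskal_wallis(list(c(7, 8, 9), c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res2$statistic, res$statistic)
  # two identically-distributed groups: H near 0, p near 1
  same <- kruskal_wallis(list(c(1, 3, 5, 7), c(1, 3, 5, 7)))
  expect_lt(same$statistic, 1e-8)
  expect_gt(same$p_value, 0.99)
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("pairwise Mann-Whitney U applies the Bonferroni rule", {
  res <- pairwise_mwu_bonferroni(list(a = c(1, 2), b = c(3, 4)))
  expect_equal(res$`a|b`$statistic, 0)  # no a exceeds any b
  expect_equal(res$`a|b`$p_value, min(1, res$`a|b`$p_raw * 1))
  set.seed(4)
  three <- list(`0` = rnorm(8), `1` = rnorm(8) + 1, `2` = rnorm(8) + 3)
  res3 <- pairwise_mwu_bonferroni(three)
  expect_length(res3, 3)
  for (r in res3) {
    expect_equal(r$p_value, min(1, r$p_raw * 3), tolerance = 1e-12)
    expect_lte(r$p_value, 1)
  }
  # the cap engages when 3 * p exceeds 1
  flat <- pairwise_mwu_bonferroni(list(a = c(1, 4, 2), b = c(2.5, 1.5, 3),
                                       c = c(3.2, 0.5, 2.2)))
  expect_true(any(vapply(flat, function(r) r$p_value == 1, logical(1))))
  expect_error(pairwise_mwu_bonferroni(list(a = 1:3, b = numeric(0))),
               "empty cluster")
})

test_that("ROC handles separation, ties, and the U-statistic identity", {
  perfect <- roc_auc(c(90, 100, 40, 50), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1.0)
  tied <- roc_auc(rep(5, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(tied$auc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
  set.seed(5)
  for (i in 1:200) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    scores <- c(rnorm(n1, 0.8), rnorm(n0))
    if (runif(1) < 0.3) scores <- round(scores)  # force ties
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    roc <- roc_auc(scores, lab)
    u <- suppressWarnings(stats::wilcox.test(scores[lab], scores[!lab],
                                             exact = FALSE))$statistic
    expect_equal(roc$auc, unname(u) / (n1 * n0), tolerance = 1e-10)
    expect_true(all(diff(roc$tpr) >= -1e-12))
    expect_true(all(diff(roc$fpr) >= -1e-12))
    flipped <- roc_auc(scores, !lab)
    expect_equal(flipped$auc, 1 - roc$auc, tolerance = 1e-10)
  }
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  scores <- c(rnorm(20, 1), rnorm(25))
  lab <- rep(c(1, 0), c(20, 25))
  ours <- roc_auc(scores, lab == 1)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(lab, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("Youden cutoff maximizes J and sits between the classes", {
  scores <- c(90, 100, 40, 50)
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  rep <- youden_cutoff(roc_auc(scores, lab), scores, lab)
  expect_equal(rep$youden_j, 1)
  expect_equal(rep$cutoff, 70)  # midpoint convention
  expect_equal(rep$sensitivity + rep$specificity - 1, rep$youden_j)
  flat <- youden_cutoff(roc_auc(rep(5, 4), c(TRUE, FALSE, TRUE, FALSE)),
                        rep(5, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(flat$youden_j, 0)
  expect_equal(flat$cutoff, 5)  # within the observed score range
})

test_that("Youden search equals an exhaustive midpoint scan", {
  set.seed(7)
  for (i in 1:100) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    scores <- round(c(rnorm(n1, 1), rnorm(n0)), sample(0:2, 1))
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    if (length(unique(scores[lab])) == 0 ||
        length(unique(scores)) < 2) next
    res <- youden_cutoff(roc_auc(scores, lab), scores, lab)
    u <- sort(unique(scores))
    cand <- c(min(u), (head(u, -1) + tail(u, -1)) / 2)
    j_oracle <- -Inf; t_oracle <- NA
    for (t in cand) {
      j <- mean(scores[lab] >= t) + mean(scores[!lab] < t) - 1
      if (j > j_oracle + 1e-12) { j_oracle <- j; t_oracle <- t }
    }
    expect_equal(res$youden_j, j_oracle, tolerance = 1e-12)
    expect_equal(res$cutoff, t_oracle, tolerance = 1e-12)
    expect_gte(res$cutoff, min(scores))
    expect_lte(res$cutoff, max(scores))
  }
})

test_that("monotone transforms leave AUC and Youden quantities unchanged", {
  set.seed(8)
  scores <- c(rexp(12, 1 / 50) + 20, rexp(10, 1 / 90) + 30)
  lab <- rep(c(FALSE, TRUE), c(12, 10))
  f <- function(s) s^3  # strictly increasing on positive volumes
  a <- roc_auc(scores, lab); b <- roc_auc(f(scores), lab)
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  ya <- youden_cutoff(a, scores, lab)
  yb <- youden_cutoff(b, f(scores), lab)
  expect_equal(ya$youden_j, yb$youden_j, tolerance = 1e-12)
  expect_equal(ya$sensitivity, yb$sensitivity)
  expect_equal(ya$specificity, yb$specificity)
  # the transformed cutoff brackets the same pair of observations
  below <- max(scores[scores < ya$cutoff]); above <- min(scores[scores >= ya$cutoff])
  expect_gte(yb$cutoff, f(below))
  expect_lte(yb$cutoff, f(above))
})
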