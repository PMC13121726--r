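test_result <- function(statistic, p_value, n, method) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 n = n, method = method),
            class = "couchshift_test")
}

#' @export
print.couchshift_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value,
              paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Used on the measured rectal volumes and on each couch-shift component to
#' justify nonparametric downstream tests.
#'
#' @param sample Numeric vector, 3 <= n <= 5000, non-constant.
#' @return A `couchshift_test` with the W statistic.
#' @export
shapiro_wilk <- function(sample) {
  sample <- sample[is.finite(sample)]
  n <- length(sample)
  if (n < 3 || n > 5000)
    stop_input("Shapiro-Wilk requires 3 <= n <= 5000, got %d", n)
  if (stats::sd(sample) < 1e-12)
    stop_input("Shapiro-Wilk is undefined for a constant sample")
  ht <- stats::shapiro.test(sample)
  test_result(ht$statistic, ht$p.value, n, "Shapiro-Wilk")
}

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of mid-ranks (ties averaged); the p-value
#' uses the large-sample approximation (two-sided), appropriate for tied
#' session-level features.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, non-constant.
#' @return A `couchshift_test` with rho as the statistic.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y))
    stop_input("x and y must have equal length (%d vs %d)",
               length(x), length(y))
  if (length(x) < 3) stop_input("Spearman requires n >= 3")
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stop_input("Spearman is undefined for a constant vector")
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  test_result(ht$estimate, ht$p.value, length(x), "Spearman rank correlation")
}

#' Kruskal-Wallis rank-sum test
#'
#' Omnibus test that the group distributions are identical; H uses the tie
#' correction and is referred to a chi-square with k-1 df.
#'
#' @param groups List of numeric samples (>= 2 groups, each non-empty).
#' @return A `couchshift_test` with the H statistic.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop_input("kruskal_wallis needs a list of >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 1)) stop_input("every group must be non-empty")
  if (sum(sizes) < 3) stop_input("total sample size must be >= 3")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  ht <- stats::kruskal.test(values, g)
  test_result(ht$statistic, ht$p.value, as.integer(sizes), "Kruskal-Wallis")
}

mwu_one <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) < 20 && length(y) < 20
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  test_result(ht$statistic, ht$p.value, c(length(x), length(y)),
              "Mann-Whitney U")
}

#' Pairwise Mann-Whitney U tests with Bonferroni correction
#'
#' Two-sided U test for every unordered pair of clusters; the adjusted
#' p-value is `min(1, p * m)` with `m` the number of pairs (m = 3 for three
#' clusters). The U statistic counts (x, y) pairs with x > y (+ 1/2 per
#' tie), so AUC = U / (n1 * n2). Exact enumeration is used for small
#' untied samples, otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param values_by_cluster Named list mapping cluster to its sample of
#'   baseline volumes.
#' @return Named list (`"a|b"`) of `couchshift_test` results, each carrying
#'   `p_raw` and Bonferroni-adjusted `p_value`.
#' @export
pairwise_mwu_bonferroni <- function(values_by_cluster) {
  if (!is.list(values_by_cluster) || length(values_by_cluster) < 2)
    stop_input("need >= 2 clusters")
  if (any(lengths(values_by_cluster) < 1))
    stop_input("empty cluster sample: %s",
               paste(names(values_by_cluster)[lengths(values_by_cluster) < 1],
                     collapse = ", "))
  nm <- names(values_by_cluster)
  if (is.null(nm)) nm <- as.character(seq_along(values_by_cluster) - 1L)
  pairs <- utils::combn(seq_along(values_by_cluster), 2, simplify = FALSE)
  m <- length(pairs)
  out <- lapply(pairs, function(pr) {
    res <- mwu_one(values_by_cluster[[pr[1]]], values_by_cluster[[pr[2]]])
    res$p_raw <- res$p_value
    res$p_value <- min(1, res$p_raw * m)
    res$method <- sprintf("Mann-Whitney U (Bonferroni m = %d)", m)
    res
  })
  names(out) <- vapply(pairs, function(pr) paste(nm[pr], collapse = "|"),
                       character(1))
  out
}

#' ROC curve for a continuous score against a binary state
#'
#' Sweeps the classification rule `score >= threshold => positive` over the
#' unique observed scores (plus sentinels yielding the (0,0) and (1,1)
#' corners) and integrates the curve by the trapezoidal rule, which under
#' ties equals the rank (Mann-Whitney) formulation of the AUC.
#'
#' @param scores Numeric vector (e.g. baseline rectal volume, cm3).
#' @param is_positive Logical vector; `TRUE` for the positive class
#'   (canonical high-volume cluster).
#' @return A `couchshift_roc` list: `thresholds` (descending), `tpr`, `fpr`
#'   (non-decreasing along the sweep), `auc`.
#' @export
roc_auc <- function(scores, is_positive) {
  if (length(scores) != length(is_positive))
    stop_input("scores and is_positive must have equal length")
  is_positive <- as.logical(is_positive)
  if (any(is.na(scores)) || any(is.na(is_positive)))
    stop_input("scores and labels must be non-missing")
  n_pos <- sum(is_positive); n_neg <- sum(!is_positive)
  if (n_pos == 0 || n_neg == 0)
    stop_input("both classes must be present (got %d positive, %d negative)",
               n_pos, n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[is_positive] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!is_positive] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "couchshift_roc")
}

#' Optimal cutoff by Youden's index
#'
#' Maximizes J(t) = sensitivity(t) + specificity(t) - 1 under the rule
#' `score >= t => positive`. Candidate thresholds are the midpoints of
#' consecutive sorted unique scores plus the minimum score (the
#' all-positive rule), so the reported cutoff always lies within the
#' observed score range; when several thresholds attain the maximal J the
#' smallest is reported.
#'
#' @param roc A `couchshift_roc` from [roc_auc()] on the same data (its AUC
#'   is echoed into the report).
#' @param scores,is_positive As in [roc_auc()].
#' @return A `couchshift_cutoff` list: `cutoff`, `youden_j`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
youden_cutoff <- function(roc, scores, is_positive) {
  is_positive <- as.logical(is_positive)
  n_pos <- sum(is_positive); n_neg <- sum(!is_positive)
  if (n_pos == 0 || n_neg == 0)
    stop_input("both classes must be present")
  u <- sort(unique(scores))
  candidates <- if (length(u) == 1) u else
    c(min(u), (utils::head(u, -1) + utils::tail(u, -1)) / 2)
  sens <- vapply(candidates, function(t) mean(scores[is_positive] >= t),
                 numeric(1))
  spec <- vapply(candidates, function(t) mean(scores[!is_positive] < t),
                 numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]  # ties -> smallest threshold
  structure(list(cutoff = candidates[best], youden_j = j[best],
                 sensitivity = sens[best], specificity = spec[best],
                 auc = roc$auc),
            class = "couchshift_cutoff")
}

#' @export
print.couchshift_cutoff <- function(x, ...) {
  cat(sprintf(
    "Youden cutoff: %.4g cm3 (J = %.3f, sens = %.3f, spec = %.3f, AUC = %.3f)\n",
    x$cutoff, x$youden_j, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}
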