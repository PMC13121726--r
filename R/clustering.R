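#' K-means clustering of patient embeddings
#'
#' Lloyd's algorithm with 10 random restarts (best inertia kept),
#' deterministic under the given seed. Three clusters reproduce the
#' patient-stratification stage; `k` is exposed for reuse.
#'
#' @param embeddings A `couchshift_embeddings` from [encode()], or a plain
#'   numeric matrix (rows = patients).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param nstart Number of restarts.
#' @return A `couchshift_clusters` list: `labels` (0-based integer per
#'   patient, named by patient id), `centroids` (`k x d` matrix), `inertia`
#'   (total within-cluster sum of squares), `k`, `seed`, `patient_order`.
#' @export
kmeans_embeddings <- function(embeddings, k = 3L, seed = 1L, nstart = 10L) {
  x <- if (inherits(embeddings, "couchshift_embeddings"))
    embeddings$vectors else as.matrix(embeddings)
  if (nrow(x) < k)
    stop_input("need at least k = %d points, got %d", k, nrow(x))
  n_distinct <- nrow(unique(x))
  if (n_distinct < k)
    stop_input("k = %d exceeds the %d distinct points", k, n_distinct)
  fit <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      centers <- x[sample.int(nrow(x), k), , drop = FALSE]
      if (nrow(unique(centers)) < k) next
      cand <- tryCatch(
        stats::kmeans(x, centers = centers, iter.max = 100L,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(cand) &&
          (is.null(best) || cand$tot.withinss < best$tot.withinss))
        best <- cand
    }
    if (is.null(best))
      stop_input("k-means failed for every restart (degenerate input?)")
    best
  })
  labels <- as.integer(fit$cluster) - 1L
  names(labels) <- rownames(x)
  structure(list(labels = labels, centroids = fit$centers,
                 inertia = fit$tot.withinss, k = as.integer(k),
                 seed = as.integer(seed),
                 patient_order = rownames(x)),
            class = "couchshift_clusters")
}

#' Canonicalize cluster labels by baseline rectal volume
#'
#' Renumbers clusters so the per-cluster median planning-CT rectal volume is
#' ascending: canonical cluster 2 is always the high-baseline-volume group
#' that the downstream ROC cutoff separates from clusters 0 and 1. Ties in
#' medians break toward the lower original index. Pure relabeling: group
#' compositions are unchanged.
#'
#' @param clusters A `couchshift_clusters` from [kmeans_embeddings()].
#' @param cohort A list of patient series from [split_cohort()] covering
#'   every clustered patient.
#' @return A `couchshift_canonical` list: `labels` (0-based canonical index
#'   per patient, named), `mapping` (canonical label per original label),
#'   `ordering_key` (per-canonical-cluster median baseline volume,
#'   ascending), `patient_order`.
#' @export
canonicalize_clusters <- function(clusters, cohort) {
  baseline <- vapply(cohort, function(s) s$planning$rectum_volume_cm3,
                     numeric(1))
  names(baseline) <- vapply(cohort, function(s) s$patient_id, character(1))
  ids <- clusters$patient_order
  if (!all(ids %in% names(baseline)))
    stop_input("cohort is missing patient(s): %s",
               paste(setdiff(ids, names(baseline)), collapse = ", "))
  baseline <- baseline[ids]
  raw <- clusters$labels
  meds <- vapply(0:(clusters$k - 1L),
                 function(c) stats::median(baseline[raw == c]), numeric(1))
  ord <- order(meds, seq_along(meds))  # stable: ties -> lower original index
  mapping <- integer(clusters$k)
  mapping[ord] <- 0:(clusters$k - 1L)
  labels <- mapping[raw + 1L]
  names(labels) <- ids
  structure(list(labels = labels,
                 mapping = stats::setNames(mapping, 0:(clusters$k - 1L)),
                 ordering_key = meds[ord],
                 patient_order = ids),
            class = "couchshift_canonical")
}

#' Two-dimensional t-SNE projection of patient embeddings
#'
#' Exact (dense) t-distributed stochastic neighbor embedding for
#' visualization of the patient embedding space: Gaussian input affinities
#' calibrated per point to the target perplexity by bisection, symmetrized,
#' then a Student-t low-dimensional map fitted by gradient descent with
#' momentum and early exaggeration. Cohort sizes here are tens of patients,
#' so the dense formulation is appropriate. Visualization only — no
#' geometric guarantee is asserted or tested beyond shape, finiteness and
#' determinism.
#'
#' @param embeddings A `couchshift_embeddings` or numeric matrix.
#' @param seed Integer seed.
#' @param perplexity Target perplexity; must be `< n` patients.
#' @param n_iter Gradient-descent iterations.
#' @return `n x 2` matrix of map coordinates (rownames = patient ids).
#' @export
tsne_project <- function(embeddings, seed = 1L, perplexity = NULL,
                         n_iter = 1000L) {
  x <- if (inherits(embeddings, "couchshift_embeddings"))
    embeddings$vectors else as.matrix(embeddings)
  n <- nrow(x)
  if (is.null(perplexity)) perplexity <- min(30, floor((n - 1) / 3))
  if (perplexity >= n)
    stop_input("perplexity (%s) must be < number of patients (%d)",
               format(perplexity), n)
  if (perplexity < 1) stop_input("perplexity must be >= 1")
  D2 <- as.matrix(stats::dist(x))^2
  P <- matrix(0, n, n)
  target_entropy <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (iter in 1:64) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { hi <- beta; beta <- (lo + hi) / 2; next }
      p <- w / sw
      entropy <- -sum(ifelse(p > 0, p * log(p), 0))
      if (abs(entropy - target_entropy) < 1e-5) break
      if (entropy > target_entropy) lo <- beta else hi <- beta
      beta <- if (is.finite(hi) && hi < 1e19) (lo + hi) / 2 else beta * 2
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    gains <- matrix(1, n, 2)
    inc <- matrix(0, n, 2)
    for (iter in seq_len(n_iter)) {
      exaggeration <- if (iter <= 250) 12 else 1
      momentum <- if (iter <= 250) 0.5 else 0.8
      d2y <- as.matrix(stats::dist(Y))^2
      Wq <- 1 / (1 + d2y)
      diag(Wq) <- 0
      Q <- pmax(Wq / sum(Wq), 1e-12)
      M <- (exaggeration * P - Q) * Wq
      grad <- 4 * (diag(rowSums(M)) - M) %*% Y
      gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
      gains <- pmax(gains, 0.01)
      inc <- momentum * inc - 200 * gains * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    rownames(Y) <- rownames(x)
    colnames(Y) <- c("tsne1", "tsne2")
    Y
  })
}
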