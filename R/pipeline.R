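#' Write a cohort session table to CSV
#'
#' Comma-separated, UTF-8, period decimal; volumes in cm3, shifts in cm.
#' Planning rows (`session_index = 0`) carry empty shift fields.
#'
#' @param cohort Long-format session data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a cohort session table
#'
#' Expects the header `patient_id,session_index,rectum_volume_cm3,vrt_cm,
#' lng_cm,lat_cm`. Planning rows have `session_index = 0` and empty shift
#' fields; every CBCT row must carry all three shifts. Violations are
#' reported with the offending patient.
#'
#' @param path CSV path.
#' @return Long-format session data.frame (rows ordered by patient then
#'   session index).
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_input("cohort file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "session_index", "rectum_volume_cm3",
           "vrt_cm", "lng_cm", "lat_cm")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop_input("cohort CSV is missing column(s): %s",
               paste(missing_cols, collapse = ", "))
  for (col in c("session_index", "rectum_volume_cm3", "vrt_cm", "lng_cm",
                "lat_cm")) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(v <- as.numeric(df[[col]]))
      bad <- which(!is.na(df[[col]]) & df[[col]] != "" & is.na(v))
      if (length(bad) > 0)
        stop_input("unparsable %s for patient %s (row %d)", col,
                   df$patient_id[bad[1]], bad[1])
      df[[col]] <- v
    }
  }
  plan_rows <- df$session_index == 0
  if (any(plan_rows & (!is.na(df$vrt_cm) | !is.na(df$lng_cm) |
                       !is.na(df$lat_cm))))
    stop_input("planning rows must have empty shift fields (patient %s)",
               df$patient_id[which(plan_rows & !is.na(df$vrt_cm))[1]])
  # full per-patient validation (planning row presence, duplicates,
  # positive volumes, shifts on CBCT rows)
  split_cohort(df)
  df <- df[order(df$patient_id, df$session_index), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Configure a full pipeline run
#'
#' @param input `"simulate"` or a path to a cohort CSV (exactly one data
#'   source).
#' @param simulation A [simulation_config()]; used only when
#'   `input = "simulate"`.
#' @param encoder An [encoder_config()].
#' @param k_clusters Number of clusters.
#' @param output_dir Directory for the run artifacts, or `NULL` to skip
#'   writing files.
#' @param seed Global seed fanned out to every stochastic stage.
#' @param figures Write diagnostic figures (t-SNE scatter, cluster box plot,
#'   ROC curve)?
#' @return A `couchshift_run_config` list.
#' @export
run_config <- function(input = "simulate",
                       simulation = default_cohort_config(),
                       encoder = encoder_config(),
                       k_clusters = 3L,
                       output_dir = NULL,
                       seed = 1L,
                       figures = FALSE) {
  if (!is.character(input) || length(input) != 1)
    stop_input("input must be 'simulate' or a CSV path")
  structure(list(input = input, simulation = simulation, encoder = encoder,
                 k_clusters = as.integer(k_clusters),
                 output_dir = output_dir, seed = as.integer(seed),
                 figures = isTRUE(figures)),
            class = "couchshift_run_config")
}

cohort_summary <- function(cohort) {
  cbct <- cohort[cohort$session_index > 0, ]
  list(
    n_patients = length(unique(cohort$patient_id)),
    n_cbct_sessions = nrow(cbct),
    mean_rv_cm3 = mean(cbct$rectum_volume_cm3),
    median_rv_cm3 = stats::median(cbct$rectum_volume_cm3),
    mean_shift_cm = c(vrt = mean(cbct$vrt_cm), lng = mean(cbct$lng_cm),
                      lat = mean(cbct$lat_cm))
  )
}

#' Run the full two-stage analysis
#'
#' simulate (or read) -> per-session features -> cross-validated autoencoder
#' training -> patient embeddings -> K-means -> canonical relabeling by
#' baseline volume -> statistical chain (Shapiro-Wilk on volumes and each
#' shift component, Spearman of volume change vs displacement magnitude,
#' Kruskal-Wallis of baseline volume across clusters, pairwise
#' Bonferroni-corrected Mann-Whitney U, ROC and Youden cutoff with the
#' high-volume canonical cluster as the positive class). One global seed
#' controls every stochastic stage.
#'
#' @param config A [run_config()].
#' @return A `couchshift_report` list with `config_echo`, `cohort_summary`,
#'   `cv_report`, `cluster_sizes`, `tests`, `cutoff_report`, `embeddings`,
#'   `clusters`, `canonical`, `truth` (when simulated), `timestamp`,
#'   `versions`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "couchshift_run_config"))
    stop_input("config must come from run_config()")
  stage <- "input"
  result <- tryCatch({
    truth <- NULL
    if (identical(config$input, "simulate")) {
      sim_cfg <- config$simulation
      sim_cfg$seed <- derive_seed(config$seed, "simulate-stage")
      sim <- simulate_cohort(sim_cfg)
      cohort_df <- sim$cohort
      truth <- sim$truth
    } else {
      cohort_df <- read_cohort_csv(config$input)
    }
    series <- split_cohort(cohort_df)

    stage <- "features"
    features <- build_feature_tensor(series)

    stage <- "encoder"
    enc_cfg <- config$encoder
    enc_cfg$seed <- derive_seed(config$seed, "encoder-stage")
    encoder <- train_encoder(features, enc_cfg)
    embeddings <- embed_cohort(encoder, series)

    stage <- "clustering"
    clusters <- kmeans_embeddings(embeddings, k = config$k_clusters,
                                  seed = derive_seed(config$seed, "kmeans"))
    canonical <- canonicalize_clusters(clusters, series)

    stage <- "stats"
    cbct <- cohort_df[cohort_df$session_index > 0, ]
    planning_vol <- vapply(series, function(s) s$planning$rectum_volume_cm3,
                           numeric(1))
    planning_vol <- planning_vol[canonical$patient_order]
    sess_feats <- do.call(rbind, lapply(series, series_features))
    drv <- sess_feats[, "delta_rectum_volume"]
    mag <- sess_feats[, "displacement_magnitude"]
    tests <- list(
      shapiro = list(
        rectum_volume = shapiro_wilk(cbct$rectum_volume_cm3),
        vrt = shapiro_wilk(cbct$vrt_cm),
        lng = shapiro_wilk(cbct$lng_cm),
        lat = shapiro_wilk(cbct$lat_cm)
      ),
      spearman_drv_vs_magnitude = spearman(drv, mag)
    )
    by_cluster <- split(planning_vol, canonical$labels)
    tests$kruskal_baseline_by_cluster <- kruskal_wallis(by_cluster)
    tests$pairwise_mwu <- pairwise_mwu_bonferroni(by_cluster)
    is_positive <- canonical$labels == config$k_clusters - 1L
    roc <- roc_auc(planning_vol, is_positive)
    cut <- youden_cutoff(roc, planning_vol, is_positive)
    cutoff_report <- list(
      cutoff = cut$cutoff, youden_j = cut$youden_j,
      sensitivity = cut$sensitivity, specificity = cut$specificity,
      auc = roc$auc,
      omnibus_p = tests$kruskal_baseline_by_cluster$p_value,
      pairwise_p = vapply(tests$pairwise_mwu, function(t) t$p_value,
                          numeric(1))
    )

    report <- structure(list(
      config_echo = config,
      cohort_summary = cohort_summary(cohort_df),
      cv_report = encoder$cv_report,
      selected_fold = encoder$selected_fold,
      cluster_sizes = as.integer(table(factor(canonical$labels,
                                              levels = 0:(config$k_clusters - 1L)))),
      tests = tests,
      roc = roc,
      cutoff_report = cutoff_report,
      embeddings = embeddings,
      clusters = clusters,
      canonical = canonical,
      truth = truth,
      cohort = cohort_df,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      versions = list(package = as.character(utils::packageVersion("couchshift")),
                      r = R.version.string)
    ), class = "couchshift_report")

    stage <- "output"
    if (!is.null(config$output_dir))
      write_run_outputs(report, config$output_dir)
    report
  }, error = function(e) {
    stop_input("pipeline failed at stage '%s': %s", stage,
               conditionMessage(e))
  })
  result
}

report_json_payload <- function(report) {
  strip_test <- function(t) list(statistic = t$statistic,
                                 p_value = t$p_value, n = t$n,
                                 method = t$method)
  list(
    cohort_summary = report$cohort_summary,
    cv_report = report$cv_report,
    selected_fold = report$selected_fold,
    cluster_sizes = report$cluster_sizes,
    shapiro = lapply(report$tests$shapiro, strip_test),
    spearman_drv_vs_magnitude = strip_test(report$tests$spearman_drv_vs_magnitude),
    kruskal_baseline_by_cluster = strip_test(report$tests$kruskal_baseline_by_cluster),
    pairwise_mwu = lapply(report$tests$pairwise_mwu, strip_test),
    roc = list(thresholds = report$roc$thresholds, tpr = report$roc$tpr,
               fpr = report$roc$fpr, auc = report$roc$auc),
    cutoff_report = report$cutoff_report,
    seed = report$config_echo$seed,
    versions = report$versions
  )
}

write_run_outputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (identical(report$config_echo$input, "simulate")) {
    write_cohort_csv(report$cohort, file.path(dir, "cohort.csv"))
    write_ground_truth(report$truth, file.path(dir, "ground_truth.csv"))
  }
  emb <- data.frame(patient_id = report$embeddings$patient_order,
                    report$embeddings$vectors, check.names = FALSE)
  names(emb)[-1] <- paste0("e", seq_len(ncol(emb) - 1) - 1)
  utils::write.csv(emb, file.path(dir, "embeddings.csv"), row.names = FALSE)
  cl <- data.frame(patient_id = report$clusters$patient_order,
                   raw_label = unname(report$clusters$labels),
                   canonical_label = unname(report$canonical$labels))
  utils::write.csv(cl, file.path(dir, "clusters.csv"), row.names = FALSE)
  payload <- report_json_payload(report)
  payload$timestamp <- report$timestamp
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (isTRUE(report$config_echo$figures)) {
    coords <- tsne_project(report$embeddings,
                           seed = derive_seed(report$config_echo$seed,
                                              "tsne"))
    utils::write.csv(
      data.frame(patient_id = rownames(coords), coords,
                 cluster = unname(report$canonical$labels)),
      file.path(dir, "tsne.csv"), row.names = FALSE)
    ggplot2::ggsave(file.path(dir, "tsne.png"),
                    plot_tsne(coords, report$canonical$labels),
                    width = 5, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(dir, "cluster_volumes.png"),
                    plot_cluster_volumes(report),
                    width = 5, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(dir, "roc.png"), plot_roc(report$roc),
                    width = 4.5, height = 4.5, dpi = 150)
  }
  invisible(dir)
}

#' t-SNE scatter of patient embeddings colored by cluster
#' @param coords `n x 2` matrix from [tsne_project()].
#' @param labels Canonical cluster labels aligned with `coords` rows.
#' @return A ggplot object.
#' @export
plot_tsne <- function(coords, labels) {
  df <- data.frame(tsne1 = coords[, 1], tsne2 = coords[, 2],
                   cluster = factor(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tsne1, y = .data$tsne2,
                                   color = .data$cluster)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", color = "Cluster") +
    ggplot2::theme_minimal()
}

#' Box plot of baseline rectal volume by canonical cluster
#' @param report A `couchshift_report`.
#' @return A ggplot object.
#' @export
plot_cluster_volumes <- function(report) {
  series <- split_cohort(report$cohort)
  vols <- vapply(series, function(s) s$planning$rectum_volume_cm3,
                 numeric(1))
  names(vols) <- vapply(series, function(s) s$patient_id, character(1))
  df <- data.frame(cluster = factor(report$canonical$labels),
                   volume = vols[report$canonical$patient_order])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$volume,
                                   fill = .data$cluster)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = "Canonical cluster",
                  y = "Baseline rectal volume (cm3)") +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#' @param roc A `couchshift_roc`.
#' @return A ggplot object.
#' @export
plot_roc <- function(roc) {
  df <- data.frame(fpr = roc$fpr, tpr = roc$tpr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::annotate("text", x = 0.7, y = 0.1,
                      label = sprintf("AUC = %.3f", roc$auc)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}

#' @export
print.couchshift_report <- function(x, ...) {
  cs <- x$cohort_summary
  cat(sprintf("couchshift run: %d patients, %d CBCT sessions\n",
              cs$n_patients, cs$n_cbct_sessions))
  cat(sprintf("  rectal volume mean/median: %.2f / %.2f cm3\n",
              cs$mean_rv_cm3, cs$median_rv_cm3))
  cat(sprintf("  CV reconstruction MSE (selected fold %d): %.4f\n",
              x$selected_fold, min(x$cv_report$val_mse)))
  cat(sprintf("  cluster sizes: %s\n",
              paste(x$cluster_sizes, collapse = ", ")))
  cat(sprintf("  Kruskal-Wallis p = %.3g\n", x$cutoff_report$omnibus_p))
  cat(sprintf("  ROC AUC = %.3f; Youden cutoff = %.2f cm3 (J = %.3f)\n",
              x$cutoff_report$auc, x$cutoff_report$cutoff,
              x$cutoff_report$youden_j))
  invisible(x)
}
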