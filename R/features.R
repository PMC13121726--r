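FEATURE_NAMES <- c("delta_rectum_volume", "displacement_magnitude",
                   "rectum_volume")

#' Rectal volume change relative to planning CT
#'
#' `delta_rv = volume_cbct - volume_planning` (signed, cm3): positive when
#' the rectum is fuller at treatment than at simulation.
#'
#' @param planning_volume Planning-CT rectal volume, cm3 (> 0).
#' @param cbct_volume CBCT rectal volume, cm3 (> 0). Both arguments recycle.
#' @return Signed volume change, cm3.
#' @export
delta_rv <- function(planning_volume, cbct_volume) {
  if (any(!is.finite(planning_volume)) || any(planning_volume <= 0))
    stop_input("planning_volume must be finite and > 0 cm3")
  if (any(!is.finite(cbct_volume)) || any(cbct_volume <= 0))
    stop_input("cbct_volume must be finite and > 0 cm3")
  cbct_volume - planning_volume
}

#' Couch displacement vector of a CBCT session
#'
#' The recorded per-CBCT couch correction triple (Vrt, Lng, Lat) *is* the
#' displacement relative to the planning CT — match values exported from the
#' oncology information system are already planning-relative, so no further
#' differencing is applied.
#'
#' @param record A session record (a one-row data.frame or named list) with
#'   `session_index`, `vrt_cm`, `lng_cm`, `lat_cm`.
#' @return Named numeric triple `c(vrt, lng, lat)`, cm.
#' @export
displacement_vector <- function(record) {
  record <- as.list(record)
  if (is.null(record$session_index) || record$session_index == 0)
    stop_input("displacement_vector() is defined for CBCT sessions only; got a planning row (session_index 0)")
  v <- c(vrt = record$vrt_cm, lng = record$lng_cm, lat = record$lat_cm)
  if (length(v) != 3 || any(is.na(v)) || any(!is.finite(v)))
    stop_input("session record is missing a finite vrt/lng/lat shift component")
  stats::setNames(as.numeric(v), c("vrt", "lng", "lat"))
}

#' Euclidean magnitude of a displacement vector
#'
#' `sqrt(vrt^2 + lng^2 + lat^2)`, cm — the total 3D couch correction for one
#' CBCT session.
#'
#' @param v Numeric triple of displacement components, cm.
#' @return Non-negative magnitude, cm.
#' @export
displacement_magnitude <- function(v) {
  v <- as.numeric(v)
  if (length(v) != 3 || any(!is.finite(v)))
    stop_input("displacement vector must be 3 finite components")
  sqrt(sum(v * v))
}

#' Split a cohort session table into per-patient series
#'
#' Validates the cohort invariants (exactly one planning row per patient,
#' unique session indices, positive volumes, shifts present on every CBCT
#' row) and returns one series per patient with CBCT sessions ordered by
#' session index.
#'
#' @param cohort Long-format session data.frame as produced by
#'   [simulate_cohort()] or [read_cohort_csv()].
#' @return A named list of `couchshift_series` objects, each with
#'   `patient_id`, `planning` (one-row data.frame) and `cbct` (data.frame).
#' @export
split_cohort <- function(cohort) {
  req <- c("patient_id", "session_index", "rectum_volume_cm3",
           "vrt_cm", "lng_cm", "lat_cm")
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols) > 0)
    stop_input("cohort is missing column(s): %s",
               paste(missing_cols, collapse = ", "))
  out <- lapply(split(cohort, factor(cohort$patient_id,
                                     levels = unique(cohort$patient_id))),
                function(df) {
    pid <- df$patient_id[1]
    df <- df[order(df$session_index), , drop = FALSE]
    if (anyDuplicated(df$session_index))
      stop_input("patient %s: duplicate session_index", pid)
    if (sum(df$session_index == 0) != 1)
      stop_input("patient %s: exactly one planning row (session_index 0) required",
                 pid)
    if (any(!is.finite(df$rectum_volume_cm3)) ||
        any(df$rectum_volume_cm3 <= 0))
      stop_input("patient %s: rectum_volume_cm3 must be finite and > 0", pid)
    planning <- df[df$session_index == 0, , drop = FALSE]
    cbct <- df[df$session_index > 0, , drop = FALSE]
    if (nrow(cbct) < 1)
      stop_input("patient %s: needs at least one CBCT session", pid)
    if (any(is.na(cbct$vrt_cm)) || any(is.na(cbct$lng_cm)) ||
        any(is.na(cbct$lat_cm)))
      stop_input("patient %s: CBCT rows must carry vrt/lng/lat shifts", pid)
    structure(list(patient_id = pid, planning = planning, cbct = cbct),
              class = "couchshift_series")
  })
  out
}

# Raw 3-column feature matrix (dRV, magnitude, RV) for one patient's CBCT rows.
series_features <- function(series) {
  planning_vol <- series$planning$rectum_volume_cm3
  drv <- delta_rv(planning_vol, series$cbct$rectum_volume_cm3)
  mag <- sqrt(series$cbct$vrt_cm^2 + series$cbct$lng_cm^2 +
                series$cbct$lat_cm^2)
  cbind(delta_rectum_volume = drv,
        displacement_magnitude = mag,
        rectum_volume = series$cbct$rectum_volume_cm3)
}

#' Assemble the standardized, padded, masked feature tensor
#'
#' Computes the three per-session features (rectal volume change,
#' displacement magnitude, rectal volume), standardizes each to zero mean
#' and unit sd over the real (non-padding) tokens, and pads all patients to
#' the cohort maximum sequence length. Padding positions are exactly 0
#' (the post-standardization feature mean) and are recorded in a boolean
#' mask so the encoder can exclude them from attention, pooling and loss.
#'
#' @param cohort A list of patient series from [split_cohort()].
#' @param scaler Optional per-feature `list(mean =, sd =)` to apply (e.g.
#'   fitted on training folds); when `NULL` the scaler is fitted on this
#'   cohort's real tokens.
#' @return A `couchshift_features` list: `values` (`n x max_len x 3` array,
#'   standardized), `raw` (same shape, unstandardized), `mask`
#'   (`n x max_len` logical, `TRUE` = real token), `scaler`, `patient_order`,
#'   `feature_names`, `lengths`.
#' @export
build_feature_tensor <- function(cohort, scaler = NULL) {
  if (length(cohort) == 0) stop_input("empty cohort")
  feats <- lapply(cohort, series_features)
  lens <- vapply(feats, nrow, integer(1))
  max_len <- max(lens)
  n <- length(cohort)
  all_rows <- do.call(rbind, feats)
  if (is.null(scaler)) {
    mu <- colMeans(all_rows)
    sdv <- apply(all_rows, 2, stats::sd)
    zero_var <- sdv < 1e-12
    if (any(zero_var))
      stop_input("zero-variance feature(s) when fitting scaler: %s",
                 paste(FEATURE_NAMES[zero_var], collapse = ", "))
    scaler <- list(mean = mu, sd = sdv)
  } else {
    if (!all(c("mean", "sd") %in% names(scaler)) ||
        length(scaler$mean) != 3 || length(scaler$sd) != 3)
      stop_input("scaler must be list(mean =, sd =) of length-3 vectors")
  }
  values <- array(0, dim = c(n, max_len, 3))
  raw <- array(0, dim = c(n, max_len, 3))
  mask <- matrix(FALSE, n, max_len)
  for (i in seq_len(n)) {
    L <- lens[i]
    raw[i, seq_len(L), ] <- feats[[i]]
    values[i, seq_len(L), ] <- sweep(
      sweep(feats[[i]], 2, scaler$mean, "-"), 2, scaler$sd, "/")
    mask[i, seq_len(L)] <- TRUE
  }
  structure(list(
    values = values, raw = raw, mask = mask, scaler = scaler,
    patient_order = vapply(cohort, function(s) s$patient_id, character(1),
                           USE.NAMES = FALSE),
    feature_names = FEATURE_NAMES, lengths = lens
  ), class = "couchshift_features")
}

# Re-standardize a tensor's raw values with a (possibly fold-specific) scaler.
apply_scaler <- function(features, scaler) {
  values <- features$raw
  n <- dim(values)[1]
  for (i in seq_len(n)) {
    L <- features$lengths[i]
    m <- matrix(features$raw[i, seq_len(L), ], nrow = L)
    values[i, seq_len(L), ] <- sweep(sweep(m, 2, scaler$mean, "-"),
                                     2, scaler$sd, "/")
  }
  features$values <- values
  features$scaler <- scaler
  features
}

# Fit a scaler over real tokens of a patient subset (indices into dim 1).
fit_scaler <- function(features, idx = seq_len(dim(features$raw)[1])) {
  rows <- do.call(rbind, lapply(idx, function(i) {
    L <- features$lengths[i]
    matrix(features$raw[i, seq_len(L), ], nrow = L)
  }))
  mu <- colMeans(rows)
  sdv <- apply(rows, 2, stats::sd)
  zero_var <- sdv < 1e-12
  if (any(zero_var))
    stop_input("zero-variance feature(s) when fitting scaler: %s",
               paste(FEATURE_NAMES[zero_var], collapse = ", "))
  list(mean = stats::setNames(mu, FEATURE_NAMES),
       sd = stats::setNames(sdv, FEATURE_NAMES))
}
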