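# Small fixtures shared across test files; everything is generated in code.

# A compact simulated cohort for fast encoder/pipeline tests.
small_sim_config <- function(seed = 3L) {
  simulation_config(n_patients = 12, sessions_per_patient = c(4L, 7L),
                    seed = seed)
}

small_series <- function(seed = 3L) {
  split_cohort(simulate_cohort(small_sim_config(seed))$cohort)
}

# A tiny encoder: same architecture family, scaled down for test runtime.
small_encoder_config <- function(seed = 5L, epochs = 15L) {
  encoder_config(d_model = 16L, n_head = 2L, num_encoder_layers = 2L,
                 dim_feedforward = 32L, epochs = epochs, batch_size = 8L,
                 patience = 8L, seed = seed)
}

# Hand-built two-patient cohort with known numbers (volumes cm3, shifts cm).
toy_cohort_df <- function() {
  data.frame(
    patient_id = rep(c("A", "B"), each = 4),
    session_index = rep(0:3, 2),
    rectum_volume_cm3 = c(60, 75, 50, 66, 80, 64, 90, 77),
    vrt_cm = c(NA, 0.10, -0.05, 0.00, NA, -0.20, 0.30, 0.05),
    lng_cm = c(NA, 0.20, 0.14, -0.10, NA, 0.10, -0.10, 0.25),
    lat_cm = c(NA, 0.00, 0.03, 0.20, NA, 0.05, 0.20, -0.15),
    stringsAsFactors = FALSE
  )
}

# Extend a feature tensor with `extra` all-padding positions per patient.
pad_extend <- function(features, extra = 5L) {
  n <- dim(features$values)[1]
  old_len <- dim(features$values)[2]
  grow <- function(a) {
    out <- array(0, dim = c(n, old_len + extra, dim(a)[3]))
    out[, seq_len(old_len), ] <- a
    out
  }
  features$values <- grow(features$values)
  features$raw <- grow(features$raw)
  features$mask <- cbind(features$mask, matrix(FALSE, n, extra))
  features
}
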