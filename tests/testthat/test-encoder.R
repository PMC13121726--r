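test_that("folds partition the patients with near-equal validation sizes", {
  folds <- make_folds(10, 5, seed = 1L)
  expect_length(folds, 5)
  val_sizes <- lengths(lapply(folds, `[[`, "val"))
  expect_true(all(val_sizes == 2))
  expect_setequal(unlist(lapply(folds, `[[`, "val")), 1:10)
  big <- make_folds(498, 5, seed = 2L)
  expect_true(all(lengths(lapply(big, `[[`, "val")) %in% c(99, 100)))
  expect_setequal(unlist(lapply(big, `[[`, "val")), 1:498)
  for (f in big) expect_setequal(c(f$train, f$val), 1:498)
  expect_identical(make_folds(38, 5, seed = 3L), make_folds(38, 5, seed = 3L))
  expect_error(make_folds(4, 5), ">= k")
})

test_that("analytic gradients match central finite differences", {
  cfg <- encoder_config(d_model = 8L, n_head = 2L, num_encoder_layers = 2L,
                        dim_feedforward = 16L, seed = 3L)
  ft <- build_feature_tensor(small_series(seed = 2L)[1:5])
  ns <- asNamespace("couchshift")
  pe <- ns$positional_encoding(12L, cfg$d_model)
  params <- ns$init_encoder_params(cfg, 11L)
  batch <- ns$stack_batch(ft, 1:5)
  cache <- ns$encoder_forward(params, batch, cfg, pe)
  grads <- ns$encoder_backward(params, batch, cfg, cache)
  theta <- unlist(params, use.names = FALSE)
  gflat <- unlist(grads, use.names = FALSE)
  loss_at <- function(th) {
    p <- utils::relist(th, params)
    ns$masked_mse(ns$encoder_forward(p, batch, cfg, pe))
  }
  set.seed(5)
  idx <- sample(length(theta), 30)
  h <- 1e-5
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (loss_at(tp) - loss_at(tm)) / (2 * h)
  }, numeric(1))
  rel <- abs(num - gflat[idx]) / pmax(abs(num) + abs(gflat[idx]), 1e-8)
  expect_lt(max(rel), 1e-5)
})

test_that("an untrained model reconstructs unit-variance data at O(1) MSE", {
  ft <- build_feature_tensor(small_series())
  enc <- structure(list(params = couchshift:::init_encoder_params(
    small_encoder_config(), 7L),
    config = small_encoder_config(), scaler = ft$scaler),
    class = "couchshift_encoder")
  mse <- reconstruction_mse(enc, ft)
  expect_gt(mse, 0.1)
  expect_lt(mse, 10)
})

test_that("masked MSE equals an elementwise recomputation over real tokens", {
  ft <- build_feature_tensor(small_series())
  cfg <- small_encoder_config()
  enc <- structure(list(params = couchshift:::init_encoder_params(cfg, 7L),
                        config = cfg, scaler = ft$scaler),
                   class = "couchshift_encoder")
  rec <- reconstruct(enc, ft)
  expect_equal(dim(rec), dim(ft$values))
  mask3 <- array(rep(ft$mask, 3), dim = dim(ft$values))
  oracle <- mean((rec[mask3] - ft$values[mask3])^2)
  expect_equal(reconstruction_mse(enc, ft), oracle, tolerance = 1e-12)
  # padding positions carry no reconstruction
  expect_true(all(rec[!mask3] == 0))
})

test_that("appended padding never changes embeddings (trained or not)", {
  ft <- build_feature_tensor(small_series())
  cfg <- small_encoder_config()
  untrained <- structure(list(params = couchshift:::init_encoder_params(cfg, 7L),
                              config = cfg, scaler = ft$scaler),
                         class = "couchshift_encoder")
  trained <- train_encoder(ft, small_encoder_config(epochs = 5L))
  for (enc in list(untrained, trained)) {
    e1 <- encode(enc, ft)$vectors
    e2 <- encode(enc, pad_extend(ft, 5L))$vectors
    expect_lt(max(abs(e1 - e2)), 1e-5)
  }
})

test_that("a single-token patient's embedding is that token's encoder output", {
  df <- toy_cohort_df()
  df <- df[df$patient_id == "B" | df$session_index <= 1, ]  # A keeps 1 CBCT
  ft <- build_feature_tensor(split_cohort(df))
  cfg <- small_encoder_config()
  enc <- structure(list(params = couchshift:::init_encoder_params(cfg, 7L),
                        config = cfg, scaler = ft$scaler),
                   class = "couchshift_encoder")
  emb <- encode(enc, ft)
  ns <- asNamespace("couchshift")
  pe <- ns$positional_encoding(max(ft$lengths) + 8L, cfg$d_model)
  batch <- ns$stack_batch(ft, seq_along(ft$patient_order))
  Z <- ns$encoder_forward(enc$params, batch, cfg, pe)$Z
  a <- which(ft$patient_order == "A")
  expect_equal(unname(emb$vectors[a, ]), unname(Z[batch$starts[a], ]))
})

test_that("identical sequences embed identically and order permutes rows", {
  series <- small_series()
  twice <- c(series[1], series[1])
  twice[[2]]$patient_id <- "copy"
  ft2 <- build_feature_tensor(twice)
  cfg <- small_encoder_config()
  enc <- structure(list(params = couchshift:::init_encoder_params(cfg, 7L),
                        config = cfg, scaler = ft2$scaler),
                   class = "couchshift_encoder")
  e <- encode(enc, ft2)$vectors
  expect_equal(unname(e[1, ]), unname(e[2, ]))
  # patient-order permutation permutes embedding rows identically
  ft <- build_feature_tensor(series)
  perm <- rev(seq_along(series))
  ftp <- build_feature_tensor(series[perm], scaler = ft$scaler)
  encf <- structure(list(params = couchshift:::init_encoder_params(cfg, 7L),
                         config = cfg, scaler = ft$scaler),
                    class = "couchshift_encoder")
  ea <- encode(encf, ft)$vectors
  eb <- encode(encf, ftp)$vectors
  expect_equal(unname(eb), unname(ea[perm, ]), tolerance = 1e-12)
})

test_that("cross-validated training reduces validation MSE and is seeded", {
  ft <- build_feature_tensor(small_series())
  enc <- train_encoder(ft, small_encoder_config(epochs = 15L))
  expect_equal(nrow(enc$cv_report), 5)
  expect_true(all(enc$cv_report$val_mse <= enc$cv_report$first_val_mse))
  sel <- enc$cv_report[enc$selected_fold, ]
  expect_lt(sel$val_mse, sel$first_val_mse)
  expect_equal(enc$cv_report$val_mse[enc$selected_fold],
               min(enc$cv_report$val_mse))
  enc2 <- train_encoder(ft, small_encoder_config(epochs = 15L))
  expect_identical(enc$cv_report, enc2$cv_report)
  expect_identical(enc$params, enc2$params)
})

test_that("encoder configuration is validated", {
  expect_error(encoder_config(d_model = 10L, n_head = 4L), "divisible")
  expect_error(encoder_config(epochs = 0L), ">= 1")
  ft <- build_feature_tensor(small_series()[1:3])
  expect_error(train_encoder(ft, small_encoder_config()), "5")
})
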