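#' Configure the sequence autoencoder
#'
#' Architecture of the Stage-1 model: a linear embedding of the 3 session
#' features into `d_model` dimensions, additive sinusoidal positional
#' encoding, `num_encoder_layers` post-norm Transformer encoder layers
#' (multi-head self-attention + ReLU feed-forward, residual connections,
#' layer normalization), masked mean pooling over real tokens for the
#' patient embedding, and a per-token linear readout back to the 3 features
#' for the reconstruction loss.
#'
#' @param d_model Embedding width; must be divisible by `n_head`.
#' @param n_head Number of attention heads.
#' @param num_encoder_layers Number of encoder layers.
#' @param dim_feedforward Hidden width of the position-wise feed-forward net.
#' @param n_features Input features per token (3).
#' @param learning_rate Adam step size.
#' @param epochs Maximum training epochs per fold.
#' @param batch_size Patients per minibatch.
#' @param patience Early-stopping patience on fold-validation MSE, epochs.
#' @param seed Integer seed controlling folds, initialization and batching.
#' @return An `couchshift_encoder_config` list.
#' @export
encoder_config <- function(d_model = 64L, n_head = 4L,
                           num_encoder_layers = 2L, dim_feedforward = 128L,
                           n_features = 3L, learning_rate = 1e-3,
                           epochs = 80L, batch_size = 16L, patience = 10L,
                           seed = 1L) {
  if (d_model %% n_head != 0)
    stop_input("d_model (%d) must be divisible by n_head (%d)",
               d_model, n_head)
  if (!is_count(epochs) || !is_count(batch_size))
    stop_input("epochs and batch_size must be >= 1")
  structure(list(
    d_model = as.integer(d_model), n_head = as.integer(n_head),
    num_encoder_layers = as.integer(num_encoder_layers),
    dim_feedforward = as.integer(dim_feedforward),
    n_features = as.integer(n_features),
    learning_rate = learning_rate, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), patience = as.integer(patience),
    seed = as.integer(seed)
  ), class = "couchshift_encoder_config")
}

#' Grouped k-fold partition
#'
#' Shuffles `n_items` indices and deals them into `k` validation folds whose
#' sizes differ by at most one; every index appears in exactly one
#' validation set. Used with patients as items so no patient straddles the
#' train/validation boundary.
#'
#' @param n_items Number of items (patients).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of `k` lists with integer `train` and `val` indices (1-based).
#' @export
make_folds <- function(n_items, k = 5L, seed = 1L) {
  if (!is_count(n_items) || n_items < k)
    stop_input("n_items (%s) must be >= k (%d)", deparse(n_items), k)
  with_seed(seed, {
    perm <- sample.int(n_items)
    # deal fold ids cyclically along the shuffled order
    fold_of <- integer(n_items)
    fold_of[perm] <- rep(seq_len(k), length.out = n_items)
    lapply(seq_len(k), function(f) {
      val <- which(fold_of == f)
      list(train = setdiff(seq_len(n_items), val), val = val)
    })
  })
}

# --- parameters ------------------------------------------------------------

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_encoder_params <- function(config, seed) {
  with_seed(seed, {
    d <- config$d_model; f <- config$dim_feedforward
    nf <- config$n_features
    layer <- function() list(
      Wq = glorot(d, d), bq = numeric(d),
      Wk = glorot(d, d), bk = numeric(d),
      Wv = glorot(d, d), bv = numeric(d),
      Wo = glorot(d, d), bo = numeric(d),
      g1 = rep(1, d), be1 = numeric(d),
      W1 = glorot(d, f), b1 = numeric(f),
      W2 = glorot(f, d), b2 = numeric(d),
      g2 = rep(1, d), be2 = numeric(d)
    )
    list(W_in = glorot(nf, d), b_in = numeric(d),
         layers = lapply(seq_len(config$num_encoder_layers),
                         function(i) layer()),
         W_out = glorot(d, nf), b_out = numeric(nf))
  })
}

# Sinusoidal positional encoding, positions 0..(max_len-1).
positional_encoding <- function(max_len, d_model) {
  pos <- 0:(max_len - 1)
  pe <- matrix(0, max_len, d_model)
  i <- seq_len(d_model %/% 2)
  freq <- 1 / 10000^((2 * (i - 1)) / d_model)
  ang <- outer(pos, freq)
  pe[, 2 * i - 1] <- sin(ang)
  pe[, 2 * i] <- cos(ang)
  pe
}

# --- forward / backward ----------------------------------------------------

# Tokens of all patients in the batch are stacked row-wise into T x d
# matrices; `blocks` holds each patient's row range so self-attention (the
# only cross-token operation) is confined to one patient's tokens. Padding
# tokens are never stacked, which realizes the key-padding mask exactly:
# masked positions contribute nothing to attention, pooling or loss.
stack_batch <- function(features, idx) {
  lens <- features$lengths[idx]
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  X <- do.call(rbind, lapply(seq_along(idx), function(j) {
    i <- idx[j]
    matrix(features$values[i, seq_len(lens[j]), ], nrow = lens[j])
  }))
  list(X = X, starts = starts, ends = ends, lens = lens)
}

layer_norm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, gamma, "*") + rep(beta, each = nrow(x)),
       xhat = xhat, inv = inv)
}

layer_norm_bwd <- function(dy, cache, gamma) {
  xhat <- cache$xhat; inv <- cache$inv
  dxhat <- sweep(dy, 2, gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * inv
  list(dx = dx, dgamma = colSums(dy * xhat), dbeta = colSums(dy))
}

encoder_forward <- function(params, batch, config, pe) {
  d <- config$d_model; nh <- config$n_head; dh <- d %/% nh
  X <- batch$X
  npat <- length(batch$lens)
  posrows <- unlist(lapply(batch$lens, seq_len))
  H <- X %*% params$W_in + rep(params$b_in, each = nrow(X)) + pe[posrows, ]
  cache <- list(X = X, H0 = H, posrows = posrows, layers = list())
  for (l in seq_along(params$layers)) {
    p <- params$layers[[l]]
    Hin <- H
    Q <- Hin %*% p$Wq + rep(p$bq, each = nrow(Hin))
    K <- Hin %*% p$Wk + rep(p$bk, each = nrow(Hin))
    V <- Hin %*% p$Wv + rep(p$bv, each = nrow(Hin))
    Ocat <- matrix(0, nrow(Hin), d)
    Pmats <- vector("list", npat * nh)
    for (b in seq_len(npat)) {
      rows <- batch$starts[b]:batch$ends[b]
      for (h in seq_len(nh)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        S <- tcrossprod(Q[rows, cols, drop = FALSE],
                        K[rows, cols, drop = FALSE]) / sqrt(dh)
        S <- S - apply(S, 1, max)
        P <- exp(S)
        P <- P / rowSums(P)
        Pmats[[(b - 1) * nh + h]] <- P
        Ocat[rows, cols] <- P %*% V[rows, cols, drop = FALSE]
      }
    }
    O <- Ocat %*% p$Wo + rep(p$bo, each = nrow(Hin))
    res1 <- Hin + O
    ln1 <- layer_norm_fwd(res1, p$g1, p$be1)
    H1 <- ln1$y
    B <- H1 %*% p$W1 + rep(p$b1, each = nrow(H1))
    A <- pmax(B, 0)
    Ff <- A %*% p$W2 + rep(p$b2, each = nrow(H1))
    res2 <- H1 + Ff
    ln2 <- layer_norm_fwd(res2, p$g2, p$be2)
    H <- ln2$y
    cache$layers[[l]] <- list(Hin = Hin, Q = Q, K = K, V = V,
                              Pmats = Pmats, Ocat = Ocat, ln1 = ln1,
                              H1 = H1, B = B, A = A, ln2 = ln2)
  }
  Xhat <- H %*% params$W_out + rep(params$b_out, each = nrow(H))
  cache$Z <- H
  cache$Xhat <- Xhat
  cache
}

encoder_backward <- function(params, batch, config, cache) {
  d <- config$d_model; nh <- config$n_head; dh <- d %/% nh
  X <- cache$X
  N <- length(X)  # tokens * features
  dXhat <- 2 * (cache$Xhat - X) / N
  g <- list(W_out = crossprod(cache$Z, dXhat), b_out = colSums(dXhat),
            layers = vector("list", length(params$layers)))
  dH <- dXhat %*% t(params$W_out)
  npat <- length(batch$lens)
  for (l in rev(seq_along(params$layers))) {
    p <- params$layers[[l]]
    cl <- cache$layers[[l]]
    ln2b <- layer_norm_bwd(dH, cl$ln2, p$g2)
    dres2 <- ln2b$dx
    dH1 <- dres2
    dFf <- dres2
    gW2 <- crossprod(cl$A, dFf); gb2 <- colSums(dFf)
    dA <- dFf %*% t(p$W2)
    dB <- dA * (cl$B > 0)
    gW1 <- crossprod(cl$H1, dB); gb1 <- colSums(dB)
    dH1 <- dH1 + dB %*% t(p$W1)
    ln1b <- layer_norm_bwd(dH1, cl$ln1, p$g1)
    dres1 <- ln1b$dx
    dHin <- dres1
    dO <- dres1
    gWo <- crossprod(cl$Ocat, dO); gbo <- colSums(dO)
    dOcat <- dO %*% t(p$Wo)
    dQ <- matrix(0, nrow(X), d)
    dK <- matrix(0, nrow(X), d)
    dV <- matrix(0, nrow(X), d)
    for (b in seq_len(npat)) {
      rows <- batch$starts[b]:batch$ends[b]
      for (h in seq_len(nh)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        P <- cl$Pmats[[(b - 1) * nh + h]]
        dOb <- dOcat[rows, cols, drop = FALSE]
        Vb <- cl$V[rows, cols, drop = FALSE]
        dP <- tcrossprod(dOb, Vb)
        dV[rows, cols] <- crossprod(P, dOb)
        dS <- P * (dP - rowSums(dP * P))
        dQ[rows, cols] <- dS %*% cl$K[rows, cols, drop = FALSE] / sqrt(dh)
        dK[rows, cols] <- crossprod(dS, cl$Q[rows, cols, drop = FALSE]) /
          sqrt(dh)
      }
    }
    gWq <- crossprod(cl$Hin, dQ); gbq <- colSums(dQ)
    gWk <- crossprod(cl$Hin, dK); gbk <- colSums(dK)
    gWv <- crossprod(cl$Hin, dV); gbv <- colSums(dV)
    dHin <- dHin + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    g$layers[[l]] <- list(Wq = gWq, bq = gbq, Wk = gWk, bk = gbk,
                          Wv = gWv, bv = gbv, Wo = gWo, bo = gbo,
                          g1 = ln1b$dgamma, be1 = ln1b$dbeta,
                          W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                          g2 = ln2b$dgamma, be2 = ln2b$dbeta)
    dH <- dHin
  }
  g$W_in <- crossprod(X, dH)
  g$b_in <- colSums(dH)
  # reorder to match params element order for flattening
  g[names(params)]
}

masked_mse <- function(cache) {
  mean((cache$Xhat - cache$X)^2)
}

# --- training --------------------------------------------------------------

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

flatten_params <- function(params) unlist(params, use.names = FALSE)

unflatten_params <- function(theta, skeleton) {
  utils::relist(theta, skeleton)
}

eval_mse <- function(params, features, idx, config, pe) {
  batch <- stack_batch(features, idx)
  masked_mse(encoder_forward(params, batch, config, pe))
}

train_on_fold <- function(features, train_idx, val_idx, config, pe, seed) {
  params <- init_encoder_params(config, derive_seed(seed, "init"))
  skeleton <- params
  theta <- flatten_params(params)
  state <- list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0)
  best <- list(val = Inf, theta = theta, epoch = 0L)
  first_val <- NA_real_
  wait <- 0L
  with_seed(derive_seed(seed, "batches"), {
    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample(train_idx)
      chunks <- split(order_idx,
                      ceiling(seq_along(order_idx) / config$batch_size))
      for (ch in chunks) {
        batch <- stack_batch(features, ch)
        cache <- encoder_forward(params, batch, config, pe)
        if (!is.finite(masked_mse(cache)))
          stop_input("training diverged (non-finite loss) at epoch %d", epoch)
        grads <- encoder_backward(params, batch, config, cache)
        upd <- adam_step(theta, flatten_params(grads), state,
                         config$learning_rate)
        theta <- upd$theta
        state <- upd$state
        params <- unflatten_params(theta, skeleton)
      }
      val <- eval_mse(params, features, val_idx, config, pe)
      if (epoch == 1) first_val <- val
      if (val < best$val - 1e-6) {
        best <- list(val = val, theta = theta, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  list(params = unflatten_params(best$theta, skeleton),
       val_mse = best$val, epoch = best$epoch, first_val_mse = first_val)
}

#' Train the sequence autoencoder with grouped 5-fold cross-validation
#'
#' Patients are partitioned into 5 non-overlapping folds. In each fold the
#' feature scaler is refitted on the training patients only (leakage-safe),
#' the model is trained by Adam on the masked reconstruction MSE of training
#' patients, and the best epoch by validation MSE is recorded (early
#' stopping). The checkpoint from the fold with the lowest validation MSE
#' becomes the final encoder, paired with a scaler refitted on all patients
#' for the full-cohort embedding pass.
#'
#' @param features A `couchshift_features` tensor from
#'   [build_feature_tensor()].
#' @param config An [encoder_config()].
#' @param k Number of folds.
#' @return A `couchshift_encoder`: `params`, `config`, `scaler`, `cv_report`
#'   (data.frame: fold, best_epoch, val_mse, first_val_mse), `selected_fold`,
#'   `max_len`.
#' @export
train_encoder <- function(features, config = encoder_config(), k = 5L) {
  n <- dim(features$values)[1]
  if (n < k) stop_input("need at least %d patients for %d-fold CV", k, k)
  pe <- positional_encoding(max(features$lengths) + 8L, config$d_model)
  folds <- make_folds(n, k, derive_seed(config$seed, "folds"))
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    scaler_f <- fit_scaler(features, folds[[f]]$train)
    feats_f <- apply_scaler(features, scaler_f)
    fits[[f]] <- train_on_fold(feats_f, folds[[f]]$train, folds[[f]]$val,
                               config, pe,
                               derive_seed(config$seed, paste0("fold", f)))
  }
  cv_report <- data.frame(
    fold = seq_len(k),
    best_epoch = vapply(fits, function(x) x$epoch, integer(1)),
    val_mse = vapply(fits, function(x) x$val_mse, numeric(1)),
    first_val_mse = vapply(fits, function(x) x$first_val_mse, numeric(1))
  )
  sel <- which.min(cv_report$val_mse)
  final_scaler <- fit_scaler(features)
  structure(list(
    params = fits[[sel]]$params,
    config = config,
    scaler = final_scaler,
    cv_report = cv_report,
    selected_fold = sel,
    max_len = max(features$lengths)
  ), class = "couchshift_encoder")
}

#' Embed patients with a trained encoder
#'
#' Runs the token pipeline (linear projection, positional encoding, encoder
#' layers restricted to real tokens) and mean-pools encoder outputs over the
#' real tokens of each patient, yielding one `d_model`-vector per patient.
#' Padding tokens cannot influence the result.
#'
#' @param encoder A `couchshift_encoder` from [train_encoder()].
#' @param features A `couchshift_features` tensor built with the encoder's
#'   scaler (see [embed_cohort()] for the convenience path).
#' @return A `couchshift_embeddings` list: `vectors` (`n x d_model` matrix,
#'   rownames = patient ids) and `patient_order`.
#' @export
encode <- function(encoder, features) {
  if (dim(features$values)[3] != encoder$config$n_features)
    stop_input("feature tensor has %d features; encoder expects %d",
               dim(features$values)[3], encoder$config$n_features)
  pe <- positional_encoding(max(features$lengths) + 8L,
                            encoder$config$d_model)
  n <- dim(features$values)[1]
  batch <- stack_batch(features, seq_len(n))
  cache <- encoder_forward(encoder$params, batch, encoder$config, pe)
  vectors <- t(vapply(seq_len(n), function(b) {
    rows <- batch$starts[b]:batch$ends[b]
    colMeans(cache$Z[rows, , drop = FALSE])
  }, numeric(encoder$config$d_model)))
  rownames(vectors) <- features$patient_order
  structure(list(vectors = vectors, patient_order = features$patient_order),
            class = "couchshift_embeddings")
}

#' Reconstruct the feature tensor through the autoencoder
#'
#' Applies the per-token linear readout to the encoder outputs, returning an
#' array shaped like `features$values`; padding positions are 0 and carry no
#' loss.
#'
#' @inheritParams encode
#' @return Array `n x max_len x 3` of reconstructed standardized features.
#' @export
reconstruct <- function(encoder, features) {
  pe <- positional_encoding(max(features$lengths) + 8L,
                            encoder$config$d_model)
  n <- dim(features$values)[1]
  batch <- stack_batch(features, seq_len(n))
  cache <- encoder_forward(encoder$params, batch, encoder$config, pe)
  out <- array(0, dim = dim(features$values))
  for (b in seq_len(n)) {
    rows <- batch$starts[b]:batch$ends[b]
    out[b, seq_len(batch$lens[b]), ] <- cache$Xhat[rows, , drop = FALSE]
  }
  out
}

#' Masked reconstruction mean squared error
#'
#' MSE over real tokens and features only; padding positions are excluded by
#' construction.
#'
#' @inheritParams encode
#' @return A single number.
#' @export
reconstruction_mse <- function(encoder, features) {
  pe <- positional_encoding(max(features$lengths) + 8L,
                            encoder$config$d_model)
  n <- dim(features$values)[1]
  eval_mse(encoder$params, features, seq_len(n), encoder$config, pe)
}

#' Build features with an encoder's scaler and embed a cohort
#'
#' @param encoder A trained `couchshift_encoder`.
#' @param cohort A list of patient series from [split_cohort()].
#' @return A `couchshift_embeddings`.
#' @export
embed_cohort <- function(encoder, cohort) {
  feats <- build_feature_tensor(cohort, scaler = encoder$scaler)
  encode(encoder, feats)
}
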