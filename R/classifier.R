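## The supervised kinase-substrate_motif classifier: two bilinear layers
## combine the kinase vector with the substrate and motif vectors, a third
## bilinear layer fuses the two combinations, and a small feed-forward head
## (40 and 50 neurons, ReLU + dropout after each) emits a sigmoid
## phosphorylation probability. Trained with binary cross-entropy via
## manually derived gradients and Adam.

#' Bilinear transformation
#'
#' Output component `j = u' W[,,j] v + b[j]`. `W` may be a `d_u x d_v x
#' d_b` array or its column-major flattening (a `(d_u*d_v) x d_b` matrix).
#'
#' @param u,v numeric input vectors.
#' @param W bilinear tensor.
#' @param b bias vector of length `d_b`.
#' @return Numeric vector of length `d_b`.
#' @export
bilinear <- function(u, v, W, b) {
  if (is.array(W) && length(dim(W)) == 3L) {
    dims <- dim(W)
    if (dims[1L] != length(u) || dims[2L] != length(v)) {
      stop("bilinear shape mismatch", call. = FALSE)
    }
    W <- matrix(W, dims[1L] * dims[2L], dims[3L])
  }
  if (nrow(W) != length(u) * length(v) || ncol(W) != length(b)) {
    stop("bilinear shape mismatch", call. = FALSE)
  }
  X <- .rowkron(matrix(u, 1L), matrix(v, 1L))
  drop(X %*% W) + b
}

## row-wise Kronecker: X[i, (q-1)*du + p] = U[i,p] * V[i,q]
.rowkron <- function(U, V) {
  du <- ncol(U); dv <- ncol(V)
  U[, rep.int(seq_len(du), dv), drop = FALSE] *
    V[, rep(seq_len(dv), each = du), drop = FALSE]
}

#' Classifier configuration
#'
#' Training hyperparameters are package defaults (Adam, learning rate
#' 1e-3, minibatches of 512, at most 200 epochs with patience 10 on a 10%
#' seeded carve-out of the training data), not protocol constants. The
#' bilinear output width `d_b` defaults to 50 to keep single-CPU training
#' practical; the hidden widths (40, 50) and the 0.5 dropout are part of
#' the architecture.
#'
#' @param d_b bilinear output dimension (`NULL` = 50).
#' @param dropout_p dropout probability after each hidden layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param patience consecutive epochs without carve-out loss improvement
#'   before stopping.
#' @param val_fraction carve-out fraction for early stopping.
#' @param pos_weight optional positive-class weight in the loss
#'   (`NULL` = unweighted, the default protocol).
#' @param seed integer seed.
#' @return List of class `ksmo_clf_config`.
#' @export
clf_config <- function(d_b = NULL, dropout_p = 0.5, learning_rate = 1e-3,
                       batch_size = 512L, max_epochs = 200L, patience = 10L,
                       val_fraction = 0.1, pos_weight = NULL, seed = 1L) {
  stopifnot(dropout_p >= 0, dropout_p < 1, learning_rate > 0,
            batch_size >= 1L, max_epochs >= 1L, patience >= 1L,
            val_fraction > 0, val_fraction < 1)
  structure(as.list(environment()), class = "ksmo_clf_config")
}

#' Initialize classifier parameters
#'
#' Xavier-style uniform initialization scaled by fan-in/fan-out, seeded.
#'
#' @param d input embedding dimension.
#' @param d_b bilinear output dimension.
#' @param hidden hidden layer widths (fixed architecture: 40 then 50).
#' @param dropout_p dropout probability.
#' @param seed integer seed.
#' @return Object of class `ksmo_classifier` holding all parameter
#'   matrices (bilinear tensors stored flattened, `(d*d) x d_b`).
#' @export
init_classifier <- function(d, d_b = 50L, hidden = c(40L, 50L),
                            dropout_p = 0.5, seed = 1L) {
  old <- .seed_state(seed)
  on.exit(.restore_seed(old), add = TRUE)
  xav <- function(fan_in, fan_out, n_row, n_col) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(n_row * n_col, -lim, lim), n_row, n_col)
  }
  structure(list(
    W_ks = xav(d * d, d_b, d * d, d_b), b_ks = numeric(d_b),
    W_km = xav(d * d, d_b, d * d, d_b), b_km = numeric(d_b),
    W_ksm = xav(d_b * d_b, d_b, d_b * d_b, d_b), b_ksm = numeric(d_b),
    H1 = xav(d_b, hidden[1L], d_b, hidden[1L]), c1 = numeric(hidden[1L]),
    H2 = xav(hidden[1L], hidden[2L], hidden[1L], hidden[2L]),
    c2 = numeric(hidden[2L]),
    w_out = xav(hidden[2L], 1L, hidden[2L], 1L), c_out = 0,
    d = as.integer(d), d_b = as.integer(d_b), hidden = as.integer(hidden),
    dropout_p = dropout_p
  ), class = "ksmo_classifier")
}

#' @export
print.ksmo_classifier <- function(x, ...) {
  cat("Bilinear kinase-substrate_motif classifier: d =", x$d,
      ", d_b =", x$d_b, ", head", paste(x$hidden, collapse = "/"),
      ", dropout", x$dropout_p, "\n")
  invisible(x)
}

## Batched forward pass. K, S, M: n x d matrices. Returns activations
## needed for the backward pass. Dropout masks are drawn from the current
## RNG stream when training = TRUE.
.clf_forward <- function(params, K, S, M, training = FALSE) {
  n <- nrow(K)
  Xks <- .rowkron(K, S)
  Vks <- Xks %*% params$W_ks
  Vks <- sweep(Vks, 2L, params$b_ks, "+")
  Xkm <- .rowkron(K, M)
  Vkm <- Xkm %*% params$W_km
  Vkm <- sweep(Vkm, 2L, params$b_km, "+")
  Xksm <- .rowkron(Vks, Vkm)
  Vksm <- Xksm %*% params$W_ksm
  Vksm <- sweep(Vksm, 2L, params$b_ksm, "+")

  a1 <- sweep(Vksm %*% params$H1, 2L, params$c1, "+")
  h1 <- pmax(a1, 0)
  p_drop <- params$dropout_p
  if (training && p_drop > 0) {
    mask1 <- matrix(rbinom(length(h1), 1L, 1 - p_drop), n) / (1 - p_drop)
  } else mask1 <- NULL
  h1d <- if (is.null(mask1)) h1 else h1 * mask1

  a2 <- sweep(h1d %*% params$H2, 2L, params$c2, "+")
  h2 <- pmax(a2, 0)
  if (training && p_drop > 0) {
    mask2 <- matrix(rbinom(length(h2), 1L, 1 - p_drop), n) / (1 - p_drop)
  } else mask2 <- NULL
  h2d <- if (is.null(mask2)) h2 else h2 * mask2

  z <- drop(h2d %*% params$w_out) + params$c_out
  p <- 1 / (1 + exp(-z))
  list(Xks = Xks, Xkm = Xkm, Vks = Vks, Vkm = Vkm, Xksm = Xksm,
       Vksm = Vksm, a1 = a1, h1d = h1d, mask1 = mask1,
       a2 = a2, h2d = h2d, mask2 = mask2, z = z, p = p)
}

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood
#' `-(1/n) sum(y*log(p) + (1-y)*log(1-p))`; predictions are clamped to
#' `[1e-7, 1 - 1e-7]` before taking logs.
#'
#' @param predictions probabilities in (0, 1).
#' @param labels binary labels (0/1).
#' @param weights optional per-sample weights.
#' @return Scalar loss.
#' @export
bce_loss <- function(predictions, labels, weights = NULL) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length", call. = FALSE)
  }
  eps <- 1e-7
  p <- pmin(pmax(predictions, eps), 1 - eps)
  ll <- labels * log(p) + (1 - labels) * log(1 - p)
  if (!is.null(weights)) ll <- ll * weights
  -mean(ll)
}

## Loss and full analytic gradient over a batch (no dropout when masks are
## NULL; with masks they must come from a forward pass in training mode).
.clf_grads <- function(params, K, S, M, y, fw, weights = NULL) {
  n <- nrow(K)
  w <- if (is.null(weights)) rep(1, n) else weights
  loss <- bce_loss(fw$p, y, weights = w)
  dz <- w * (fw$p - y) / n

  d_wout <- crossprod(fw$h2d, dz)
  d_cout <- sum(dz)
  dh2d <- outer(dz, drop(params$w_out))  # n x h2
  dh2 <- if (is.null(fw$mask2)) dh2d else dh2d * fw$mask2
  da2 <- dh2 * (fw$a2 > 0)
  d_H2 <- crossprod(fw$h1d, da2)
  d_c2 <- colSums(da2)
  dh1d <- da2 %*% t(params$H2)
  dh1 <- if (is.null(fw$mask1)) dh1d else dh1d * fw$mask1
  da1 <- dh1 * (fw$a1 > 0)
  d_H1 <- crossprod(fw$Vksm, da1)
  d_c1 <- colSums(da1)
  dVksm <- da1 %*% t(params$H1)

  d_Wksm <- crossprod(fw$Xksm, dVksm)
  d_bksm <- colSums(dVksm)
  dXksm <- dVksm %*% t(params$W_ksm)  # n x d_b^2
  db <- params$d_b
  dVks <- matrix(0, n, db); dVkm <- matrix(0, n, db)
  for (q in seq_len(db)) {
    block <- dXksm[, (q - 1L) * db + seq_len(db), drop = FALSE]
    dVks <- dVks + block * fw$Vkm[, q]
    dVkm[, q] <- rowSums(block * fw$Vks)
  }
  d_Wks <- crossprod(fw$Xks, dVks)
  d_bks <- colSums(dVks)
  d_Wkm <- crossprod(fw$Xkm, dVkm)
  d_bkm <- colSums(dVkm)

  list(loss = loss,
       grads = list(W_ks = d_Wks, b_ks = d_bks, W_km = d_Wkm, b_km = d_bkm,
                    W_ksm = d_Wksm, b_ksm = d_bksm, H1 = d_H1, c1 = d_c1,
                    H2 = d_H2, c2 = d_c2, w_out = d_wout, c_out = d_cout))
}

.param_names <- c("W_ks", "b_ks", "W_km", "b_km", "W_ksm", "b_ksm",
                  "H1", "c1", "H2", "c2", "w_out", "c_out")

#' Forward pass for one sample
#'
#' Computes the full activation trace `V_ks`, `V_km`, `V_ksm` and the
#' output probability for one (kinase, substrate, motif) identifier
#' triple. With `training = TRUE` the two dropout layers are active
#' (seeded); in inference mode the pass is deterministic.
#'
#' @param k,s,m entity identifiers.
#' @param emb a `ksmo_embeddings` covering all three identifiers.
#' @param params a `ksmo_classifier`.
#' @param training apply dropout.
#' @param seed RNG seed for the dropout masks (training mode only).
#' @return List with `V_k`, `V_s`, `V_m`, `V_ks`, `V_km`, `V_ksm`, `p`.
#' @export
forward <- function(k, s, m, emb, params, training = FALSE, seed = NULL) {
  K <- embedding_rows(emb, k); S <- embedding_rows(emb, s)
  M <- embedding_rows(emb, m)
  if (training && !is.null(seed)) {
    old <- .seed_state(seed)
    on.exit(.restore_seed(old), add = TRUE)
  }
  fw <- .clf_forward(params, K, S, M, training = training)
  list(V_k = drop(K), V_s = drop(S), V_m = drop(M),
       V_ks = drop(fw$Vks), V_km = drop(fw$Vkm), V_ksm = drop(fw$Vksm),
       p = unname(fw$p))
}

#' Train the bilinear classifier
#'
#' Minibatch Adam on the binary cross-entropy; a seeded 10% carve-out of
#' the training samples serves as validation, training stops after
#' `patience` epochs without carve-out loss improvement and the
#' best-validation parameters are returned. Samples whose kinase,
#' substrate or motif has no embedding are dropped with a message.
#'
#' @param bundle a `ksmo_bundle` (its `train` table is used) or a plain
#'   sample table with columns `kinase`, `substrate`, `motif`, `label`.
#' @param emb a `ksmo_embeddings`.
#' @param config a `ksmo_clf_config`.
#' @param verbose print per-epoch losses.
#' @return A `ksmo_classifier` with attributes `loss_curve` (data.table
#'   epoch/train_loss/val_loss) and `n_dropped`.
#' @export
train_classifier <- function(bundle, emb, config = clf_config(),
                             verbose = FALSE) {
  samples <- if (inherits(bundle, "ksmo_bundle")) bundle$train else
    as.data.table(bundle)
  samples <- as.data.table(samples)
  stopifnot(nrow(samples) > 0L,
            all(c("kinase", "substrate", "motif", "label") %in% names(samples)))
  known <- rownames(emb$entities)
  ok <- samples$kinase %chin% known & samples$substrate %chin% known &
    samples$motif %chin% known
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message("dropping ", n_dropped, " sample(s) with missing embeddings")
    samples <- samples[ok]
  }
  if (nrow(samples) == 0L) stop("empty training set", call. = FALSE)

  d <- emb$dim
  d_b <- if (is.null(config$d_b)) 50L else as.integer(config$d_b)
  old <- .seed_state(config$seed)
  on.exit(.restore_seed(old), add = TRUE)

  params <- init_classifier(d, d_b = d_b, dropout_p = config$dropout_p,
                            seed = sample.int(.Machine$integer.max, 1L))

  n <- nrow(samples)
  n_val <- max(1L, round(config$val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr <- samples[-val_idx]; va <- samples[val_idx]
  if (nrow(tr) == 0L) stop("training carve-out left no samples", call. = FALSE)

  Ktr <- embedding_rows(emb, tr$kinase)
  Str <- embedding_rows(emb, tr$substrate)
  Mtr <- embedding_rows(emb, tr$motif)
  ytr <- tr$label
  Kva <- embedding_rows(emb, va$kinase)
  Sva <- embedding_rows(emb, va$substrate)
  Mva <- embedding_rows(emb, va$motif)
  yva <- va$label

  wtr <- if (is.null(config$pos_weight)) NULL else
    ifelse(ytr == 1L, config$pos_weight, 1)

  adam <- .adam_init(params)
  lr <- config$learning_rate
  best <- list(loss = Inf, params = params)
  stale <- 0L
  curve <- vector("list", config$max_epochs)
  ntr <- nrow(tr)

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(ntr)
    ep_loss <- 0; ep_n <- 0L
    for (s0 in seq(1L, ntr, by = config$batch_size)) {
      idx <- perm[s0:min(s0 + config$batch_size - 1L, ntr)]
      fw <- .clf_forward(params, Ktr[idx, , drop = FALSE],
                         Str[idx, , drop = FALSE], Mtr[idx, , drop = FALSE],
                         training = TRUE)
      g <- .clf_grads(params, Ktr[idx, , drop = FALSE],
                      Str[idx, , drop = FALSE], Mtr[idx, , drop = FALSE],
                      ytr[idx], fw,
                      weights = if (is.null(wtr)) NULL else wtr[idx])
      adam <- .adam_step(adam, params, g$grads, lr)
      params <- adam$params
      ep_loss <- ep_loss + g$loss * length(idx); ep_n <- ep_n + length(idx)
    }
    val_p <- .clf_forward(params, Kva, Sva, Mva, training = FALSE)$p
    val_loss <- bce_loss(val_p, yva)
    curve[[epoch]] <- data.table(epoch = epoch,
                                 train_loss = ep_loss / ep_n,
                                 val_loss = val_loss)
    if (verbose) {
      message(sprintf("epoch %d train %.4f val %.4f", epoch,
                      ep_loss / ep_n, val_loss))
    }
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, params = params)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  out <- best$params
  attr(out, "loss_curve") <- rbindlist(curve[!vapply(curve, is.null,
                                                     logical(1))])
  attr(out, "n_dropped") <- n_dropped
  out
}

.adam_init <- function(params) {
  zeros <- lapply(params[.param_names], function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
  list(m = zeros, v = zeros, t = 0L, params = params)
}

.adam_step <- function(state, params, grads, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in .param_names) {
    g <- grads[[nm]]
    if (is.matrix(params[[nm]]) && !is.matrix(g)) {
      g <- matrix(g, nrow(params[[nm]]), ncol(params[[nm]]))
    }
    if (!is.matrix(params[[nm]])) g <- as.numeric(g)
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  state$params <- params
  state
}

#' Predict phosphorylation probabilities
#'
#' Inference-mode (deterministic, dropout off) forward pass for each
#' sample, order-preserving.
#'
#' @param object a trained `ksmo_classifier`.
#' @param emb a `ksmo_embeddings`.
#' @param samples table with columns `kinase`, `substrate`, `motif`.
#' @param batch_size internal batch size (results are batch-invariant).
#' @param ... unused.
#' @return Numeric vector of probabilities, one per row of `samples`.
#' @export
predict.ksmo_classifier <- function(object, emb, samples,
                                    batch_size = 2048L, ...) {
  samples <- as.data.table(samples)
  miss <- which(!(samples$kinase %chin% rownames(emb$entities) &
                  samples$substrate %chin% rownames(emb$entities) &
                  samples$motif %chin% rownames(emb$entities)))
  if (length(miss) > 0L) {
    stop("missing embedding for sample index(es): ",
         paste(head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  n <- nrow(samples)
  p <- numeric(n)
  for (s0 in seq(1L, n, by = batch_size)) {
    idx <- s0:min(s0 + batch_size - 1L, n)
    p[idx] <- .clf_forward(
      object,
      embedding_rows(emb, samples$kinase[idx]),
      embedding_rows(emb, samples$substrate[idx]),
      embedding_rows(emb, samples$motif[idx]),
      training = FALSE)$p
  }
  p
}
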