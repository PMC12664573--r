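test_that("bilinear worked examples", {
  ## all-zero tensor: output is the bias for any inputs
  W <- array(0, c(3, 3, 2))
  expect_equal(bilinear(rnorm(3), rnorm(3), W, c(1, 2)), c(1, 2))
  ## 1x1x1: u * w * v + b
  expect_equal(bilinear(2, 3, array(5, c(1, 1, 1)), 1), 31)
  expect_error(bilinear(1:3, 1:2, W, c(1, 2)), "shape mismatch")
})

test_that("bilinear matches the naive triple-loop oracle", {
  set.seed(8)
  for (i in 1:30) {
    du <- sample(1:6, 1L); dv <- sample(1:6, 1L); db <- sample(1:5, 1L)
    u <- rnorm(du); v <- rnorm(dv)
    W <- array(rnorm(du * dv * db), c(du, dv, db))
    b <- rnorm(db)
    out <- bilinear(u, v, W, b)
    oracle <- numeric(db)
    for (j in seq_len(db)) {
      acc <- 0
      for (p in seq_len(du)) for (q in seq_len(dv)) {
        acc <- acc + u[p] * W[p, q, j] * v[q]
      }
      oracle[j] <- acc + b[j]
    }
    expect_equal(out, oracle, tolerance = 1e-10)
  }
})

test_that("zeroed parameters give probability 0.5 and inference is pure", {
  emb <- toy_embeddings(c("K", "S", "M"), d = 4L, seed = 2)
  params <- init_classifier(4L, d_b = 3L, seed = 1)
  for (nm in c("W_ks", "b_ks", "W_km", "b_km", "W_ksm", "b_ksm",
               "H1", "c1", "H2", "c2", "w_out")) {
    params[[nm]][] <- 0
  }
  params$c_out <- 0
  fw <- forward("K", "S", "M", emb, params)
  expect_equal(fw$p, 0.5)
  ## inference is deterministic
  params2 <- init_classifier(4L, d_b = 3L, seed = 3)
  f1 <- forward("K", "S", "M", emb, params2)
  f2 <- forward("K", "S", "M", emb, params2)
  expect_identical(f1$p, f2$p)
  expect_error(forward("K", "S", "X", emb, params2), "X")
})

test_that("forward pass matches an independent hand-rolled oracle", {
  set.seed(12)
  d <- 2L; db <- 2L
  emb <- toy_embeddings(c("K", "S", "M"), d = d, seed = 4)
  params <- init_classifier(d, d_b = db, seed = 9)
  fw <- forward("K", "S", "M", emb, params)
  ## oracle: scalar arithmetic through the published architecture
  k <- emb$entities["K", ]; s <- emb$entities["S", ]; m <- emb$entities["M", ]
  bil <- function(u, v, Wm, b) {
    vapply(seq_along(b), function(j) {
      Wj <- matrix(Wm[, j], length(u), length(v))
      drop(t(u) %*% Wj %*% v) + b[j]
    }, numeric(1))
  }
  vks <- bil(k, s, params$W_ks, params$b_ks)
  vkm <- bil(k, m, params$W_km, params$b_km)
  vksm <- bil(vks, vkm, params$W_ksm, params$b_ksm)
  h1 <- pmax(drop(vksm %*% params$H1) + params$c1, 0)
  h2 <- pmax(drop(h1 %*% params$H2) + params$c2, 0)
  p <- 1 / (1 + exp(-(drop(h2 %*% params$w_out) + params$c_out)))
  expect_equal(fw$V_ks, vks, tolerance = 1e-6)
  expect_equal(fw$V_km, vkm, tolerance = 1e-6)
  expect_equal(fw$V_ksm, vksm, tolerance = 1e-6)
  expect_equal(fw$p, p, tolerance = 1e-6)
})

test_that("bce_loss worked examples and loop oracle", {
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-10)
  expect_equal(bce_loss(c(0.9, 0.1), c(1, 0)), -mean(log(c(0.9, 0.9))),
               tolerance = 1e-10)
  expect_error(bce_loss(c(0.5, 0.5), 1), "length")
  set.seed(3)
  p <- runif(50, 0.01, 0.99); y <- rbinom(50, 1, 0.5)
  acc <- 0
  for (i in 1:50) acc <- acc - (y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))
  expect_equal(bce_loss(p, y), acc / 50, tolerance = 1e-10)
  expect_gte(bce_loss(p, y), 0)
  ## approaches 0 as predictions approach labels
  expect_lt(bce_loss(c(1e-6, 1 - 1e-6), c(0, 1)), 1e-5)
})

test_that("analytic gradients match central finite differences", {
  set.seed(30)
  d <- 3L; db <- 4L; n <- 5L
  params <- init_classifier(d, d_b = db, seed = 11)
  K <- matrix(rnorm(n * d), n); S <- matrix(rnorm(n * d), n)
  M <- matrix(rnorm(n * d), n)
  y <- rbinom(n, 1, 0.5)
  fw <- ksmofinder:::.clf_forward(params, K, S, M, training = FALSE)
  g <- ksmofinder:::.clf_grads(params, K, S, M, y, fw)
  eps <- 1e-5
  loss_at <- function(p) {
    f <- ksmofinder:::.clf_forward(p, K, S, M, training = FALSE)
    bce_loss(f$p, y)
  }
  for (nm in ksmofinder:::.param_names) {
    v <- params[[nm]]
    idx <- sample(length(v), min(5L, length(v)))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      an <- as.numeric(g$grads[[nm]])[i]
      denom <- max(abs(fd), abs(an), 1e-8)
      expect_lt(abs(fd - an) / denom, 1e-4)
    }
  }
})

test_that("one small gradient step reduces the sample loss", {
  set.seed(14)
  d <- 3L; db <- 4L
  params <- init_classifier(d, d_b = db, seed = 21)
  K <- matrix(rnorm(d), 1L); S <- matrix(rnorm(d), 1L)
  M <- matrix(rnorm(d), 1L); y <- 1
  fw <- ksmofinder:::.clf_forward(params, K, S, M, training = FALSE)
  g <- ksmofinder:::.clf_grads(params, K, S, M, y, fw)
  lr <- 1e-3
  p2 <- params
  for (nm in ksmofinder:::.param_names) {
    gr <- g$grads[[nm]]
    if (is.matrix(p2[[nm]])) {
      gr <- matrix(as.numeric(gr), nrow(p2[[nm]]), ncol(p2[[nm]]))
    } else {
      gr <- as.numeric(gr)
    }
    p2[[nm]] <- p2[[nm]] - lr * gr
  }
  fw2 <- ksmofinder:::.clf_forward(p2, K, S, M, training = FALSE)
  expect_lt(bce_loss(fw2$p, y), g$loss)
})

test_that("prediction is order-preserving, pure and batch-invariant", {
  set.seed(17)
  ids <- c(sprintf("K%d", 1:5), sprintf("S%d", 1:5), sprintf("M%d", 1:5))
  emb <- toy_embeddings(ids, d = 6L, seed = 5)
  params <- init_classifier(6L, d_b = 5L, seed = 2)
  samples <- data.table(kinase = sample(sprintf("K%d", 1:5), 30L, TRUE),
                        substrate = sample(sprintf("S%d", 1:5), 30L, TRUE),
                        motif = sample(sprintf("M%d", 1:5), 30L, TRUE))
  p_all <- predict(params, emb, samples)
  p_one <- vapply(seq_len(30L), function(i)
    predict(params, emb, samples[i]), numeric(1))
  expect_equal(p_all, p_one, tolerance = 1e-6)
  p_b7 <- predict(params, emb, samples, batch_size = 7L)
  expect_equal(p_all, p_b7, tolerance = 1e-12)
  ## duplicated sample, duplicated probability
  dup <- rbind(samples[1], samples[1])
  expect_equal(predict(params, emb, dup)[1], predict(params, emb, dup)[2])
  bad <- data.table(kinase = "K1", substrate = "S1", motif = "NOPE")
  expect_error(predict(params, emb, bad), "index")
})

test_that("training recovers planted entity-level signal; permuted labels do not", {
  ## plant class flags on the first embedding coordinate of every entity;
  ## the label depends on all three entities, so recovery requires
  ## generalization to unseen (k, s, m) combinations
  set.seed(40)
  n <- 800L; d <- 8L
  kin <- sprintf("K%d", 1:10); subs <- sprintf("S%d", 1:20)
  mots <- sprintf("M%d", 1:40)
  ids <- c(kin, subs, mots)
  set.seed(6)
  E <- matrix(rnorm(length(ids) * d), length(ids),
              dimnames = list(ids, NULL))
  kin_flag <- setNames(sample(c(1, -1), 10L, TRUE), kin)
  mot_flag <- setNames(sample(c(1, -1), 40L, TRUE), mots)
  sub_flag <- setNames(sample(c(1, -1), 20L, TRUE), subs)
  E[kin, 1L] <- kin_flag; E[mots, 1L] <- mot_flag; E[subs, 1L] <- sub_flag
  emb <- embedding_table(E, algorithm = "random")
  samples <- data.table(kinase = sample(kin, n, TRUE),
                        substrate = sample(subs, n, TRUE),
                        motif = sample(mots, n, TRUE))
  samples[, label := as.integer(kin_flag[kinase] + mot_flag[motif] +
                                sub_flag[substrate] > 0)]
  idx <- sample(n, 200L)
  test <- samples[idx]; train <- samples[-idx]
  cfg <- clf_config(d_b = 8L, batch_size = 64L, max_epochs = 60L,
                    patience = 10L, seed = 3)
  model <- train_classifier(train, emb, cfg)
  auc <- roc_auc(predict(model, emb, test), test$label)
  expect_gt(auc, 0.65)
  ## determinism under identical config and seed
  model2 <- train_classifier(train, emb, cfg)
  expect_identical(model$W_ks, model2$W_ks)
  expect_identical(model$w_out, model2$w_out)
  ## no-signal control: permuted labels stay near chance
  set.seed(99)
  train_perm <- data.table::copy(train)[, label := sample(label)]
  m_perm <- train_classifier(train_perm, emb, cfg)
  auc_perm <- roc_auc(predict(m_perm, emb, test), test$label)
  expect_gt(auc_perm, 0.35)
  expect_lt(auc_perm, 0.65)
})
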