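## Scoring-quality evaluation: ROC-AUC and PR-AUC with fixed tie handling,
## percentile bootstrap confidence intervals, the easy-test filter based on
## similar kinases, and the random-embedding control experiment.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) computation with mean-rank tie handling:
#' equals the probability that a random positive outscores a random
#' negative, ties counted one half. Invariant under strictly monotone
#' score transforms.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average-precision rule: thresholds sweep the distinct score
#' values in decreasing order and the area is
#' `sum (R_i - R_{i-1}) * P_i`. Handling ties at the threshold level makes
#' the value independent of input order.
#'
#' @param scores numeric scores.
#' @param labels binary labels with at least one positive.
#' @return PR-AUC in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("at least one positive required", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  ## indices where the score changes next (threshold boundaries)
  last <- which(s != c(s[-1L], NA))
  last[length(last) + 1L] <- length(s)
  last <- unique(last)
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples (score, label) pairs with replacement `n_boot` times and
#' returns the 2.5th and 97.5th percentiles of the metric across
#' resamples. Degenerate resamples containing a single class are redrawn.
#'
#' @param scores,labels the evaluated predictions.
#' @param metric a function `(scores, labels) -> numeric`, e.g.
#'   [roc_auc()] or [pr_auc()].
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(scores, labels, metric = roc_auc, n_boot = 1000L,
                         seed = 1L, level = 0.95) {
  stopifnot(n_boot >= 1L)
  old <- .seed_state(seed)
  on.exit(.restore_seed(old), add = TRUE)
  n <- length(scores)
  vals <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) > 1L) break
    }
    vals[b] <- metric(scores[idx], labels[idx])
  }
  alpha <- (1 - level) / 2
  ci <- unname(quantile(vals, c(alpha, 1 - alpha), type = 7))
  c(low = ci[1L], high = ci[2L])
}

#' Evaluate predictions on a labelled test set
#'
#' Convenience wrapper computing ROC-AUC and PR-AUC with bootstrap
#' confidence intervals.
#'
#' @param scores,labels predictions and truth.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return List of class `ksmo_eval`: `roc_auc`, `pr_auc`, their CIs,
#'   class counts, `n_bootstrap`, `seed`.
#' @export
eval_report <- function(scores, labels, n_boot = 1000L, seed = 1L) {
  structure(list(
    roc_auc = roc_auc(scores, labels),
    pr_auc = pr_auc(scores, labels),
    roc_ci = bootstrap_ci(scores, labels, roc_auc, n_boot, seed),
    pr_ci = bootstrap_ci(scores, labels, pr_auc, n_boot, seed),
    n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
    n_bootstrap = n_boot, seed = seed
  ), class = "ksmo_eval")
}

#' @export
print.ksmo_eval <- function(x, ...) {
  cat(sprintf("ROC-AUC %.3f [%.3f, %.3f]  PR-AUC %.3f [%.3f, %.3f]  (+%d/-%d)\n",
              x$roc_auc, x$roc_ci[1L], x$roc_ci[2L],
              x$pr_auc, x$pr_ci[1L], x$pr_ci[2L], x$n_pos, x$n_neg))
  invisible(x)
}

#' Find similar kinase pairs from the knowledge graph
#'
#' Kinases sharing at least one family (`belongs_to_family`) or one domain
#' (`has_domain`) entity form a symmetric, irreflexive pair set.
#'
#' @param kg a `ksmo_kg`.
#' @return `data.table` with columns `kinase_a < kinase_b`, deduplicated.
#' @export
find_similar_kinases <- function(kg) {
  tr <- kg$triples[relation %in% c("belongs_to_family", "has_domain")]
  pairs_of <- function(members) {
    if (length(members) < 2L) return(NULL)
    m <- sort(unique(members))
    cmb <- utils::combn(m, 2L)
    data.table(kinase_a = cmb[1L, ], kinase_b = cmb[2L, ])
  }
  out <- rbindlist(
    lapply(split(tr$head, tr$tail), pairs_of))
  if (nrow(out) == 0L) {
    return(data.table(kinase_a = character(), kinase_b = character()))
  }
  unique(out)
}

#' Remove easy test scenarios
#'
#' A test sample `<k1, s, m, l>` is easy when some kinase `k2` similar to
#' `k1` occurs with the same motif `m` in the training data exclusively
#' with label `l`: the label is then already resolved by a near-duplicate.
#' If `(k2, m)` occurs in training with both labels the sample is kept.
#'
#' @param train training samples (`kinase`, `motif`, `label`).
#' @param test test samples.
#' @param similar symmetric pair table from [find_similar_kinases()].
#' @return List `hard_test` (filtered test table) and `n_removed`.
#' @export
filter_easy_tests <- function(train, test, similar) {
  train <- as.data.table(train); test <- as.data.table(test)
  similar <- as.data.table(similar)
  if (nrow(similar) == 0L || nrow(test) == 0L) {
    return(list(hard_test = test, n_removed = 0L))
  }
  ## training (kinase, motif) -> set of labels seen
  km <- train[, .(labs = list(sort(unique(label)))), by = .(kinase, motif)]
  km_key <- paste(km$kinase, km$motif, sep = "\r")
  km_env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(km_key)) assign(km_key[i], km$labs[[i]], envir = km_env)
  ## symmetric adjacency of similar kinases
  adj <- split(c(similar$kinase_b, similar$kinase_a),
               c(similar$kinase_a, similar$kinase_b))
  adj <- lapply(adj, unique)
  easy <- vapply(seq_len(nrow(test)), function(i) {
    k1 <- test$kinase[i]; m <- test$motif[i]; l <- test$label[i]
    for (k2 in adj[[k1]]) {
      labs <- get0(paste(k2, m, sep = "\r"), envir = km_env,
                   inherits = FALSE)
      if (!is.null(labs) && length(labs) == 1L && labs == l) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(hard_test = test[!easy], n_removed = sum(easy))
}

#' Random-embedding control experiment
#'
#' Assigns every kinase, substrate and motif in the bundle an independent
#' standard-normal vector, trains the classifier on the training split and
#' evaluates on both test sets. On an unbiased classification dataset the
#' balanced test set yields ROC-AUC near 0.5 and the natural-ratio test
#' set yields PR-AUC near the positive prevalence.
#'
#' @param bundle a `ksmo_bundle`.
#' @param dim embedding dimension (default 100).
#' @param config a `ksmo_clf_config` for the classifier training.
#' @param seed integer seed (controls embeddings, training and bootstrap).
#' @param n_boot bootstrap resamples for the confidence intervals.
#' @return List with `test1` and `test2` [eval_report()]s and the
#'   embeddings used.
#' @export
random_embedding_control <- function(bundle, dim = 100L,
                                     config = clf_config(), seed = 1L,
                                     n_boot = 1000L) {
  stopifnot(inherits(bundle, "ksmo_bundle"))
  all_samples <- rbind(bundle$train, bundle$test1, bundle$test2)
  entities <- unique(c(all_samples$kinase, all_samples$substrate,
                       all_samples$motif))
  emb <- random_embeddings(entities, dim = dim, seed = seed)
  config$seed <- seed
  model <- train_classifier(bundle, emb, config)
  p1 <- predict(model, emb, bundle$test1)
  p2 <- predict(model, emb, bundle$test2)
  list(
    test1 = eval_report(p1, bundle$test1$label, n_boot = n_boot, seed = seed),
    test2 = eval_report(p2, bundle$test2$label, n_boot = n_boot, seed = seed),
    embeddings = emb, model = model
  )
}
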