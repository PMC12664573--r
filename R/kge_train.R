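## Knowledge-graph embedding training: Adam minibatch optimization of a
## pairwise hinge objective over (positive, corrupted) triple pairs, with
## validation MRR early stopping and best-checkpoint return.

#' Embedding table constructor
#'
#' @param entities numeric matrix, one row per entity (rownames are the
#'   entity identifiers).
#' @param relations numeric matrix, one row per relation.
#' @param algorithm scoring model the vectors were trained for.
#' @return Object of class `ksmo_embeddings`.
#' @export
embedding_table <- function(entities, relations = NULL,
                            algorithm = c("transe", "distmult", "complex",
                                          "random")) {
  algorithm <- match.arg(algorithm)
  stopifnot(is.matrix(entities), !is.null(rownames(entities)))
  if (!is.null(relations)) {
    stopifnot(is.matrix(relations), !is.null(rownames(relations)),
              ncol(relations) == ncol(entities))
  }
  structure(
    list(entities = entities, relations = relations,
         dim = ncol(entities), algorithm = algorithm),
    class = "ksmo_embeddings"
  )
}

#' @export
print.ksmo_embeddings <- function(x, ...) {
  cat("Embeddings (", x$algorithm, "): ", nrow(x$entities), " entities",
      if (!is.null(x$relations)) paste0(", ", nrow(x$relations), " relations"),
      ", dimension ", x$dim, "\n", sep = "")
  invisible(x)
}

#' Look up entity vectors, erroring on missing identifiers
#' @param emb a `ksmo_embeddings`.
#' @param ids character vector of entity identifiers.
#' @return Numeric matrix of the requested rows.
#' @export
embedding_rows <- function(emb, ids) {
  miss <- setdiff(unique(ids), rownames(emb$entities))
  if (length(miss) > 0L) {
    stop("no embedding for entit", if (length(miss) == 1L) "y: " else "ies: ",
         paste(head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  emb$entities[ids, , drop = FALSE]
}

#' Seeded random embeddings
#'
#' Independent standard-normal vectors for every identifier; the control
#' representation used to check that a classification dataset carries no
#' exploitable bias on its own.
#'
#' @param entities character vector of entity identifiers.
#' @param dim embedding dimension (default 100).
#' @param seed integer seed.
#' @return A `ksmo_embeddings` with `algorithm = "random"`.
#' @export
random_embeddings <- function(entities, dim = 100L, seed = 1L) {
  entities <- unique(as.character(entities))
  old <- .seed_state(seed)
  on.exit(.restore_seed(old), add = TRUE)
  m <- matrix(rnorm(length(entities) * dim), nrow = length(entities),
              dimnames = list(entities, NULL))
  embedding_table(m, algorithm = "random")
}

#' KGE training configuration
#'
#' Defaults follow the training protocol of the embedding stage: dimension
#' 100, batch size 25000, Adam, pairwise hinge loss with one corruption
#' negative per positive, learning rate 1e-3, validation MRR evaluated
#' every 20 epochs with patience 2. The margin (1.0) and the epoch cap are
#' package defaults, not protocol constants.
#'
#' @param algorithm one of `"transe"`, `"distmult"`, `"complex"`.
#' @param dim embedding dimension.
#' @param batch_size minibatch size.
#' @param margin hinge margin.
#' @param negatives_per_positive corruption negatives per positive triple.
#' @param learning_rate Adam learning rate.
#' @param eval_every epochs between validation MRR evaluations.
#' @param patience consecutive non-improving evaluations before stopping.
#' @param max_epochs hard epoch cap.
#' @param filtered use filtered ranking (mask known true triples) for MRR.
#' @param seed integer seed.
#' @return List of class `ksmo_kge_config`.
#' @export
kge_config <- function(algorithm = c("transe", "distmult", "complex"),
                       dim = 100L, batch_size = 25000L, margin = 1,
                       negatives_per_positive = 1L, learning_rate = 1e-3,
                       eval_every = 20L, patience = 2L, max_epochs = 500L,
                       filtered = FALSE, seed = 1L) {
  if (identical(algorithm, "expressive") ||
      identical(tolower(algorithm[1L]), "expressive")) {
    stop("the ExpressivE scoring model is not implemented; ",
         "use transe, distmult or complex", call. = FALSE)
  }
  algorithm <- match.arg(algorithm)
  stopifnot(dim >= 1L, batch_size >= 1L, margin > 0,
            negatives_per_positive >= 1L, learning_rate > 0,
            eval_every >= 1L, patience >= 1L, max_epochs >= 1L)
  if (algorithm == "complex" && dim %% 2L != 0L) {
    stop("ComplEx needs an even dimension", call. = FALSE)
  }
  structure(as.list(environment()), class = "ksmo_kge_config")
}

#' Rank validation triples against all entities
#'
#' For each validation triple, both the head-replacement and the
#' tail-replacement rankings over all graph entities are computed with the
#' configured scorer. The true entity's rank is the realistic rank (mean
#' of optimistic and pessimistic under score ties); the mean reciprocal
#' rank (MRR) averages both sides of every triple.
#'
#' @param validation triple `data.table` (head/relation/tail).
#' @param emb a `ksmo_embeddings` with relation vectors.
#' @param kg a `ksmo_kg` supplying the candidate entity set (and the known
#'   triples to mask when `filtered = TRUE`).
#' @param filtered mask entities forming other known true triples.
#' @return List of class `ksmo_ranking`: `reciprocal_ranks` (one per
#'   triple-side), `mrr`.
#' @export
rank_triples <- function(validation, emb, kg, filtered = FALSE) {
  validation <- as.data.table(validation)
  stopifnot(nrow(validation) > 0L, inherits(emb, "ksmo_embeddings"),
            !is.null(emb$relations))
  entities <- kg_entities(kg)
  E <- embedding_rows(emb, entities)
  missr <- setdiff(unique(validation$relation), rownames(emb$relations))
  if (length(missr) > 0L) {
    stop("no embedding for relation(s): ", paste(missr, collapse = ", "),
         call. = FALSE)
  }
  ent_idx <- seq_along(entities)
  names(ent_idx) <- entities
  known <- if (filtered) {
    all_tr <- kg$triples
    list(
      by_rt = split(ent_idx[all_tr$head], paste(all_tr$relation, all_tr$tail)),
      by_hr = split(ent_idx[all_tr$tail], paste(all_tr$head, all_tr$relation))
    )
  } else NULL
  alg <- emb$algorithm
  rr <- numeric(2L * nrow(validation))
  for (i in seq_len(nrow(validation))) {
    h <- validation$head[i]; r <- validation$relation[i]
    t <- validation$tail[i]
    for (side in c("head", "tail")) {
      true_ent <- if (side == "head") h else t
      ti <- match(true_ent, entities)
      if (is.na(ti)) stop("entity not in graph: ", true_ent, call. = FALSE)
      scores <- .score_against_all(alg, E, emb$relations[r, ],
                                   fixed = embedding_rows(
                                     emb, if (side == "head") t else h)[1L, ],
                                   side = side)
      if (filtered) {
        mask <- if (side == "head") known$by_rt[[paste(r, t)]]
                else known$by_hr[[paste(h, r)]]
        mask <- setdiff(mask, ti)
        if (length(mask) > 0L) scores[mask] <- -Inf
      }
      s0 <- scores[ti]
      greater <- sum(scores > s0)
      ties <- sum(scores == s0)  # includes the true entity itself
      realistic <- greater + (ties + 1) / 2
      rr[2L * (i - 1L) + (side == "tail") + 1L] <- 1 / realistic
    }
  }
  structure(list(reciprocal_ranks = rr, mrr = mean(rr)),
            class = "ksmo_ranking")
}

## score all candidate entities substituted on `side`; `fixed` is the vector
## of the entity kept on the other side.
.score_against_all <- function(algorithm, E, r_vec, fixed, side) {
  n <- nrow(E)
  Rm <- matrix(r_vec, n, length(r_vec), byrow = TRUE)
  Fm <- matrix(fixed, n, length(fixed), byrow = TRUE)
  if (side == "head") .batch_score(algorithm, E, Rm, Fm)
  else .batch_score(algorithm, Fm, Rm, E)
}

#' Train knowledge-graph embeddings
#'
#' Minibatch Adam on the pairwise hinge objective
#' `max(0, margin + s(corrupted) - s(positive))`, one (by default)
#' corruption negative per positive. Validation MRR is evaluated every
#' `eval_every` epochs; after `patience` consecutive evaluations without
#' improvement training stops and the parameters of the best-MRR
#' checkpoint are returned. TransE entity rows are L2-normalized after
#' every update (the original translation-embedding recipe); the
#' initialization is uniform in `[-6/sqrt(d), 6/sqrt(d)]`.
#'
#' @param split a `ksmo_kg_split` from [split_kg()].
#' @param config a `ksmo_kge_config`.
#' @param verbose print the MRR trajectory.
#' @return A `ksmo_embeddings` carrying attributes `mrr_trajectory`
#'   (data.table epoch/mrr), `best_mrr` and `epochs_run`.
#' @export
train_kge <- function(split, config = kge_config(), verbose = FALSE) {
  stopifnot(inherits(split, "ksmo_kg_split"),
            inherits(config, "ksmo_kge_config"))
  train_tr <- split$train$triples
  if (nrow(train_tr) == 0L) stop("empty training set", call. = FALSE)
  entities <- sort(unique(c(train_tr$head, train_tr$tail,
                            split$validation$head, split$validation$tail)))
  relations <- sort(unique(c(train_tr$relation, split$validation$relation)))
  n_e <- length(entities); n_r <- length(relations); d <- config$dim
  ent_idx <- seq_len(n_e); names(ent_idx) <- entities
  rel_idx <- seq_len(n_r); names(rel_idx) <- relations

  hi <- ent_idx[train_tr$head]
  ri <- rel_idx[train_tr$relation]
  ti <- ent_idx[train_tr$tail]
  n_tr <- length(hi)

  old <- .seed_state(config$seed)
  on.exit(.restore_seed(old), add = TRUE)

  bound <- 6 / sqrt(d)
  E <- matrix(runif(n_e * d, -bound, bound), n_e)
  Rm <- matrix(runif(n_r * d, -bound, bound), n_r)
  if (config$algorithm == "transe") E <- E / sqrt(rowSums(E^2))

  ## Adam state
  mE <- vE <- matrix(0, n_e, d); mR <- vR <- matrix(0, n_r, d)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  lr <- config$learning_rate; margin <- config$margin
  nneg <- config$negatives_per_positive

  ## full KG (pre-split) used as candidate entity pool for validation MRR
  val_kg <- knowledge_graph(
    rbind(train_tr, split$validation),
    vocabulary = split$train$vocabulary)

  best <- list(mrr = -Inf, E = E, R = Rm, epoch = 0L)
  stale <- 0L
  traj <- list()
  epoch_loss <- numeric(config$max_epochs)
  do_eval <- nrow(split$validation) > 0L
  epochs_run <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n_tr)
    loss_sum <- 0; loss_n <- 0L
    starts <- seq(1L, n_tr, by = config$batch_size)
    for (s0 in starts) {
      idx <- perm[s0:min(s0 + config$batch_size - 1L, n_tr)]
      if (nneg > 1L) idx <- rep(idx, times = nneg)
      B <- length(idx)
      bh <- hi[idx]; br <- ri[idx]; bt <- ti[idx]
      ## corruption: uniform side, uniform replacement entity != original
      side_head <- runif(B) < 0.5
      repl <- sample.int(n_e, B, replace = TRUE)
      orig <- bt; orig[side_head] <- bh[side_head]
      coll <- which(repl == orig)
      while (length(coll) > 0L) {
        repl[coll] <- sample.int(n_e, length(coll), replace = TRUE)
        coll <- coll[repl[coll] == orig[coll]]
      }
      nh <- bh; nh[side_head] <- repl[side_head]
      nt <- bt; nt[!side_head] <- repl[!side_head]

      g <- .kge_batch_grads(config$algorithm, E, Rm, bh, br, bt, nh, nt,
                            margin)
      loss_sum <- loss_sum + (if (is.null(g)) 0 else g$loss_sum)
      loss_n <- loss_n + B
      if (is.null(g)) next  # no active pairs
      step <- step + 1L
      ## dense Adam over the full tables with sparse gradients
      gE <- matrix(0, n_e, d); gR <- matrix(0, n_r, d)
      for (part in g$ent_parts) {
        agg <- rowsum(part$grad, part$rows)
        ridx <- as.integer(rownames(agg))
        gE[ridx, ] <- gE[ridx, , drop = FALSE] + agg
      }
      agg_r <- rowsum(g$rel_grad, g$rel_rows)
      ridx <- as.integer(rownames(agg_r))
      gR[ridx, ] <- gR[ridx, , drop = FALSE] + agg_r
      gE <- gE / B; gR <- gR / B

      mE <- b1 * mE + (1 - b1) * gE; vE <- b2 * vE + (1 - b2) * gE^2
      mR <- b1 * mR + (1 - b1) * gR; vR <- b2 * vR + (1 - b2) * gR^2
      c1 <- 1 - b1^step; c2 <- 1 - b2^step
      E <- E - lr * (mE / c1) / (sqrt(vE / c2) + eps)
      Rm <- Rm - lr * (mR / c1) / (sqrt(vR / c2) + eps)
      if (config$algorithm == "transe") {
        E <- E / pmax(sqrt(rowSums(E^2)), 1e-12)
      }
    }
    epoch_loss[epoch] <- if (loss_n > 0L) loss_sum / loss_n else 0
    epochs_run <- epoch

    if (do_eval && epoch %% config$eval_every == 0L) {
      emb <- embedding_table(
        `rownames<-`(E, entities),
        `rownames<-`(Rm, relations),
        algorithm = config$algorithm)
      mrr <- rank_triples(split$validation, emb, val_kg,
                          filtered = config$filtered)$mrr
      traj[[length(traj) + 1L]] <- data.table(epoch = epoch, mrr = mrr)
      if (verbose) message("epoch ", epoch, " validation MRR ", round(mrr, 4))
      if (mrr > best$mrr) {
        best <- list(mrr = mrr, E = E, R = Rm, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
  }

  if (!do_eval || best$epoch == 0L) best <- list(mrr = NA_real_, E = E, R = Rm,
                                                 epoch = epochs_run)
  out <- embedding_table(
    `rownames<-`(best$E, entities),
    `rownames<-`(best$R, relations),
    algorithm = config$algorithm)
  attr(out, "mrr_trajectory") <- if (length(traj)) rbindlist(traj) else
    data.table(epoch = integer(), mrr = numeric())
  attr(out, "best_mrr") <- best$mrr
  attr(out, "epochs_run") <- epochs_run
  attr(out, "loss_curve") <- epoch_loss[seq_len(epochs_run)]
  out
}

## Gradients of the summed hinge loss over a batch of (positive, negative)
## pairs. Returns per-row gradient contributions grouped by parameter row
## (aggregated by the caller via rowsum), or NULL if no pair is active.
.kge_batch_grads <- function(algorithm, E, Rm, bh, br, bt, nh, nt, margin) {
  Rp <- Rm[br, , drop = FALSE]
  if (algorithm == "transe") {
    ## share the translation residuals between scoring and gradients
    Dp <- E[bh, , drop = FALSE] + Rp - E[bt, , drop = FALSE]
    Dn <- E[nh, , drop = FALSE] + Rp - E[nt, , drop = FALSE]
    lv <- pmax(0, margin - rowSums(abs(Dn)) + rowSums(abs(Dp)))
    a <- which(lv > 0)
    if (length(a) == 0L) return(NULL)
    sp <- sign(Dp[a, , drop = FALSE])
    sn <- sign(Dn[a, , drop = FALSE])
    sg <- list(dh = -sp, dr = -sp, dt = sp)
    sgn <- list(dh = -sn, dr = -sn, dt = sn)
    return(list(
      ent_parts = list(
        list(rows = bh[a], grad = -sg$dh),
        list(rows = bt[a], grad = -sg$dt),
        list(rows = nh[a], grad = sgn$dh),
        list(rows = nt[a], grad = sgn$dt)
      ),
      rel_rows = c(br[a], br[a]),
      rel_grad = rbind(-sg$dr, sgn$dr),
      loss_sum = sum(lv)
    ))
  }
  Hp <- E[bh, , drop = FALSE]
  Tp <- E[bt, , drop = FALSE]
  Hn <- E[nh, , drop = FALSE]; Tn <- E[nt, , drop = FALSE]
  s_pos <- .batch_score(algorithm, Hp, Rp, Tp)
  s_neg <- .batch_score(algorithm, Hn, Rp, Tn)
  lv <- pmax(0, margin + s_neg - s_pos)
  active <- which(lv > 0)
  if (length(active) == 0L) return(NULL)
  a <- active
  Hp <- Hp[a, , drop = FALSE]; Rp <- Rp[a, , drop = FALSE]
  Tp <- Tp[a, , drop = FALSE]
  Hn <- Hn[a, , drop = FALSE]; Tn <- Tn[a, , drop = FALSE]

  ## d(loss)/d(s_pos) = -1, d(loss)/d(s_neg) = +1 on active pairs
  sg <- .score_grads(algorithm, Hp, Rp, Tp)
  sgn <- .score_grads(algorithm, Hn, Rp, Tn)
  list(
    ent_parts = list(
      list(rows = bh[a], grad = -sg$dh),
      list(rows = bt[a], grad = -sg$dt),
      list(rows = nh[a], grad = sgn$dh),
      list(rows = nt[a], grad = sgn$dt)
    ),
    rel_rows = c(br[a], br[a]),
    rel_grad = rbind(-sg$dr, sgn$dr),
    loss_sum = sum(lv)
  )
}

## per-row gradients of the batched score wrt head/relation/tail rows
.score_grads <- function(algorithm, H, R, T) {
  switch(algorithm,
    transe = {
      s <- sign(H + R - T)
      list(dh = -s, dr = -s, dt = s)
    },
    distmult = list(dh = R * T, dr = H * T, dt = H * R),
    complex = {
      d <- ncol(H); i1 <- seq_len(d / 2L); i2 <- i1 + d / 2L
      hr <- H[, i1, drop = FALSE]; hi2 <- H[, i2, drop = FALSE]
      rr <- R[, i1, drop = FALSE]; ri <- R[, i2, drop = FALSE]
      tr <- T[, i1, drop = FALSE]; ti <- T[, i2, drop = FALSE]
      list(
        dh = cbind(rr * tr + ri * ti, rr * ti - ri * tr),
        dr = cbind(hr * tr + hi2 * ti, hr * ti - hi2 * tr),
        dt = cbind(hr * rr - hi2 * ri, hi2 * rr + hr * ri)
      )
    },
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
}

#' Serialize embeddings as TSV
#'
#' One row per identifier: the identifier followed by `d` floats printed
#' with 17 significant digits, so a round trip through
#' [read_embeddings()] is lossless well below 1e-7. Entity and relation
#' tables are written to separate files.
#'
#' @param emb a `ksmo_embeddings`.
#' @param path output path for the entity table; relations (if present) go
#'   to `paste0(path, ".relations")`.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  .write_emb_matrix(emb$entities, path)
  if (!is.null(emb$relations)) {
    .write_emb_matrix(emb$relations, paste0(path, ".relations"))
  }
  meta <- list(dim = emb$dim, algorithm = emb$algorithm,
               has_relations = !is.null(emb$relations))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

.write_emb_matrix <- function(m, path) {
  vals <- apply(m, 1L, function(row)
    paste(formatC(row, format = "g", digits = 17), collapse = "\t"))
  writeLines(paste(rownames(m), vals, sep = "\t"), path, useBytes = TRUE)
}

#' Read embeddings written by [write_embeddings()]
#' @param path path given to [write_embeddings()].
#' @return A `ksmo_embeddings`.
#' @export
read_embeddings <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  ents <- .read_emb_matrix(path)
  rels <- if (isTRUE(meta$has_relations)) {
    .read_emb_matrix(paste0(path, ".relations"))
  } else NULL
  embedding_table(ents, rels, algorithm = meta$algorithm)
}

.read_emb_matrix <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  ids <- dt[[1L]]
  m <- as.matrix(dt[, -1L])
  dimnames(m) <- list(ids, NULL)
  m
}
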