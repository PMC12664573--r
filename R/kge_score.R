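## Knowledge-graph embedding scoring functions. All three scorers map
## (head vector, relation vector, tail vector) to a real plausibility
## score, higher = more plausible. Batched forms take row-matrices.

#' TransE triple score
#'
#' Translation-based score: `-||h + r - t||_1`. A perfectly translated
#' triple scores 0; all other triples score negative.
#'
#' @param h_vec,r_vec,t_vec numeric vectors of equal dimension.
#' @return Scalar score.
#' @export
score_transe <- function(h_vec, r_vec, t_vec) {
  .check_dims(h_vec, r_vec, t_vec)
  -sum(abs(h_vec + r_vec - t_vec))
}

#' DistMult triple score
#'
#' Trilinear product `sum_i h_i r_i t_i`; symmetric in head and tail.
#'
#' @inheritParams score_transe
#' @return Scalar score.
#' @export
score_distmult <- function(h_vec, r_vec, t_vec) {
  .check_dims(h_vec, r_vec, t_vec)
  sum(h_vec * r_vec * t_vec)
}

#' ComplEx triple score
#'
#' Vectors of even raw dimension `d` are read as `d/2` complex coordinates
#' (first half real parts, second half imaginary parts). The score is
#' `Re(sum_i h_i r_i conj(t_i))`; with all imaginary parts zero this
#' reduces exactly to DistMult on the real parts.
#'
#' @inheritParams score_transe
#' @return Scalar score.
#' @export
score_complex <- function(h_vec, r_vec, t_vec) {
  .check_dims(h_vec, r_vec, t_vec)
  d <- length(h_vec)
  if (d %% 2L != 0L) {
    stop("ComplEx needs an even raw dimension, got ", d, call. = FALSE)
  }
  i1 <- seq_len(d / 2L)
  i2 <- i1 + d / 2L
  hr <- h_vec[i1]; hi <- h_vec[i2]
  rr <- r_vec[i1]; ri <- r_vec[i2]
  tr <- t_vec[i1]; ti <- t_vec[i2]
  sum(hr * rr * tr + hi * rr * ti + hr * ri * ti - hi * ri * tr)
}

.check_dims <- function(h, r, t) {
  if (length(h) != length(r) || length(r) != length(t)) {
    stop("dimension mismatch: ", length(h), "/", length(r), "/", length(t),
         call. = FALSE)
  }
  invisible(TRUE)
}

## Batched scorers: H, R, T are n x d matrices, return length-n vector.
.batch_score <- function(algorithm, H, R, T) {
  switch(algorithm,
    transe = -rowSums(abs(H + R - T)),
    distmult = rowSums(H * R * T),
    complex = {
      d <- ncol(H)
      i1 <- seq_len(d / 2L); i2 <- i1 + d / 2L
      rowSums(H[, i1, drop = FALSE] * R[, i1, drop = FALSE] * T[, i1, drop = FALSE] +
              H[, i2, drop = FALSE] * R[, i1, drop = FALSE] * T[, i2, drop = FALSE] +
              H[, i1, drop = FALSE] * R[, i2, drop = FALSE] * T[, i2, drop = FALSE] -
              H[, i2, drop = FALSE] * R[, i2, drop = FALSE] * T[, i1, drop = FALSE])
    },
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
}

#' Pairwise hinge loss
#'
#' `max(0, margin + neg_score - pos_score)`: zero once the positive triple
#' outscores the negative by at least the margin. Vectorized over pairs.
#'
#' @param pos_score,neg_score numeric score vectors (recycled pairwise).
#' @param margin positive margin, default 1.
#' @return Numeric vector of per-pair losses.
#' @export
hinge_loss <- function(pos_score, neg_score, margin = 1) {
  stopifnot(margin > 0)
  pmax(0, margin + neg_score - pos_score)
}

#' Corrupt a triple into negative triples
#'
#' Each negative replaces either the head or the tail (side chosen
#' uniformly) with an entity drawn uniformly from the graph's entities,
#' excluding the entity being replaced; the relation is kept.
#'
#' @param triple list or 1-row data.frame with `head`, `relation`, `tail`.
#' @param kg a `ksmo_kg` (or a character vector of candidate entities).
#' @param n number of negatives to draw.
#' @param seed optional integer seed.
#' @return `data.table` of `n` corrupted triples.
#' @export
corrupt <- function(triple, kg, n = 1L, seed = NULL) {
  stopifnot(n >= 1L)
  entities <- if (inherits(kg, "ksmo_kg")) kg_entities(kg) else as.character(kg)
  if (length(entities) < 2L) {
    stop("need at least 2 entities to corrupt", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- .seed_state(seed)
    on.exit(.restore_seed(old), add = TRUE)
  }
  h <- as.character(triple[["head"]])
  r <- as.character(triple[["relation"]])
  t <- as.character(triple[["tail"]])
  side <- sample(c("head", "tail"), n, replace = TRUE)
  repl <- vapply(side, function(s) {
    orig <- if (s == "head") h else t
    sample(setdiff(entities, orig), 1L)
  }, character(1))
  data.table(
    head = ifelse(side == "head", repl, h),
    relation = r,
    tail = ifelse(side == "tail", repl, t)
  )
}
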