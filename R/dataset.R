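## Supervised classification dataset construction: positive
## kinase-substrate_motif samples, the neg-ks / neg-km negative pools, the
## four-way negative generation with fallback, and the per-kinase 20%
## train/test split producing the balanced and natural-ratio test sets.

#' Load positive kinase-phosphosite samples
#'
#' Accepts kinase-phosphosite exports with columns `kinase`, `substrate`
#' and either a precomputed `motif` or a `site` position (in which case the
#' 9-mer is derived from the supplied substrate sequences). Rows carrying a
#' confidence score below `min_confidence` are dropped; rows without a
#' score (e.g. curated kinase-substrate exports) are kept. Duplicates of
#' the same (kinase, substrate, motif) collapse to one sample.
#'
#' @param tables a `data.frame` or list of data.frames to concatenate.
#' @param min_confidence minimum confidence score (default 1, the curation
#'   threshold used for integrated phosphosite resources).
#' @param sequences named character vector of substrate sequences, needed
#'   only when motifs must be derived from `site` positions.
#' @return `data.table` with columns `kinase`, `substrate`, `motif`,
#'   `label` (all 1).
#' @export
load_positives <- function(tables, min_confidence = 1, sequences = NULL) {
  if (is.data.frame(tables)) tables <- list(tables)
  dt <- rbindlist(lapply(tables, as.data.table), fill = TRUE)
  if (nrow(dt) == 0L) stop("no positive rows supplied", call. = FALSE)
  if ("confidence" %in% names(dt)) {
    dt <- dt[is.na(confidence) | confidence >= min_confidence]
  }
  if (!"motif" %in% names(dt)) dt[, motif := NA_character_]
  need <- which(is.na(dt$motif) | dt$motif == "")
  if (length(need) > 0L) {
    if (!"site" %in% names(dt)) {
      stop("rows without motifs need a `site` column", call. = FALSE)
    }
    subs <- unique(dt$substrate[need])
    unknown <- setdiff(subs, names(sequences))
    if (length(unknown) > 0L) {
      stop("no sequence for substrate(s): ",
           paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
    }
    dt$motif[need] <- mapply(function(s, p) extract_motif(sequences[[s]], p),
                             dt$substrate[need], dt$site[need])
  }
  out <- unique(dt[, .(kinase = as.character(kinase),
                       substrate = as.character(substrate),
                       motif = normalize_motif(motif))])
  centers <- substr(out$motif, 5L, 5L)
  if (any(!centers %in% c("S", "T", "Y"))) {
    stop("positive motif(s) without S/T/Y center", call. = FALSE)
  }
  out[, label := 1L]
  out[]
}

#' Construct an undirected protein-interaction evidence set
#'
#' Pairs are stored orientation-independently; self-pairs are dropped.
#' Confidence scores on the 0-999 integer dialect are normalized to 0-1.
#'
#' @param pairs `data.frame` with columns `protein_a`, `protein_b`,
#'   optional `source` tag and `confidence`.
#' @return `data.table` of class columns `protein_a < protein_b`, `source`,
#'   `confidence` in `[0, 1]`.
#' @export
interaction_set <- function(pairs) {
  dt <- as.data.table(pairs)
  stopifnot(all(c("protein_a", "protein_b") %in% names(dt)))
  if (!"source" %in% names(dt)) dt[, source := "unknown"]
  if (!"confidence" %in% names(dt)) dt[, confidence := 1]
  dt[, confidence := as.numeric(confidence)]
  if (any(dt$confidence > 1, na.rm = TRUE)) {
    dt[confidence > 1, confidence := confidence / 1000]
  }
  if (any(dt$confidence < 0 | dt$confidence > 1, na.rm = TRUE)) {
    stop("interaction confidence outside [0, 1] after normalization",
         call. = FALSE)
  }
  a <- pmin(dt$protein_a, dt$protein_b)
  b <- pmax(dt$protein_a, dt$protein_b)
  out <- data.table(protein_a = a, protein_b = b,
                    source = dt$source, confidence = dt$confidence)
  unique(out[protein_a != protein_b])
}

#' Build the negative kinase-substrate pool (neg-ks)
#'
#' Kinase/substrate pairs with no evidence of interaction: STRING-tagged
#' evidence below the confidence threshold is discarded first, then every
#' (kinase, substrate) combination absent from the union of the remaining
#' evidence (any source) is returned. Self-pairs are never emitted.
#'
#' @param kinases,substrates character vectors of identifiers.
#' @param interactions an [interaction_set()] table.
#' @param string_threshold minimum STRING confidence for a pair to count as
#'   evidence (default 0.75).
#' @return `data.table` with columns `kinase`, `substrate`.
#' @export
build_neg_ks <- function(kinases, substrates, interactions,
                         string_threshold = 0.75) {
  stopifnot(string_threshold >= 0, string_threshold <= 1)
  kinases <- unique(as.character(kinases))
  substrates <- unique(as.character(substrates))
  if (length(kinases) == 0L || length(substrates) == 0L) {
    stop("empty kinase or substrate list", call. = FALSE)
  }
  ev <- as.data.table(interactions)
  ev <- ev[!(tolower(source) == "string" & confidence < string_threshold)]
  ev_keys <- unique(c(paste(ev$protein_a, ev$protein_b, sep = "\r"),
                      paste(ev$protein_b, ev$protein_a, sep = "\r")))
  all_pairs <- CJ(kinase = kinases, substrate = substrates)[kinase != substrate]
  keep <- !(paste(all_pairs$kinase, all_pairs$substrate, sep = "\r") %chin%
              ev_keys)
  all_pairs[keep]
}

#' Build the negative kinase-motif pool (neg-km)
#'
#' Serine/threonine kinase-motif pairs whose specificity rank is at or
#' beyond `st_rank` (rank 1 = most favored), plus tyrosine kinase-motif
#' pairs at or below the `y_percentile` specificity percentile. Both
#' boundaries are inclusive.
#'
#' @param st_table `data.frame` with columns `kinase`, `motif`, `rank`
#'   (integers >= 1) for serine/threonine kinases.
#' @param y_table `data.frame` with columns `kinase`, `motif`,
#'   `percentile` (0-100) for tyrosine kinases.
#' @param st_rank rank threshold, default 150.
#' @param y_percentile percentile threshold, default 10.
#' @return `data.table` with columns `kinase`, `motif`.
#' @export
build_neg_km <- function(st_table, y_table, st_rank = 150,
                         y_percentile = 10) {
  st <- as.data.table(st_table)
  y <- as.data.table(y_table)
  if (nrow(st) > 0L) {
    stopifnot(all(c("kinase", "motif", "rank") %in% names(st)))
    if (any(st$rank < 1)) stop("ST ranks must be >= 1", call. = FALSE)
  }
  if (nrow(y) > 0L) {
    stopifnot(all(c("kinase", "motif", "percentile") %in% names(y)))
    if (any(y$percentile < 0 | y$percentile > 100)) {
      stop("Y percentiles must be in [0, 100]", call. = FALSE)
    }
  }
  both <- intersect(unique(st$kinase), unique(y$kinase))
  if (length(both) > 0L) {
    stop("kinase(s) present in both ST and Y specificity tables: ",
         paste(head(both, 5L), collapse = ", "), call. = FALSE)
  }
  neg_st <- if (nrow(st) > 0L) {
    st[rank >= st_rank, .(kinase = as.character(kinase),
                          motif = as.character(motif))]
  } else data.table(kinase = character(), motif = character())
  neg_y <- if (nrow(y) > 0L) {
    y[percentile <= y_percentile, .(kinase = as.character(kinase),
                                    motif = as.character(motif))]
  } else data.table(kinase = character(), motif = character())
  unique(rbind(neg_st, neg_y))
}

#' Generate negative classification samples
#'
#' For each positive `<k, s, m>`, one negative is attempted per method:
#' \enumerate{
#'   \item a random kinase `k'` with `(k', m)` in neg-km replaces the
#'     kinase;
#'   \item a random kinase `k''` with `(k'', s)` in neg-ks replaces the
#'     kinase;
#'   \item a random motif `m'` with `(k, m')` in neg-km and `(s, m')` in
#'     the substrate-motif registry replaces the motif;
#'   \item a random substrate `s'` with `(k, s')` in neg-ks and `(s', m)`
#'     in the registry replaces the substrate.
#' }
#' When method 3 or 4 has no candidate, the fallback draws a random sample
#' with a negative motif (any neg-km motif of `k` on any registry carrier)
#' or a negative substrate (any neg-ks substrate of `k` with any of its
#' registry motifs) of the kinase. Every emitted sample is a valid
#' registry substrate-motif pair, never equals a positive, and the emitted
#' set is deduplicated, so at most 4 negatives arise per positive.
#' Sampling is uniform over admissible candidates and seeded per positive
#' (a hash of the sample identifiers combined with `seed`), so the output
#' is independent of input order.
#'
#' @param positives positive samples (`kinase`, `substrate`, `motif`).
#' @param neg_ks neg-ks pool from [build_neg_ks()].
#' @param neg_km neg-km pool from [build_neg_km()].
#' @param registry substrate-motif registry (`substrate`, `motif`): the set
#'   of valid phosphosite pairs.
#' @param seed integer seed.
#' @param max_attempts resampling attempts when a candidate collides with a
#'   positive or an already-emitted negative (default 20), after which the
#'   method is skipped for that positive.
#' @return `data.table` with columns `kinase`, `substrate`, `motif`,
#'   `label` (all 0) and `method`; attribute `n_failed` counts positives
#'   that yielded no negative at all.
#' @export
generate_negatives <- function(positives, neg_ks, neg_km, registry,
                               seed = 1L, max_attempts = 20L) {
  pos <- as.data.table(positives)
  stopifnot(nrow(pos) > 0L)
  neg_ks <- as.data.table(neg_ks)
  neg_km <- as.data.table(neg_km)
  registry <- unique(as.data.table(registry)[, .(substrate = as.character(substrate),
                                                 motif = as.character(motif))])
  if (nrow(neg_ks) == 0L || nrow(neg_km) == 0L) {
    stop("neg-ks and neg-km pools must be non-empty", call. = FALSE)
  }

  ## hashed lookup structures
  km_by_motif <- list2env(split(neg_km$kinase, neg_km$motif), hash = TRUE)
  km_by_kinase <- list2env(split(neg_km$motif, neg_km$kinase), hash = TRUE)
  ks_by_substrate <- list2env(split(neg_ks$kinase, neg_ks$substrate),
                              hash = TRUE)
  ks_by_kinase <- list2env(split(neg_ks$substrate, neg_ks$kinase),
                           hash = TRUE)
  reg_by_substrate <- list2env(split(registry$motif, registry$substrate),
                               hash = TRUE)
  reg_by_motif <- list2env(split(registry$substrate, registry$motif),
                           hash = TRUE)
  km_pair <- .key_env(paste(neg_km$kinase, neg_km$motif, sep = "\r"))
  ks_pair <- .key_env(paste(neg_ks$kinase, neg_ks$substrate, sep = "\r"))
  pos_key <- .key_env(paste(pos$kinase, pos$substrate, pos$motif, sep = "\r"))
  emitted <- new.env(hash = TRUE, parent = emptyenv())

  cap <- 4L * nrow(pos)
  res_k <- character(cap); res_s <- character(cap); res_m <- character(cap)
  res_method <- integer(cap)
  n_out <- 0L
  n_failed <- 0L
  grab <- function(env, key) {
    v <- get0(key, envir = env, inherits = FALSE)
    if (is.null(v)) character(0) else v
  }
  base_seed <- as.integer(seed)

  for (i in seq_len(nrow(pos))) {
    k <- pos$kinase[i]; s <- pos$substrate[i]; m <- pos$motif[i]
    h <- .string_hash(paste(k, s, m, sep = "\r"))
    set.seed(bitwXor(h, base_seed) %% 2147483647L)
    any_emitted <- FALSE

    for (method in 1:4) {
      cand <- switch(method,
        grab(km_by_motif, m),                               # kinases
        grab(ks_by_substrate, s),                           # kinases
        {                                                   # motifs on s
          mm <- grab(reg_by_substrate, s)
          mm[vapply(paste(k, mm, sep = "\r"),
                    function(key) !is.null(get0(key, envir = km_pair,
                                                inherits = FALSE)),
                    logical(1), USE.NAMES = FALSE)]
        },
        {                                                   # carriers of m
          ss <- grab(reg_by_motif, m)
          ss[vapply(paste(k, ss, sep = "\r"),
                    function(key) !is.null(get0(key, envir = ks_pair,
                                                inherits = FALSE)),
                    logical(1), USE.NAMES = FALSE)]
        })

      mk_sample <- NULL
      if (length(cand) > 0L) {
        mk_sample <- switch(method,
          function(x) c(x, s, m), function(x) c(x, s, m),
          function(x) c(k, s, x), function(x) c(k, x, m))
      } else if (method == 3L) {
        ## fallback: random negative motif of k on any registry carrier
        mk_sample <- function(x) {
          carriers <- grab(reg_by_motif, x)
          if (length(carriers) == 0L) return(NULL)
          c(k, carriers[sample.int(length(carriers), 1L)], x)
        }
        cand <- grab(km_by_kinase, k)
      } else if (method == 4L) {
        ## fallback: random negative substrate of k with one of its motifs
        mk_sample <- function(x) {
          mm <- grab(reg_by_substrate, x)
          if (length(mm) == 0L) return(NULL)
          c(k, x, mm[sample.int(length(mm), 1L)])
        }
        cand <- grab(ks_by_kinase, k)
      }
      if (length(cand) == 0L) next

      for (attempt in seq_len(max_attempts)) {
        trial <- mk_sample(cand[sample.int(length(cand), 1L)])
        if (is.null(trial)) next
        key <- paste(trial[1L], trial[2L], trial[3L], sep = "\r")
        if (!is.null(get0(key, envir = pos_key, inherits = FALSE))) next
        if (!is.null(get0(key, envir = emitted, inherits = FALSE))) next
        assign(key, TRUE, envir = emitted)
        n_out <- n_out + 1L
        res_k[n_out] <- trial[1L]; res_s[n_out] <- trial[2L]
        res_m[n_out] <- trial[3L]; res_method[n_out] <- method
        any_emitted <- TRUE
        break
      }
    }
    if (!any_emitted) n_failed <- n_failed + 1L
  }
  if (n_failed > 0L) {
    message(n_failed, " positive(s) yielded no negative sample")
  }
  keep <- seq_len(n_out)
  out <- data.table(kinase = res_k[keep], substrate = res_s[keep],
                    motif = res_m[keep], label = 0L,
                    method = res_method[keep])
  setattr(out, "n_failed", n_failed)
  out[]
}

.key_env <- function(keys) {
  e <- new.env(hash = TRUE, parent = emptyenv(), size = max(29L, length(keys)))
  for (k in unique(keys)) assign(k, TRUE, envir = e)
  e
}

#' Per-kinase train/test split with balanced and natural-ratio test sets
#'
#' For every kinase, `round(test_fraction * n)` of its positives and,
#' separately, of its negatives are held out. The full held-out set is
#' Testing Dataset 2 (natural class ratio); Testing Dataset 1 keeps all
#' held-out positives plus an equal-size seeded uniform subsample of the
#' held-out negatives (1:1 ratio). A kinase contributing a single sample
#' stays entirely in training (with a warning).
#'
#' @param samples labelled samples (`kinase`, `substrate`, `motif`,
#'   `label`).
#' @param test_fraction held-out proportion per kinase and class
#'   (default 0.2).
#' @param seed integer seed.
#' @return Object of class `ksmo_bundle`: list with `train`, `test1`,
#'   `test2` sample tables and `split_seed`.
#' @export
split_per_kinase <- function(samples, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  dt <- as.data.table(samples)
  stopifnot(all(c("kinase", "substrate", "motif", "label") %in% names(dt)))
  both <- dt[, .(n = uniqueN(label)), by = .(kinase, substrate, motif)]
  if (any(both$n > 1L)) {
    stop("sample(s) present with both labels", call. = FALSE)
  }
  old <- .seed_state(seed)
  on.exit(.restore_seed(old), add = TRUE)

  dt <- dt[order(kinase, label, substrate, motif)]
  singletons <- dt[, .N, by = kinase][N == 1L, kinase]
  if (length(singletons) > 0L) {
    warning(length(singletons),
            " kinase(s) with a single sample kept entirely in training",
            call. = FALSE)
  }
  test_rows <- integer(0)
  groups <- split(seq_len(nrow(dt)), list(dt$kinase, dt$label), drop = TRUE)
  for (g in groups[order(names(groups))]) {
    kin <- dt$kinase[g[1L]]
    if (kin %in% singletons) next
    n_take <- round(test_fraction * length(g))
    if (n_take > 0L) test_rows <- c(test_rows, sample(g, n_take))
  }
  test_rows <- sort(test_rows)
  test2 <- dt[test_rows]
  train <- dt[-test_rows]

  pos_idx <- which(test2$label == 1L)
  neg_idx <- which(test2$label == 0L)
  n1 <- min(length(pos_idx), length(neg_idx))
  take_pos <- if (length(pos_idx) > n1) sort(sample(pos_idx, n1)) else pos_idx
  take_neg <- if (length(neg_idx) > n1) sort(sample(neg_idx, n1)) else neg_idx
  test1 <- test2[sort(c(take_pos, take_neg))]

  structure(list(train = train, test1 = test1, test2 = test2,
                 split_seed = as.integer(seed)),
            class = "ksmo_bundle")
}

#' @export
print.ksmo_bundle <- function(x, ...) {
  f <- function(s) sprintf("%d (+%d/-%d)", nrow(s), sum(s$label == 1L),
                           sum(s$label == 0L))
  cat("Classification bundle\n")
  cat("  train:", f(x$train), "\n")
  cat("  test1:", f(x$test1), "(balanced)\n")
  cat("  test2:", f(x$test2), "(natural ratio)\n")
  invisible(x)
}

#' Write classification samples as 4-column TSV
#' @param samples sample table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  dt <- as.data.table(samples)[, .(kinase, substrate, motif, label)]
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read classification samples written by [write_samples()]
#' @param path input path.
#' @return `data.table` with columns `kinase`, `substrate`, `motif`,
#'   `label`.
#' @export
read_samples <- function(path) {
  fread(path, sep = "\t", colClasses = list(
    character = c("kinase", "substrate", "motif"), integer = "label"))
}
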