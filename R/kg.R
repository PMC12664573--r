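## Typed knowledge graph: deduplicated triple store with a closed relation
## vocabulary, optional entity namespaces, leakage guard and the
## train/validation split used for embedding early stopping.

#' Construct a knowledge graph from a triple table
#'
#' Deduplicates the triples, validates the relation vocabulary and checks
#' the basic invariants (non-empty head/tail identifiers). The shipped
#' default vocabulary has no direct kinase-to-substrate relation, so a graph
#' over it can never encode a direct kinase/substrate protein link; that
#' association is only reachable through shared annotations and motifs.
#'
#' @param triples `data.frame`/`data.table` with columns `head`, `relation`,
#'   `tail` (or three unnamed columns in that order).
#' @param vocabulary allowed relation names; triples with relations outside
#'   it are rejected. Default [ksmo_relations()].
#' @param namespaces optional named character vector mapping entity
#'   identifiers to category tags (`protein`, `motif`, ...).
#' @return An object of class `ksmo_kg`: a list with the deduplicated
#'   `triples` table (keyed, sorted), the `vocabulary`, and `namespaces`.
#' @export
knowledge_graph <- function(triples, vocabulary = ksmo_relations(),
                            namespaces = NULL) {
  triples <- as.data.table(triples)
  if (ncol(triples) < 3L) stop("triple table needs 3 columns", call. = FALSE)
  if (!all(c("head", "relation", "tail") %in% names(triples))) {
    setnames(triples, 1:3, c("head", "relation", "tail"))
  }
  triples <- triples[, .(head = as.character(head),
                         relation = as.character(relation),
                         tail = as.character(tail))]
  if (nrow(triples) > 0L) {
    if (any(triples$head == "" | triples$tail == "")) {
      stop("empty head or tail entity identifier", call. = FALSE)
    }
    unknown <- setdiff(unique(triples$relation), vocabulary)
    if (length(unknown) > 0L) {
      stop("unknown relation(s): ", paste(head(unknown, 5L), collapse = ", "),
           "; configure `vocabulary` to override", call. = FALSE)
    }
  }
  triples <- unique(triples)
  setkey(triples, relation, head, tail)
  structure(
    list(triples = triples, vocabulary = vocabulary, namespaces = namespaces),
    class = "ksmo_kg"
  )
}

#' @export
print.ksmo_kg <- function(x, ...) {
  cat("Phosphorylation knowledge graph\n")
  cat("  triples:  ", nrow(x$triples), "\n")
  cat("  entities: ", length(kg_entities(x)), "\n")
  cat("  relations:", length(unique(x$triples$relation)), "of",
      length(x$vocabulary), "in vocabulary\n")
  invisible(x)
}

#' Distinct entities of a knowledge graph
#' @param kg a `ksmo_kg`.
#' @return Sorted character vector of entity identifiers.
#' @export
kg_entities <- function(kg) {
  sort(unique(c(kg$triples$head, kg$triples$tail)))
}

#' Triple counts per relation
#' @param kg a `ksmo_kg`.
#' @return `data.table` with columns `relation`, `n`.
#' @export
kg_relation_counts <- function(kg) {
  kg$triples[, .(n = .N), by = relation][order(relation)]
}

#' Read a knowledge graph from a tab-separated triple table
#'
#' Expects three tab-separated columns head/relation/tail, UTF-8, no
#' quoting; an optional header line `head<TAB>relation<TAB>tail` is
#' detected and skipped. Duplicated lines collapse to one triple.
#' Malformed lines (not exactly 3 fields) raise an error naming the line.
#'
#' @param path file path, or a character vector of paths whose contents are
#'   concatenated before deduplication.
#' @param vocabulary,namespaces passed to [knowledge_graph()].
#' @return A `ksmo_kg`.
#' @export
ingest_triples <- function(path, vocabulary = ksmo_relations(),
                           namespaces = NULL) {
  parts <- lapply(path, .read_triple_file)
  triples <- rbindlist(parts)
  if (nrow(triples) == 0L) {
    warning("no triples read from ", paste(path, collapse = ", "),
            "; returning empty graph", call. = FALSE)
  }
  knowledge_graph(triples, vocabulary = vocabulary, namespaces = namespaces)
}

.read_triple_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) {
    return(data.table(head = character(), relation = character(),
                      tail = character()))
  }
  start <- 1L
  if (identical(tolower(lines[1L]), "head\trelation\ttail")) start <- 2L
  lines <- lines[seq.int(start, length.out = max(0L, length(lines) - start + 1L))]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.table(head = character(), relation = character(),
                      tail = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    bad <- which(nf != 3L)[1L]
    stop("malformed triple line ", bad + start - 1L, " in ", path, ": '",
         lines[bad], "'", call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  data.table(head = m[, 1L], relation = m[, 2L], tail = m[, 3L])
}

#' Write a knowledge graph (or triple table) as sorted TSV
#'
#' Emits 3-column tab-separated output sorted by relation, head, tail so
#' that serializations are diffable and ingestion is idempotent.
#'
#' @param kg a `ksmo_kg` or a triple `data.frame`.
#' @param path output file path.
#' @param header write the `head/relation/tail` header line.
#' @return `path`, invisibly.
#' @export
write_triples <- function(kg, path, header = TRUE) {
  triples <- if (inherits(kg, "ksmo_kg")) kg$triples else as.data.table(kg)
  triples <- triples[order(relation, head, tail)]
  lines <- paste(triples$head, triples$relation, triples$tail, sep = "\t")
  if (header) lines <- c("head\trelation\ttail", lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Remove kinase-motif triples that leak classification positives
#'
#' Drops every `k_specific_motif` triple whose (kinase, motif) pair occurs
#' as the (kinase, motif) of a positive classification sample, so that the
#' embedding step never sees the supervised positives. All other triples
#' are untouched.
#'
#' @param kg a `ksmo_kg`.
#' @param positives `data.frame` with columns `kinase` and `motif`
#'   (classification samples; labels, if present, are ignored and all rows
#'   are treated as positives unless a `label` column exists, in which case
#'   only `label == 1` rows are used).
#' @return List with elements `kg` (guarded graph) and `n_removed`.
#' @export
apply_leakage_guard <- function(kg, positives) {
  stopifnot(inherits(kg, "ksmo_kg"))
  pos <- as.data.table(positives)
  if ("label" %in% names(pos)) pos <- pos[label == 1]
  if (nrow(pos) == 0L) return(list(kg = kg, n_removed = 0L))
  banned <- unique(pos[, .(head = as.character(kinase),
                           tail = as.character(motif))])
  tr <- kg$triples
  drop <- tr$relation == "k_specific_motif" &
    paste(tr$head, tr$tail, sep = "\r") %chin%
      paste(banned$head, banned$tail, sep = "\r")
  out <- knowledge_graph(tr[!drop], vocabulary = kg$vocabulary,
                         namespaces = kg$namespaces)
  list(kg = out, n_removed = sum(drop))
}

#' Split a knowledge graph into training triples and a validation set
#'
#' For each relation in `eval_relations`, samples `round(fraction * n)`
#' triples (at least 1 when the relation is populated and `fraction > 0`)
#' without replacement into the validation set; everything else stays in
#' the training graph. The split is exhaustive and disjoint:
#' `|train| + |validation| = |kg|`.
#'
#' @param kg a `ksmo_kg`.
#' @param eval_relations relation names eligible for validation sampling;
#'   each must be present in the graph.
#' @param fraction proportion sampled per eval relation (default 0.025).
#' @param seed integer seed; the split is reproducible.
#' @return An object of class `ksmo_kg_split`: list with `train` (a
#'   `ksmo_kg`), `validation` (triple `data.table`), `eval_relations`,
#'   `fraction`, `seed`.
#' @export
split_kg <- function(kg, eval_relations, fraction = 0.025, seed = 1L) {
  stopifnot(inherits(kg, "ksmo_kg"), fraction > 0, fraction < 1)
  present <- unique(kg$triples$relation)
  missing <- setdiff(eval_relations, present)
  if (length(missing) > 0L) {
    stop("eval relation(s) absent from graph: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tr <- kg$triples
  val_idx <- integer(0)
  old <- .seed_state(seed)
  on.exit(.restore_seed(old), add = TRUE)
  for (rel in sort(eval_relations)) {
    idx <- which(tr$relation == rel)
    n_take <- max(1L, round(fraction * length(idx)))
    val_idx <- c(val_idx, sample(idx, n_take))
  }
  validation <- tr[sort(val_idx)]
  train <- knowledge_graph(tr[-sort(val_idx)], vocabulary = kg$vocabulary,
                           namespaces = kg$namespaces)
  structure(
    list(train = train, validation = validation,
         eval_relations = eval_relations, fraction = fraction, seed = seed),
    class = "ksmo_kg_split"
  )
}

#' @export
print.ksmo_kg_split <- function(x, ...) {
  cat("KG split: ", nrow(x$train$triples), "training /",
      nrow(x$validation), "validation triples (fraction ", x$fraction,
      ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

## Seed helpers: run code under a fixed seed without clobbering the
## caller's RNG stream.
.seed_state <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

## Deterministic 31-bit string hash (polynomial, mod 2^31 - 1); used to
## derive per-record RNG substreams that are independent of input order.
.string_hash <- function(x) {
  m <- 2147483647
  vapply(x, function(s) {
    h <- 0
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% m
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}
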