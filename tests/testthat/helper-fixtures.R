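## Shared fixtures: tiny graphs, embeddings and worlds built in code.

library(data.table)

## a random 9-mer with S/T/Y center
rand_motif <- function(n = 1L) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  vapply(seq_len(n), function(i) {
    ch <- sample(aa, 9L, replace = TRUE)
    ch[5L] <- sample(c("S", "T", "Y"), 1L)
    paste(ch, collapse = "")
  }, character(1))
}

## small random triple table over a closed vocabulary
rand_triples <- function(n, n_entities = 20L,
                         relations = c("participating_pathway",
                                       "expressed_in", "has_domain")) {
  ents <- sprintf("E%03d", seq_len(n_entities))
  data.table(head = sample(ents, n, replace = TRUE),
             relation = sample(relations, n, replace = TRUE),
             tail = sample(ents, n, replace = TRUE))
}

## deterministic toy embeddings for a set of identifiers
toy_embeddings <- function(ids, d = 4L, relations = NULL, seed = 1L,
                           algorithm = "transe") {
  set.seed(seed)
  E <- matrix(rnorm(length(ids) * d), length(ids),
              dimnames = list(ids, NULL))
  R <- if (!is.null(relations)) {
    matrix(rnorm(length(relations) * d), length(relations),
           dimnames = list(relations, NULL))
  } else NULL
  embedding_table(E, R, algorithm = algorithm)
}

## a micro world for integration-style tests (fast to simulate)
micro_world <- function(seed = 1L, ...) {
  cf <- world_config(n_kinases = 6L, n_substrates = 40L, n_families = 3L,
                     n_pathways = 5L, n_tissues = 4L, n_components = 3L,
                     n_domains = 4L, sites_per_substrate = 4L,
                     regulators_per_substrate = 2L, seed = seed)
  extra <- list(...)
  for (nm in names(extra)) cf[[nm]] <- extra[[nm]]
  simulate_world(cf)
}

expect_setequal_dt <- function(a, b) {
  key_a <- do.call(paste, c(as.list(as.data.table(a)), sep = "\r"))
  key_b <- do.call(paste, c(as.list(as.data.table(b)), sep = "\r"))
  expect_setequal(key_a, key_b)
}
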