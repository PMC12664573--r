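## End-to-end orchestration: world/tables -> guarded KG -> embeddings ->
## negative pools -> classification bundle -> classifier -> evaluation.

#' Build the classification bundle from world-style inputs
#'
#' Runs the dataset-construction protocol: STRING-thresholded neg-ks,
#' rank/percentile-thresholded neg-km, four-way negative generation with
#' fallback, and the per-kinase 20% split.
#'
#' @param world a `ksmo_world` (or a list with `positives`,
#'   `interactions`, `st_table`, `y_table`, `registry`).
#' @param seed integer seed for negative generation and the split.
#' @param string_threshold STRING confidence threshold (default 0.75).
#' @param st_rank ST specificity rank threshold (default 150).
#' @param y_percentile Y specificity percentile threshold (default 10).
#' @param test_fraction held-out fraction per kinase (default 0.2).
#' @return A `ksmo_bundle`; the generated negatives are attached as
#'   attribute `negatives`.
#' @export
build_dataset <- function(world, seed = 1L, string_threshold = 0.75,
                          st_rank = 150, y_percentile = 10,
                          test_fraction = 0.2) {
  positives <- as.data.table(world$positives)
  kinases <- unique(c(world$st_table$kinase, world$y_table$kinase,
                      positives$kinase))
  substrates <- unique(world$registry$substrate)
  neg_ks <- build_neg_ks(kinases, substrates, world$interactions,
                         string_threshold = string_threshold)
  neg_km <- build_neg_km(world$st_table, world$y_table,
                         st_rank = st_rank, y_percentile = y_percentile)
  negatives <- generate_negatives(positives, neg_ks, neg_km,
                                  world$registry, seed = seed)
  samples <- rbind(positives[, .(kinase, substrate, motif, label)],
                   negatives[, .(kinase, substrate, motif, label)])
  bundle <- split_per_kinase(samples, test_fraction = test_fraction,
                             seed = seed)
  attr(bundle, "negatives") <- negatives
  bundle
}

#' Train knowledge-graph embeddings for a world
#'
#' Applies the leakage guard (positive kinase-motif pairs removed from
#' `k_specific_motif`), splits the guarded graph per eval relation and
#' trains the configured embedding model.
#'
#' @param world a `ksmo_world`.
#' @param positives the positive classification samples to guard against
#'   (defaults to the world's positives).
#' @param config a `ksmo_kge_config`.
#' @param eval_relations relations sampled into the validation set;
#'   defaults to the kinase/substrate/motif-facing relations present.
#' @param fraction validation fraction per relation (default 0.025).
#' @param verbose print the MRR trajectory.
#' @return A `ksmo_embeddings`.
#' @export
train_world_embeddings <- function(world, positives = world$positives,
                                   config = kge_config(),
                                   eval_relations = NULL,
                                   fraction = 0.025, verbose = FALSE) {
  guarded <- apply_leakage_guard(world$kg, positives)
  if (is.null(eval_relations)) {
    present <- unique(guarded$kg$triples$relation)
    eval_relations <- intersect(
      c("k_specific_motif", "has_motif", "belongs_to_family", "has_domain",
        residue_relations()),
      present)
  }
  split <- split_kg(guarded$kg, eval_relations, fraction = fraction,
                    seed = config$seed)
  train_kge(split, config, verbose = verbose)
}

#' Run the full prediction pipeline on a synthetic world
#'
#' Knowledge graph (leakage-guarded) -> embeddings -> classification
#' bundle -> bilinear classifier -> evaluation on both test sets.
#'
#' @param world a `ksmo_world`.
#' @param kge a `ksmo_kge_config` (ignored when
#'   `embeddings = "random"`).
#' @param clf a `ksmo_clf_config`.
#' @param embeddings `"kge"` (train on the guarded graph) or `"random"`
#'   (seeded standard-normal control vectors).
#' @param dim dimension of the random control embeddings.
#' @param seed integer seed for dataset construction.
#' @param n_boot bootstrap resamples in the reports.
#' @param bundle optionally, a prebuilt `ksmo_bundle` to reuse (so
#'   KGE and control runs share the exact same dataset).
#' @return List with `bundle`, `embeddings`, `model`, `test1`, `test2`
#'   ([eval_report()]s).
#' @export
run_pipeline <- function(world, kge = kge_config(), clf = clf_config(),
                         embeddings = c("kge", "random"), dim = 100L,
                         seed = 1L, n_boot = 1000L, bundle = NULL) {
  embeddings <- match.arg(embeddings)
  if (is.null(bundle)) bundle <- build_dataset(world, seed = seed)
  emb <- if (embeddings == "kge") {
    train_world_embeddings(world, config = kge)
  } else {
    all_samples <- rbind(bundle$train, bundle$test1, bundle$test2)
    random_embeddings(unique(c(all_samples$kinase, all_samples$substrate,
                               all_samples$motif)),
                      dim = dim, seed = clf$seed)
  }
  model <- train_classifier(bundle, emb, clf)
  p1 <- predict(model, emb, bundle$test1)
  p2 <- predict(model, emb, bundle$test2)
  list(bundle = bundle, embeddings = emb, model = model,
       test1 = eval_report(p1, bundle$test1$label, n_boot = n_boot,
                           seed = seed),
       test2 = eval_report(p2, bundle$test2$label, n_boot = n_boot,
                           seed = seed))
}
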