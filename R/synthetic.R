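## Seeded generator of a toy phosphorylation world: kinase families with
## position-specific motif preferences, substrates with phosphosites drawn
## from the profiles of their regulator kinases, functional annotation
## modules (pathways, tissues, cellular components), interaction evidence,
## and specificity tables derived from profile log-likelihoods. The planted
## structure makes every pipeline stage testable without downloads.

#' Synthetic world configuration
#'
#' @param n_kinases,n_substrates,n_families,n_pathways,n_tissues,n_components,n_domains
#'   entity counts (all >= 1).
#' @param sites_per_substrate phosphosites generated per substrate.
#' @param regulators_per_substrate distinct kinases regulating each
#'   substrate; sites are dealt round-robin among them and the assignment
#'   is load-balanced across kinases, so in the zero-bias limit no kinase
#'   carries a base-rate signal.
#' @param family_motif_bias sharpness of each family's positional residue
#'   preferences in `[0, 1]`; 0 = uniform (no motif signal).
#' @param functional_coupling probability that a true kinase-substrate
#'   pair is forced to share a pathway or cellular component.
#' @param interaction_noise fraction of spurious interaction edges added
#'   relative to the number of true pairs.
#' @param multi_kinase_prob probability a site gains a second kinase from
#'   the same family (phosphosites targeted by several kinases).
#' @param y_family_fraction fraction of families that are tyrosine-kinase
#'   families (the rest are serine/threonine).
#' @param st_rank_threshold specificity rank below which an ST
#'   kinase-motif pair is emitted as a `k_specific_motif` triple
#'   (mirrors the rank-150 negative threshold).
#' @param y_percentile_threshold specificity percentile at or above which
#'   a Y kinase-motif pair is emitted as favored.
#' @param seed integer seed.
#' @return List of class `ksmo_world_config`.
#' @export
world_config <- function(n_kinases = 50L, n_substrates = 1000L,
                         n_families = 10L, n_pathways = 25L,
                         n_tissues = 10L, n_components = 6L,
                         n_domains = 12L, sites_per_substrate = 15L,
                         regulators_per_substrate = 3L,
                         family_motif_bias = 0.8,
                         functional_coupling = 0.7,
                         interaction_noise = 0.05,
                         multi_kinase_prob = 0.27,
                         y_family_fraction = 0.25,
                         st_rank_threshold = 150L,
                         y_percentile_threshold = 90,
                         seed = 1L) {
  stopifnot(n_kinases >= 1L, n_substrates >= 1L, n_families >= 1L,
            n_pathways >= 1L, n_tissues >= 1L, n_components >= 1L,
            n_domains >= 1L, sites_per_substrate >= 1L,
            regulators_per_substrate >= 1L,
            family_motif_bias >= 0, family_motif_bias <= 1,
            functional_coupling >= 0, functional_coupling <= 1,
            interaction_noise >= 0, multi_kinase_prob >= 0,
            multi_kinase_prob <= 1)
  if (n_families > n_kinases) {
    stop("cannot have more families than kinases", call. = FALSE)
  }
  if (regulators_per_substrate > n_kinases) {
    stop("more regulators per substrate than kinases", call. = FALSE)
  }
  structure(as.list(environment()), class = "ksmo_world_config")
}

#' Named world presets
#'
#' `"small"` (20 kinases / 200 substrates) finishes a full pipeline run in
#' minutes on one CPU; `"default"` (50 / 1000) matches the data regime the
#' classification protocol assumes; `"stress"` covers the 430-kinase scale
#' of the human kinome.
#'
#' @param name one of `"small"`, `"default"`, `"stress"`.
#' @param seed integer seed stored in the config.
#' @return A `ksmo_world_config`.
#' @export
preset <- function(name, seed = 1L) {
  switch(name,
    small = world_config(n_kinases = 20L, n_substrates = 200L,
                         n_families = 5L, n_pathways = 10L, n_tissues = 6L,
                         n_components = 4L, n_domains = 6L,
                         sites_per_substrate = 6L, seed = seed),
    default = world_config(seed = seed),
    stress = world_config(n_kinases = 430L, n_substrates = 5000L,
                          n_families = 40L, n_pathways = 60L,
                          n_tissues = 20L, n_components = 8L,
                          n_domains = 50L, sites_per_substrate = 15L,
                          seed = seed),
    stop("unknown preset '", name, "'; available: small, default, stress",
         call. = FALSE)
  )
}

## the 20 standard residues (no pad, no X) used for generation
.std_aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate a toy phosphorylation world
#'
#' Generates, fully reproducibly under the config seed: kinases grouped
#' into families with position-specific residue-preference profiles;
#' substrates carrying phosphosites whose 9-mer motifs are drawn from the
#' profiles of their regulator kinases (centers forced to S/T or Y by
#' family class); pathway/tissue/component annotations with optional
#' forced co-membership of true kinase-substrate pairs; interaction
#' evidence (true pairs plus noise edges); ST rank and Y percentile
#' specificity tables derived from profile log-likelihoods; the
#' substrate-motif registry; knowledge-graph triples for every populated
#' relation; and the ground-truth event list (emitted for testing only --
#' the pipeline never reads it).
#'
#' @param config a `ksmo_world_config`.
#' @return Object of class `ksmo_world`: list with `kg` (a `ksmo_kg`),
#'   `positives`, `interactions`, `st_table`, `y_table`, `registry`,
#'   `truth`, `config`.
#' @export
simulate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "ksmo_world_config"))
  cf <- config
  old <- .seed_state(cf$seed)
  on.exit(.restore_seed(old), add = TRUE)

  kin <- sprintf("K%04d", seq_len(cf$n_kinases))
  sub <- sprintf("P%05d", seq_len(cf$n_substrates))
  fam <- sprintf("FAM%02d", seq_len(cf$n_families))
  pwy <- sprintf("PWY%03d", seq_len(cf$n_pathways))
  tis <- sprintf("TIS%02d", seq_len(cf$n_tissues))
  loc <- sprintf("LOC%02d", seq_len(cf$n_components))
  dom <- sprintf("DOM%02d", seq_len(cf$n_domains))

  ## family classes: Y-kinase families vs serine/threonine families
  n_y <- max(if (cf$n_families >= 2L) 1L else 0L,
             round(cf$y_family_fraction * cf$n_families))
  fam_class <- c(rep("Y", n_y), rep("ST", cf$n_families - n_y))
  fam_class <- setNames(sample(fam_class), fam)

  ## every family has >= 1 kinase; remaining kinases assigned uniformly
  kin_fam <- setNames(
    c(fam, sample(fam, cf$n_kinases - cf$n_families, replace = TRUE))[
      seq_len(cf$n_kinases)],
    kin)
  kin_class <- fam_class[kin_fam]
  names(kin_class) <- kin

  ## position-specific residue preference profiles (8 flank positions):
  ## bias 0 = uniform over the 20 residues
  A <- length(.std_aa)
  profiles <- lapply(setNames(fam, fam), function(f) {
    pref <- sample.int(A, 8L, replace = TRUE)
    p <- matrix((1 - cf$family_motif_bias) / A, A, 8L,
                dimnames = list(.std_aa, NULL))
    p[cbind(pref, 1:8)] <- p[cbind(pref, 1:8)] + cf$family_motif_bias
    p
  })

  ## one domain per family (domains may be shared across families);
  ## membership of the same domain makes kinases "similar"
  fam_dom <- setNames(sample(dom, cf$n_families, replace = TRUE), fam)

  ## annotation modules
  pick <- function(pool, n_min, n_max) {
    sample(pool, sample.int(n_max - n_min + 1L, 1L) + n_min - 1L)
  }
  kin_pwy <- lapply(setNames(kin, kin), function(k) pick(pwy, 1L, 2L))
  sub_pwy <- lapply(setNames(sub, sub), function(s) pick(pwy, 1L, 2L))
  kin_tis <- lapply(setNames(kin, kin), function(k) pick(tis, 1L, 2L))
  sub_tis <- lapply(setNames(sub, sub), function(s) pick(tis, 1L, 2L))
  kin_loc <- lapply(setNames(kin, kin), function(k) sample(loc, 1L))
  sub_loc <- lapply(setNames(sub, sub), function(s) sample(loc, 1L))

  ## regulator kinases per substrate and site generation
  fam_members <- split(kin, kin_fam)
  draw_motif <- function(k) {
    f <- kin_fam[[k]]
    p <- profiles[[f]]
    flank <- vapply(1:8, function(j) sample(.std_aa, 1L, prob = p[, j]),
                    character(1))
    center <- if (fam_class[[f]] == "Y") "Y" else sample(c("S", "T"), 1L)
    paste(c(flank[1:4], center, flank[5:8]), collapse = "")
  }
  ## second kinase for a multi-kinase site: drawn with probability
  ## proportional to each kinase's profile likelihood of the motif (and a
  ## compatible phosphoacceptor class). With strong bias this concentrates
  ## on the drawing kinase's own family; with bias 0 every
  ## class-compatible kinase is equally likely, so multi-kinase sites
  ## carry no family signal in the zero-bias world.
  second_kinase <- function(k, motif_chars) {
    center_y <- motif_chars[5L] == "Y"
    flank <- match(motif_chars[c(1:4, 6:9)], .std_aa)
    cand <- kin[kin != k &
                  (fam_class[kin_fam[kin]] == "Y") == center_y]
    if (length(cand) == 0L) return(NULL)
    fam_lik <- vapply(fam, function(f) {
      prod(profiles[[f]][cbind(flank, 1:8)])
    }, numeric(1))
    wgt <- fam_lik[kin_fam[cand]]
    cand[sample.int(length(cand), 1L, prob = wgt)]
  }

  ## load-balanced regulator assignment: every substrate gets the
  ## currently least-loaded kinases (random tie-break), keeping positives
  ## per kinase near-uniform so the zero-bias world has no kinase
  ## base-rate channel
  n_reg <- cf$regulators_per_substrate
  load <- setNames(numeric(cf$n_kinases), kin)
  res <- vector("list", cf$n_substrates)
  for (si in seq_len(cf$n_substrates)) {
    s <- sub[si]
    regs <- names(sort(load + runif(cf$n_kinases)))[seq_len(n_reg)]
    load[regs] <- load[regs] + 1
    rows_k <- character(0); rows_m <- character(0)
    for (site in seq_len(cf$sites_per_substrate)) {
      k <- regs[(site - 1L) %% n_reg + 1L]
      m <- draw_motif(k)
      rows_k <- c(rows_k, k); rows_m <- c(rows_m, m)
      if (runif(1L) < cf$multi_kinase_prob) {
        k2 <- second_kinase(k, strsplit(m, "", fixed = TRUE)[[1L]])
        if (!is.null(k2)) {
          rows_k <- c(rows_k, k2); rows_m <- c(rows_m, m)
        }
      }
    }
    res[[si]] <- data.table(kinase = rows_k, substrate = s, motif = rows_m)
  }
  positives <- unique(rbindlist(res))
  positives[, label := 1L]

  registry <- unique(positives[, .(substrate, motif)])
  motifs <- sort(unique(registry$motif))

  ## functional coupling: true pairs share a pathway or component
  true_pairs <- unique(positives[, .(kinase, substrate)])
  couple <- runif(nrow(true_pairs)) < cf$functional_coupling
  for (i in which(couple)) {
    k <- true_pairs$kinase[i]; s <- true_pairs$substrate[i]
    if (runif(1L) < 0.5) {
      shared <- sample(kin_pwy[[k]], 1L)
      sub_pwy[[s]] <- unique(c(sub_pwy[[s]], shared))
    } else {
      sub_loc[[s]] <- unique(c(sub_loc[[s]], kin_loc[[k]]))
    }
  }

  ## interaction evidence: every true pair plus noise edges
  src <- sample(c("string", "biogrid", "bioplex"), nrow(true_pairs),
                replace = TRUE)
  conf <- ifelse(src == "string", runif(nrow(true_pairs), 0.75, 1),
                 runif(nrow(true_pairs), 0.5, 1))
  inter <- data.table(protein_a = true_pairs$kinase,
                      protein_b = true_pairs$substrate,
                      source = src, confidence = conf)
  n_noise <- round(cf$interaction_noise * nrow(true_pairs))
  if (n_noise > 0L) {
    noise <- data.table(protein_a = sample(kin, n_noise, replace = TRUE),
                        protein_b = sample(sub, n_noise, replace = TRUE),
                        source = sample(c("string", "biogrid", "bioplex"),
                                        n_noise, replace = TRUE),
                        confidence = runif(n_noise, 0.4, 1))
    inter <- rbind(inter, noise)
  }
  interactions <- interaction_set(inter)

  ## specificity from profile log-likelihoods: rank 1 / high percentile =
  ## most favored motif of the kinase
  spec <- .specificity_tables(motifs, kin, kin_fam, kin_class, profiles,
                              fam_class)

  ## favored kinase-motif pairs become k_specific_motif triples
  st_fav <- spec$st[rank_ < cf$st_rank_threshold,
                    .(head = kinase, relation = "k_specific_motif",
                      tail = motif)]
  y_fav <- spec$y[percentile >= cf$y_percentile_threshold,
                  .(head = kinase, relation = "k_specific_motif",
                    tail = motif)]

  ann <- function(members, rel) {
    data.table(head = rep(names(members), lengths(members)),
               relation = rel, tail = unlist(members, use.names = FALSE))
  }
  triples <- rbindlist(list(
    ann(c(kin_pwy, sub_pwy), "participating_pathway"),
    ann(c(kin_tis, sub_tis), "expressed_in"),
    ann(c(kin_loc, sub_loc), "cellular_comp"),
    data.table(head = kin, relation = "belongs_to_family",
               tail = unname(kin_fam)),
    data.table(head = kin, relation = "has_domain",
               tail = unname(fam_dom[kin_fam])),
    registry[, .(head = substrate, relation = "has_motif", tail = motif)],
    st_fav, y_fav,
    encode_motifs(motifs)
  ))

  namespaces <- c(
    setNames(rep("protein", length(kin) + length(sub)), c(kin, sub)),
    setNames(rep("motif", length(motifs)), motifs),
    setNames(rep("pathway", length(pwy)), pwy),
    setNames(rep("tissue", length(tis)), tis),
    setNames(rep("component", length(loc)), loc),
    setNames(rep("family", length(fam)), fam),
    setNames(rep("domain", length(dom)), dom)
  )
  aa_nodes <- unique(triples[relation %in% residue_relations(), tail])
  namespaces <- c(namespaces,
                  setNames(rep("amino-acid-node", length(aa_nodes)),
                           aa_nodes))

  kg <- knowledge_graph(triples, namespaces = namespaces)

  structure(list(
    kg = kg,
    positives = positives[order(kinase, substrate, motif)],
    interactions = interactions,
    st_table = spec$st_out,
    y_table = spec$y_out,
    registry = registry[order(substrate, motif)],
    truth = list(events = copy(positives)[, label := NULL],
                 true_pairs = true_pairs,
                 kinase_family = kin_fam,
                 kinase_class = kin_class),
    config = cf
  ), class = "ksmo_world")
}

## log-likelihood of every motif under every kinase's family profile,
## converted to per-kinase ranks (ST) and percentiles (Y)
.specificity_tables <- function(motifs, kin, kin_fam, kin_class, profiles,
                                fam_class) {
  n_m <- length(motifs)
  chars <- matrix(unlist(strsplit(motifs, "", fixed = TRUE)), nrow = n_m,
                  byrow = TRUE)
  flank_idx <- match(chars[, c(1:4, 6:9), drop = FALSE], .std_aa)
  flank_idx <- matrix(flank_idx, n_m, 8L)
  centers <- chars[, 5L]
  fam_ll <- lapply(profiles, function(p) {
    lp <- log(p)
    ll <- numeric(n_m)
    for (j in 1:8) ll <- ll + lp[cbind(flank_idx[, j], j)]
    ll
  })
  ## center compatibility: matching phosphoacceptor class keeps the
  ## likelihood; mismatched class is heavily penalized
  center_ll <- function(class) {
    if (class == "Y") ifelse(centers == "Y", 0, log(1e-6))
    else ifelse(centers %in% c("S", "T"), log(0.5), log(1e-6))
  }

  st_list <- list(); y_list <- list()
  for (k in kin) {
    f <- kin_fam[[k]]
    ## per-kinase random tie-break jitter: in the zero-bias limit all
    ## log-likelihoods tie, and a deterministic tie-break would give every
    ## kinase the same favored set (a spurious, shared hub structure)
    ll <- fam_ll[[f]] + center_ll(fam_class[[f]]) + runif(n_m) * 1e-9
    if (kin_class[[k]] == "ST") {
      r <- frank(-ll, ties.method = "first")
      st_list[[k]] <- data.table(kinase = k, motif = motifs, rank_ = r)
    } else {
      pct <- 100 * (frank(ll, ties.method = "average") - 0.5) / n_m
      y_list[[k]] <- data.table(kinase = k, motif = motifs,
                                percentile = pct)
    }
  }
  st <- rbindlist(st_list)
  y <- if (length(y_list)) rbindlist(y_list) else
    data.table(kinase = character(), motif = character(),
               percentile = numeric())
  list(st = st, y = y,
       st_out = if (nrow(st)) setnames(copy(st), "rank_", "rank") else
         data.table(kinase = character(), motif = character(),
                    rank = integer()),
       y_out = copy(y))
}

#' @export
print.ksmo_world <- function(x, ...) {
  cat("Synthetic phosphorylation world (seed ", x$config$seed, ")\n",
      sep = "")
  cat("  kinases/substrates: ", x$config$n_kinases, "/",
      x$config$n_substrates, "\n", sep = "")
  cat("  positives:", nrow(x$positives), " registry:", nrow(x$registry),
      " KG triples:", nrow(x$kg$triples), "\n")
  invisible(x)
}

#' Write a synthetic world as plain-text tables
#'
#' Emits the exact TSV dialects the ingestion functions consume:
#' `kg_triples.tsv`, `positives.tsv`, `interactions.tsv`,
#' `st_specificity.tsv`, `y_specificity.tsv`, `registry.tsv` and
#' `truth_events.tsv`. Output is sorted, so identical configs produce
#' byte-identical files.
#'
#' @param world a `ksmo_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_triples(world$kg, file.path(dir, "kg_triples.tsv"))
  fwrite(world$positives[order(kinase, substrate, motif)],
         file.path(dir, "positives.tsv"), sep = "\t")
  fwrite(world$interactions[order(protein_a, protein_b, source)],
         file.path(dir, "interactions.tsv"), sep = "\t")
  fwrite(world$st_table[order(kinase, motif)],
         file.path(dir, "st_specificity.tsv"), sep = "\t")
  fwrite(world$y_table[order(kinase, motif)],
         file.path(dir, "y_specificity.tsv"), sep = "\t")
  fwrite(world$registry[order(substrate, motif)],
         file.path(dir, "registry.tsv"), sep = "\t")
  fwrite(world$truth$events[order(kinase, substrate, motif)],
         file.path(dir, "truth_events.tsv"), sep = "\t")
  invisible(dir)
}
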