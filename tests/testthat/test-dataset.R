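test_that("load_positives applies the confidence threshold and dedups", {
  tab <- data.table(
    kinase = c("K1", "K1", "K2", "K2"),
    substrate = c("S1", "S1", "S2", "S2"),
    motif = c("AAAASAAAA", "AAAASAAAA", "CCCCTCCCC", "CCCCYCCCC"),
    confidence = c(2, 2, 0.5, NA))
  out <- load_positives(tab, min_confidence = 1)
  ## row 2 duplicates row 1; row 3 fails the threshold; row 4 has no
  ## score and is kept
  expect_equal(nrow(out), 2L)
  expect_true(all(out$label == 1L))
  expect_setequal(out$motif, c("AAAASAAAA", "CCCCYCCCC"))
})

test_that("load_positives derives motifs from site positions", {
  seqs <- c(S1 = "MKKKSAAAAPPS")
  tab <- data.frame(kinase = "K1", substrate = "S1", site = 5)
  out <- load_positives(tab, sequences = seqs)
  expect_equal(out$motif, extract_motif(seqs[["S1"]], 5L))
  expect_error(load_positives(data.frame(kinase = "K", substrate = "S9",
                                         site = 1)),
               "S9")
})

test_that("load_positives survivors equal the row-wise filter oracle", {
  set.seed(13)
  n <- 300L
  tab <- data.table(kinase = sample(sprintf("K%d", 1:10), n, TRUE),
                    substrate = sample(sprintf("S%d", 1:20), n, TRUE),
                    motif = sample(rand_motif(40L), n, TRUE),
                    confidence = sample(c(NA, 0.2, 0.5, 1, 2), n, TRUE))
  out <- load_positives(tab, min_confidence = 1)
  oracle <- unique(tab[is.na(confidence) | confidence >= 1,
                       .(kinase, substrate, motif)])
  expect_equal(nrow(out), nrow(oracle))
})

test_that("interaction_set normalizes scales and orientation", {
  raw <- data.frame(protein_a = c("B", "A", "C"),
                    protein_b = c("A", "B", "C"),
                    source = "string",
                    confidence = c(900, 0.9, 500))
  out <- interaction_set(raw)
  ## self-pair dropped; (A,B) stored once per distinct confidence scale
  expect_true(all(out$protein_a < out$protein_b))
  expect_true(all(out$confidence >= 0 & out$confidence <= 1))
  expect_false(any(out$protein_a == out$protein_b))
})

test_that("build_neg_ks is the complement of thresholded evidence", {
  inter <- interaction_set(data.frame(
    protein_a = c("K1", "K2"), protein_b = c("S1", "S2"),
    source = c("biogrid", "string"), confidence = c(1, 0.6)))
  neg <- build_neg_ks(c("K1", "K2"), c("S1", "S2"), inter,
                      string_threshold = 0.75)
  ## (K1,S1) is evidence; (K2,S2) is STRING below threshold, so treated
  ## as non-interacting
  expect_setequal_dt(neg, data.table(kinase = c("K1", "K2", "K2"),
                                     substrate = c("S2", "S1", "S2")))
  expect_error(build_neg_ks(character(0), "S1", inter), "empty")
})

test_that("build_neg_ks equals the set-algebra oracle on random input", {
  set.seed(77)
  kin <- sprintf("K%d", 1:8); sub <- sprintf("S%d", 1:15)
  ev <- data.frame(protein_a = sample(kin, 40L, TRUE),
                   protein_b = sample(sub, 40L, TRUE),
                   source = sample(c("string", "biogrid", "bioplex"),
                                   40L, TRUE),
                   confidence = runif(40L))
  inter <- interaction_set(ev)
  neg <- build_neg_ks(kin, sub, inter, string_threshold = 0.75)
  ## oracle: brute-force over all pairs
  kept_ev <- inter[!(source == "string" & confidence < 0.75)]
  ev_keys <- c(paste(kept_ev$protein_a, kept_ev$protein_b),
               paste(kept_ev$protein_b, kept_ev$protein_a))
  oracle <- data.table(expand.grid(kinase = kin, substrate = sub,
                                   stringsAsFactors = FALSE))
  oracle <- oracle[!(paste(kinase, substrate) %in% ev_keys)]
  expect_setequal_dt(neg, oracle)
})

test_that("build_neg_km boundary semantics are inclusive as specified", {
  st <- data.frame(kinase = "KST", motif = c("M1", "M2", "M3"),
                   rank = c(149L, 150L, 151L))
  y <- data.frame(kinase = "KY", motif = c("M1", "M2", "M3"),
                  percentile = c(9.9, 10.0, 10.1))
  neg <- build_neg_km(st, y)
  ## ST: rank >= 150 selected; Y: percentile <= 10 selected
  expect_setequal_dt(neg, data.table(
    kinase = c("KST", "KST", "KY", "KY"),
    motif = c("M2", "M3", "M1", "M2")))
  ## a kinase cannot be in both classes
  expect_error(build_neg_km(data.frame(kinase = "KY", motif = "M",
                                       rank = 1L), y),
               "both")
})

test_that("build_neg_km equals the row-wise threshold oracle", {
  set.seed(19)
  st <- data.table(kinase = rep(sprintf("A%d", 1:5), each = 30L),
                   motif = rep(sprintf("M%d", 1:30), 5L),
                   rank = sample(1:300, 150L, TRUE))
  y <- data.table(kinase = rep(sprintf("B%d", 1:3), each = 30L),
                  motif = rep(sprintf("M%d", 1:30), 3L),
                  percentile = runif(90L, 0, 100))
  neg <- build_neg_km(st, y)
  oracle <- rbind(st[rank >= 150, .(kinase, motif)],
                  y[percentile <= 10, .(kinase, motif)])
  expect_setequal_dt(neg, unique(oracle))
})

## a small closed universe for negative-generation tests
neg_fixture <- function() {
  positives <- data.table(
    kinase = c("K1", "K2"), substrate = c("S1", "S2"),
    motif = c("M1", "M2"), label = 1L)
  registry <- data.table(
    substrate = c("S1", "S1", "S2", "S3"),
    motif = c("M1", "M3", "M2", "M1"))
  neg_km <- data.table(
    kinase = c("K3", "K1", "K3"),
    motif = c("M1", "M3", "M2"))
  neg_ks <- data.table(
    kinase = c("K4", "K1", "K2"),
    substrate = c("S1", "S3", "S3"))
  list(positives = positives, registry = registry, neg_km = neg_km,
       neg_ks = neg_ks)
}

test_that("generate_negatives attains four negatives when pools allow", {
  fx <- neg_fixture()
  out <- generate_negatives(fx$positives[1L], fx$neg_ks, fx$neg_km,
                            fx$registry, seed = 1)
  ## positive <K1,S1,M1>: method 1 -> (K3,S1,M1); method 2 -> (K4,S1,M1);
  ## method 3 -> (K1,S1,M3); method 4 -> (K1,S3,M1)
  expect_equal(nrow(out), 4L)
  expect_setequal_dt(out[, .(kinase, substrate, motif)],
                     data.table(kinase = c("K3", "K4", "K1", "K1"),
                                substrate = c("S1", "S1", "S1", "S3"),
                                motif = c("M1", "M1", "M3", "M1")))
  expect_true(all(out$label == 0L))
})

test_that("generated negatives are admissible, deduplicated and positive-free", {
  w <- micro_world(seed = 6)
  neg_ks <- build_neg_ks(unique(w$positives$kinase),
                         unique(w$registry$substrate), w$interactions)
  neg_km <- build_neg_km(w$st_table, w$y_table)
  out <- generate_negatives(w$positives, neg_ks, neg_km, w$registry,
                            seed = 3)
  expect_lte(nrow(out), 4L * nrow(w$positives))
  key <- paste(out$kinase, out$substrate, out$motif)
  expect_false(anyDuplicated(key) > 0L)
  pos_key <- paste(w$positives$kinase, w$positives$substrate,
                   w$positives$motif)
  expect_length(intersect(key, pos_key), 0L)
  ## registry invariant: every emitted (s, m) is a valid phosphosite pair
  reg_key <- paste(w$registry$substrate, w$registry$motif)
  expect_true(all(paste(out$substrate, out$motif) %in% reg_key))
  ## admissibility oracle per method
  km_key <- paste(neg_km$kinase, neg_km$motif)
  ks_key <- paste(neg_ks$kinase, neg_ks$substrate)
  expect_true(all(paste(out$kinase[out$method == 1L],
                        out$motif[out$method == 1L]) %in% km_key))
  expect_true(all(paste(out$kinase[out$method == 2L],
                        out$substrate[out$method == 2L]) %in% ks_key))
  ## methods 3/4 (incl. fallback): negative motif or substrate of the kinase
  expect_true(all(paste(out$kinase[out$method == 3L],
                        out$motif[out$method == 3L]) %in% km_key))
  expect_true(all(paste(out$kinase[out$method == 4L],
                        out$substrate[out$method == 4L]) %in% ks_key))
  ## every negative satisfies the defining disjunction
  expect_true(all(paste(out$kinase, out$substrate) %in% ks_key |
                  paste(out$kinase, out$motif) %in% km_key))
})

test_that("negative generation is a pure function of inputs and seed", {
  w <- micro_world(seed = 9)
  neg_ks <- build_neg_ks(unique(w$positives$kinase),
                         unique(w$registry$substrate), w$interactions)
  neg_km <- build_neg_km(w$st_table, w$y_table)
  a <- generate_negatives(w$positives, neg_ks, neg_km, w$registry, seed = 5)
  b <- generate_negatives(w$positives, neg_ks, neg_km, w$registry, seed = 5)
  expect_identical(a, b)
  ## per-positive hashed substreams: the primary draw for a positive does
  ## not depend on input order (cross-positive dedup can still differ, so
  ## compare on a collision-free single positive)
  shuf <- w$positives[sample(.N)]
  one <- w$positives[5L]
  a1 <- generate_negatives(one, neg_ks, neg_km, w$registry, seed = 5)
  idx <- which(shuf$kinase == one$kinase & shuf$substrate == one$substrate &
               shuf$motif == one$motif)
  a2 <- generate_negatives(shuf[idx], neg_ks, neg_km, w$registry, seed = 5)
  expect_identical(a1, a2)
  ## different seed, different draws (overwhelmingly)
  d_ <- generate_negatives(w$positives, neg_ks, neg_km, w$registry,
                           seed = 6)
  expect_false(identical(a[, .(kinase, substrate, motif)],
                         d_[, .(kinase, substrate, motif)]))
})

test_that("split_per_kinase holds out 20% per kinase and class", {
  set.seed(1)
  samples <- rbind(
    data.table(kinase = "K1", substrate = sprintf("S%d", 1:10),
               motif = sprintf("MP%d", 1:10), label = 1L),
    data.table(kinase = "K1", substrate = sprintf("S%d", 1:40),
               motif = sprintf("MN%d", 1:40), label = 0L))
  b <- split_per_kinase(samples, test_fraction = 0.2, seed = 2)
  expect_equal(sum(b$test2$label == 1L), 2L)
  expect_equal(sum(b$test2$label == 0L), 8L)
  ## partition
  expect_equal(nrow(b$train) + nrow(b$test2), nrow(samples))
  key_tr <- paste(b$train$kinase, b$train$substrate, b$train$motif)
  key_te <- paste(b$test2$kinase, b$test2$substrate, b$test2$motif)
  expect_length(intersect(key_tr, key_te), 0L)
  ## test1 balanced for any seed
  for (s in c(7L, 8L)) {
    bs <- split_per_kinase(samples, test_fraction = 0.2, seed = s)
    expect_equal(sum(bs$test1$label == 1L), sum(bs$test1$label == 0L))
    expect_true(all(paste(bs$test1$kinase, bs$test1$substrate,
                          bs$test1$motif) %in%
                    paste(bs$test2$kinase, bs$test2$substrate,
                          bs$test2$motif)))
  }
})

test_that("single-sample kinases stay in training with a warning", {
  samples <- data.table(kinase = c("K1", "K2", "K2", "K2", "K2", "K2",
                                   "K2", "K2", "K2", "K2", "K2"),
                        substrate = sprintf("S%d", 1:11),
                        motif = sprintf("M%d", 1:11),
                        label = c(1L, rep(c(1L, 0L), length.out = 10L)))
  expect_warning(b <- split_per_kinase(samples, seed = 1), "single")
  expect_true("K1" %in% b$train$kinase)
  expect_false("K1" %in% b$test2$kinase)
})

test_that("samples with both labels are rejected", {
  samples <- data.table(kinase = "K1", substrate = "S1", motif = "M1",
                        label = c(0L, 1L))
  expect_error(split_per_kinase(samples, seed = 1), "both labels")
})

test_that("sample TSV round trip preserves the table", {
  w <- micro_world(seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_samples(w$positives, path)
  back <- read_samples(path)
  expect_equal(back, w$positives[, .(kinase, substrate, motif, label)])
})
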