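# ksmofinder

Kinase–substrate–motif prediction from a phosphorylation knowledge
graph, for computational biologists studying kinase signaling and
phosphoproteomics.

Most kinase–substrate predictors score only the phosphosite motif — the
9-mer of four residues either side of the phosphoacceptor (S/T/Y) — and
ignore whether the kinase and the substrate protein plausibly meet:
shared pathways, complexes, compartments, tissues. `ksmofinder`
implements a *substrate_motif*-level predictor that combines both. A
sample is ⟨k, s, m⟩ — kinase, substrate protein, 9-mer motif — and the
model outputs P(k phosphorylates site m on s).

## Method

1. **Phosphorylation knowledge graph.** Typed triples (h, r, t) over a
   closed 32-relation vocabulary: protein annotations
   (`participating_pathway`, `bio_process`, `cellular_comp`,
   `expressed_in`, ...), kinase classification (`belongs_to_family`,
   `has_domain`, ...), kinase specificity (`k_specific_motif`),
   substrate sites (`has_motif`), and per-position motif composition —
   a motif node connects to nine amino-acid nodes, e.g.
   `SSPSTPVGS | residue_5 | aa_T`. There is no direct kinase→substrate
   relation, and a leakage guard strips every `k_specific_motif` edge
   matching a supervised positive.
2. **Knowledge-graph embeddings.** TransE (−‖h + r − t‖₁), DistMult
   (Σ hᵢrᵢtᵢ) or ComplEx (Re Σ hᵢrᵢt̄ᵢ), dimension 100, pairwise hinge
   loss with uniform corruption negatives, Adam, early stopping on
   validation mean reciprocal rank (evaluated every 20 epochs,
   patience 2, best checkpoint returned).
3. **Biologically motivated negatives.** Pools of non-interacting
   kinase–substrate pairs (STRING/BioGRID/BioPlex-style evidence,
   STRING confidence ≥ 0.75) and experimentally disfavored
   kinase–motif pairs (S/T rank ≥ 150, Y percentile ≤ 10); four
   replacement methods per positive with a fallback, ≤ 4 negatives per
   positive, per-kinase 20% held-out split producing a balanced test
   set (Testing Dataset 1) and a natural-ratio test set (Testing
   Dataset 2).
4. **Bilinear classifier.**
   V_ks = V_kᵀ W_ks V_s + b_ks, V_km = V_kᵀ W_km V_m + b_km, fused by a
   third bilinear layer into V_ksm, then 40- and 50-neuron hidden
   layers (ReLU + dropout 0.5 each) and a sigmoid; binary cross-entropy
   with manually derived, finite-difference-checked gradients.
5. **Evaluation.** ROC-AUC (rank statistic, ties half), PR-AUC
   (average precision), 1000-resample percentile bootstrap CIs,
   easy-test filtering via similar kinases (shared family/domain), and
   a random-embedding control that certifies the dataset carries no
   exploitable bias on its own.

A seeded synthetic-world generator (`simulate_world()`, presets
`small` / `default` / `stress`) emits every table the pipeline consumes
with planted, tunable signal, so everything is testable offline.

## Worked example

```r
library(ksmofinder)

## a self-contained toy phosphorylation world
world <- simulate_world(preset("small", seed = 1))
world
#> Synthetic phosphorylation world (seed 1)
#>   kinases/substrates: 20/200
#>   positives: 1525  registry: 1173  KG triples: 13414

## leakage-guarded knowledge graph -> TransE embeddings
emb <- train_world_embeddings(
  world, config = kge_config("transe", max_epochs = 400, seed = 1))
attr(emb, "best_mrr")
#> [1] 0.1891453

## biologically motivated negatives + per-kinase 20% split
bundle <- build_dataset(world, seed = 1)
bundle
#> Classification bundle
#>   train: 6003 (+1220/-4783)
#>   test1: 610 (+305/-305) (balanced)
#>   test2: 1498 (+305/-1193) (natural ratio)

## bilinear classifier on the embeddings
model <- train_classifier(
  bundle, emb, clf_config(max_epochs = 60, patience = 8, seed = 1))
p1 <- predict(model, emb, bundle$test1)
eval_report(p1, bundle$test1$label, n_boot = 1000, seed = 1)
#> ROC-AUC 0.906 [0.877, 0.930]  PR-AUC 0.856 [0.805, 0.901]  (+305/-305)

## random-embedding control on the same bundle
ctrl <- random_embedding_control(
  bundle, dim = 100,
  config = clf_config(max_epochs = 12, patience = 3, seed = 1),
  seed = 1, n_boot = 1000)
ctrl$test1
#> ROC-AUC 0.468 [0.420, 0.514]  PR-AUC 0.490 [0.441, 0.548]  (+305/-305)
```

Read: with the planted family-specificity and functional-coupling
signal, KG embeddings lift balanced-test ROC-AUC to 0.906 while the
same classifier on random embeddings sits at chance (0.468, CI spanning
0.5) — the discrimination comes from the graph, not from dataset bias.
The whole run takes ~3 minutes on one CPU.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ksmofinder", package = "ksmofinder"))')
$CLI simulate     --preset small --seed 3 --out world/
$CLI build-kg     --triples world/kg_triples.tsv --positives world/positives.tsv \
                  --out kg/ --seed 3 --fraction 0.025
$CLI train-kge    --kg kg/ --algo transe --dim 100 --batch 25000 --lr 1e-3 \
                  --margin 1.0 --neg 1 --eval-every 20 --patience 2 --seed 3 \
                  --out emb.tsv
$CLI make-dataset --positives world/positives.tsv --interactions world/interactions.tsv \
                  --st-spec world/st_specificity.tsv --y-spec world/y_specificity.tsv \
                  --registry world/registry.tsv --seed 3 --out dataset/
$CLI train-clf    --embeddings emb.tsv --train dataset/train.tsv --seed 3 --out model/
$CLI predict      --model model/ --embeddings emb.tsv --samples dataset/test1.tsv \
                  --out predictions.tsv
$CLI evaluate     --model model/ --embeddings emb.tsv --test dataset/test1.tsv \
                  --bootstrap 1000 --seed 3 --out evaluation.json
```

## Package layout

`R/` — knowledge graph (`kg.R`, `motif.R`), embeddings
(`kge_score.R`, `kge_train.R`), dataset construction (`dataset.R`),
classifier (`classifier.R`), evaluation (`evaluation.R`), synthetic
world (`synthetic.R`), orchestration (`pipeline.R`), CLI (`cli.R`).
`vignettes/ksmofinder-methods.Rmd` documents the models, parameter
choices and the synthetic world's design and limits.
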