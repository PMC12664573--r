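---
title: "Kinase-substrate-motif prediction from a phosphorylation knowledge graph: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ksmofinder methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Protein kinases phosphorylate specific serine, threonine or tyrosine
residues (phosphosites) on substrate proteins. Fewer than 7% of the
hundreds of thousands of known human phosphosites have an annotated
kinase. Classical predictors score only the local sequence motif — the
9-mer window of four residues on either side of the phosphoacceptor —
and ignore whether the kinase and the substrate protein plausibly meet at
all: shared pathways, complexes, subcellular compartments, tissues.

`ksmofinder` implements a *substrate_motif*-level predictor: a sample is
the triple $\langle k, s, m \rangle$ of a kinase, a substrate protein and
a 9-mer motif, and the model outputs the probability that $k$
phosphorylates site $m$ on $s$. Two components carry the method:

1. **A phosphorylation knowledge graph (KG)** over kinases, substrate
   proteins, motifs and annotation entities, with a closed vocabulary of
   32 relations. Motifs are first-class nodes decomposed into nine
   positional amino-acid links (`residue_1` ... `residue_9`, the 5th
   position being the phosphoacceptor), and kinase specificity enters as
   `k_specific_motif` links derived from synthetic-peptide profiling
   data. The vocabulary deliberately contains **no** direct
   kinase-to-substrate relation, and a leakage guard removes every
   `k_specific_motif` edge that coincides with a supervised positive, so
   the embedding stage cannot memorize the labels.
2. **Knowledge-graph embeddings (KGE) + a bilinear classifier.**
   Entities and relations are embedded (TransE, DistMult or ComplEx;
   dimension 100) by minimizing a pairwise hinge loss against corruption
   negatives, with early stopping on validation mean reciprocal rank
   (MRR). The classifier computes
   $V_{ks} = V_k^\top W_{ks} V_s + b_{ks}$,
   $V_{km} = V_k^\top W_{km} V_m + b_{km}$, fuses them with a third
   bilinear map into $V_{ksm}$, and applies a 40-neuron and a 50-neuron
   hidden layer (ReLU + dropout 0.5 after each) and a sigmoid output,
   trained with binary cross-entropy.

## Embedding training

The KG is split per relation: 2.5% of the triples of each evaluation
relation (rounded, minimum one) form the validation set; the remainder
trains the model. Scoring functions follow the standard definitions —
TransE $-\lVert h + r - t\rVert_1$, DistMult $\sum_i h_i r_i t_i$,
ComplEx $\mathrm{Re}\sum_i h_i r_i \bar t_i$ — with one uniform
corruption negative per positive (head or tail replaced, never by the
original entity). Optimization is Adam (learning rate $10^{-3}$, batch
25 000). Validation MRR is computed every 20 epochs by ranking each
validation triple's true head and true tail against every graph entity
(raw ranking by default; a `filtered` switch masks known true triples);
tied scores receive the realistic rank, the mean of the optimistic and
pessimistic rank. Training stops after two consecutive evaluations
without MRR improvement and returns the best-MRR checkpoint.

Choices the protocol leaves open, and what this package does:

* **Hinge margin** $\gamma = 1.0$ — the conventional default for
  pairwise hinge in KGE; configurable.
* **"Every 20 iterations"** is read as every 20 *epochs*; with batches
  of 25 000 a minibatch reading would make a patience of 2 meaningless.
* **Validation relations** (the protocol does not enumerate them):
  all kinase/substrate/motif-facing relations
  present in the graph — `k_specific_motif`, `has_motif`,
  `belongs_to_family`, `has_domain` and the nine residue relations.
  Including the residue relations matters in practice: they make the
  validation set dense enough that the patience-2 rule tracks genuine
  convergence; with a sparse validation set the MRR estimate is noisy
  and training halts long before the embeddings are useful.
* **Initialization** uniform in $[-6/\sqrt d, 6/\sqrt d]$, entity
  vectors L2-normalized after every update for TransE only (the original
  translation-embedding recipe).
* **ExpressivE** is not implemented (TransE-family scorers cover the
  selected configuration); the config rejects it with a clear message.

## Classification dataset

Positives are kinase-phosphosite records (curated exports; integrated
resources contribute rows with a confidence score, kept at score
$\ge 1$). Negatives are *biologically motivated*, built from two pools:

* **neg-ks** — kinase/substrate pairs with no interaction evidence in
  any source after discarding STRING edges below confidence 0.75;
* **neg-km** — kinase/motif pairs experimentally disfavored:
  serine/threonine kinases at specificity rank $\ge 150$, tyrosine
  kinases at percentile $\le 10$ (both boundaries inclusive).

For each positive $\langle k, s, m\rangle$ four negatives are attempted:
replace the kinase by one disfavoring $m$ (1) or one not interacting
with $s$ (2); replace the motif by a disfavored motif of $k$ that is a
real site on $s$ (3); replace the substrate by a non-interactor of $k$
that carries $m$ (4). When (3) or (4) has no admissible candidate, the
fallback draws a random negative-motif or negative-substrate sample of
$k$ over the substrate-motif registry. Every emitted sample is a valid
registry phosphosite pair, never equals a positive, and collisions are
resampled up to 20 times before the method is skipped. Sampling is
seeded per positive (a string hash of the sample combined with the
global seed), so the draw for a given positive does not depend on input
order; the cross-positive deduplication pass is the one order-dependent
step, and reruns on identical input are byte-identical.

The split holds out, per kinase and per class, 20% of samples (rounded):
the full held-out set is Testing Dataset 2 (natural class ratio,
roughly 1:3.5), and Testing Dataset 1 keeps all held-out positives plus
an equal-size uniform subsample of held-out negatives. Kinases with a
single sample stay in training.

## Classifier training

Manual analytic gradients (verified against central finite differences
at $10^{-4}$ relative tolerance in the test suite) drive Adam with
package-default hyperparameters: learning rate $10^{-3}$, batches of
512, at most 200 epochs, early stopping with patience 10 on the loss of
a seeded 10% carve-out of the training data, best-checkpoint return.
These are defaults, not protocol constants (the protocol does not fix
the classifier's training hyperparameters). The
bilinear output width $d_b$ is likewise unstated; this package defaults
to $d_b = 50$ — at $d_b = d = 100$ the $(d^2 \times d_b)$ bilinear
layers double the single-CPU cost of every pass without measurable
benefit at desk scale. Class imbalance is left unweighted by default
(`pos_weight` exists but is off), matching the apparent protocol.

## Evaluation

ROC-AUC uses the rank statistic with mean-rank tie handling (equal to
the probability a random positive outscores a random negative, ties
half); PR-AUC uses threshold-stepped average precision. Both are
deliberately library-independent so values are bit-stable. Confidence
intervals are 95% percentile bootstrap over 1000 resamples of
(score, label) pairs, redrawing degenerate single-class resamples.

The *easy-test filter* removes test samples $\langle k_1, s, m, l\rangle$
for which a similar kinase $k_2$ (same family or same domain, read off
the KG) occurs with the same motif in training exclusively with label
$l$; samples whose $(k_2, m)$ occurs with both labels are kept.

The *random-embedding control* replaces every entity vector with an
independent standard-normal 100-vector and retrains the classifier: on
an unbiased dataset the balanced test set must score near ROC-AUC 0.5
and the natural-ratio test set near PR-AUC equal to the positive
prevalence. Standard normal is chosen because the classifier's first
bilinear layer makes the control scale-free.

## The synthetic world

The generator emits everything the pipeline consumes — KG triples,
positives, interaction evidence, ST/Y specificity tables, the
substrate-motif registry — plus a ground-truth event list that only the
tests read. Its stated world:

* Kinases belong to families; each family has a position-specific
  residue preference profile over the eight flank positions, sharpened
  by `family_motif_bias` $b$: the preferred residue has probability
  $(1-b)/20 + b$, so $b = 0$ is exactly uniform. Family class (Y vs
  S/T) forces the phosphoacceptor.
* Each substrate carries `sites_per_substrate` phosphosites dealt
  round-robin among its regulator kinases; motifs are drawn from the
  regulator's family profile.
* With probability `functional_coupling` a true kinase-substrate pair
  is forced to share a pathway or cellular component; interaction
  evidence covers every true pair plus `interaction_noise` spurious
  edges (STRING-tagged noise spans confidences 0.4-1, exercising the
  0.75 threshold).
* Specificity ranks/percentiles are the motif's rank under the
  kinase's profile log-likelihood among all registry motifs, so the
  rank-150/percentile-10 thresholds have real discriminative meaning;
  pairs above the favorability threshold become `k_specific_motif`
  triples.
* With probability `multi_kinase_prob` (0.27, the reported fraction of
  multi-kinase phosphosites) a site gains a second kinase.

Three design points exist specifically so that the zero-signal limit is
genuinely uninformative (the spec's null criterion is definitional for
the world, and early designs leaked):

1. **Random tie-breaks in specificity.** At $b = 0$ all log-likelihoods
   tie; a deterministic tie-break would give every kinase the *same*
   alphabetically-first favored set — a shared hub structure the
   embeddings can exploit. A per-kinase random jitter removes it.
2. **Load-balanced regulator assignment** (least-loaded-first with
   random tie-break): otherwise kinases regulating more substrates have
   higher positive rates, a base-rate channel that survives $b = 0$.
3. **Likelihood-weighted second kinases.** Multi-kinase sites draw the
   second kinase proportionally to profile likelihood of the motif, so
   the "similar kinase, same motif, same label" duplication channel
   scales with the planted bias and vanishes at $b = 0$.

What a green run does *not* establish: the toy world has uniform
sequence statistics (no real proteome composition), complete
interaction coverage of true pairs, noise-free positive labels, and
far fewer entities than the human kinome; absolute metric values do not
transfer to real data. One known residual leak remains by construction:
a (kinase, substrate) pair contributes several sites, and the
per-kinase split puts some in training and some in test — the real
protocol shares this property. It bounds the zero-bias ROC-AUC away
from exactly 0.5 (measured ≈ 0.52 at the small preset).

Presets: `small` (20 kinases / 200 substrates; full pipeline in
minutes), `default` (50 / 1000; the scale assumed by the dataset
protocol, whose held-out natural-ratio test set comfortably contains
the 3025 + 8489 samples of the reference class counts), `stress`
(430 kinases — human-kinome coverage — / 5000).

## Numerical choices

* BCE predictions clamped to $[10^{-7}, 1-10^{-7}]$ before logs.
* Embedding TSVs print 17 significant digits; round trips are lossless
  below $10^{-7}$.
* `round()` (banker's rounding, as in base R) for the 2.5% and 20%
  split counts; minimum one validation triple per populated relation.
* Nonstandard residues (U, B, Z, O, J) map to the node `aa_X`;
  sub-9-mer windows at protein termini are padded with `_` mapping to
  node `aa__`, keeping the residue relations positional.
* Specificity tables accept STRING-style confidences on either the 0-1
  or 0-999 scale (normalized on ingestion).

## Known limitations

* Pure-R training: practical up to a few hundred thousand triples and
  ~100k classification samples; multi-million-triple graphs from full
  phosphoproteome integrations need GPU tooling out of scope here.
* The KGE stage implements the three classical scorers only.
* Real-data ingestion starts at triple/sample tables; no database
  retrieval code is included by design.
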