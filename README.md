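# syndromeKG

Knowledge-graph-augmented multilabel syndrome differentiation for
TCM-style electronic medical records.

## The problem

In traditional Chinese medicine, each case is summarized by a *syndrome*
(e.g. "damp-heat obstructing the meridians"). Syndromes are too numerous
and too variably phrased to classify directly, so the practical
reformulation is to decompose them into **disease-nature** labels
(damp-heat, obstruction, heat, ...) and **disease-location** labels
(meridians, gallbladder, ...) and rank those labels for each record — a
multilabel ranking task over a fixed label space.

`syndromeKG` implements the full pipeline:

* **Graph construction** — a typed knowledge graph with four relations
  built from structured records: chief-complaint → syndrome,
  symptom → syndrome, syndrome → nature, syndrome → location.
* **Graph embedding** — TransE (L1/L2) with margin ranking loss and typed
  negative sampling; DistMult and ComplEx as bilinear comparators. For a
  triple (h, r, t) the translational score is `−‖h + r − t‖`, so an exact
  translation scores 0, the maximum. Link prediction is evaluated with
  MRR, MR and Hits@N in raw and filtered modes with mid-rank tie handling.
* **Text model with entity fusion** — a character-level transformer
  encoder; each linked entity's graph vector is added onto the hidden
  states of the characters that mention it; a multi-head attention block
  integrates the pooled symptom/chief-complaint span vectors into the CLS
  state; a linear head produces one raw score per label, trained with
  per-label binary cross-entropy (all gradients analytic, finite-difference
  checked).
* **Metrics** — P@1/P@3/P@5, average precision, Hamming loss, label
  ranking loss, each cross-checked against brute-force oracles.
* **KG-only baseline** — labels ranked purely by two-hop link-prediction
  scores, `max_s min(f(e, r_e, s), f(s, r_L, L))` averaged over a record's
  entities, for quantifying what the text model adds.
* **Synthetic worlds** — a generator that plants syndromes, symptom sets,
  labels, controllable noise, skew, and surface-ambiguous homographs, so
  every stage is testable without access to clinical data.

## A worked example

```r
library(syndromeKG)

cfg <- run_config(
  seed = 1,
  synth = synth_config(n_syndromes = 5, n_symptom_vocab = 20,
                       n_records = 150, seed = 1),
  kge = kge_config(dim = 32, epochs = 150),
  clf = clf_config(epochs = 12))
report <- run_pipeline(cfg)
print(report)
```

```
Pipeline run (seed 1 ): 120 train / 30 test records
Link prediction (filtered, 8 queries): MRR 0.8750  MR 1.2
  Hits@1       0.7500
  Hits@10      1.0000
  Hits@100     1.0000
Classifier:
Multilabel metrics (30 samples, 6 labels)
  P@1                  1.0000
  P@3                  1.0000
  P@5                  0.6000
  average precision    1.0000
  hamming loss         0.0000
  label ranking loss   0.0000
KG baseline:
Multilabel metrics (30 samples, 6 labels)
  P@1                  1.0000
  P@3                  0.9333
  P@5                  0.6000
  average precision    0.9611
  hamming loss         0.5000
  label ranking loss   0.0444
```

Reading the output: the world has 5 syndromes whose labels are a
deterministic function of their symptom sets, so a well-trained classifier
should approach perfect ranking (P@1 = 1, ranking loss = 0) — which it
does. The label space is the 6 nature/location entities realized in the
training graph. P@5 is 0.6 because each record carries exactly 3 gold
labels, so even a perfect top-5 contains at most 3 positives (3/5 = 0.6). The
graph-only baseline ranks the right labels first (P@1 = 1) but is weaker
further down the ranking and poorly calibrated (its Hamming loss reflects
raw graph scores pushed through a sigmoid, not fitted probabilities).

A command-line front end over the same functions is installed with the
package (`system.file("cli", "skg", package = "syndromeKG")`) with
subcommands `run`, `synth`, `build-kg`, `train-kge`, `eval-kge`, and
`evaluate`.

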