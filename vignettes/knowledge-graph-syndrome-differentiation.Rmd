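---
title: "Knowledge-graph-augmented syndrome differentiation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-graph-augmented syndrome differentiation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In traditional Chinese medicine (TCM), a clinical case is summarized by a
*syndrome* (证候) — a diagnostic category such as "damp-heat obstructing the
meridians". Syndromes are so numerous and so variably phrased that treating
syndrome differentiation as flat multiclass classification is hopeless: most
syndromes occur once or twice in any record collection. The workable
reformulation is to decompose each syndrome into *disease-nature* labels
(damp-heat, obstruction, heat, ...) and *disease-location* labels (meridians,
gallbladder, ...) and predict those as a **multilabel ranking task** over a
fixed label space.

`syndromeKG` implements this pipeline end to end:

1. **Graph construction** — from structured EMR-like records, build a typed
   knowledge graph with four relations: chief-complaint → syndrome,
   symptom → syndrome, syndrome → nature, syndrome → location.
2. **Graph embedding** — train entity/relation vectors with a translational
   scorer (TransE, L1 or L2) or the bilinear comparators DistMult and
   ComplEx, under margin ranking loss with typed negative sampling.
3. **Text encoding and fusion** — encode each record's character sequence
   with a small transformer, add each linked entity's graph vector onto the
   hidden states of the characters that mention it, integrate the pooled
   symptom/chief-complaint span vectors into the CLS state with one
   multi-head attention block, and read labels off a linear head.
4. **Evaluation** — P@k, average precision, Hamming loss, label ranking loss
   for the classifier; MRR, MR and Hits@N (raw and filtered) for the
   embeddings; plus a graph-only baseline that predicts labels by two-hop
   link-prediction scores without looking at the text.

## The models

### Graph embedding

A triple $(h, r, t)$ is scored by
$f(h,r,t) = -\lVert \mathbf{h} + \mathbf{r} - \mathbf{t} \rVert_{1/2}$
for the translational scorer, by the trilinear product
$\sum_i h_i r_i t_i$ for DistMult, and by
$\mathrm{Re}\langle \mathbf{h}, \mathbf{r}, \bar{\mathbf{t}}\rangle$ for
ComplEx. Higher scores always mean more plausible; a perfect translation
scores exactly 0, the global maximum of the translational family. We train
with margin ranking loss
$\max(0,\ \gamma - f(\text{pos}) + f(\text{neg}))$, plain SGD, and entity
vectors renormalized to the unit sphere each epoch. One sign convention is
worth stating: distance-based scorers are sometimes described as assigning
positive scores to true triples; with score = −distance that inequality
cannot hold literally, so we read it as the margin-separation contract the
ranking loss enforces (true triples must outscore corruptions by γ).

Negative sampling corrupts head or tail with a fair coin, restricted to the
corrupted slot's schema category (a corrupted nature tail is always a nature
entity), and rejects corruptions that are themselves true triples. When a
category has a single entity the other slot is corrupted; when every
candidate is a true triple the sampler reports the impossibility after a
bounded number of retries.

### Link-prediction evaluation

For each test triple both queries $(h, r, ?)$ and $(?, r, t)$ are ranked.
Candidates are restricted to the open slot's category by default (the typed
schema makes cross-category candidates meaningless; a flag ranks all
entities). Ties receive the mid-rank — 1 + #strictly better + ½·#equal —
which makes MRR/MR/Hits@N invariant to candidate ordering. *Filtered* mode
removes other known-true completions before ranking and is the default;
filtered ranks are provably never worse than raw ranks, and both are
implemented.

### Text model and fusion

The input sequence is
`[CLS] field₁ [UNK] field₂ [UNK] … chief-entity [UNK] … [SEP]`,
with the five symptom fields in the conventional order (pulse, tongue,
listening/smelling, inspection, physical examination) and the
chief-complaint entities extracted by longest-match dictionary lookup. Each
field and each chief entity is followed by its own `[UNK]` separator; a
switch collapses the symptom block to a single separator for users who
prefer one delimiter between blocks. Sequences are right-truncated before
`[SEP]` at `max_len` (default 256 in clinical settings; 64 in the desk-scale
defaults), dropping spans that no longer fit.

The encoder is a small configurable transformer (token + position
embeddings, multi-head self-attention and feed-forward blocks with residual
connections) standing in for a pretrained character-level language model. It
honours the same contract — per-character hidden states, CLS pooling — so
any stronger encoder can be dropped in behind `encode()`. We deliberately
train it from scratch: the component under study is the fusion
architecture, not pretrained weights.

**Fusion** adds, for every entity span $k$ covering characters
$j \dots j{+}L(e_k)$, the projected entity vector to each covered hidden
state: $S_i \leftarrow S_i + P\,\mathbf{e}_k$. Characters outside any span
are left bit-identical — this locality is asserted in the tests. The
projection $P$ is a trained linear map (initialized to the identity when
the dimensions already agree). Entity mentions that cannot be linked to the
graph receive a seeded random vector, cached per surface within a run, so
unseen mentions behave consistently.

**Attention integration** builds the sequence
$[\,C;\ S_{1..M};\ Cc_{1..N}\,]$ from the CLS state and the mean-pooled
span vectors of symptom and chief-complaint mentions, projects it with a
shared input matrix, applies one multi-head self-attention block with
per-head query/key/value projections and an output projection, and takes
the output at the $C$ position as the integrated representation $C'$. A
linear head maps $C'$ to one raw score per label; the sigmoid is applied
only inside the loss and the Hamming-loss binarization, so the scores feed
the ranking metrics directly.

Training minimizes per-label binary cross-entropy with logits (the standard
multilabel ranking surrogate) using minibatch Adam. Every gradient is
written out analytically — through the head, the integration block, the
fusion additions, and the encoder — and the test suite checks the full
parameter set against central finite differences at $10^{-4}$ relative
tolerance on a toy model.

### Decisions taken where the design was open

* **Separator placement.** One separator *per* symptom field (not one per
  block); the per-field form is what lets span pooling distinguish fields,
  and the block form remains available via `per_field_sep = FALSE`.
* **Order of fusion and integration.** encode → fuse → integrate. Fusing
  first lets the integration block attend over entity-aware span vectors;
  the alternative order is a config seam (`integrate`, `fusion` toggles)
  rather than a code fork.
* **Span vectors for integration.** Mean-pooled hidden states of each
  entity span. Raw per-token states would make $M$ and $N$ depend on surface
  length; pooled vectors keep the integration sequence one row per mention.
* **Multilabel loss.** Binary cross-entropy per label; compatible with
  ranking metrics and the Hamming threshold.
* **Tie handling in metrics.** P@k breaks score ties by stable label index
  (deterministic); ranking loss counts ties as violations (pessimistic
  strict-inequality reading). Hamming loss binarizes sigmoid scores at 0.5.
  Average precision and ranking loss exclude degenerate rows (no positive,
  or no negative) and report the exclusion count as an attribute.
* **Ranking-loss normalization.** Per sample, violations are divided by
  $|y|\,(n_{\text{labels}} - |y|)$ — the number of (positive, negative)
  pairs — then averaged over samples; this is the standard normalization
  "by the inverse of the number of ordered pairs".
* **Graph-only baseline.** For a record's entity set, each label $L$ is
  scored by the two-hop plausibility
  $\max_s \min\big(f(e, r_e, s),\ f(s, r_L, L)\big)$ (the weakest hop
  limits a path; the best syndrome carries the label), averaged over the
  record's entities. The aggregation is a strategy argument (`mean`, `max`,
  `sum`) so alternatives stay testable. The full score vector is returned,
  not just the argmax, so the same metric suite applies.
* **Edge direction.** Chief-complaint and symptom edges point *into* the
  syndrome, as the schema states them; inverse-edge materialization is
  intentionally not provided.
* **Syndrome identity.** The whitespace-normalized syndrome string (or the
  generator's syndrome id when present); no fuzzy merging of surface
  variants.

## The synthetic world

Real clinical corpora of this kind are private, so the generator plants the
structure the pipeline must recover: `n_syndromes` latent syndromes, each
owning a symptom set drawn without replacement, a chief-complaint set, and
non-empty nature/location label sets. Records sample a syndrome (uniformly,
or skewed), write its symptom surfaces into the five fields, interleave its
chief entities with filler tokens, and attach the syndrome's labels as gold.
Noise replaces one symptom token per affected record with a uniform
vocabulary draw; labels are never perturbed, so label noise and symptom
noise stay separable. Symbolic tokens (`sym_007`) stand in for clinical
surface strings; since all matching is token-level the pipeline is
script-agnostic, and the tests exercise genuine multi-character matching
with Chinese strings separately.

Two features deserve comment:

* **Homographs** (`n_homographs`, and the purpose-built
  `ambiguous_world()`): pairs of distinct symptom entities share one
  surface token, and paired syndromes differ *only* in which homograph they
  carry while owning different labels. Surface text alone cannot separate
  such pairs; the entity-fusion pathway can. This is the planted structure
  behind the ablation test, which requires fusion to win on average
  precision across six paired seeds (one-sided sign test, p < 0.05).
* **The split rule.** Train/test splitting moves any test record whose gold
  label never occurs in training back into the training set and reports it.
  The property is asserted across 100 random worlds.

What the generator does **not** emulate: realistic clinical prose, field-
dependent vocabulary, label correlations beyond syndrome co-ownership,
extraction-confidence noise (the confidence scorer is injectable and
defaults to 1.0 for exact dictionary hits, with the 0.5 deletion threshold
still enforced), and demographic or date fields. Passing tests therefore
demonstrate that the machinery recovers planted structure, not that it
reaches any particular accuracy on real records.

## Numerical choices and problem sizes

Defaults follow the embedding literature: dimension 100, margin 1.0, L2
norm, one negative per positive, uniform init in
$[-6/\sqrt{d}, 6/\sqrt{d}]$, relation vectors normalized once at init.
The verification suite runs at desk scale, chosen so the whole suite and
the acceptance script complete in minutes on one CPU:

* metric oracles: 1,000 random batches, ≤ 5 samples × ≤ 8 labels, agreement
  to 1e−12;
* link-prediction oracle: a ≤ 20-entity graph, all four scorers, raw and
  filtered;
* held-out embedding recovery: a 62-entity graph (10 syndromes, 30
  symptoms at 12 per syndrome, so each symptom supports ~4 membership
  edges), 10% of triples held out under an entity-coverage constraint,
  TransE at dim 64, margin 0.5, 4 negatives, 600 epochs — filtered
  Hits@10 ≥ 0.9. The density is deliberate: a held-out membership edge is
  only *implied* by the trained geometry when the symptom's remaining
  edges overlap the syndrome's neighbourhood, so sparse worlds make the
  task information-theoretically unattainable rather than hard;
* end-to-end learnability: 5 syndromes / 20 symptoms / 8 labels, 150
  noiseless records, encoder at hidden 32, one layer, two heads, 12 Adam
  epochs at 5e−3 — validation P@1 ≥ 0.95 (labels are a deterministic
  function of symptoms by construction, so near-perfect recovery is the
  correct expectation, not an optimistic one).

Degenerate inputs are defined rather than avoided: empty chief complaints
yield empty extractions; records with no linkable entity get uniform
baseline scores with a warning; all-delimiter field text segments to an
empty list; sequences are truncated before `[SEP]`, never after.

## Determinism

Every stochastic stage derives its own seed from the global run seed
(`derive_seed(seed, stage)`), so toggling one stage never shifts another's
random stream, and a repeated run reproduces every metric report
byte-identically — asserted in the tests. Sentinel vectors restore the
caller's RNG state after drawing, so enabling fusion does not perturb
training randomness elsewhere.

## Known limitations

* The encoder is deliberately small; nothing here speaks to the behaviour
  of large pretrained encoders beyond the shared interface.
* Entity linking is exact-surface dictionary matching (plus gold hints in
  synthetic worlds); no learned extractor, no synonym resolution.
* The KGE trainer is plain SGD on dense matrices — appropriate for graphs
  of thousands of triples, not millions.
* Scores across records are not calibrated probabilities; Hamming loss at
  the 0.5 sigmoid threshold should be read with that in mind.

## A worked example

```{r example}
library(syndromeKG)

cfg <- run_config(
  seed = 1,
  synth = synth_config(n_syndromes = 5, n_symptom_vocab = 20,
                       n_records = 150, seed = 1),
  kge = kge_config(dim = 32, epochs = 150),
  clf = clf_config(epochs = 12))
report <- run_pipeline(cfg)
print(report)

# graph-only baseline vs the fusion classifier
report$kg_baseline$p_at_k
report$metrics$p_at_k
```
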