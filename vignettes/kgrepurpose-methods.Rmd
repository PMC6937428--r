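---
title: "Confidence-aware knowledge-graph embeddings for drug repurposing: models and methods"
author: "kgrepurpose authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-aware knowledge-graph embeddings for drug repurposing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgrepurpose)
```

## The problem and the data model

Literature-mined biomedical graphs link drugs, diseases and genes by a
small vocabulary of semantic themes, and attach to every themed edge a
support score in [0, 1] — a continuous confidence that the stated
relationship actually holds, derived from how the relationship is
expressed across abstracts. Treating such edges as binary discards
exactly the information that distinguishes a well-established treatment
(support near 1) from a speculative mention. `kgrepurpose` therefore
regresses a *predicted* confidence onto the *observed* support rather
than classifying edges as present/absent.

A `knowledge_graph` holds typed entities (`drug`, `disease`, `gene`),
themed multi-edges with supports, and a theme vocabulary. The default
vocabulary (`gnbr_themes()`) has 32 themes in four categories keyed by
the endpoint types (Dr-Dz, Dr-G, Dz-G, G-G); codes are unique within a
category but may recur across categories (`E+` is both drug-gene and
gene-gene, `J` both drug-disease and disease-gene). Connectivity is
always taken undirected and theme-blind: the graph is filtered to the
largest connected component after restricting to gene nodes,
high-priority disease nodes, and drug/disease nodes occurring in known
indications (`filter_for_repurposing()`).

## The embedding model

For a triple $l = (h, r, t)$ with embeddings $\mathbf h, \mathbf r,
\mathbf t \in \mathbb R^d$, the plausibility is the bilinear form
$g(l) = \mathbf r \cdot (\mathbf h \circ \mathbf t)$, symmetric in head
and tail. The predicted confidence is $f(l) = \phi(g(l))$ with the
bounded rectifier $\phi(x) = \min(\max(wx + b, 0), 1)$, where $w$ and
$b$ are *global* learned scalars shared by all relations. Training
minimises

$$J = \sum_{l \in L^+} |f(l) - s_l|^2 + \sum_{l \in L^-} |f(l)|^2,$$

where $L^-$ contains one corrupted negative per positive per epoch: the
tail is resampled uniformly from all entities (excluding the original
tail) and assigned support 0. At evaluation time the bounding is removed
(`test_score` $= w\,g(l) + b$) so that rankings over candidate triples
are strictly monotone in plausibility and tie-free.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `d` | 128 | embedding dimension (desk-scale runs use 8–32) |
| `epochs` | 100 | full passes over the training triples |
| `batch_size` | 1024 | minibatch size for Adam |
| `learning_rate` | 0.01 | Adam step size; tuned over {0.001, 0.005, 0.01} by `tune_learning_rate()` on validation MSE, ties to the smaller rate |
| `adam_beta1`, `adam_beta2` | 0.9, 0.99 | Adam moment decay rates |
| `negatives_per_positive` | 1 | corrupted triples per positive per epoch |
| `early_stop_patience` | 5 | validation evaluations without improvement before stopping |

Splitting (`split_triples()`) is stratified: triples whose unordered
endpoint pair occurs in the gold-standard indication list — under *any*
theme, since correlated non-treatment themes carry treatment signal —
go 60/20/20 into train/validation/test; all remaining triples go
90/5/5. Fold sizes use floor allocation with the remainder to training.
A `by_pair` flag instead assigns all triples of one pair to a single
fold, for leakage-free pair-level evaluation; the default is per-triple.

### Numerical choices

* **Initialisation.** Entity and relation vectors start uniform in
  $[-0.5/\sqrt d, +0.5/\sqrt d]$; $w = 1$, $b = 0$.
* **Clamp subgradient and the dead-rectifier trap.** The exact
  subgradient of $\phi$ is zero outside $(0,1)$, so a triple whose
  pre-activation drifts below 0 while its target support is high
  receives no gradient and can never recover. By default the trainer
  uses a *leaky* search direction (`leaky_gradient = TRUE`): at clamped
  points whose target lies inside the bounds the slope is kept at $w$.
  The objective itself is unchanged — `ukge_loss()` and the exact
  subgradient in the gradient checks are untouched — only the search
  direction at the kinks differs. Without this, convergence is visibly
  seed-dependent (some runs stall at several times the typical held-out
  error).
* **Early stopping.** Validation MSE is computed on held-out positives
  with the bounded (training-mode) confidence, each epoch; the returned
  model is the one with the best validation MSE seen. With an empty
  validation set, training runs to the epoch limit.
* **Negative churn.** Negatives are resampled each epoch (flag to fix
  them once); corrupted triples colliding with observed positives are
  kept by default (flag to filter), matching the assumption that a
  random corruption has support 0.
* **Divergence.** A non-finite batch loss aborts with the epoch number.
* **Determinism.** All randomness (initialisation, shuffling, negative
  sampling) flows from the config seed; helpers save and restore the
  caller's RNG state.

### A note on the convergence floor

On a noise-free synthetic graph one might expect training loss to
approach zero. It cannot: resampled corrupted negatives carry target 0,
but under any coherent generative truth a random triple has a small
*positive* confidence, so the objective's floor is roughly the loss of
the generating parameters themselves. The training tests therefore
assert (i) a large loss reduction and (ii) that the fitted model reaches
or beats the generative oracle's objective value, rather than an
arbitrary near-zero threshold.

## The synthetic generator

`generate_kg()` plants a bilinear ground truth so that every downstream
stage has a recoverable signal:

* Latent vectors are **sparse and nonnegative** — half-normal magnitudes
  with each coordinate active with probability `latent_sparsity` (0.3),
  at least two active coordinates per vector. Consequently ~80% of
  random triples have latent product exactly zero: the typical (and any
  corrupted) triple is weakly supported, while a small aligned minority
  is strongly supported. This mirrors literature mining, where most
  co-mentions are weak and a few relationships are heavily attested,
  and it is *consistent with the training assumption* that corrupted
  negatives have support ≈ 0. (An earlier dense, signed design placed
  random triples at support ≈ 0.5 and made the objective internally
  contradictory.)
* The affine scale maps a zero latent match to support 0.05 and the
  weakest planted pair to 0.92, so the planted treatment pairs — the
  `n_planted_indications` drug–disease pairs with the highest noise-free
  `T` score, forced into the edge set — all have noise-free support
  ≥ 0.9. The extreme upper tail may clamp at 1, as real supports do.
* Candidate (pair, theme) combinations are sampled independently at
  `edge_density` (default 0.4, about seven observations per free latent
  parameter at the default sizes of 20 drugs / 20 diseases / 50 genes /
  4 themes per category) — enough data that the planted structure is
  identifiable at `d = latent_dim`; observed supports add Gaussian noise
  (`noise_sd` 0.05) before clamping.

What the generator does *not* emulate: literature biases (cancer is
over-represented in real graphs), hub degree distributions, sentence
provenance, and correlated multi-theme evidence on one pair. Passing
tests on synthetic graphs therefore demonstrate that the machinery
recovers a planted signal under realistic noise — not that any
particular real-world AUROC will be attained.

`generate_proximity_fixture()` builds the proximity-test fixture. Under
`effect = 0` the two gene sets are drawn with replacement from all
proteins — *exactly* the permutation null — so the p-value is uniform by
exchangeability, which is what the calibration test checks. Under
`effect > 0` the member proteins are relocated to `effect`·**u** + noise
for a common unit direction **u**, separating the sets from the null.

## Evaluation

`evaluate_gold_standard()` computes AUROC as the midrank Mann–Whitney
concordance (ties half-credited), which equals the trapezoidal area
under the returned ROC points; AUPR uses step-wise interpolation, which
avoids the optimism of linear interpolation between precision–recall
points. Negative pairs are sampled from the gold-standard drug and
disease universes, excluding gold pairs, without duplicates
(`sample_negative_pairs()`). Theme structure is inspected with
`theme_similarity()` (cosine similarity, average-linkage clustering on
1 − cosine; the linkage is configurable since nothing pins it down) and
`per_theme_precision_at_recall()`, which scores all pairs under each
theme's relation vector — unbounded scores by default, consistent with
test-time ranking; a `bounded` flag is provided.

## Explanations

Paths between a drug and a disease with at most 4 nodes (3 edges) are
enumerated by depth-first search over the collapsed undirected edge set,
simple (no repeated nodes), with a configurable cap (default 10^6) that
aborts rather than hang on hub-dense graphs. Each step is reduced to its
highest-supported theme (alphabetical tie-break), a path scores the
minimum of its step supports, and paths rank by score, then length, then
lexicographic node sequence — all tie-breaks deterministic. Motifs are
assigned from interior node types; 2-node paths are `direct` and are
excluded only from motif statistics, which are defined over 4-node
paths; 3-node and unlisted 4-node shapes are classified `other` rather
than guessed. Interior gene nodes of the top paths
(`potential_mediators()`) name the putative mechanism.

## Proximity validation

`median_cosine()` takes the median of all |A|×|B| pairwise cosines
between two protein sets in a supplied embedding of a
protein-interaction network (the embedding is consumed, not computed —
it comes from an off-the-shelf node-embedding method; this package's
contribution is the statistic). Ids missing from the embedding are
dropped with a count; a set empty after intersection yields the `NA`
"no gene set" marker and is excluded from the Bonferroni denominator.
The permutation p-value is the add-one estimator
$(1 + \#\{\text{replicate} \ge \text{observed}\})/(1 + N)$ with
$N = 10{,}000$ by default: strictly positive, at most 1, and uniform
under the null. Resampling is plain uniform with replacement — no
degree or covariate matching — and duplicates within a replicate set
are kept, which is why `median_cosine()` accepts id vectors rather than
strict sets.

## Problem sizes used by the test-suite

Unit tests run on graphs of tens of nodes; the recovery test trains
d = 8 embeddings on a ~5,800-triple synthetic graph (300 epoch budget,
early stopping typically ends training near epoch 100); calibration uses
200 null fixtures at 500 permutations each. These sizes were chosen so
the full suite exercises every stage end-to-end in well under a minute
per file while keeping each statistical check adequately powered.

## Known limitations

* Edge direction and negation in the source literature are not
  modelled; paths are undirected, so an explanation cannot distinguish
  "drug targets gene" from "gene affects drug response".
* The bounded rectifier yields exact zeros/ones; ranking within
  saturated regions at train time is undefined (resolved at test time
  by removing the bounds).
* Validation MSE on positives only (the default) can prefer models that
  inflate scores of unobserved triples; the `val_include_negatives`
  flag adds sampled negatives to the criterion.
* The proximity null ignores protein degree; hub-heavy gene sets can
  look proximal for topological rather than biological reasons.
* With per-triple splitting, different themes of one entity pair can
  land in different folds; use `by_pair = TRUE` for strict pair-level
  held-out claims.
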