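---
title: "Predicting gene essentiality from interaction-network structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gene essentiality from interaction-network structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netess)
```

## The problem and the model

Experimentally determined gene essentiality exists for only a handful of
bacteria, while functional-association networks (STRING-style) exist for
thousands. `netess` transfers essentiality labels across organisms using
*only* network structure: no sequence, no annotation, no homology. The
premise is the long-standing centrality–lethality observation — essential
gene products sit in structurally distinctive network positions — pushed
beyond single centrality indices to a rich recursive description of each
gene's neighborhood.

The classifier itself is deliberately ordinary: a random-forest ensemble
over a fixed 283-column per-gene feature schema. Everything
organism-specific is pushed into the features, which is what makes
cross-species transfer (train on organisms A..Z, predict on an unseen
organism) coherent: the columns mean the same thing in every network.

## The feature schema

**Base features (6).** Degree; weighted degree (sum of incident
confidence weights); the egonet internal edge count (edges with both
endpoints in `{v} ∪ N(v)`); the egonet boundary edge count (edges with
exactly one endpoint in the egonet); and weighted variants of the two
egonet counts. An isolated node is all zeros.

**Recursion.** Each iteration appends, for every existing column, its sum
and mean over each node's neighbors (the mean over an empty neighborhood
is 0, so the matrix never contains missing values). The cumulative width
triples per iteration: 6, 18, 54, 162, 486. Children are named
`parent.s<g>` / `parent.m<g>` after aggregator and iteration. Note that
re-aggregating a column born before the previous iteration reproduces an
earlier child by value; we keep these redundant columns in schema mode
because the alternative — a de-duplicated enumeration — would make column
identity depend on the data, and cross-organism training requires an
input-independent schema. Random forests are indifferent to duplicated
columns (they only dilute `mtry` slightly).

**Schema mode vs research mode.** Canonical training uses *schema mode*:
recursion runs to the first depth whose width reaches 267 (depth 4, width
486) and the first 267 columns are kept in enumeration order. Every input
graph thus yields byte-identical column names. *Research mode* instead
follows the classic recursive-feature-extraction loop: bin each column by
vertical logarithmic binning (a fraction `p = 0.5` of the remaining
values per successive bin, ties never split), connect features whose bins
differ by at most `s = 0` everywhere, keep the earliest feature per
connected component, and stop when an iteration contributes nothing new.
Research mode is exposed for feature-set exploration; its width is data
dependent, so it cannot feed the cross-organism model. The specific 267
columns retained by schema mode are this package's canonical stand-in for
the historically used 267-feature set, whose exact identities were never
published alongside the model family we re-implement.

**Explicit block (16).** Twelve centralities — degree, betweenness,
closeness, harmonic closeness, eigenvector, PageRank (damping 0.85), Katz
(attenuation 0.005), load, subgraph, current-flow closeness (information
centrality), current-flow betweenness, and coreness — plus per-node
clique number, local clustering coefficient, biconnected-component
membership count, and weighted degree. The twelve identities are a
documented, configurable choice spanning the standard
degree/path/spectral/flow/core families; we include coreness rather than
communicability betweenness because the latter requires one matrix
exponential per node (quartic in network size), which is out of
proportion for interactome-scale graphs, while the k-core index is cheap
and is itself a classic correlate of gene essentiality in
protein-interaction networks. All centralities are computed on the
unweighted topology (weights enter via the weighted degree and weighted
recursive features only); component-bound measures are computed per
connected component with component-size normalization so every column is
finite on any graph, isolated nodes included.

## Labels, imbalance, and the ensemble

Labels follow the DEG convention: database-listed genes are essential,
every other network gene non-essential, giving roughly 10.5% positives.
Rather than reweighting, training undersamples: negatives are shuffled
(seeded) and partitioned into `n_folds = 10` disjoint chunks differing in
size by at most one; fold *k* trains one probability forest (150 trees,
`sqrt` features per split) on all positives plus chunk *k*. This reading
of "undersample, but let every negative be seen at least once" gives a
literal coverage guarantee — the chunks partition the negatives — and a
deterministic, testable contract. The ensemble probability is the
arithmetic mean over member forests, so it is bounded by the member range.

One backend note: R's random-forest implementations (`ranger`,
`randomForest`) offer Gini-impurity splitting but not entropy. The model
configuration accepts and records `criterion = "entropy"` as provenance,
while the `ranger` backend splits on Gini in both cases; the two criteria
are interchangeable for forest quality in practice, and none of the
package's validated quantities depend on the split rule.

Evaluation is leave-one-species-out: for each organism, train on the
pooled remaining organisms and compute the rank-based (Mann–Whitney,
midrank-tied) AUROC on the held-out organism. Organisms with single-class
labels are skipped and excluded from the cohort mean, never imputed. The
label-version comparison (`compare_label_versions()`) reports both a
paired and a Welch t-test because the historical analysis did not state
its variant; with zero-variance differences the paired test is flagged as
degenerate rather than forced.

## Reporting

A gene is reported essential when its ensemble probability is at least
0.70 — read inclusively, which the reported score floor of exactly 70.0
supports — and its essentiality score is 100 × probability rounded to one
decimal (matching the 70.0–100.0 presentation). Output tables are sorted
by descending score with gene-id tie-break and are byte-stable across
reruns for fixed inputs and seed.

## The synthetic cohort: what it does and does not show

The generator builds preferential-attachment graphs (heavy-tailed degree
distributions, guaranteed connectivity, closed-form edge count
`m(m−1)/2 + (n−m)m`) with integer edge confidences uniform on
`[150, 999]`, and plants essentiality by a logistic model on standardized
log-degree and standardized betweenness; the intercept is solved by
bisection so the expected prevalence over the realized nodes equals the
target π = 0.105. Cohort defaults — 6 organisms × 800 genes, m = 4 (mean
degree ≈ 8), effects β_deg = 2, β_btw = 1 — are fixed once as a
desk-scale analogue of a bacterial training cohort: π matches the
~8,750 : 74,500 label imbalance of DEG-labelled training data, the node
count keeps ≥ ~80 positives per organism so per-organism AUROCs are
stable, and m = 4 gives densities at which the structural features are
informative without being trivially saturated.

Under these conditions the full pipeline recovers the planted signal
(LOSO mean AUROC ≥ 0.70 — in practice ≈ 0.95 at these effect sizes) and,
with β = 0, sits at chance within binomial noise (mean ∈ [0.45, 0.55]),
which doubles as a leakage check: nothing about the held-out organism
reaches training. What the synthetic cohort does **not** emulate: the
evidence-channel correlation structure of real STRING scores, modularity
and complex/pathway structure, phylogenetic correlation between
organisms, or annotation biases in DEG labels. Passing synthetic
recovery therefore demonstrates the machinery is correct and sensitive,
not that real-organism AUROCs will match any particular value.

## Numerical choices and degenerate inputs

- Duplicate symmetric edge rows keep the maximum confidence
  (conservative, deterministic); self-loops are dropped with a warning.
- No default confidence cutoff is applied when reading networks
  (`min_score = 0`), keeping "almost all proteins" in the graph;
  sparsification is exposed as an option.
- Mean over an empty neighborhood is 0; every feature column is finite by
  construction on every graph.
- Vertical binning is rank-based, so any strictly increasing transform of
  a column leaves its bins unchanged; ties always share a bin.
- Pruning ties break toward the earliest generation, then lexicographic
  name; pruning is idempotent.
- Katz attenuation 0.005 must stay below the reciprocal spectral radius;
  failure raises an error naming the measure rather than returning
  non-converged values. Clique enumeration carries a node-count guard.
- All randomness (undersampling, tree growth, synthetic generation) is
  seeded; sub-seeds are derived per organism/fold and kept inside 32-bit
  integer range. Identical inputs + configuration + seed give identical
  outputs end to end.

## Problem sizes

The shipped tests run the complete pipeline at the cohort defaults above
(12 organism-networks of 800 genes across the signal and null cohorts)
and exercise unit properties on graphs of 3–12 nodes against brute-force
oracles (exhaustive pair counting for AUROC, simple-path enumeration for
betweenness, edge-subset enumeration for egonet counts). These sizes were
chosen so the whole suite completes in a few minutes on one CPU while
every contract — schema width, coverage, determinism, recovery, null
behavior — is exercised at full fidelity.

## Known limitations

- Schema mode's 267 columns are a canonical enumeration, not the
  historical feature identities; models trained here are not
  weight-compatible with any previously distributed model.
- Centralities are exact, not approximated; million-edge interactomes
  will be slow (clique enumeration and current-flow measures dominate).
  The intended scale is desk-scale cohorts and single organisms.
- Probabilities are raw forest means, not calibrated; the 0.70 threshold
  is a reporting convention, not a calibrated error rate.
- Fitness genes (conditionally essential) are outside the binary label
  scheme.
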