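---
title: "Community-level metabolic networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community-level metabolic networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(konet)
```

This vignette documents the models behind `konet`, the choices made where
the methodology leaves room, and what the synthetic benchmarks do and do
not establish.

## The supraorganism model

The package treats a microbial community as one metabolic system. Its unit
of analysis is the KEGG Orthology (KO) group: a family of orthologous
enzymatic genes with a shared function. Three data structures carry the
pipeline:

* an **annotation profile** per sample — read-to-reference hits with
  alignment e-values and the KOs annotating each reference sequence;
* an **abundance table** — samples × KOs counts and relative abundances;
* a **metabolic network** — a simple directed graph over KOs.

### Even-split abundance estimation

Every read contributes total weight 1. Among a read's hits, only those at
the read's minimum e-value are kept; the unique KOs across the kept hits
are pooled and each receives `1/n`. This encodes two counting guidelines:
a hit to one reference annotated with several KOs splits its count evenly
across them, and several references tied at the best e-value split the
count evenly across all their KOs. Two consequences are worth noting:

* a KO appearing on two tied references receives one share, not two — the
  pooled KOs are a set;
* the sample's total count equals its number of KO-assigned reads, so
  dividing each row by its sum ("relative abundance") both sums to 1 and
  normalizes for sequencing depth. We read "normalizing by the total
  number of reads of enzymatic genes" this way because it is the only
  reading under which the rows are probability vectors, which the
  downstream scores assume.

E-value ties are compared with a relative tolerance of `1e-9`: annotation
services print rounded scientific notation, so exact float equality after
parsing is the intended notion of "the same e-value", and the tolerance
only absorbs decimal-formatting noise.

No default e-value cutoff is applied beyond best-hit selection; a
`max_e_value` option exists for users who want one.

### The edge rule

From a reaction table (reaction id, direction, catalyzing KOs, substrates,
products) the reference network draws a directed edge A → B whenever some
compound is a product of a reaction catalyzed by A and a substrate of a
reaction catalyzed by B. Decisions around this rule:

* **Reversibility.** The table carries an explicit direction column; a
  reversible reaction contributes both orientations (its substrate and
  product sets are merged on both sides of the rule). Dropping direction
  information would arbitrarily inflate or deflate connectivity, so the
  choice lives in the data file and is handled deterministically.
* **Currency metabolites.** ATP, water and common cofactors connect almost
  everything to almost everything. They are *not* excluded by default —
  the stated rule is preserved literally — but `exclude_compounds` lets
  the analyst remove them, and excluding a compound can only delete edges
  (a tested monotonicity property).
* **Self-loops** (an enzyme feeding itself via a shared compound) are
  uninformative for inter-enzyme topology and are off by default;
  `allow_self_loops = TRUE` restores them.
* **Evidence.** Parallel evidence collapses onto a single directed edge;
  every `(compound, from_reaction, to_reaction)` triple is retained as an
  edge attribute and survives GraphML export/import.

### State-specific networks

An SSN is the vertex-induced subgraph of the reference on the KOs
identified in one sample, never more: no edge appears unless both
endpoints are retained, and every reference edge between retained nodes
appears. Presence defaults to "relative abundance strictly above 0",
matching identification at any depth; `min_abundance` raises the bar
monotonically. Node attributes store the relative abundance (the quantity
every downstream score is defined on) and, secondarily, the raw count.
KOs observed in a sample but missing from the reference are reported, not
silently added.

## Topology

Four per-node properties are computed on the SSN: degree (in + out),
betweenness centrality, local clustering coefficient, and PageRank.
Directionality is respected where it is meaningful — shortest paths and
the random walk — while clustering uses the undirected projection: a
directed triangle census has seven motif classes, and "number of triangles
through the node" reads as the undirected quantity. Conventions:

* betweenness excludes endpoints and splits over multiple shortest paths;
  both the raw value and the `(n−1)(n−2)`-normalized value are reported,
  since the normalization convention in the field varies;
* clustering of a node with fewer than two neighbors is 0;
* PageRank uses the conventional damping 0.85, uniform teleport, uniform
  redistribution of dangling mass, power iteration to an L1 tolerance of
  `1e-10` (cap 1000 iterations, a numeric error beyond that), and sums
  to 1. It is implemented directly so the convergence contract is explicit;
  the test suite checks it against the stationarity linear system solved
  exactly.

`analyze_topology()` writes the metrics back as node attributes and
reports both Pearson and Spearman correlation of each metric with
abundance, with two-sided p-values. Neither correlation is privileged:
abundance–topology coupling has no canonical scale. With fewer than three
nodes or a zero-variance vector the correlation is reported `NA` with a
note rather than a number.

## Differential abundance

Three descriptive scores contrast `state1` against `state2`; none is a
hypothesis test, and no multiplicity correction is applied — the scores
rank enzymes, they do not certify significance.

* **OR.** The odds ratio of KO `k` uses, per state, the KO's summed
  relative abundance over the summed abundance of all *other* KOs. The
  score is `|log2 OR|`. A pseudocount (default `1e-6`, on the
  relative-abundance scale) is added to each of the four sums: it keeps
  KOs absent from one state finite while preserving the ordering of
  scores; `pseudocount = 0` reproduces the bare formula, with infinite
  scores flagged. The scale (`1e-6`) sits well below any observable
  relative abundance at realistic sequencing depth (10⁴ reads resolves
  `1e-4`), so it acts only at true zeros.
* **RANK.** Abundances are ranked within each sample, rank 1 = most
  abundant, ties averaged (zero-abundance KOs tie at the bottom); the
  score is the absolute difference of mean ranks between states. It is
  invariant under any strictly monotone per-sample transformation.
* **JSD.** The base-2 Jensen–Shannon divergence. A divergence is defined
  between distributions, yet a per-enzyme score is wanted; the adopted
  construction compares, per KO, the two states' Bernoulli distributions
  ("fraction of enzymatic reads that are this KO", averaged over the
  state's samples). This is an interpretation — the methodology names the
  divergence without fixing the per-enzyme construction — and it keeps
  the score symmetric in the states and bounded in `[0, 1]`.

`differential_analyze()` merges the SSNs of both states into one
community-level network (union of nodes and edges) and colors nodes by
call: enriched in `state1` red (`#FF0000`), depleted green (`#00AA00`),
unchanged gray (`#CCCCCC`). "Significantly enriched" is deliberately a
score cutoff, not a test: the default threshold is the 0.9 quantile of the
nonzero scores (so roughly the top decile is colored), overridable as an
absolute value. A KO is `unchanged` exactly when its score does not exceed
the threshold.

## The synthetic generator

`generate_profiles()` emulates the annotation structure the estimator must
cope with, with known ground truth:

* per-state KO probability vectors — an exponential-weight baseline (a
  mildly heavy-tailed community, drawn once per seed), with the planted
  KO's weight scaled by `2^planted_log2_fold` in state1 and the vector
  renormalized. By default the planted KO is the one with median baseline
  weight, so the planted odds ratio stays close to the planted fold;
* a configurable fraction of reads hit a two-KO reference sequence
  (default 0.1), and a fraction have two tied best hits plus a worse
  decoy hit that best-hit filtering must discard (default 0.1). Tied
  e-values are emitted as identical decimal strings, so the tie detector
  is exercised through the file dialect, not only in memory;
* partner KOs for both mechanisms are drawn from the same state
  distribution as primary hits. This makes even-split counting unbiased in
  expectation — the returned probability vectors are exactly the expected
  relative abundances — which is what lets recovery benchmarks measure
  estimator bias rather than simulator bias.

`generate_reference()` draws reactions with 1–2 substrates and 1–2
products (disjoint within a reaction) and cycles the first catalyst
through the KO pool, so with at least as many reactions as KOs every
enzyme participates in metabolism — as in real reference data, where the
KO universe derives from reaction annotations. It returns, next to the
table, the edge set from an exhaustive O(KO² · reactions²) enumeration
kept deliberately independent of the constructor's compound-indexed
algorithm, so each can verify the other.

One integer seed drives everything; per-sample substreams use fixed
offsets, so results are reproducible across machines and independent of
evaluation order.

**What the benchmarks do not show.** The simulator draws reads i.i.d. from
a multinomial: no GC or length bias, no sequencing-error model, no
taxonomic covariance between KOs, no compositional coupling beyond the
shared simplex, and abundance independent of network position. Passing the
recovery benchmarks therefore demonstrates correctness of the counting,
wiring and scoring machinery under clean sampling noise — not robustness
to real annotation artifacts such as database redundancy or systematically
shifted e-values.

## Problem sizes and numerical conventions

The test suite runs entirely on generated data: edge-rule checks on random
tables of up to 30 reactions over up to 15 KOs (200 tables in the
verification suite); topology oracles on digraphs of up to 10 nodes, where
exhaustive path and triangle enumeration is exact; recovery studies at 50
KOs, 20 samples per state and 10⁴ reads per sample with planted log2 folds
of 1 and 2 — sizes at which binomial noise on the planted KO's log2 OR is
well under the 0.2 bias band being verified. Determinism conventions:
edges sort lexicographically; counts accumulate in doubles with identities
asserted to `1e-9`; BIOM numbers are written unrounded.

Degenerate inputs are defined, not errors, wherever a sensible value
exists: an empty reaction table yields the empty network; a sample with no
enzymatic reads keeps an all-zero row (with a warning); an empty SSN
yields an empty topology result. Errors are classed conditions
(`konet_parse_error`, `konet_validation_error`, ...) so the command-line
layer can map them to exit codes (2 for usage, 1 for data errors) without
string matching.

## Scope and limitations

The package deliberately stops short of: stoichiometry, mass balance and
flux modeling (edges encode adjacency, not rates); compound-level
bipartite views; copy-number or genome-size correction of abundances;
rarefaction; statistical testing of differential scores; and more than two
states per contrast. Live annotation or pathway-database services are out
of scope by design — all inputs are documented file dialects, which makes
every analysis reproducible from the files alone.
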