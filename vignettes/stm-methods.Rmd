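---
title: "Randomized Steiner-tree marker discovery: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomized Steiner-tree marker discovery: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmarker)
```

## The problem and the model

Differential-expression analyses of the same disease on different cohorts
notoriously disagree: gene lists selected independently from two breast
cancer metastasis cohorts can share only a handful of genes. A recurring
observation in network biology is that the genes that *connect*
differentially expressed (DE) genes in a protein–protein interaction (PPI)
network — rather than the DE genes themselves — are often the ones with a
mechanistic role in the disease. `stmarker` operationalizes that idea as a
Steiner tree problem.

Given an edge-weighted undirected graph $G = (V, E, w)$ and a terminal set
$R \subseteq V$ (the DE genes mapped onto the network), a Steiner tree is a
minimum-weight connected subtree spanning all of $R$, possibly passing
through non-terminal *Steiner vertices*. The problem is NP-hard, so we use
the classical shortest-path 2-approximation heuristic:

1. start with a forest consisting of the terminals and no edges;
2. while the forest is disconnected, find the two forest vertices in
   different components at minimum weighted shortest-path distance and add
   every vertex of that path to the forest;
3. build a minimum spanning tree of the subgraph of $G$ induced by the
   collected vertices;
4. iteratively delete non-terminal leaves.

The candidate markers from one tree are its **internal vertices** (tree
degree > 1): all Steiner vertices plus the terminals that are internal,
since both actively connect the remaining DE genes. Because step 4 removes
every non-terminal leaf, "internal vertex" and "degree > 1" coincide.

A single tree is one of many near-optimal solutions, and alternative trees
can represent redundant or parallel pathways. To collect them without
modifying the algorithm, every edge is assigned an independent uniform
random weight in $[0.99, 1)$ and the tree is recomputed; the narrow band
below 1 leaves shortest paths hop-count-optimal while breaking ties among
equal-length paths at random. The union of internal vertices across the
randomized ensemble is the set of **Steiner-tree-based markers (STMs)**.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `weight_low`, `weight_high` | 0.99, 1.0 | perturbation band (dimensionless edge weights). The band must stay above $1 - 1/\mathrm{diam}$ so that a longer path can never undercut a shorter one; at width 0.01 this holds for any path up to 100 edges, far beyond PPI diameters. Sampling is on the half-open interval — no result can depend on a measure-zero endpoint. |
| `max_iterations` | 500 | hard cap on ensemble size |
| `patience` | 50 | stop after this many consecutive trees contributing no new marker. The published account of convergence is informal ("the rate of new markers drops after a few hundred iterations"), so the package fixes an explicit, configurable rule: patience-50 early stop under a 500-iteration cap. |
| `seed` | 1 | master seed; iteration $i$ reseeds from $(\mathrm{seed} + 10007\,i) \bmod (2^{31}-1)$, so a run's prefix is identical however early stopping triggers |

The union is deliberately plain: no frequency threshold filters the
markers (per-tree occurrence counts are recorded as metadata only), and no
multiple-testing correction is applied to the overlap tests, matching the
method as published.

## Numerical and design choices

**Tie-breaking.** With exactly equal weights (e.g. the unperturbed unit
graph), ties in the closest-pair search and in the spanning tree are broken
lexicographically by vertex name, making single-tree runs deterministic. In
ensemble use the perturbation makes ties a probability-zero event, which is
the intended mechanism. Vertices are handed to the compiled core renumbered
in name order, so "smallest index" and "lexicographically smallest name"
agree.

**Distances.** Step 2 uses Dijkstra shortest paths under the *perturbed*
weights of the current iteration, and step 3 reuses the same weights. The
forest-merging formulation is implemented as printed rather than any
further-optimized variant; the compiled core keeps one full distance and
predecessor row per forest vertex so each merge costs one scan plus one
Dijkstra per newly added path vertex.

**Degenerate inputs.** A single terminal yields the one-vertex, zero-edge
tree. Terminals in different components are an error naming the offending
genes — the intended workflow is `largest_component()` then
`restrict_terminals()`, which also reports seed genes absent from the
network (platform mismatches are the caller's problem: identifiers are
opaque strings, and no translation layer is attempted). Self-loops in edge
lists are dropped and counted rather than rejected, because public PPI
dumps contain them. Weights read from a three-column edge list are
honoured by `steiner_tree()`, but the discovery ensemble overwrites them
with its own perturbation — the method is defined on the unweighted
interaction graph.

**Overlap statistics.** The stability of two marker sets is their percent
overlap $100\,o/(m+n-o)$ and the one-sided Fisher's exact
(hypergeometric upper-tail) p-value against the $N$ genes of the network's
largest connected component. Published values reach $10^{-159}$, far below
double underflow, so the tail is summed in log space with `lchoose` and
log-sum-exp; `log10_p` is the authoritative output for $p < 10^{-15}$, and
the linear value is clamped at the smallest positive double. Impossible
tail terms contribute probability zero. The implementation is checked in
the test suite against exact rational enumeration for all $N \le 12$ and
against `phyper` wherever the latter does not underflow.

**Classification.** `evaluate_features()` estimates the discriminative
power of a marker set by repeated stratified $k$-fold cross-validation
(default $100 \times 10$-fold) with unregularized logistic regression or a
linear-kernel SVM at default cost — no tuning and no internal feature
selection, so the evaluation reflects the full marker set rather than a
classifier's pruning of it. The published protocol does not say whether
folds were stratified nor how per-run AUC was aggregated; the package
stratifies (the defensible default when the event class is a 27–37%
minority) and computes one AUC per repetition from the pooled out-of-fold
scores (lower variance than per-fold averaging). Fold assignments derive
from the seed, so two feature sets evaluated with the same seed share
splits and can be compared run by run with a paired t-test
(`paired_run_comparison()`, with an epsilon guard for zero-variance
differences).

## What the synthetic benchmark emulates — and what it does not

Real inputs (cohort microarrays, curated PPI networks) are not
distributed, so the package ships a generator whose defaults define its
reference benchmark: a preferential-attachment network of 2000 genes
(3 edges per new node, giving heavy-tailed degrees like a PPI network), 20
high-degree pairwise non-adjacent hubs planted as hidden "disease"
connectors, 100 DE seed genes drawn from the connectors' neighborhoods
(so connectors lie on many shortest paths between seeds), and a 200-sample
two-class expression matrix in which DE genes are mean-shifted by 2
within-class standard deviations. The sample size and class balance are in
the range of the original cohorts; the effect size is chosen so that a
plain t-test detects essentially all DE genes, isolating the network
machinery from the DE-selection step (which is an external input to this
package, not part of it).

The generator reproduces only the features the method relies on:
heavy-tailed degrees, connectors bridging seeds, Gaussian class shifts. It
does *not* emulate PPI clustering structure, correlated expression,
batch effects, or cross-platform noise. Passing the planted-connector
recovery and classification checks therefore demonstrates that the
implementation does what the method claims under its own assumptions — not
that the markers would validate on real cohorts. Published cohort-specific
numbers (marker counts near a thousand per cohort, coverage of curated
susceptibility genes, absolute cross-data AUCs) require the original data
and are out of reach by design.

Problem sizes used in the automated checks are chosen at desk scale: exact
brute-force comparisons on graphs of at most 12 nodes (the solver
enumerates subsets of non-terminals, so 16 nodes is its default refusal
bound), recovery benchmarks at the default 2000-node scenario across 10
seeds, and classification checks at 200 samples with 100 features.

## Known limitations

- The heuristic guarantees only a factor-2 approximation; the ensemble
  mitigates but does not remove suboptimality.
- The union over trees has no significance filter; on very dense networks
  the STM set can grow large before the patience rule triggers.
- Cross-dataset evaluation assumes the two expression matrices share gene
  identifiers; no expression harmonization is performed.
- `steiner_exact()` is exponential and refuses more than 16 nodes; it
  exists as ground truth for tests, not as an analysis tool.
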