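---
title: "Inferring and comparing gene logic networks"
author: "logicnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and comparing gene logic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logicnet)
```

## The model

logicnet asks, for every ordered gene triplet, whether a target gene C is
*better predicted by a logic function of two genes A and B together than by
either gene alone*. Triplets that pass this test become directed hyperedges
(A, B) → C of a *logic network*, whose structure is then summarized by four
parameters — degree, clustering, path length, betweenness — generalized from
ordinary graphs to this hypergraph, and compared between two experimental
conditions to nominate *structural key genes*.

### Discretization

Expression vectors are first min-max normalized to [0, 1] (per gene, over
the pooled samples of both conditions, so both networks share one scale)
and then discretized onto `2k` symbolic levels: `k` "down" levels
$x_i = (i-1)/2k$ below 1/2 and `k` "up" levels $x^i = 1-(i-1)/2k$ at or
above it. The granularity `k` is the first tunable parameter
(dimensionless, default `k = 1`, the Boolean case); larger `k` retains
more expression detail but fragments the sample into more level
combinations, so entropy estimates degrade quickly with the few dozen
samples typical of expression studies.

Discretization intervals are half-open `[lo, hi)`; the midpoint 1/2 falls
on the up side and the value 1 maps to the top level. (Closed intervals
would overlap at every boundary.) Levels are stored as integer codes so
comparisons are exact; negation is the code mirror $x_i \leftrightarrow x^i$,
AND is the componentwise minimum of level values, OR the maximum.

### Scoring a triplet

For a discretized vector the *down-* and *up-regulation self-entropies*
are the entropy contributions of the down and up levels; they sum to the
ordinary Shannon entropy $H$ (base 2 throughout — the base cancels in the
score but not in reported entropies). Joint entropies are likewise split
over the four sign quadrants of the joint level distribution. Frequencies
are maximum-likelihood plug-ins without smoothing; no bias-corrected
estimators are used.

The *uncertainty coefficient*
$$U(C\,|\,F) \;=\; \frac{H(C) + H(F) - H(C, F)}{H(C)}$$
is normalized mutual information: 1 when $F$ determines $C$, 0 under
independence. It is clamped to [0, 1] to absorb floating-point negatives,
and undefined for constant targets ($H(C)=0$), which are skipped.

$F$ ranges over ten two-argument *proper functions* built from min, max
and negation: AND, NAND, OR, NOR, the two asymmetric conjunctions, the two
implications, XNOR and XOR. The printed XNOR formula in the source
material reduces to a single implication and cannot express equivalence;
the package uses the standard min-of-implications form, whose `k = 1`
truth table is A↔B. Because negating a predictor merely relabels its
levels, every function scores identically to its complement (AND~NAND,
OR~NOR, XNOR~XOR, each conjunction with the opposite implication): a logic
type is identifiable from data *only up to complement*. Ties are broken
toward the lowest type id, and `equivalent_logic_types()` exposes the
equivalence classes for downstream comparisons.

### The acceptance filter

All raw U values of a dataset — second-order and first-order — are
normalized by the single dataset-wide maximum ("U / max U" within each
condition's own database), and a relation is accepted iff
$$U(C\,|\,f_2(A,B)) \;\ge\; \max\{\,U(C\,|\,A),\; U(C\,|\,B)\,\} + t .$$
The threshold `t` (dimensionless, on the normalized U scale) is the second
tunable parameter. It trades sensitivity against specificity: the accepted
set is nested and shrinks as `t` grows, so a sweep over `t = 0.1 … 0.9`
(step 0.1, `run_pipeline`'s sweep mode) shows how every structural
parameter responds to the threshold. The default `t = 0.3` keeps planted
relations with ~10 % level noise while rejecting almost all noise triplets
in the presence of genuine signal; note that on a dataset with *no* signal
the self-normalization makes the bar scale with the noise maximum, so
low-`t` scans of null data accept liberally — the screening step and real
biological signal are what anchor the scale in practice.

Source pairs are unordered (the asymmetric function variants cover both
orderings) and only the best function per (pair, target) is kept.

### Candidate screening

Scanning is cubic in the number of genes, so genes are first screened with
the Wilcoxon rank-sum statistic $T_0/n_0 - T_1/n_1$ (per-sample mean rank
difference between conditions, zero-expectation under the null). The
two-sided p-value uses the normal approximation with midranks,
tie-corrected variance and continuity correction; the cut `alpha`
(default `1e-5`, matching the stringency used for genome-scale chips) is
the third tunable parameter. No multiple-testing correction is applied —
the screen is a computational funnel, not an inference.

## Structural parameters of the hypergraph

* **Degree** — each relation adds 1 to its target's in-degree and 1/2 to
  each source's out-degree, so in- and out-degree totals both equal the
  relation count.
* **Doublet clustering** — a *doublet* at node v is an unordered pair of
  relations incident to v; it is *strong connected* when the two relations
  share a second node besides v. The clustering coefficient of v is the
  strong fraction of its doublets (0 when it has none).
* **Path length** — edge lengths are reciprocal uncertainty coefficients.
  AND relations require both tails: $d = \max(d_{tails}) + 1/U$ (from a
  tail, the path routes through the other tail). OR relations split U
  equally over the two sources, giving branch length $2/U$ from either
  tail, minimized over branches. XOR relations behave like AND when both
  tails are reachable (or the query source is a tail) and like OR when
  exactly one is. The network average is taken over all ordered pairs at
  finite distance; the per-node value used in comparisons is the
  source-role mean of finite outgoing distances (a declared choice — the
  per-node variant is not otherwise pinned down).
* **Betweenness** — the fraction of all tied shortest paths (over all
  ordered finite pairs, deduplicated by node sequence) that contain the
  node as an intermediate; always in [0, 1].

### Numerical conventions

Distances are computed by a two-phase label-correcting relaxation: a
monotone reachability closure first (an XOR head is reachable when at
least one tail is), then distance relaxation with each XOR relation's
AND/OR rule pinned by that final reachability. The pinning matters: the
XOR rule switch is not monotone in intermediate labels, and rare cyclic
XOR/AND dependencies admit no self-consistent rule assignment at all —
such nodes are conservatively left unreachable, so a node can be
reachability-closed yet have infinite distance. Distance ties are compared
with absolute tolerance 1e-9; all tied shortest paths enter the
betweenness path set, capped at 64 per ordered pair. Traversal depends
only on a relation's AND/OR/XOR class (types 1, 2, 4, 5a, 5b / 3, 6a, 6b /
7, 8); inhibitory polarity is deliberately ignored.

## Communities and the two-network comparison

The hypergraph is projected onto an undirected simple graph (edges
source–target for every relation) and partitioned with the Newman fast
greedy modularity algorithm (igraph's implementation; the partition is cut
at the maximum-Q step of the merge sequence, which igraph's default cut
does not always return). Modularity is unweighted. Each community is
summarized by its inside/crossing edge ratio $\alpha = n_1/n_2$
(infinite for a component with no crossing edge).

Two condition-specific networks are compared per node over the union gene
set (a gene absent from one network scores 0 there): for each of total
degree, mean path length, clustering and betweenness, genes are ranked by
absolute difference (descending, ties by gene id) and the intersection of
the four top-`top_n` lists is the set of structural key genes. `top_n`
defaults to 6 and is configurable.

## The synthetic-data generator

`generate_expression_dataset()` emulates a realistic two-condition
microarray layout so the entire pipeline is testable without external
data: two conditions with unequal
sample counts (defaults 42 and 52), nonnegative expression, a subset of
genes location-shifted between conditions (default shift 5 expression
units, directions alternating so both tails occur; down-shifts truncate at
zero to preserve nonnegativity), and planted relations C = f2(A, B)
corrupted by level noise among independent decoys.

Decoys are lognormal(0, 1), mimicking skewed nonnegative microarray
intensities. One consequence is deliberate: a min-max-normalized lognormal
vector discretizes at `k = 1` to roughly 90 % down levels, and the AND of
two such sparse vectors is almost always constant (unscorable). Planted
*source* rows are therefore drawn from a balanced 50/50 low/high bimodal
mixture, so every function type produces a scorable target; decoys keep
the skewed profile. Planting works in discretized space and writes the
target row as the midpoint of each level's interval, which survives
normalization exactly whenever the planted row spans both extreme levels —
always true at `k = 1` for non-degenerate rows. At `k ≥ 2` a row missing
an extreme level re-discretizes to a strictly monotone recoding: the
functional dependence (hence U = 1 at zero noise) is preserved exactly,
but individual level labels may shift. `noise_prob` randomizes that
fraction of samples uniformly over the levels, so the realized
disagreement rate is about half the nominal noise.

What the generator does **not** model: probe-level artifacts,
normalization pipelines, correlated decoys, batch effects, or any
dependence structure beyond the planted triplets. Passing tests therefore
demonstrate correctness of the algorithms under the stated generative
assumptions, not performance on real microarray data.

## Problem sizes and test design

The test suite exercises the scan at 35 genes × 60 samples (≈ 6,500
triplets), noise precision at 20 genes × 100 samples, hyperpath distances
against an exhaustive recursion oracle on networks of ≤ 8 nodes and ≤ 6
relations over 100 seeds, community detection against brute-force
enumeration of all 4,140 partitions of 8 nodes, screening calibration with
10,000 null replicates, and an end-to-end two-condition run with a planted
condition-specific hub of 14 genes. These sizes were chosen so every check
runs from scratch in seconds while keeping the estimates' Monte-Carlo
error well below the tested margins.

One operating characteristic is worth knowing: with 10 % level noise,
`t = 0.3` and ~60 samples, the acceptance margin of AND/OR-class planted
triplets is close to zero, so single-seed recovery of *every* planted
triplet is a coin flip even though per-relation recovery is high; the
recovery checks in `scripts/acceptance.R` therefore report a rate over
replicate datasets.

## Known limitations

* Logic types are identifiable only up to complement; reported types are
  canonical representatives.
* The U normalization is relative to each dataset's own maximum, so
  thresholds are not transferable between datasets with different signal
  strength, and null datasets self-normalize noise upward.
* Entropy plug-ins are biased upward at small sample sizes; with the
  default `k = 1` and ≥ 40 samples the bias is well below the acceptance
  margins, but larger `k` needs proportionally more samples.
* Networks of a few hundred nodes are the intended scale; the all-pairs
  path enumeration is exhaustive, not approximate.
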