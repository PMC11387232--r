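---
title: "Methods: motif-based TRN inference and structural analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-based TRN inference and structural analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizotrn)
```

## The inference model

`rhizotrn` infers a directed transcriptional regulatory network from two
kinds of motif evidence and a genome annotation:

1. a clustering of per-gene position weight matrices (PWMs) by similarity,
   in the `clusters_motif_names.tab` format (one cluster id per line
   followed by matrix names `<gene>_m<k>`), and
2. a table of motif-scan hits, each a (regulator, target gene, p-value)
   record meaning the regulator's matrix matched the target's promoter.

The underlying biological assumption is that a regulator and its targets
share a binding motif: if a TF's matrices cluster with the matrices of
other genes, those genes are candidate regulon members, and the scan
p-value grades the evidence. Because each gene carries up to five deduced
matrices, clusters frequently group several matrices of the same gene;
deduplication to *unique genes* precedes every rule. A cluster seeds the
search only if it contains at least two distinct genes and at least one
regulator. Sigma factors are tracked separately from TFs in all composition
counts, but they act as regulators everywhere: they satisfy the one-TF
cluster rule and may source edges.

### The stratified three-tier target search

Edges are assigned in three passes at thresholds 10⁻⁶, 10⁻⁵, 10⁻⁴
(inclusive; `1e-06` exactly is strict):

* pass 1 (STRICT): every candidate hit by *any* regulator at p ≤ 10⁻⁶
  receives edges from *all* regulators hitting it at that threshold, and is
  removed from the candidate list;
* pass 2 (MEDIUM) and pass 3 (LOW): the same rule on the remaining
  candidates at the next thresholds.

Two consequences matter. First, a target holds edges in exactly one tier —
the strictest stratum any regulator reaches — so the network is built from
the lowest p-values possible and `tier_composition()` is a meaningful
quality report. Second, within that tier *all* qualifying regulators keep
their edges: genes regulated by dozens of TFs are representable, which
single-best-edge retention would forbid. Duplicate hits for one
(regulator, target) pair — the several matrices of a gene produce them —
collapse to the minimum p-value *before* tier assignment. Candidates never
hit at p ≤ 10⁻⁴ are excluded from the node set by default
(`keep_isolated = FALSE`); whether such genes should persist as isolated
nodes is genuinely open, so it is a flag rather than a fixed choice.

## Hierarchy reconstruction

Edge (a, b) is *descendent* when kout(a) > kout(b), strictly, with kout
computed on the full network including self-loops (self-regulation is a
first-class feature here, so a self-loop contributes to out-connectivity;
it can never be descendent since kout(a) > kout(a) is false). All other
edges — ties, reversals, self-loops — are *ascendant* and constitute the
feedback. Because kout strictly decreases along every descendent edge, the
descendent subgraph is acyclic by construction; this is verified
property-style over random graphs in the test suite rather than assumed.

"Topological layering" is realized as Kahn-style peeling: layer 1 is the
set of nodes with no incoming descendent edge; those nodes and their
out-edges are removed and the peeling repeats. This is the minimal
algorithm satisfying the layer property (each node regulates only strictly
lower layers); no node is dropped, and the recorded ascendant edges can be
re-attached for display. The ascendant fraction is reported because the
layering only summarizes the network faithfully when it is small.

A separate breadth-first hierarchy (`bfs_hierarchy()`) emulates the
root-based layout view: level 0 is a root (named, or the maximal-degree
node under `"auto"`, ties lexicographic), each next level the unvisited
direct targets of the previous one. Directed traversal is the default;
level counts from the BFS view and from the topological layering answer
different questions and both are exposed, since reported "level" numbers in
this literature do not always say which view they use.

## Structural properties and normalization

The 13-entry property vector is designed for *cross-network* comparison, so
every raw quantity is normalized:

| property | definition |
|---|---|
| regulators_frac | nodes with kout > 0, / n |
| selfreg_frac | self-loops / n |
| kmax_out_frac | max kout / n |
| giant_component_frac | largest weakly connected component / n |
| density_times_reg_frac | m/(n(n−1)) × regulators_frac (self-loops excluded from m) |
| ffl_norm, complex_ffl_norm | motif count / [n(n−1)(n−2) · (TFn/n)²] |
| fbl3_norm | 3-cycle count / [n(n−1)(n−2) · (TFn/n)³] |
| avg_shortest_path | mean directed distance over reachable ordered pairs |
| diameter_norm | longest directed shortest path / (n − 2) |
| avg_clustering | mean local clustering, undirected projection, degree < 2 → 0 |
| r2adj_pk, r2adj_ck | adjusted R² of log₁₀–log₁₀ OLS on P(k), C(k) |

Motif counting is per unordered node triple (each triple contributes at
most once per motif class), with self-loops ignored. The *complex*
feed-forward loop is not a standard named motif; here it is defined as a
3-node feed-forward with mutual regulation between the two regulators
(A↔B, A→C, B→C). That definition is forced by its normalization — TFm = 2
regulators on a 3-node motif, distinct from the simple FFL — and a triple
realizing it is counted as complex, not also as a simple FFL, so the two
classes partition the convergent triangles. The implementation enumerates
triangles of the undirected projection and classifies their directed edge
patterns; the test suite checks it against an independent exhaustive
enumeration over all ordered triples for graphs up to n = 50.

The potential-motif denominator n!/(n−r)! · (TFn/n)^TFm is evaluated as a
falling factorial (no factorial overflow; at TFn = n it reduces to
n!/(n−3)!). TFn counts flagged regulators (TFs plus sigma factors).

Two normalization readings were genuinely ambiguous and are resolved as
defaults with flags:

* the diameter divisor "(number of nodes, 2)" is read as n − 2 (a
  shortcut-free chain interpretation); n/2 is available via
  `diameter_divisor = "n/2"`;
* P(k) and C(k) fits use total degree on the undirected projection — C(k)
  is undirected by construction and the two fits should share an x-axis;
  out-degree mode exists in `network_degrees()`.

Average shortest path averages over reachable ordered pairs only; no
infinite-distance imputation, because these networks have several
components. Degenerate regression inputs (fewer than 3 nonzero log–log
bins) yield `NA`, and `compare_networks()` handles `NA` pairwise-complete
with a reported mask.

### Erdős–Rényi null ensembles

Null replicates are directed G(n, m): m distinct ordered pairs, no
self-loops, uniform. Replicates are *not* matched on regulator count — the
plain G(n, m) is the stated null — and the per-property mean over
replicates (ER_avg) is the comparison profile. One analytic check in the
tests is worth recording: on the undirected projection of a directed
G(n, m), two nodes are adjacent when either ordered pair was drawn, so the
expected clustering is q·P(deg ≥ 2) with q = 1 − (1 − p)² and
p = m/(n(n−1)) — approximately 2p, not p. The test asserts the correctly
derived expectation.

Cross-network comparison min–max scales each property across networks
(constant columns to 0), applies Ward clustering (`ward.D2` on Euclidean
distances of scaled profiles) to networks and to properties, and computes
pairwise Pearson correlations of the raw profiles.

## Degree-distribution fitting

Degrees are integers, so all three families are discrete, with support
k ≥ xmin: geometric (the discrete exponential; closed-form MLE), power law
P(k) ∝ k^(−α) with α > 1 (1-D likelihood optimization; the Hurwitz-zeta
normalizer is computed by partial sum plus Euler–Maclaurin tail), and
truncated power law P(k) ∝ k^(−α)e^(−λk) with α > 1, λ > 0 (Nelder–Mead
over (log(α−1), log λ) from three fixed starts; deterministic). The α > 1
constraint is the conventional support of the discrete truncated family;
without it the family degenerates into the geometric at α → 0 and the
three-way comparison loses its meaning. Because the truncated family nests
the pure power law at λ = 0, the fit falls back to that boundary whenever
the optimizer cannot beat the pure power-law likelihood, so the truncated
likelihood is never inferior; the nesting is asserted on the likelihood, as
maximum-likelihood fitting does not guarantee an ordering of KS distances.

The KS distance is the supremum over observed degrees of |empirical CDF −
fitted CDF|. `xmin` is fixed at 1 by default — the networks of interest
have hundreds of nodes, too few for a stable tail-only xmin scan — but is a
parameter. `preference_report()` flags a verdict "indistinguishable" when
the KS margin between the two best families is below ε (default 0.005);
this is the honest outcome for small inferred networks, where the
exponential often cannot be excluded.

## Genome context

Neighbor groups link two genes of a set when they lie on the same replicon
with at most `max_gap` intervening genes; "distance of three genes" is read
as ≤ 3 intervening (ordinal gap ≤ 4) and the parameter is exposed because
the phrase admits readings off by one. Groups are connected components of
this relation — symmetric, order-independent, never spanning replicons —
numbered from 0 by smallest ordinal; singletons are not groups. Strand is
reported but never splits a group: operon-like blocks on opposite strands
are real. Module cross-tabulation consumes externally computed module
labels only (co-expression analysis itself is out of scope here) and always
conserves 100% per gene set via an "unassigned" bin.

## The synthetic-data generator

The generator exists so that every stage is testable offline; its defaults
are the study conditions, chosen once:

* 300 genes on 3 replicons, 40 TFs + 4 sigma factors (~15% regulators,
  the high-regulator regime typical of inferred condition-dependent
  networks);
* regulon sizes NB(mean 6, dispersion 2) — a few targets per regulator
  with occasional hubs;
* true-hit tier mixture 0.60 / 0.396 / 0.004, reproducing the observed
  regime of ≈ 60% strict edges and well under 1% in the low stratum;
* false-hit rate 10⁻³ per (regulator, non-target) pair, concentrated at
  weak p-values (half in the LOW stratum, half above 10⁻⁴ where the
  builder discards them) so tier composition is a meaningful dial;
* operon-block probability 0.3 with the same neighbor window used by
  `find_neighbor_groups()` — one neighborhood definition everywhere;
* self-regulation probability 0.2 for regulators with targets, since
  networks built from self-recognizing matrices are rich in self-loops;
* PWM noise: per-cell Poisson resampling scaled by the noise level
  (`rpois(counts/κ)·κ`), which preserves non-negativity and collapses to
  exact copies at κ = 0. Each gene carries 1–5 matrices, capped at 5 even
  when a gene sits in several regulons (later clusters re-expose existing
  matrices).

What the generator *does not* emulate: actual promoter sequences or motif
scanning (p-values are sampled, not computed from alignments), matrix
quality differences between genes, operon structure beyond ordinal
adjacency, and any condition dependence of expression. Passing tests
therefore demonstrate that the pipeline's logic is correct under its own
statistical assumptions — exact recovery of a planted network in the
noise-free limit, monotone precision loss with the false-hit rate — not
that real motif scans have these error characteristics.

`cluster_pwms()` is likewise a stand-in for external matrix-clustering
tools, kept deliberately simple (max-Pearson over ungapped offsets and both
orientations, average-linkage cut at 1 − threshold): real runs consume an
externally produced cluster file, and the stand-in exists so synthetic runs
need no external tool. It is not a reproduction of any specific tool's
similarity metric.

## Problem sizes and determinism

The test suite exercises: 100 random hit tables (≤ 200 genes) against a
brute-force tier oracle; exact planted-network recovery over 20 seeds;
hierarchy invariants over 200 random graphs (n ≤ 100); motif counts against
exhaustive enumeration on 50 graphs (n ≤ 50); an ER ensemble at n = 200,
m = 600, 50 replicates against the analytic clustering expectation; and
50 + 50 parameter-recovery replicates at sample size 1,000 for the
power-law (α = 2.5, recovered within ±0.3) and geometric families. These
sizes keep the full suite under two minutes on one CPU while leaving each
stochastic check enough replicates for its stated tolerance. Every source
of randomness flows from explicit integer seeds; the pipeline writes a
manifest and identical configuration reproduces outputs byte-for-byte.

## Known limitations

* Edge signs are not modeled: the construction predicts positive
  regulation candidates only, and repression is invisible to it.
* The inferred "regulation" is motif co-occurrence; the method cannot
  distinguish direct binding from conserved motif chance co-location, and
  tier composition only bounds, never removes, false positives.
* Networks with very few distinct degrees defeat the distribution fits
  (degenerate-sample error) — by design, since a three-family verdict on
  such data would be noise.
* `compare_networks()` requires a shared property set; properties that are
  `NA` for some networks reduce the effective dimensionality of exactly
  those comparisons.
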