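# rhizotrn

Inference and structural analysis of bacterial transcriptional regulatory
networks (TRNs) from DNA-motif evidence.

Many bacteria of interest — notably the multi-replicon rhizobia that fix
nitrogen in symbiosis with legumes — lack the ChIP-seq-scale experimental
data behind curated TRNs such as those of *E. coli* or *B. subtilis*. What
is often available instead is motif evidence: position weight matrices
(PWMs) deduced per gene from promoter footprints of orthologs, genome-wide
motif-scan hits with p-values, and a clustering of the matrices by
similarity. `rhizotrn` turns that evidence into a directed TRN and
characterizes its structure, for computational biologists who want a
reproducible, testable version of this class of pipeline.

## What it computes

**Network construction.** Matrix clusters (`clusters_motif_names.tab`
format) are deduplicated to unique genes; clusters with ≥ 2 distinct genes
and ≥ 1 regulator (TF or sigma factor) seed the search. Targets are then
assigned by a stratified three-pass search over scan hits: every candidate
hit by any regulator at *p* ≤ 10⁻⁶ takes edges from **all** regulators
reaching it at that stringency and leaves the candidate list; the remainder
is searched at *p* ≤ 10⁻⁵, then *p* ≤ 10⁻⁴. Each target therefore carries
edges in exactly one tier — the strictest any regulator attains — and the
network is built from the lowest p-value relationships possible.

**Hierarchy.** Each edge (a, b) is *descendent* if k<sub>a</sub><sup>out</sup> >
k<sub>b</sub><sup>out</sup>, otherwise *ascendant*. Removing the ascendant
(feedback) edges leaves a DAG, which a Kahn-style topological layering
converts into ordered layers where a node regulates only lower layers. A
breadth-first root hierarchy is also provided.

**Structural properties.** Thirteen normalized properties per network:
regulator, self-regulation, maximum out-connectivity and giant-component
fractions; density × regulator fraction; feed-forward, complex feed-forward
and 3-feedback loop counts normalized by the potential-motif number
n!/(n−r)! · (TF<sub>n</sub>/n)<sup>TF<sub>m</sub></sup>; mean shortest path;
normalized diameter; mean clustering coefficient; and adjusted R² of
log–log P(k) and C(k) fits. Profiles are min–max scaled across networks,
clustered by Ward's method, and compared against directed Erdős–Rényi
G(n, m) null ensembles. Shortcut fractions and regulator/structural
proportions round out the suite.

**Degree-distribution fitting.** Maximum-likelihood fits of the nonzero
degree sequence to discrete exponential, power-law and truncated power-law
families, ranked by Kolmogorov–Smirnov distance, with an
"indistinguishable" flag when the margin between the two best families is
tiny.

**Genome context.** Regulon annotation by COG category and gene number,
neighbor-gene group detection (same replicon, bounded intervening-gene
count), and cross-tabulation of gene sets against externally supplied
co-expression module labels.

**Synthetic data.** A seeded generator produces multi-replicon genomes,
planted regulons, stratified scan hits, TRANSFAC matrices and cluster files
with controllable noise, so the full pipeline is testable end to end
without any external database.

## Worked example

```r
library(rhizotrn)

cfg    <- synth_config(n_genes = 200, n_tfs = 25, n_sigma = 3, seed = 42)
genome <- generate_genome(cfg)
truth  <- generate_truth_network(genome, cfg)
hits   <- generate_scan_hits(truth, genome, cfg)
cluster_file <- tempfile(fileext = ".tab")
pwms <- generate_pwms_and_clusters(truth, genome, cfg, cluster_file)

clusters <- parse_cluster_file(cluster_file, genome)
sel <- select_clustered_tf_clusters(clusters, genome)
net <- stratified_target_search(sel$tfs, sel$genes, hits, genome = genome)
net
#> <reg_network> clustered-TF network - 127 nodes, 152 edges
#>   regulator-flagged nodes: 27 | self-regulations: 4

tier_composition(net)
#>   tier   n_edges percent
#> 1 STRICT     120  78.9
#> 2 MEDIUM      31  20.4
#> 3 LOW          1   0.658

layer_hierarchy(net)
#> <hierarchy_layering> 4 layers; 4.61% ascendant (feedback) edges
#>   layer 1: 14 node(s)
#>   layer 2: 58 node(s)
#>   layer 3: 41 node(s)
#>   layer 4: 14 node(s)

fit_distributions(network_degrees(net))[, c("family", "ks_distance")]
#>   family              ks_distance
#> 1 power_law                0.0339
#> 2 truncated_power_law      0.0356
#> 3 exponential              0.1851
```

Reading the output: about 79% of the network's regulator–target relations
sit in the strict (*p* ≤ 10⁻⁶) stratum and under 1% in the low stratum, the
quality profile this construction aims for; under 5% of edges are feedback
(ascendant), so the four-layer hierarchy summarizes the network faithfully;
and the degree distribution is far from exponential, though the power-law
and truncated power-law fits are nearly indistinguishable — exactly the
kind of verdict `preference_report()` flags.

A whole run (cluster selection → network → hierarchy → properties → fits →
genome context, with all TSV outputs and a manifest) is one call:

```r
run_pipeline(list(seed = 42, out_dir = "run1",
                  synthetic = list(n_genes = 200, n_tfs = 25, n_sigma = 3)))
```

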