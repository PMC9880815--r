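---
title: "Methods: motif, hub and hierarchy analysis of TF–miRNA networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif, hub and hierarchy analysis of TF-miRNA networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirffl)
```

# The model

`mirffl` analyses integrated gene regulatory networks that combine three
directed interaction classes: transcription factor → target gene (TTI),
transcription factor → miRNA locus (TMI), and miRNA → target (MTI). Nodes
carry one of four roles — `core_tf` (TFs with genome-wide binding data),
`tf`, `mirna`, `target_gene` — and edges are constrained by role: TTIs and
TMIs emanate from TFs, MTIs from miRNAs, and TTIs never point at a miRNA
locus. Typical networks of this kind in plants comprise a few thousand nodes
and tens of thousands of edges; the statistics below (degree balance, motif
enrichment, hub and layer structure) are the quantities through which such a
network is usually interpreted.

Edges are identified by `(source, target, edge_class)`; the same ordered
pair may carry both an MTI and a TTI (a miRNA and a TF converging is
impossible by the role constraints, but a TF target that is also predicted as
a miRNA target is not). Motif and degree statistics operate on the simple
digraph of distinct directed adjacencies. Self-loops are stored and flagged
but excluded from degrees, motifs, hub rules and layers, because the
three-node loop definitions are loop-free.

## Degree statistics

The O/T ratio of a node is its out-degree over total degree. Summing over
the network, every edge contributes one out- and one in-degree, so the
network-level O/T ratio is exactly 0.5 whenever at least one edge exists —
an identity the package asserts rather than estimates, and a useful check
on any assembled network.

Mean connectivity is defined as the mean over nodes of (total degree)/2, so
that the whole-network value equals |E|/|N| (e.g. 9.68 for a network of
2,096 nodes and 20,282 edges). For node subsets (e.g. the miRNA nodes) the
same per-node statistic is averaged over the subset. Because the subset
formula is not uniquely determined by the network-level identity, a
`raw_degree` variant (plain mean total degree, twice the default) is also
exposed; both are reported where it matters.

Clustering coefficients are computed on the undirected simple projection
(parallel and antiparallel edges collapsed); nodes with fewer than two
neighbours get CC = 0, matching the convention of the usual network-analysis
GUIs. Betweenness and closeness are computed on the directed graph;
closeness of a node is (number of reachable nodes)/(sum of directed
distances to them), undefined when nothing is reachable. The degree
power-law exponent is fitted by least squares on the log–log degree
histogram with zero-count bins dropped — a descriptive fit, not a maximum
likelihood estimate.

# Peak-to-gene assignment

A ChIP binding peak is linked to a locus when the peak midpoint falls inside
the locus's binding window. Windows are strand-aware and anchored at the
first transcribed base: 2000 bp upstream to 300 bp downstream of the TSS
for coding genes, and 2000 bp upstream (no downstream extension) of the
first base of the pre-miRNA for miRNA loci. Coordinates are 0-based
half-open internally (BED-native; GFF3 is converted on read); windows are
closed intervals, inclusive at both ends, clipped at zero; the midpoint of
an even-length peak is the lower median base. These conventions are fixed
and documented because assignment results at window boundaries depend on
them. A peak may be assigned to every window containing its midpoint — no
nearest-gene tie-breaking — and assignments are collapsed to unique
(TF, gene) pairs with supporting peak counts when building candidate
TMI/TTI edges.

Peak genomic context is classified by midpoint with the priority
5' UTR > 3' UTR > exon > intron > intergenic when features overlap. The
priority is a package choice (configurable), mirroring the order in which
such contexts are usually reported.

# MTI compilation

Candidate miRNA–target pairs from two prediction programs (filtered by
penalty score at read time; 2.2/2.5 and 2.5/3.0 are the conventional
stringency pairs) are merged by the rule

> result = (A ∩ B) ∪ ((A ∪ B) ∩ degradome-supported),

i.e. dual-program agreement, or single-program calls rescued by degradome
(PARE) cleavage evidence. Degradome compatibility is consumed as a boolean
per pair (with an optional category tag); cleavage-site classification is
out of scope. Curated/validated pairs are then unioned in, so the final
count is |pipeline| + |curated \ pipeline|. Benchmark evaluation reports
the recovered fraction of a validated pair set per candidate set and leaves
the choice of operating point (coverage vs false-positive tradeoff) to the
user. Pair identity is at gene level; transcript isoforms are collapsed.

# Motif census and enrichment

A feed-forward loop (FFL) is an ordered triple (X, Y, Z) with edges X→Y,
Y→Z and X→Z; a feedback loop (FBL) is a directed 3-cycle, the isomer in
which the direct edge is reversed. Two census modes are provided:

* **induced** (default): a triple counts only if the induced subgraph on
  its three nodes contains exactly the pattern edges — the standard
  subgraph-type census convention, and the mode cross-checked against
  igraph's triad classification (classes 030T and 030C) in the tests;
* **match**: every role assignment satisfying the pattern counts,
  tolerating extra edges among the triple. Per-hub loop fans in dense
  neighbourhoods are better described in this mode.

FFLs are counted per role assignment (the roles are distinguishable; in an
induced FFL the assignment is unique per node set), FBLs once per unordered
node set (a 3-cycle has three rotations). Match-mode counts always dominate
induced counts.

Enrichment is scored against a permutation null that preserves the number
of nodes and the number of distinct non-self edges while redrawing the
connections uniformly (a simple digraph each time). This is the literal
"size-only" null; a `role_preserving` option additionally redraws each edge
class only among role-compatible pairs, and preserves per-class edge
counts. Degree-preserving edge swaps are deliberately not the default. The
Z-score is (observed − null mean)/null sd per motif class; when the null sd
is zero, Z is 0 if the observed count equals the null mean and signed
infinity (with a warning) otherwise. Results are bit-for-bit reproducible
for a fixed seed and permutation count.

miRNA positions within FFLs are tallied with the miRNA-containing loops as
denominator; a loop with miRNAs at two positions contributes to each
position and is counted separately, so position counts sum to at least the
number of miRNA-containing loops. FFL coherence multiplies the signs of the
indirect path (activating = +1, repressing = −1) and compares with the
direct edge: equal signs are coherent, opposite incoherent, any unknown
sign leaves the loop unclassified. Proportion comparisons use the Pearson
chi-square on the 2×2 table without continuity correction by default (a
flag restores the Yates correction).

# Hubs and hierarchy

Hub rules are strict inequalities: in hubs have in-degree > 10, out hubs
out-degree > 10; party/date candidates have out-degree > 5 and clustering
coefficient above the network average CC_a (computed once on the full
network). Candidates split into **party** hubs (targets share similar
functional annotation, acting within one module) and **date** hubs
(dissimilar targets, bridging modules). The package quantifies "similar" as
the mean pairwise Jaccard index over the GO term sets of the annotated
targets, party at or above a threshold of 0.3 by default. This replaces a
manual curation step with a reproducible rule; the threshold is exposed and
candidates with fewer than two annotated targets are reported as
unclassifiable. Topological generalization of a hub's loop fan is
summarised as the number of FFLs with the hub as intermediate node and the
numbers of distinct input and output partners.

Hierarchy is assigned on the TF–miRNA core network (the induced subnetwork
on TF and miRNA nodes). Nodes with CC strictly above the core CC_a form one
layer; the remaining nodes split by degree (threshold 10, "no less than"
inclusive): out-heavy nodes (D_out ≥ 10, D_in < 10) versus in-heavy nodes
(D_in ≥ 10, D_out < 10). The package maps the high-CC group to the
**middle** layer, out-heavy regulators to the **top** and in-heavy nodes to
the **bottom**: the middle layer is the natural home of the high-CC group
because high clustering is rare in sparse digraphs (the printed middle
layers of such analyses are the smallest) and because the out-heavy group
is dominated by the broadly binding core TFs that iconographically sit on
top. Nodes matching neither degree sub-rule default to the bottom layer so
the partition is total; CC ties with CC_a fall to the non-middle branch
(the rule says strictly "greater"). All of this is a documented
interpretation — the underlying published rule does not name the layers —
and the mapping is configurable in spirit: the returned table carries `cc`,
`d_in`, `d_out` so any other mapping can be derived.

FFL layer orientation compares layer(X) against layer(Z) under
top > middle > bottom and reports the higher/equal/lower tally, overall and
for the miRNA-containing subset.

Expression overlays compare relative expression (mutant vs wild-type
log-ratios) between node groups per condition with the rank-sum
(Mann–Whitney) test by default; a t-test is available. The figure legends of
the source analyses cite a chi-square test for these panels, which is not
directly applicable to continuous expression values; the rank-sum test is
the package's choice and is recorded as such. Groups with fewer than three
measured members are summarised but not tested.

# The synthetic-data generators

Because networks of this kind derive from dozens of ChIP experiments and
predictor runs that cannot be reproduced at desk scale, every pipeline
stage is exercised on synthetic data with planted ground truth.

`simulate_network()` draws per-class Bernoulli background edges over
role-compatible ordered pairs (defaults: 10 core TFs, 30 TFs, 40 miRNAs,
150 targets; edge probability 0.01 per class — a sparse background of
roughly 170 edges) and plants:

* 30 FFLs in the canonical TF → miRNA → target configuration (the
  dominant arrangement in real miRNA FFL sets), each with a dedicated Y and
  Z node, activating TMI and repressing MTI/TTI signs (coherent loops);
* one party hub and one date hub, each a miRNA with four upstream core TFs
  and a target fan (10 and 8 targets respectively), a full FFL fan (every
  upstream TF binds every hub target) and interconnected upstream TFs so
  the hub neighbourhood is genuinely clustered. Party targets share one GO
  term set; date targets carry pairwise disjoint sets and the date hub's
  upstream TFs belong to distinct functional modules. Background edges
  avoid the two hub miRNAs: the planted hubs' adjacency — hence their
  candidacy and GO similarity — is exactly the planted construction, while
  the rest of the network stays noisy.

`simulate_layered_core()` builds the layered scaffold deterministically:
each bottom node receives exactly ten top-layer regulators by round-robin
(so top out-degrees are at or above the threshold, bottom in-degrees
exactly at it), middle nodes form fully connected four-cliques with CC = 1,
and planted FFLs run top → bottom with a fresh miRNA intermediate whose two
neighbours are connected (placing it in the middle layer). Extra downward
edges can be drawn with a configurable probability, defaulting to zero so
that the planted layer margins hold by construction; the layer-recovery
check is a correctness test of the rule implementation, not a robustness
study.

`simulate_genome()` spaces anchors 10 kb apart on alternating strands, so
binding windows never overlap, and places a configurable fraction of peak
midpoints uniformly inside a randomly chosen window, the rest midway
between anchor slots (strictly outside all windows).
`simulate_predictions()` constructs the predictor/degradome tables so the
intended merge result is known by construction (60 dual-program pairs, 30
single-program pairs per program with half degradome-supported, 40 decoys,
a partially novel curated list and a benchmark drawn from the truth).
`simulate_expression()` shifts miRNA targets by +1 log-unit in the
ago1-like condition only (miRNA action lost, targets de-repressed), with
Gaussian noise of sd 0.3, leaving the rdr6-like condition and wild type at
baseline — the signature expected when the miRNA pathway, but not the
siRNA pathway, is disabled.

All generators run a single RNG stream per call and are byte-identical for
identical config and seed.

## What passing tests do and do not show

The generators emulate the statistical structure the analysis assumes —
FFL enrichment over a size-matched null, output-heavy hub fans, downward
layer wiring, a target-specific de-repression signal — but not the
degree-sequence heterogeneity, spatial peak clustering, annotation
incompleteness or measurement error of real data, and they make no attempt
to mimic the real network's absolute counts. Recovery of planted structure
therefore validates the implementation of the rules, not their biological
sensitivity on real inputs.

# Numerical choices and problem sizes

Permutation runs in the tests and the acceptance script use 200
permutations on networks of ~230 nodes, 20 generator seeds for recovery
properties, 200 random graphs of at most 15 nodes for the census oracle,
and 50 seeds for the expression power property — sizes chosen so the whole
suite completes in minutes while leaving the monitored margins (Z > 2,
p < 0.01, exact recovery) wide. The production-scale defaults (1000
permutations) are a function argument away.

Known limitations: no 4-node motifs; no degree-preserving null by default;
GO similarity is term-set overlap, not ontology-aware semantic similarity;
no automated naming of functional modules; SIF export is write-only. The
question of whether published per-hub loop counts were induced or
pattern-matched is left open by providing both census modes.
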