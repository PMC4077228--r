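---
title: "Seed-anchored interaction networks and mediator analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-anchored interaction networks and mediator analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seednet)
```

## The model

seednet studies the interactome neighbourhood shared by two seed sets: the
proteins genetically associated with a disease group (`S_DG`) and the
primary molecular targets of the drugs developed against it (`S_DT`). The
working assumptions are the standard ones of binary interactome analysis:
interactions are undirected and unweighted (a reported physical interaction
carries no direction or strength), the graph is simple (self-interactions
and duplicate reports are artefacts of the source tables, not biology), and
computationally predicted (homology-transferred) interactions are noise
relative to experimentally supported ones and are excluded by default.

Construction proceeds in three steps.

1. **Integration.** Seed gene symbols are mapped to protein accessions. A
   symbol that maps to several accessions contributes *all* of them: the
   mapping step favours recall, because a seed silently lost to an
   ambiguous symbol biases everything downstream, while a spurious extra
   accession usually has no interactions and stays inert. Unmapped symbols
   are reported, never fatal.
2. **One-step expansion.** The network's node set is the seeds plus every
   direct interaction partner of a seed; the edge set is the **full induced
   subgraph** of the filtered interaction table on those nodes. Keeping
   neighbour–neighbour edges (rather than only seed spokes) is deliberate:
   hub neighbours genuinely have hundreds of partners inside the
   neighbourhood, and degree rankings computed on a spokes-only graph would
   be bounded by the seed count and scientifically meaningless. Seeds with
   no recorded interaction are retained as isolated nodes — they are real
   members of the study design and legitimately raise the component count.
3. **Mediators.** With `N_i` the neighbourhood of node *i*, the class
   neighbourhoods are `I_DG = ∪_{i∈S_DG} N_i` and `I_DT = ∪_{i∈S_DT} N_i`,
   and the mediator set is `M = I_DG ∩ I_DT`. Seeds are *eligible*
   mediators: a disease protein that also touches a drug target's partner
   mediates exactly like any other node, and excluding seeds would silently
   delete the biologically most interesting cases. Mediator extraction on
   the full filtered record graph and on the integrated network give the
   same result (the integrated network is the induced subgraph on seeds and
   neighbours, so every seed adjacency survives); the test suite asserts
   this equality.

## Topology statistics

`summarize_network()` reports the conventional whole-network measures.
Definitions that needed a decision:

- **Radius, two conventions.** The *minimum pairwise distance* between two
  distinct nodes is 1 on any network with at least one edge; the
  *minimum eccentricity* (the standard graph-theoretic radius) is computed
  within the giant component. Both are reported (`radius_paper`,
  `radius_standard`) because network tools in this field have used the
  first convention — a radius of 1 printed next to a diameter of 9 is only
  consistent with the min-pair-distance reading — and silently choosing one
  would make results incomparable with one lineage of published tables.
- **Disconnected graphs.** The diameter is the maximum over component
  diameters, and the average shortest path length is the mean over
  connected (finite-distance) unordered pairs only; otherwise both are
  undefined on any graph with an isolated seed.
- **Clustering.** `C_n = 2 e_n / (k_n (k_n − 1))`; nodes of degree 0 or 1
  have no neighbour pair and are assigned 0, and the network average runs
  over *all* nodes (the NetworkAnalyzer convention). This depresses the
  average on sparse graphs relative to averaging over degree-≥2 nodes;
  comparisons should use one convention consistently.
- **Centralization** is Freeman degree centralization,
  `(N/(N−2)) · (k_max/(N−1) − density)`: exactly 1 on stars, exactly 0 on
  regular graphs, undefined below 3 nodes.
- **Heterogeneity** is the coefficient of variation of the degree
  distribution (population standard deviation over mean): 0 for regular
  graphs, large when connectivity concentrates in hubs.

## Enrichment

Over-representation of annotation terms in a gene list uses the exact
hypergeometric upper tail `P(X ≥ x)` for an overlap of `x` in a query of
size `n` against a term of size `K` in a background of `N` genes, evaluated
through the log-space-stable distribution function so small tails do not
underflow. Decisions:

- **Background universe.** Default: every gene annotated to at least one
  term in the loaded annotation set. This is the least-assumption choice
  when the annotation's source universe is unknown; it can be overridden
  (e.g. with the network's node set). Query genes outside the background
  are dropped from `n` with a warning.
- **Significance** is declared on the *raw* p-value at `alpha = 0.001`, the
  threshold convention of the analysis this package operationalises;
  Benjamini–Hochberg adjusted values are always reported alongside so FDR
  control can be applied instead.
- **Discreteness.** The exact test is conservative: its achieved level sits
  below the nominal `alpha` (typically at 0.55–0.75·alpha for realistic
  term sizes), because the discrete tail cannot land exactly on the
  threshold. The calibration test therefore compares the simulated
  false-positive rate against the *exact discrete null level* (computed
  independently from log-binomial coefficients), with nominal `alpha` as an
  upper bound — demanding FPR ≈ alpha exactly would reject any correctly
  implemented exact test.

The **term graph** summarises a significant-term list: all `C(T, 2)`
pairwise similarities are ranked and the strongest
`ceiling(f · C(T, 2))` pairs with nonzero similarity become edges
(`f = 0.03` by default — the "top 3%" visualisation rule). Ties at the
cutoff are all kept, which makes the graph independent of input order at
the cost of occasionally keeping slightly more than the nominal fraction.
The default similarity is the Jaccard index of annotated gene sets, which
needs no ontology; when an `is_a` DAG is supplied, Lin similarity
`2·IC(MICA)/(IC(t1)+IC(t2))` with `IC(t) = −log(K_t/N)` over propagated
annotation counts is available. These approximate, but do not claim to
reproduce, the semantic-similarity measures of dedicated term-reduction
servers; likewise `prune_redundant_terms()` is a light substitute for full
dispensability analysis — it only drops a significant ancestor whose signal
is better explained by a more significant descendant.

## Reference overlay

`overlap_report()` places a mediator list in an independent reference
interaction network: membership, degree there, top-k degree rank, and
articulation-point status. Two choices matter. Ties at the top-k boundary
are all included, with the effective k reported — under a deterministic
rule no tied node is arbitrarily dropped. Articulation points are computed
on the *full* reference network, not the overlap-induced subgraph: the
question is whether a mediator prevents fragmentation of the reference
process map itself, which only makes sense on the intact map.

## The synthetic generator

The generator produces the study conditions for validation:
preferential-attachment graphs (heavy-tailed degrees, the dominant
structural feature of interactomes) or duplication–divergence graphs
(duplicate-and-prune growth, giving the leaf- and bridge-rich structure
where articulation analysis is informative). `plant_seeds_and_mediators()`
samples disjoint seed sets and wires planted bridge nodes to both classes;
`plant_annotations()` plants terms whose annotation probability is
multiplied by an effect size on the planted mediators.

The default end-to-end study, `paper_scale_mini()`, uses 500 nodes at mean
degree ≈ 4 (the sparsity regime of a seed-anchored human interactome, at
roughly one-seventh scale), 30 disease seeds, 40 drug-target seeds, 15
planted bridges, 40 terms with 2 planted at effect 10, and a 120-node
duplication–divergence reference containing 20 mediators, 6 of them on
top-degree positions. Everything is a pure function of one integer seed;
the fixture writer adds reversed duplicate rows and decoy predicted
interactions so the filtering stage is genuinely exercised, and rewriting
the same truth is byte-identical.

What the generator does *not* emulate: study bias (real interactomes
over-sample well-studied proteins, so real seed neighbourhoods are not
random), assortativity and motif structure, annotation term correlation
(real ontology terms overlap hierarchically; generated background terms are
independent), and identifier noise beyond simple unmapped symbols. Passing
the planted-recovery tests therefore demonstrates that the *computations*
are correct under known truth — not that mediators found in a real
interactome are complete or unbiased, which depends on the coverage of the
underlying interaction database.

## Validation strategy and problem sizes

The test suite validates every graph primitive against independent
brute-force oracles written only from definitions (adjacency-matrix degree
sums, flood-fill components, Floyd–Warshall distances, neighbour-pair
clustering, per-node-deletion articulation) on 200 random graphs of up to
60 nodes; hypergeometric tails against exhaustive subset enumeration for
every configuration with `N ≤ 12`; mediator recovery (recall 1.0 of
planted, adjacency validity of all reported) on 50 seeded instances;
enrichment calibration over 2,000 null replicates and power over 100
planted runs; and byte-for-byte determinism of the full pipeline. These
sizes were chosen so the whole suite runs in about a minute and a half on
one core while still exercising each measure far beyond its hand-checkable
cases.

## Known limitations

- Interaction confidence is binary (experimental vs predicted); no
  score-based weighting or evidence aggregation.
- Mediators are strictly one-step; path-based measures (betweenness
  mediation, two-step bridges) are out of scope.
- The Lin similarity uses annotation-derived information content only; no
  term-frequency corpus or relevance-weighted (SimRel-style) variants.
- The pipeline runs sequentially; there is no parallel or workflow-engine
  integration.
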