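---
title: "Network-based molecular process models of chemotherapy resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based molecular process models of chemotherapy resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netresist)
```

## The modeling problem

Resistance to first-line chemotherapy (platinum compounds combined with
taxanes) is the central clinical problem in high-grade serous ovarian
cancer (HGSOC): most patients respond initially and the majority relapse.
`netresist` implements a network-biology workflow for this setting. Gene
sets associated with the resistant phenotype — literature-mined and
transcriptomics-derived — are merged, projected onto a protein interaction
network, and segmented into densely interconnected subgraphs ("molecular
processes"). The same derivation applied to drug-associated gene sets
yields mechanism-of-action (MoA) models, whose membership overlap with the
disease model quantifies drug–disease interference. Expression cohorts
with progression-free survival (PFS) then drive a transcript panel for
relapse prognosis, and curated synthetic-lethality tables are screened for
gene pairs coupling two drugs inside a disease process.

Because the original inputs of such a study (a proprietary hybrid
interaction network, cohort downloads, curation-era annotation databases)
are not shippable, the package includes a first-class synthetic-data
generator that reproduces the *statistical structure* of each input, so
every stage of the pipeline runs and is testable offline.

## Feature-set consolidation

Feature sets arrive as one-identifier-per-line text or single GMT rows.
Identifiers are canonicalized (uppercased by default; configurable) and
optionally passed through an identifier map. Identifiers missing from a
supplied map are *retained* under their raw name and counted, never
silently dropped: such features simply fail to map onto the network later,
which mirrors the attrition observed with real mixed-namespace inputs.
`consolidate()` is a pure set union with per-gene provenance, hence
commutative, associative and idempotent; per-source sizes and the pairwise
overlap matrix are attached for reporting.

## Molecular model derivation

`derive_model()` runs four steps:

1. **Mapping** — intersection of the feature set with the network's node
   set, with unmapped features reported.
2. **Induced subgraph** — edges with both endpoints in the mapped set;
   isolated vertices are removed, so every retained feature interacts with
   at least one other feature. The subgraph is segmented as a whole (it is
   *not* reduced to its largest component); component sizes are reported.
3. **Segmentation** — a molecular-complex-detection (MCODE-style)
   algorithm, re-implemented here (below).
4. **Process graph** — for every pair of processes the number of network
   edges crossing the pair is tested for over-representation.

### Vertex weighting

For a vertex $v$ with closed neighborhood $N[v]$, the highest $k$-core of
the subgraph induced on $N[v]$ is found; the weight is

$$w_v = k_{\max} \cdot d(\mathrm{core}),
\qquad d = \frac{2E}{V(V-1)},$$

the core number times the density of that core subgraph. Isolated
vertices weigh 0, and every vertex of a complete graph $K_n$ weighs
$n-1$. Weighting by the *core* of the neighborhood (rather than the raw
neighborhood) makes the weight robust to spurious pendant edges.

### Complex prediction

Seeds are taken in order of weight (descending), ties broken by degree
(descending) and then lexicographic gene identifier, so segmentation is
fully deterministic and invariant under vertex relabeling up to process
numbering. From a seed with weight $w_s$, breadth-first expansion admits
an unassigned neighbor $y$ of a complex member $x$ when

* $w_y \ge w_s (1 - \mathrm{vwp})$ — the vertex-weight-percentage
  tolerance; a vertex is excluded only when its weight deviates from the
  seed weight by *more* than vwp (admission at exact equality matters in
  practice because $k$-core weights are small rationals and boundary ties
  are common); and
* the edge $(x, y)$ lies inside a *dense* (order $\ge 2$) highest
  $k$-core of the closed neighborhood of $x$ or of $y$.

The second condition is what separates adjacent dense regions: a single
bridge between two cliques belongs to neither endpoint's neighborhood
core, so the cliques become two processes rather than one. Requiring core
order $\ge 2$ stops sparse background vertices — whose tiny neighborhoods
are trivially their own 1-cores — from pulling a complex outward.
Vertices are assigned to at most one complex; complexes whose induced
subgraph lacks a 2-core are dropped, the optional haircut (default on)
iteratively removes degree-1 members, the optional fluff (default off)
adds unassigned boundary vertices above a neighborhood-density threshold,
and complexes below `min_size` (default 3) are discarded. Processes are
scored by mean member weight and numbered from 1 in score order.

The defaults `vwp = 0.2`, `haircut = TRUE`, `fluff = FALSE`,
`min_size = 3` are conventional for this algorithm family; all are
exposed through `mcode_params()`.

### Process-graph significance

With $M$ cross-process edges observed in total and $|A_i||A_j|$ possible
vertex slots for pair $(i, j)$ out of $S = \sum_{i<j}|A_i||A_j|$, the
pair's edge count is tested against the one-sided hypergeometric null
that cross-process edges land on pairs proportionally to their slot
counts. P-values are Benjamini-Hochberg adjusted across pairs and edges
with adjusted $p < 0.05$ (configurable) form the process-level graph.

## Interference

`interference()` builds the 2×2 contingency (in/out drug model × in/out
disease unit) over a gene universe and applies a chi-square test of
independence without continuity correction. The default universe is the
node set of the interaction network — the sampling frame from which model
members are drawn — configurable to the union of model members. A
one-sided exact hypergeometric tail is always reported alongside; when an
expected cell falls below 5 the function warns rather than silently
switching tests. `joint_coverage()` reports the either/or coverage of a
disease unit by several drug models.

## Pathway over-representation

`enrich()` tests each pathway of a GMT collection with the one-sided
Fisher/hypergeometric test; the *estimate* column is the percentage of
the query list inside the pathway, reported to two decimals. The default
background is the union of all pathway genes (configurable to the network
universe); query genes outside the background are dropped with a warning.
Pathways overlapping the query in fewer than `min_overlap = 2` genes are
reported but untested. An optional EASE-style variant (the Fisher table
with one overlap gene removed, the conservative penalization used by the
DAVID web tool) is available but off by default. `bh_adjust()` is the
standard step-up FDR adjustment; note that BH is not idempotent on
general adjusted vectors (only tie-collapsed fixed points re-adjust to
themselves), which is why the tests assert idempotence only there.

## Relapse classifier

**Dichotomization.** Samples with PFS strictly below 12 months are
labeled resistant, strictly above 22 months sensitive, and everything
between is excluded. The 12-month bound reflects six months of first-line
therapy plus a six-month window within which relapse counts as
resistance; the 22-month bound isolates clearly sensitive patients so the
two extremes give maximal contrast.

**Panel derivation.** `bootstrap_lasso()` fits an L1-penalized logistic
model over a candidate feature list (typically the disease-model genes),
with λ minimizing the 10-fold stratified cross-validated deviance. The
panel is the nonzero-coefficient set of this single full-data fit — a
concrete model usable downstream — while per-feature *selection
frequencies* over 200 stratified bootstrap resamples (each refit with its
own CV-min λ) quantify feature stability separately. Constant columns are
dropped with a warning; separation is handled by the penalty. All
randomness (folds and resamples) derives from one seed, so results are
exactly reproducible.

**Optimism-adjusted AUC.** For a panel, an unpenalized logistic model is
fit and evaluated on the full labeled data (`auc_obs`); per bootstrap
resample the model is refit, evaluated on the resample (`auc_boot`) and
on the full data (`auc_test`); reported values are means over runs, and

$$\mathrm{AUC}_{adj} = \mathrm{AUC}_{obs} -
(\mathrm{AUC}_{boot} - \mathrm{AUC}_{test}).$$

AUC is computed by the rank (Mann-Whitney) statistic with ties given 0.5
credit. One-class resamples are redrawn and counted. Whether the
bootstrap terms are means or a single draw is an open choice in this
design; means are used because they stabilize the optimism estimate.

**Process relevance and correlation screen.** `process_relevance()` sums
selection frequencies over each process's members — the quantity that
ranks processes for follow-up. `pfs_correlation_screen()` computes the
Pearson correlation of each feature with PFS in months over *all* samples
(not only the dichotomized extremes), flagging $|r| \ge 0.4$;
zero-variance features yield an undefined correlation with a note rather
than an error. When real probe-level matrices are supplied the screen
operates at probe level while the classifier expects one row per gene
(collapse probes upstream, e.g. by maximal variance — the package does
not impose a collapsing rule).

## Synthetic-lethality screen

`humanize_sl()` filters a curated interaction table to the evidence tags
"Synthetic Lethality" and "Negative Genetic" and to six organisms (human,
budding yeast, mouse, chicken, worm, fly; both lists configurable), then
transfers non-human pairs to human genes through an orthology map.
One-to-many orthology expands combinatorially — all pairs of mapped
endpoints — since no disambiguation rule is defensible a priori;
provenance records the source organisms per pair. Self-pairs are dropped,
pairs are unordered and deduplicated, and rows with an unmappable
endpoint are dropped and counted. `screen_pairs()` returns the SL pairs
with one endpoint in each of two gene sets (drug models) and both inside
a scope (the disease process under study); it is symmetric in the two
sets and monotone in both scope and pair set.

## The synthetic-data generator

`simulate_network()` plants Erdős–Rényi-dense modules (edge probability
`intra_module_edge_prob`) on disjoint node subsets of a
preferential-attachment background — scale-free, reflecting the
heavy-tailed degree distributions of real protein interaction networks —
and wires modules outward with a configurable number of inter-module
edges. `simulate_expression()` draws standard-normal noise features and
shifts planted signal features by `effect_size` standard deviations in
the resistant class; PFS is drawn from truncated normals consistent with
the class definitions — resistant 8.13 ± 2.77 months truncated to
(0, 12), sensitive 39.33 ± 22.40 truncated to (22, ∞), matching the
clinical characteristics of the training cohort the pipeline emulates.
`simulate_sl_table()` emits tag- and organism-distributed interaction
rows whose non-human genes always carry orthology rows back into the
human universe.

`simulate_workspace()` bundles everything into a ready-to-run input
directory: a 400-node network with three planted modules (20/15/12
genes), three overlapping disease sources, three drug sets concentrated
on module 1, a pathway collection overlapping the modules, training and
test cohorts of 82 + 63 and 29 + 45 samples (test-cohort PFS moments
5.07 ± 3.09 / 40.21 ± 16.72), ten signal genes at a standardized mean
difference of 0.8 — a moderate per-gene prognostic signal; larger values
saturate the classifier and make its validation uninformative — and a
synthetic-lethality table with two planted human pairs coupling the
third drug set to the second inside module 1. The sensitive test-cohort
size of 45 follows the cohort description; a conflicting tabulated value
of 42 exists for the real data, and the description was preferred.

What the generator deliberately does **not** emulate: probe-level
microarray artifacts, normalization residue, batch effects, censoring or
partial follow-up, correlated co-expression blocks, and namespace noise
beyond simple alias mapping. Passing tests therefore demonstrate the
correctness of the machinery under clean, well-specified signal — not
robustness to the full messiness of cohort data.

## Validation design and problem sizes

* **Oracle equivalence.** Vertex weights and complex memberships are
  compared against an independent brute-force implementation (repeated-
  pruning k-cores, recursive expansion) on every connected graph with 2–7
  vertices via the graph-atlas enumeration (995 graphs), plus randomized
  larger graphs.
* **Exact statistics.** Hypergeometric tails are checked against explicit
  binomial-coefficient sums on all 2×2 tables with total ≤ 60; the rank
  AUC against all-pairs counting on samples of size ≤ 30; Pearson
  correlations against the textbook covariance/sd form at 1e-12.
* **Planted-module recovery** uses the recoverable configuration:
  three modules of 10/12/15 nodes at intra-density 0.8, background
  attachment 2, segmentation at `vwp = 0.4`, assessed as the per-module
  median best-match Jaccard over 10 replicate networks. The vwp value
  follows from the weight span inside an ER(0.8) module: member weights
  range over roughly 55–100% of the seed weight, so the admission
  threshold $(1-\mathrm{vwp}) w_s$ must sit below that span — at the
  package default 0.2 the threshold ($0.8\,w_s$) always trims low-degree
  members. The median aggregates over replicates because individual ER
  draws can produce internally split modules.
* **Panel machinery.** Null calibration averages the adjusted AUC over 20
  replicate label-independent simulations (60 + 60 samples); signal
  recovery plants 10 features (effect 1.5) among 400 candidates with
  60 + 60 samples and asks for ≥ 8 of 10 inside the top 15 by selection
  frequency (median of 10 replicates at 200 bootstraps).

These problem sizes are the package's validation choices; all scale
linearly upward through the same functions.

## Known limitations

* The segmentation is deterministic but, like all greedy seeded
  expansions, order-dependent at exact weight ties; the documented
  tie-break makes this reproducible, not principled.
* The process-graph null treats cross-process edges as landing on vertex
  slots exchangeably, ignoring degree heterogeneity; hub-rich processes
  can therefore look over-connected.
* The chi-square interference test inherits the arbitrariness of its
  universe; both supported choices (network nodes, member union) are
  reported in the output for transparency.
* Enrichment p-values depend strongly on the background; results from
  differently curated collections are not comparable.
* The classifier assumes one expression row per feature and complete PFS;
  survival modeling on continuous time (Cox, Kaplan-Meier) is out of
  scope by design.
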