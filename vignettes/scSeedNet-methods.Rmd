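---
title: "Methods: seeded network reconstruction from single-cell pseudobulk DE"
author: "scSeedNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seeded network reconstruction from single-cell pseudobulk DE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scSeedNet)
```

# The problem

Differential expression alone says which genes change between tumor and
normal cells; it does not say how those changes propagate through a
regulatory system. scSeedNet reconstructs a regulatory network around a
curated *seed* gene set — for example, the genes annotated to a biological
process such as apoptosis — by combining three inputs:

1. single-cell RNA-seq counts for paired tumor/normal samples,
2. a typed gene/protein knowledge graph whose edges carry relationship
   types (*expression regulation*, *expression upregulation*, *expression
   downregulation*, *interaction*), and
3. a gene-age (phylostratum) table.

The pipeline has two reconstruction stages. Stage 1 keeps the seed genes
that are differentially expressed, together with their protein products and
all knowledge-graph edges among them. Stage 2 searches the remaining
differentially expressed genes for proteins whose interaction partners are
unexpectedly concentrated inside the stage-1 network — candidate regulators
of the process that lack the seed annotation — and adds the significant
ones.

# Preprocessing and pseudobulk

Cells detecting fewer than 100 genes are removed, then genes detected in
fewer than 3 cells (one pass, cells first). Both thresholds are strict
"fewer than" bounds. Counts are normalised per cell to a common total (the
median per-cell total by default) and `log1p`-transformed; the raw counts
are kept untouched because downstream inference is count-based.

Hepatocyte-like cells are gated on the mean log-normalised expression of
marker genes (in the liver setting: ALB, HNF4A, SERPINA1, CYP3A4, TAT, TF).
Community-detection labels are a pluggable input: when cluster labels are
supplied, a cluster is called hepatocyte when its mean marker score exceeds
the across-cluster mean. Without labels the default is an exact
one-dimensional two-means split of the per-cell scores. We chose this over
a fixed score quantile because a quantile gate always selects a fixed
fraction of cells, which silently presupposes the hepatocyte fraction; the
two-means split adapts to the actual score distribution and is
deterministic (no RNG, exact minimisation of within-group sums of squares).
A `score_quantile` argument still provides the quantile behaviour when a
known fraction is preferred.

Pseudobulk samples are gene-wise **sums of raw counts** over the selected
cells of each (patient, tissue) pair. Patients observed in only one tissue
are retained but flagged; the paired test drops them.

# Paired differential expression

For each gene, with tumor and normal CPM values $t_i, n_i$ for patient
$i$ and pseudocount $c = 0.5$:

$$r_i = \log_2 \frac{t_i + c}{n_i + c}, \qquad
\widehat{\mathrm{LFC}} = \bar r, \qquad
p = 2\,P\!\left(T_{k-1} \ge \left| \frac{\bar r}{s_r/\sqrt{k}} \right|\right)$$

a two-sided paired t-test on the per-patient log-ratios across the $k$
complete patient pairs. Genes with zero counts everywhere get
$\mathrm{LFC} = 0$, $p = 1$. A gene is called differentially expressed when
$p < 0.05$ **and** $|\mathrm{LFC}| > 0.5$, both strict, with the p-value
read as unadjusted (an optional BH mode exists but is off by default, and
the threshold choice is exposed).

The paired t-test on log ratios was chosen as the default engine because it
preserves the two design features that matter — pairing within patient and
library-size normalisation — while keeping the package self-contained; the
planted-truth recovery rate, not equality with any particular count model,
is the correctness surface. A DESeq2 engine (`engine = "deseq2"`, paired
Wald model `~ patient + tissue`) is available behind the same interface and
is used in the test suite as an independent cross-check: both engines
recover ≥ 90 % of planted DEGs and their fold-changes correlate > 0.9.
Dispersion shrinkage, independent filtering and LFC shrinkage are out of
scope.

# Two-stage network reconstruction

The knowledge graph is a typed directed graph: gene nodes, protein nodes
(each protein encodes exactly one gene), and edges of the four types above.
Expression-regulatory edges always run protein → gene; `interaction` edges
may also connect two proteins.

**Stage 1.** Network nodes are the differentially expressed seed genes plus
their protein products; edges are all knowledge-graph edges induced by that
node set (all four types — whether the curated source restricts seed
networks to regulatory edges is unspecified, so the induced-subgraph rule is
used and documented here). Gene and protein node counts are equal by
construction.

**Stage 2.** Candidates are proteins whose encoding gene is differentially
expressed but absent from the seed network, with at least one edge of the
four types into a network gene. Protein–protein `interaction` edges are
mapped to the partner protein's gene for counting, because the test's
universe is genes; a protein's edges to its own gene are excluded
throughout, since self-regulation is no evidence of being a *novel*
regulator of the process. Duplicate edges between the same pair with
different types are distinct evidence and are kept; duplicate same-type
edges are collapsed.

## The interaction-specificity test

For a candidate protein with $N$ distinct gene partners genome-wide, of
which $x$ lie among the $n$ genes of the analysed network, drawn from a
universe of $M$ protein-coding genes, the enrichment p-value is the
hypergeometric upper tail

$$p = \sum_{k=x}^{\min(n,N)}
\frac{\binom{n}{k}\binom{M-n}{N-k}}{\binom{M}{N}} .$$

The sum is evaluated in log space (`lchoose` + log-sum-exp), which is exact
to ~1e−15 against exhaustive enumeration for every parameter combination
with $M \le 12$ and matches the distribution function at $M = 20000$. The
one-sided upper tail is used because only over-representation qualifies a
regulator. Bonferroni correction runs over the number of candidates
actually tested (not the genome), and significance is
Bonferroni-$p < 0.05$. $M$ defaults to the number of distinct genes in the
supplied knowledge graph and should be set to the database's protein-coding
universe when that is known.

Significant candidates are added to the stage-1 node set and edges are
re-induced; stage-2 node count therefore equals stage-1 plus the number of
significant candidates, and every per-type edge count is monotone
non-decreasing from stage 1 to stage 2.

# Network analysis

**Connectivity** of a node is its number of distinct neighbours (parallel
edges of different types count once; self-loops never count). Whether a
published connectivity should count parallel typed edges separately is not
stated anywhere we could check; distinct neighbours is the conservative
reading and the one implemented. **Hubs** are nodes whose connectivity
strictly exceeds the empirical $1-\alpha$ quantile (nearest-rank,
$\alpha = 0.05$) of the connectivity distribution pooled over all network
nodes, genes and proteins together. On a 21-node star the critical value is
1 and the centre is the sole hub; on a complete graph there are no hubs.

**Regulation subnetworks** restrict the final network to a single edge type
— activation (`expression_upregulation`) or repression
(`expression_downregulation`) — and to the nodes those edges touch, each
annotated with its gene's expression direction. The two subnetworks are
edge-disjoint by construction.

# Phylostratigraphic enrichment

Given an age table assigning each gene to one of 20 evolutionary-age
intervals, each interval is tested for over-representation of network genes
against the protein-coding universe with the same hypergeometric upper
tail: `N_total` universe genes, `n_interval` of them in the interval,
`M_network` network genes, `m_observed` network genes in the interval,
$p = P(X \ge m)$. "Network genes" are the genes represented in the final
network either as gene nodes or through a protein node. Intervals are
flagged at unadjusted $p < 0.05$, matching the reporting convention this
procedure follows; a Bonferroni mode over the intervals is provided. The
upper tail (not the point mass) is used: the quantity of interest is the
probability of observing *m or more* network genes in the interval.

# The synthetic-data generators

`simulateCounts()` draws negative-binomial counts (shared dispersion
$\alpha$, variance $\mu + \alpha\mu^2$) — the standard count model for
scRNA-seq — for paired tumor/normal samples. Gene baselines vary
log-normally (SD 1) around `nb_mean`; each patient's tumor and normal
samples share a log-mean offset (SD 0.3), giving the paired design
something to absorb. The first `n_marker_genes` genes are hepatocyte
markers, elevated 2^5-fold in hepatocyte-like cells of both tissues;
planted DEGs (half up, half down) are shifted by ±`planted_log2fc` in tumor
hepatocyte-like cells only.

`simulateKnowledgeGraph()` gives every gene one protein node. Planted
regulators send `regulator_edges_to_network` typed edges into the seed
genes; every protein additionally carries background edges at a per-pair
Bernoulli probability. For planted regulators the background avoids the
seed set, so their network linkage is exactly the planted one.
`simulateAgeTable()` assigns strata uniformly, oversampling network genes
into the enriched strata at a configured odds ratio.

`simulateStudy()` couples the three: a configured number of planted DEGs
goes into the seed set (the recoverable stage-1 network), the planted
regulators are chosen among planted DEGs *outside* the seed set (so their
proteins qualify as candidates), their planted edges target the seed-DEG
genes (a regulator of the network should touch the network, not the
undifferential part of the seed list), and the age enrichment is planted on
the expected final-network genes.

Defaults describe the emulated study: 8 patients, 2,000 genes, 200 cells
per sample with 60 % hepatocyte-like cells, 50 planted DEGs at
|log2FC| = 2, a 100-gene seed set with 40 planted DEGs, 5 regulators with
10 network edges each over background probability 0.005, 20 age intervals
with strata 3 and 7 enriched at odds ratio 5. A single `rng_seed`
determines every output byte-for-byte.

What the generators deliberately do **not** emulate: doublets, ambient RNA,
batch effects, mean–variance trends beyond the shared dispersion,
correlated gene modules, or literature-mining noise in the knowledge graph.
Passing the recovery suites therefore demonstrates that the inference
machinery is correct and calibrated under its stated model, not that the
thresholds are optimal for any particular real dataset.

# Numerical and calibration choices

* **Discrete-test null rates.** The hypergeometric test is discrete: the
  largest achievable rejection level below 0.05 depends on $(M, n, N)$ and
  can be far below 0.05 (with $N \approx 25$ draws it is ≈ 0.014). Null
  calibration is therefore asserted in two parts: the empirical flag rate
  never exceeds 0.05 plus three binomial standard errors, and it matches
  the *exact attainable level* computed from the hypergeometric law itself
  (conditioned on candidacy, $x \ge 1$, where candidacy is part of the
  selection). The continuous paired-t null keeps the literal two-sided
  three-standard-error band around 0.05, which the test suite verifies over
  200 replicates of 1,000 null genes (measured rate ≈ 0.049).
* **Degenerate DE genes.** All-identical per-patient ratios have zero
  variance: the p-value is defined as 1 when the common ratio is 0 and 0
  otherwise.
* **Canonical ordering.** Graph constructors sort nodes and edges and
  collapse duplicate same-type edges, so identical inputs give
  byte-identical objects and manifests.
* **Tie-breaks.** Specificity results are ordered by ascending p-value,
  then protein id. Hub calls use strict `>` against the nearest-rank
  quantile, so all-equal degree distributions yield no hubs.
* **Problem sizes in the test suite.** The statistical suites run at sizes
  chosen to keep the full check fast on one CPU while retaining power:
  exhaustive tail enumeration to $M = 12$; 20 replicates of the
  5,000-gene/100-seed regulator recovery; 20 replicates of the
  2,000-gene/8-patient DEG recovery plus 200 replicates of a 1,000-gene
  null; 50 replicates of planted-hub detection in 200-node graphs; 20 + 200
  replicates of the 20,000-gene age enrichment.

# Known limitations

* The DE engine is a pseudobulk-level test; it does not model gene-specific
  dispersion and will be conservative or anticonservative for very low
  counts in ways DESeq2's shrinkage handles better — which is why the
  engine is pluggable.
* The hepatocyte gate assumes markers separate cleanly; heavily overlapping
  score distributions would need real clustering upstream (cluster labels
  are accepted for exactly that reason).
* The specificity test treats the knowledge graph as ground truth; edge
  ascertainment bias (well-studied proteins have more recorded partners)
  inflates $N$ and deflates significance for well-studied proteins rather
  than producing false positives.
* $M$, the gene universe of the knowledge base, is rarely printed by
  curated sources; the default (genes present in the graph) is a lower
  bound, and the test is monotone in $M$, so supplying a larger, correct
  universe only strengthens enrichment.
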