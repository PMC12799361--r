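# scSeedNet

Seeded gene-network reconstruction and analysis from single-cell RNA-seq
pseudobulk differential expression and a typed gene/protein knowledge graph.

## What it does, and for whom

Given paired tumor/normal single-cell counts, a curated *seed* gene set (for
example the genes annotated to apoptosis), and a knowledge graph whose edges
carry relationship types (*expression regulation / upregulation /
downregulation / interaction*), scSeedNet answers three questions a systems
biologist asks of a dysregulated process:

1. **Which seed genes actually change** in the cell type of interest?
   Cells are QC-filtered, normalised, gated to the target population by
   marker score, aggregated to per-patient pseudobulk (sums of raw counts),
   and tested with a paired tumor-vs-normal design. A gene is differentially
   expressed when `p < 0.05` and `|log2FC| > 0.5`.
2. **Which unannotated proteins regulate the process?** Starting from the
   stage-1 network (DE seed genes + their proteins + induced edges), every
   DE protein outside the network with edges into it is scored with a
   hypergeometric interaction-specificity test: with `M` protein-coding
   genes in the database, `n` genes in the network, `N` genes the protein
   touches genome-wide and `x` of them in the network,

   `p = Σ_{k=x}^{min(n,N)} C(n,k) C(M−n, N−k) / C(M,N)`,

   Bonferroni-corrected over the candidates. Significant candidates join the
   final (stage-2) network.
3. **What is the network's structure and evolutionary profile?**
   Per-node connectivity (distinct neighbours), hubs (connectivity strictly
   above the empirical 95 % quantile), single-direction regulation
   subnetworks (activation / repression), and gene-age stratum
   over-representation of network genes against the protein-coding universe
   (same hypergeometric upper tail, 20 age intervals).

A synthetic-data module (`simulateStudy()`) generates all inputs with known
planted truth — planted fold-changes, marker-high hepatocyte-like cells,
planted specific regulators, planted enriched age strata — so every stage is
validated by recovery, not by eyeballing.

## Worked example

```r
library(scSeedNet)

sim <- simulateStudy(simConfig(rng_seed = 7))   # 8 patients, 2,000 genes
mf  <- runPipeline(sim$counts, sim$kg, sim$seed_sets$seed, sim$markers,
                   ages = sim$ages)

str(mf$degs)
#> List of 5
#>  $ n_total : int 56
#>  $ n_up    : int 28
#>  $ n_down  : int 28
#>  $ pct_up  : num 50
#>  $ pct_down: num 50
```

56 genes pass the DEG thresholds (50 were planted). The stage-1 network
pairs the 40 DE seed genes with their proteins (80 nodes); 7 candidate
regulator proteins reach into it, of which 5 are Bonferroni-significant —
exactly the 5 planted ones — giving an 85-node final network:

```r
head(mf$results$association, 6)
#>    protein_id  N  x    p_raw p_bonferroni significant
#> 1 g01672_prot 16 10 2.26e-14     1.59e-13        TRUE
#> 2 g00721_prot 17 10 5.42e-14     3.80e-13        TRUE
#> 3 g01488_prot 25 10 8.16e-12     5.71e-11        TRUE
#> 4 g01875_prot 27 10 2.05e-11     1.43e-10        TRUE
#> 5 g01021_prot 28 10 3.14e-11     2.20e-10        TRUE
#> 6 g01194_prot 12  1 2.16e-01     1.00e+00       FALSE
```

Each significant row reads: the protein touches `N` genes genome-wide, `x`
of them inside the 40-gene network — far more concentration than chance
(`p_raw`), surviving correction over the 7 candidates. Downstream:

```r
mf$hubs                    # "g01488_prot"  (connectivity > 95% quantile, 10)
mf$flagged_age_intervals   # 3 7  — the two planted enriched strata
mf$results$age_enrichment[c(3, 7), ]
#>   interval_index interval_label n_interval m_observed  p_value
#> 3              3     150-225 My        104          9 3.62e-04
#> 7              7     450-525 My         96         11 4.59e-06
```

The activation subnetwork keeps only `expression_upregulation` edges
(28 nodes / 23 edges here), the repression subnetwork only
`expression_downregulation` (19 / 12); nodes carry their gene's expression
direction. `runPipeline(..., out_dir = "run1")` writes every table, the
networks as TSV + GraphML, and a JSON manifest of all stage counts.

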