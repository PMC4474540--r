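# pandys

Pan-cancer transcription-dysregulation analysis on paired tumor/normal
expression cohorts, with a planted-signal synthetic data generator that makes
every stage of the pipeline testable end to end.

## What it is for

Matched tumor/normal designs ask which genes a cancer deregulates, and which
*kinds* of genes carry that deregulation: transcription factors (TF),
RNA-binding proteins (RBP), lncRNAs, curated cancer-related genes (allOnco),
somatic-mutation classes, and tissue-specific genes.  `pandys` implements
the full analysis a pan-cancer study of this design runs per cohort, and
across cohorts:

1. **Differential expression** — paired t-test per gene on
   log2(x + c)-transformed abundances, Bonferroni-adjusted:
   for gene *g* with per-pair differences *d_i* = log2(T_i + c) − log2(N_i + c),

   t_g = d̄ / (s_d / √n),  p_adj = min(1, p · m),  DE ⇔ p_adj < α.

   The reported fold change is the mean per-pair log2 ratio, which on this
   transform equals d̄.
2. **Category enrichment / depletion** — both one-sided hypergeometric tails
   per category × cohort cell: p_enrich = P(X ≥ k), p_deplete = P(X ≤ k) for
   X ~ Hypergeom(N, K, n) on the cohort's own measured-gene universe, with
   the usual heatmap convention (white above 0.05).
3. **Amplitude comparison** — ECDFs of |log2FC| of DE genes per category,
   plus one-sided rank-sum tests between categories.
4. **RBP cascade** — rank DE RBPs by |log2FC|, take each top-20 RBP's first
   PPI neighbors, and test the neighborhood for *dual* enrichment (DE genes
   and allOnco genes); RBPs passing both tails at 0.05 are "cascade RBPs"
   and their DE∩allOnco partners are exported as a subnetwork.
5. **Genetic vs epigenetic attribution** — per RBP, R² = (Spearman ρ)²
   between per-patient log2 expression change and the copy-number (or
   methylation) value at the locus; DE vs non-DE RBPs compared by one-sided
   Wilcoxon rank-sum.
6. **Tissue-specific direction** — enrichment of the cohort-matched
   tissue-specific set among DE genes, the under-expressed fraction among
   its DE members, an exact sign test, and a rank-sum shift test against
   other DE genes.
7. **Pathway clustering** — cohorts clustered by average-linkage on
   d(a,b) = 1 − Spearman ρ of their fold-change profiles, over all shared
   genes and restricted to pathway gene sets, exported as Newick.

Because the real inputs of such studies (controlled tumor archives, curated
gene lists, PPI snapshots) cannot be redistributed, the package ships a
synthetic multi-cohort generator (`sim_config()` / `generate()`) that plants
each of these signals with known parameters and records them in a truth
ledger, so recovery of every effect is a testable property.

## Worked example

```r
library(pandys)
sim <- generate(sim_config(seed = 42))   # 4 cohorts, 5000 genes, 30 pairs
de  <- call_de(sim$cohorts$C01)
glance(de)
#>   cohort_id n_genes n_pairs  n_de alpha pseudocount
#> 1 C01          5000      30   909  0.05           1

enrichment_matrix(de, sim$catalog, sets = c("allOnco", "TF", "RBP", "lncRNA"))
#>   set_name     K     n     k  p_enrich  p_deplete direction
#> 1 allOnco    300   909   108 2.71 e-14 1.000      enriched
#> 2 TF         300   909    41 9.87 e- 1 0.0195     depleted
#> 3 RBP        300   909    78 3.29 e- 4 1.000      enriched
#> 4 lncRNA     100   909     3 1.000e+ 0 0.00000337 depleted
```

The cancer-related set and the RBPs are over-represented among the 909 DE
genes, while the sparse lncRNA set is depleted — the planted pattern.  The
cascade stage recovers exactly the four planted hub RBPs:

```r
casc <- cascade_select(de, sim$catalog, sim$network)
tidy(casc)[tidy(casc)$selected, ]
#>   gene   abs_log2fc n_neighbors  k_de k_onco p_enrich_de p_enrich_onco
#> 1 G00828       3.92          33    24     15    9.47e-12      1.29e-10
#> 2 G00649       3.87          35    24     15    7.05e-11      3.63e-10
#> 3 G00753       3.49          36    20     16    4.89e- 7      4.67e-11
#> 4 G00674       3.36          35    18     15    8.01e- 6      3.63e-10
sim$truth$hub_rbps
#> [1] "G00649" "G00674" "G00753" "G00828"
```

Attribution separates the planted genetic driver from the uncoupled
epigenetic one, tissue-specific genes come back ~80% under-expressed, and
the two cohorts sharing planted cell-cycle effects merge first:

```r
compare_groups(per_gene_attribution(sim$cohorts$C01, sim$molecular$C01$cnv,
                                    de, sim$catalog))
#>   w_stat     p_value method        alternative n_de n_non_de assay
#> 1  11931 0.000000343 normal_approx greater       78      222 cnv

tissue_specificity(de, sim$catalog)[c("k", "p_enrich", "frac_under")]
#>     k  p_enrich frac_under
#> 1 331 2.54e-196      0.798

pathway_panel(lapply(sim$cohorts, call_de), sim$catalog)$cell_cycle$newick
#> (C03:0.543438,(C04:0.486733,(C02:0.008959,C01:0.008959):0.477774):0.056706);
```

Each result type has `tidy()` / `glance()` methods and an `autoplot()`
(enrichment heatmap, amplitude ECDFs, cascade dual-enrichment plot,
attribution boxplots, dendrograms).

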