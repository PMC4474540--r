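---
title: "Models and methods behind pandys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pandys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pandys)
```

`pandys` re-implements, as a tested pipeline, the analysis pattern of
pan-cancer studies that compare matched tumor/normal expression across many
cancer types and ask how the dysregulation distributes over functional gene
classes — transcription factors, RNA-binding proteins (RBPs), lncRNAs,
cancer-related genes, mutation classes and tissue-specific genes — and what
sits upstream (copy number vs methylation) and downstream (protein
interaction partners) of the deregulated RBPs.  This vignette documents the
statistical model of every stage, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the design choices
made where the methodology was genuinely open.

## Differential expression

For each gene the paired t-test is applied to
$d_i = \log_2(T_i + c) - \log_2(N_i + c)$ over the $n$ matched pairs, with
$n - 1$ degrees of freedom, two-sided.  P-values are Bonferroni-adjusted
over all genes tested in the cohort, and a gene is called DE when
$p_{adj} < \alpha$.

* **Scale.** Whether the original analyses tested raw or log abundances is
  typically unstated; we test on the log scale, where the t-test's
  normality assumption is reasonable for abundance data.  Raw-scale testing
  can be emulated by pre-transforming the input.
* **Pseudocount** $c$ (default 1, configurable).  It guarantees finite fold
  changes for zero measurements.  Note one real consequence, shared with
  any pseudocount analysis: down-regulation of a gene with normal-sample
  abundance $N$ saturates at $-\log_2(N + 1)$, so very low-expressed genes
  cannot display large negative fold changes.
* **α** (default 0.05 on the adjusted p; Bonferroni is the stated method of
  the motivating studies, which do not print their threshold).
* **Fold change** is the mean per-pair log2 ratio — consistent with the
  paired design — rather than the ratio of means; on the tested transform
  it equals the mean difference $\bar d$, keeping the test statistic and
  the reported effect aligned.
* **Degenerate genes** (identical tumor and normal vectors) are kept with
  $p = 1$ rather than dropped, so the enrichment universe is stable.

## Enrichment and depletion

Every category × cohort cell reports both one-sided hypergeometric tails,
including the observed point: $p_{enr} = P(X \ge k)$ and
$p_{dep} = P(X \le k)$, the standard over-representation convention.  The
universe is always the cohort's own measured genes — gene sets are
intersected with the expression matrix first, which matters in practice
(e.g. only a few hundred of several thousand annotated lncRNAs appear in a
standardized mRNA-Seq matrix).  Direction is assigned at a display
threshold (default 0.05, the usual "white above 0.05" heatmap rule); no
correction is applied across the matrix, matching how such heatmaps report
raw enrichment p-values.  Tails are computed by `stats::phyper`, which
works in log space and is stable for universes up to at least $10^5$.

## Amplitude profiles

The per-category ECDFs of $|\log_2 FC|$ of DE genes reproduce the classic
descriptive comparison (cancer-related genes change most, RBPs least).  On
top of the purely descriptive display we add pairwise one-sided Wilcoxon
rank-sum tests of stochastic ordering; these are labelled an extension of
the original display, not part of it.

## RBP cascade

DE RBPs are ranked by $|\log_2 FC|$ (ties: adjusted p, then symbol) and the
top 20 retained, mirroring "top-20 RBPs with highest fold change" lists.
Each RBP's first PPI neighbors are tested twice against the universe of
cohort-measured network nodes: once for DE genes among neighbors, once for
cancer-related genes.  Selection requires both upper tails below 0.05, with
no correction across the 20 tests (two independent criteria at 0.05 imply
an approximate $\alpha^2$ false-selection rate per RBP under a null
network).  Open choices, decided and configurable:

* ranking restricted to *DE* RBPs (avoids high-fold-change genes that never
  reach significance); `de_only = FALSE` ranks all RBPs;
* the enrichment universe is the intersection of measured genes and network
  nodes, avoiding bias from proteins that cannot appear in a neighborhood;
* the exported subnetwork keeps only neighbors that are both DE and
  cancer-related (the "yellow target" display); full neighborhoods remain
  available from the per-RBP statistics.

## Attribution

For each RBP the per-patient log2 expression change is paired with the
tumor-sample molecular value at the same locus, and the squared Spearman
correlation is reported as $R^2$ — the rank-based fraction of variation the
assay can explain.  DE vs non-DE RBPs are compared with a one-sided
Wilcoxon rank-sum test (alternative: DE RBPs explain more).  The exact null
distribution is used when both groups have at most 10 tie-free members,
otherwise the normal approximation with tie correction.  Choices:

* tumor-sample assay values (not tumor-minus-normal differences) are used,
  because normal-sample CNV/methylation profiles are typically sparse in
  the motivating data; matching by patient id keeps pairs aligned;
* `min_samples = 8` matched patients are required for a rank correlation
  to be meaningful; genes below the cutoff, absent from the assay, or with
  constant profiles are excluded and counted.

## Tissue-specific genes

The tissue set mapped to the cohort is tested for enrichment among DE genes;
among its DE members we report the under-expressed fraction, an exact
two-sided sign test against 0.5, and a one-sided rank-sum comparison of
signed fold changes against all other DE genes.  No cohort is
special-cased: a non-significant tissue result (as reported for
prostate-like cohorts) is an outcome, not a rule.

## Pathway clustering

Cohorts are clustered on $d(a, b) = 1 - \rho_S(\log_2 FC_a, \log_2 FC_b)$
over the genes shared by all cohorts, optionally restricted to a pathway's
members (at least 10 shared genes required).  All expressed genes
contribute, not only DE genes, matching the "all expressed genes" clustering
convention; $1 - \rho$ rather than $1 - |\rho|$ keeps anticorrelated
cohorts far apart.  The linkage is average (UPGMA) — standard for
correlation distances and guaranteeing monotone merge heights — implemented
with an explicit deterministic tie rule (merge the pair whose smallest
member labels sort first), so identical inputs give identical trees.
Newick output uses ultrametric branch lengths (merge height / 2) rounded at
6 decimals for reproducible text files.

## The synthetic generator

`generate()` emulates the structures the analysis assumes, each with a
recorded truth ledger:

* **Expression**: log-normal abundances,
  $N_{gi} = e^{\mu_g + \varepsilon}$,
  $T_{gi} = e^{\mu_g + \delta_g \ln 2 + \varepsilon'}$, with
  $\mu_g \sim \mathcal N(5, 1)$, noise sd 0.2 on the natural-log scale, and
  planted log2 effects $\delta_g = s \cdot e$,
  $e \sim \mathrm{Exp}(\text{mean} = \text{effect\_scale}[category])$.
  Log-normality makes the paired t-test on log-transformed data exactly
  calibrated; the baseline $e^5 \approx 150$ matches the order of magnitude
  of normalized mRNA-Seq abundances and keeps the pseudocount inert (at
  much lower baselines the $-\log_2(N+1)$ saturation would clip planted
  down-regulation — a real effect, but one that would make planted-signal
  recovery tests measure the pseudocount rather than the method).
* **Categories**: sizes 300 (allOnco, TF, RBP), 100 (lncRNA) and two small
  mutation-class-like sets of 30 within a 5000-gene universe — roughly the
  proportions of curated lists in a ~20k-gene transcriptome.  DE
  probabilities (allOnco and RBP 0.3, background 0.1, lncRNA 0.03) and
  effect scales (allOnco 3 > TF 2 > lncRNA 1.5 > RBP 1) reproduce the
  reported qualitative pattern: cancer-related genes and RBPs enriched,
  lncRNA depleted, cancer genes changing most and RBPs least.  The
  magnitudes themselves are chosen for test power — the motivating studies
  print no effect sizes.
* **Network**: an Erdős–Rényi background (mean degree 6) plus hub RBPs
  wired to 30 partners of which, by exact quota, 50% are cancer-related and
  80% forced DE in every cohort.  Hubs are planted with
  $|\delta| \ge 3$ so they appear in the top-20 ranking; pathway effect
  sharing never overwrites a hub's planted effect.
* **CNV**: for an exact-quota half of each cohort's planted-DE RBPs, the
  copy-number value is a linear function of the realized per-pair log2
  change plus Gaussian noise, with the slope chosen in closed form
  ($r^* = 2\sin(\pi\rho_S/6)$ for bivariate normal ranks) so the population
  Spearman correlation is the configured 0.6; all other genes get
  independent noise.  **Methylation** is independent Beta(2, 5) noise for
  every gene — deliberately uncoupled, mirroring the negative finding the
  attribution stage is designed to detect.
* **Tissue sets**: 400 background genes per cohort (disjoint across
  cohorts), all planted DE with an exact 80% quota of negative signs.
* **Pathways**: two 100-gene sets; the designated similar cohort pair
  shares one pathway's effect vector up to sd-0.2 perturbation, planting
  the fold-change correlation that pathway-restricted clustering recovers.

Quotas rather than Bernoulli draws are used for all planted *fractions*
(tissue signs, hub composition, CNV coupling) so the ledger pins them
exactly; DE membership itself is Bernoulli per category.  All randomness
flows from the single config seed; identical config and seed give
byte-identical files.

What the generator does **not** emulate: count-based (negative binomial)
noise, mean–variance trends, batch effects, correlated co-expression
modules, scale-free network topology, segment-level CNV structure, or
promoter-level methylation summarization.  Passing the recovery suite
therefore shows the pipeline's statistics are correct and powerful under a
well-specified model, not that any particular biological claim about real
tumors is reproduced.

## Numerical and testing choices

* Hypergeometric and t-test primitives are verified against exhaustive
  subset enumeration (all universes up to 12) and quadrature of the t
  density; the rank-sum exact branch against enumeration of rank
  assignments; the clustering against `stats::hclust` on tie-free inputs.
* Type-I control uses 200 null cohorts of 5000 genes × 30 pairs; recovery
  checks use 50 simulations per condition — sizes chosen to finish in
  minutes on one CPU while leaving the planted effects many standard errors
  clear of their thresholds.  The family-wise bound in the null suite is a
  200-draw Monte Carlo estimate of an analytic value of 0.049, so that
  check retains a small intrinsic false-alarm rate by construction.
* Matrix TSVs are written with 17 significant digits and parsed with
  correctly-rounded `strtod`, so write→read is bit-exact and pipeline
  reruns are byte-identical (stage outputs are written atomically and
  cached under a hash of parameters and input digests).
* Neutral-category behavior is checked on a small (size-30) set: for large
  neutral sets, any genuinely enriched category inflates the universe-wide
  DE rate and drags neutral sets toward apparent depletion — visible in
  real category tables, where small mutation-class sets are mostly
  non-significant while large ones trend with the DE total.

## Known limitations

* Gene identity is the bare symbol string; no alias mapping.
* Expression input must already be normalized and non-negative; no library
  size or batch correction is performed.
* Enrichment p-values are reported raw across the category × cohort matrix
  (by convention); users comparing many categories may wish to adjust.
* The attribution stage requires gene-level CNV/methylation input;
  segment-to-gene and probe-to-gene summarization are upstream of this
  package.
* Real-data headline numbers from the motivating studies depend on
  controlled archives and curated snapshots and are not recomputable here;
  the acceptance machinery is planted-signal based by design.
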