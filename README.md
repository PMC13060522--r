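# coexdiff

Case-control molecular statistics and differential co-expression networks
for small postmortem cohorts.

## The problem

Postmortem brain-bank studies of psychiatric and neurodegenerative disease
routinely compare two small groups of donors (often n ≈ 5 per arm) across
several modalities at once: binary and continuous histopathology readouts,
a targeted qPCR gene panel on the relative-quantity scale, and a targeted
protein panel with loading controls. At these sample sizes the usual
large-sample machinery is unreliable: rank tests must be exact (and
tie-aware), 2×2 tables carry zero cells, variance heterogeneity is the rule
rather than the exception, and correlation-network claims need edge-wise
inference rather than eyeballing. `coexdiff` packages that entire analysis
chain as tested, composable, tibble-in/tibble-out functions, plus a
synthetic cohort generator with recorded ground truth so every stage can be
validated end to end without any donor data.

## What it computes

- **Pathology stage** — an ordinal 0/1/2 tau–amyloid colocalization index
  compared by an exact, tie-aware Mann–Whitney U test
  (U = min(U₁, U₂), 0.5 credit per tied pair, p by exhaustive enumeration
  of all C(n₁+n₂, n₁) group assignments), with the Hodges–Lehmann median
  difference and an exact-rank confidence interval, and the rank-biserial
  effect size r = 1 − 2U/(n₁n₂). Dual-positivity 2×2 tables get a
  Haldane-corrected odds ratio ((a+½)(d+½))/((b+½)(c+½)) with a Woolf
  interval, a Katz risk ratio, and one/two-sided Fisher exact p-values.
  Continuous burden is compared by Levene-gated pooled/Welch t-tests with
  Cohen's d = t·√(1/n₁+1/n₂) and a variance-ratio F test.
- **Differential expression** — per-gene Tukey-fence outlier screening
  within group, directional (case > control) Levene-gated t-tests on the
  log2 scale, fold change as the ratio of group geometric means,
  Benjamini–Hochberg q-values, and a discovery curve whose elbow guides
  the FDR threshold choice (default q ≤ 0.2).
- **Module scoring** — group-mean imputation, correlation-matrix PCA over
  FDR-passing genes with regression-method scores (standardized data ×
  R⁻¹ × loadings, pseudo-inverse in the usual cases-fewer-than-genes
  regime), scree-elbow retention, two-group MANOVA (Wilks Λ with the exact
  two-group F transform), per-component ANOVA with η² = F·df₁/(F·df₁+df₂),
  and two-model hierarchical regression adding a binary covariate
  (ΔR² F-change test).
- **Network stage** — within-group Spearman correlations with exact
  permutation p-values at small n, curated edges plus novel pairs passing
  |ρ| ≥ 0.9 with p < 0.05 in either group, Fisher r-to-z tests of
  between-group correlation change per edge, full topology metrics
  (degree, normalized betweenness/closeness, clustering, path lengths,
  heterogeneity, Freeman degree centralization), and GraphML/SIF/TSV
  export with typed attributes.
- **Protein panel** — the same gated directional framework per target with
  BH correction *within* each a-priori category (pathology, gliosis,
  excitatory, inhibitory), loading-control QC tests, and follow-up
  hierarchical regressions. Postmortem-interval QC correlates PMI against
  burden, the first expression PC, and total protein abundance before any
  outlier removal.

## Worked example

```r
library(coexdiff)

coh <- simulate_cohort(seed = 42)   # 5 vs 5 donors, 84-gene panel, truth recorded
pathology_compare(coh$pathology)
#> <pathology_report>
#>   colocalization index: U = 2.5, exact one-sided p = 0.0238, HL = 1
#>   dual positivity: OR = 33 (1.06-1.02e+03), RR = 5, Fisher p = 0.0238
#>   burden measures compared: 2

de <- run_de(coh)
glance(de)
#> # A tibble: 1 × 6
#>   n_tested n_excluded n_q05 n_q10 n_q20 inflection_q
#> 1       84          0    20    22    33        0.125

mod <- module_scores(coh, de, q_threshold = 0.2)
mod
#> <module_report> 33 genes, 2 component(s)
#>   MANOVA: Wilks lambda = 0.1166, F(2,7) = 26.528, p = 0.0005406

corr <- correlate_groups(coh, genes = mod$genes)
net  <- build_network(corr,
  curated = read_sif(system.file("extdata", "curated_edges_synthetic.sif",
                                 package = "coexdiff")))
glance(net)
#> # A tibble: 1 × 12
#>   n_nodes n_edges avg_neighbors density clustering_coefficient ...
#> 1      33      75          4.55   0.142                  0.382
```

The simulated cohort plants dual pathology in every case but only a
quarter of controls — the exact Mann–Whitney comparison of the 0/1/2
index and the Haldane odds ratio quantify that enrichment. Thirty-three
of 84 genes pass q ≤ 0.2 (the generator plants 23 true effects with fold
changes 0.33–6.7×); their two PCA components separate the groups sharply
(Wilks Λ = 0.12), and the co-expression network over those genes combines
the curated edge fixture with data-driven high-|ρ| pairs. `truth_report(coh)`
exposes the planted effects for checking any of these calls.

`run_pipeline(coh, out_dir)` chains all stages in the fixed order (PMI QC
first, before any outlier removal) and writes every table, the GraphML
network and a JSON run report; identical inputs give byte-identical
outputs.

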