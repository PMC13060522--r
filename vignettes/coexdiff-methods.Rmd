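---
title: "Statistical methods and design choices in coexdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods and design choices in coexdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexdiff)
```

`coexdiff` implements a multi-stage case-control analysis for small
postmortem cohorts measured across histopathology, a targeted gene panel
and a targeted protein panel. This vignette explains the statistical
model behind each stage, the conventions and numerical choices the
implementation fixes, and what the synthetic cohort generator does and
does not emulate.

## Exact rank inference for the ordinal pathology index

Each donor receives a colocalization score: 0 (no tau or amyloid
positivity), 1 (either), 2 (both). With four or five donors per arm and
heavy ties, asymptotic rank tests are meaningless, so
`index_group_test()` computes the tie-aware Mann–Whitney statistic
(each tied pair contributes 0.5) and derives p-values by exhaustively
enumerating all $\binom{n_1+n_2}{n_1}$ assignments of the pooled values
to groups. The reported statistic is $U = \min(U_1, U_2)$ — the
convention under which the small-sample worked examples in the field's
commercial software print U = 2 or U = 3 — and the one-sided p targets
the directed hypothesis *case > control*. The two-sided p doubles the
smaller exact tail and caps at 1, so $p_1 \le p_2 \le 2 p_1$ holds
whenever the observed direction matches the hypothesis. Enumeration is
used up to $10^6$ assignments (configurable); beyond that the test
switches to Monte-Carlo permutation and reports the standard error of
the estimated p.

The Hodges–Lehmann estimate is the median of all $n_1 n_2$ pairwise
case-minus-control differences. Its confidence interval comes from the
exact tie-free null distribution of U: the interval takes the
$(c{+}1)$-th smallest and $c$-th largest pairwise differences, where $c$
counts the null U values whose cumulative probability stays below
$\alpha/2$, and the *achieved* level $1 - 2 P(U \le c-1)$ is reported
(for two groups of four at a requested 95% this is 97.14%). With heavily
tied data the interval endpoints are clamped to the observed difference
range; no extrapolation beyond the largest observed pairwise difference
is attempted.

## Contingency statistics with small-cell corrections

`contingency_stats()` applies the Haldane–Anscombe correction
*unconditionally* — 0.5 added to every cell, not only when a zero
appears — because that is the variant that reproduces textbook
small-sample odds ratios such as OR = 21 for the table (4,0,1,3)
together with its Woolf interval
$\exp(\ln \mathrm{OR} \pm z \sqrt{\sum 1/(\mathrm{cell}+\tfrac12)})$.
The risk ratio uses the standard Katz log-scale method on the
*uncorrected* cells; it is undefined (flagged) when the reference group
has no events. One caution this package deliberately surfaces: OR and RR
answer different questions about the same data and are sensitive to which
denominators are used — an evaluable-cases OR and an all-cases RR can
legitimately coexist in one report, so the function takes explicit cell
counts rather than guessing. Fisher's exact p-values come from the
hypergeometric distribution with margins fixed: the one-sided tail sums
tables at least as enriched as observed, the two-sided sums all tables
with probability no larger than the observed one.

## Levene-gated directional t-tests

Every continuous comparison (burden, gene, protein) is gated the same
way: Levene's test — a one-way ANOVA on absolute deviations from the
group *mean*, the original Levene form; median centering is available —
selects the pooled-variance t-test unless p < 0.05, in which case
Welch's t with Satterthwaite degrees of freedom is used. The gate level
(0.05) is a tunable argument. Effect sizes are derived from the
statistic itself, $d = t\sqrt{1/n_1 + 1/n_2}$, so the printed (t, d)
pairs of any run satisfy this identity by construction.

Gene and protein tests run on the log2 scale: relative quantities and
normalized abundances are ratio-scale, and log2 stabilizes variance and
makes the planted (or estimated) fold change the exact group difference
of means. Fold change is reported on the linear scale as the ratio of
group geometric means. The directed one-tailed test (case > control) is
the default, matching the a-priori upregulation hypothesis such panels
are designed around; two-tailed p-values are always reported alongside,
and genes whose fold-change sign disagrees with the t sign cannot occur
under this convention (one coherent scale is used for both), which is
exactly why the convention is fixed internally rather than left to the
caller.

Outlier screening precedes testing (the ordering is a documented choice;
the gate then sees screened data) and uses Tukey fences at 1.5 IQR
within each group, with a z-score alternative. Vectors with fewer than
three observed values are left unscreened and flagged. Values flagged in
the expression stage are *retained* for the correlation stage — the two
stages intentionally consume different masks of the same matrix, because
rank correlations are robust to extremes and discarding donors there
would squander scarce variance.

## FDR control and the discovery curve

`bh_qvalues()` is the Benjamini–Hochberg step-up
($q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$, capped at 1), delegated to
`stats::p.adjust` and cross-checked in the tests against a brute-force
implementation. The working threshold is a user decision; the package's
default of q ≤ 0.2 reflects small-n targeted panels where the costs of
missing correlated true effects outweigh a modest false-discovery
budget, and `discovery_curve()` supports that choice by counting
discoveries along a threshold grid and marking the elbow (the grid point
maximizing the discrete second difference of the count curve — a
heuristic, clearly labelled as such). Stricter thresholds (0.05, 0.1)
are annotated on the output table so high-confidence subsets need no
recomputation. The protein panel applies BH *within* each a-priori
category; when a category concentrates the smallest p-values this is
never more conservative than panel-wide BH (the step-up terms at most
halve), which is the power rationale for grouping.

## PCA module scores and group inference

The module stage standardizes each FDR-passing gene, imputes missing
entries with group means first (imputation precedes standardization),
and eigen-decomposes the gene–gene *correlation* matrix — genes on
heterogeneous scales make covariance PCA inappropriate here. Loadings
are eigenvectors scaled by the square root of their eigenvalue;
per-donor scores use the regression method, $Z R^{-1} L$, standardized
to unit variance so that η² and β are comparable across components.
With fewer donors than genes the correlation matrix is singular; the
Moore–Penrose pseudo-inverse is used and the model is flagged. Two
numerical conventions make runs reproducible: eigenvalues are clipped at
zero, and each component's sign is fixed so its largest-magnitude
loading is positive.

Retention uses the scree elbow: with eigenvalues
$\lambda_1 \ge \lambda_2 \ge \dots$, retain $k^\ast + 1$ components
where $k^\ast$ maximizes the discrete second difference
$\lambda_i - 2\lambda_{i+1} + \lambda_{i+2}$. A flat profile has no
elbow and falls back to fixed k with a warning; fixed-k and
minimum-proportion rules are available directly.

Group separation is tested three ways. MANOVA uses Wilks
$\Lambda = |W|/|T|$ with the exact two-group transform
$F = \frac{1-\Lambda}{\Lambda}\cdot\frac{n-p-1}{p}$ on $(p, n-p-1)$
degrees of freedom, equivalent to Hotelling's $T^2$ (the equivalence is
an oracle test). Per-component ANOVA reports
$\eta^2 = F\,df_1/(F\,df_1 + df_2)$. Hierarchical regression fits two
OLS models on standardized variables — group alone, then group plus the
binary covariate — and tests the increment with
$F_{change} = \Delta R^2 / ((1-R^2_2)/(n-3))$. Covariate entries
recorded as *unknown* are treated as *no* by default (absence of a
documented event), with listwise deletion behind a switch; a covariate
collinear with group is flagged and its model-2 increment reported as
zero rather than produced from a rank-deficient fit.

## Differential co-expression networks

Within each group, every gene pair gets a midrank Spearman correlation
with an exact permutation p-value when the group has at most eight
donors (at most 8! = 40320 permutations enumerated), otherwise the
t-approximation. Within-group significance is two-sided. The
between-group change per edge is tested by Fisher's r-to-z:
$z = (\mathrm{atanh}\,r_{case} - \mathrm{atanh}\,r_{ctrl}) /
\sqrt{1/(n_1-3) + 1/(n_2-3)}$, with boundary correlations clamped to
$1 - 10^{-6}$ and flagged. The plain $1/(n-3)$ variance is the default;
a 1.06 inflation factor sometimes recommended for rank correlations sits
behind a flag. At five donors per group the normal approximation for z
is rough — the calibration tests therefore check it at larger n, and at
study scale the z values should be read as effect-ordering devices
rather than precise p-values.

The edge set is the union of a curated interaction list (an input file;
the package ships a clearly-labelled synthetic fixture, not a database
export) and novel pairs with $|\rho| \ge 0.9$ *and* p < 0.05 in at least
one group. Curated edges are never pruned, whatever their correlations;
deduplication keeps a curated pair as a single curated edge even when it
also passes the novel rule. Topology metrics follow the conventions of
the standard network-analyzer tools: betweenness normalized by
$(n-1)(n-2)/2$, closeness computed within a node's connected component
as (component size − 1)/Σdistances, mean local clustering with isolated
and degree-1 nodes contributing zero, heterogeneity as the coefficient
of variation of the degree distribution (population variance), and
Freeman degree centralization $\frac{n}{n-2}(k_{max}/(n-1) - density)$.
Disconnected graphs are flagged and path-based metrics are computed
within components. Exports (GraphML with typed attributes, SIF, node and
edge TSVs) carry every encoding — fold-change direction class, component
membership, loading magnitude, per-group ρ/p, z and its p, significance
class (solid iff min within-group p < 0.05) — as data attributes;
rendering is left to graph tools.

## The synthetic cohort generator

`simulate_cohort()` draws the structure the analysis assumes: two arms
(default five donors each), an 84-gene panel in which a configurable set
of genes carries planted linear fold changes (defaults span 0.33–6.7×)
on top of log2-normal noise (default SD 0.45, so planted standardized
effects span roughly 1.2–6 — the regime such targeted panels report), a
two-module latent-factor correlation structure (gene pairs sharing a
module with loadings $\lambda_i, \lambda_j$ have implied log-scale
correlation $\lambda_i\lambda_j$), missing values and symmetric
outliers injected at configurable rates (defaults 2%; outliers at ±4
noise SDs so both tails of the screen are exercised), per-group dual
pathology probabilities (defaults 1.0 for cases, 0.25 for controls —
4-in-4 vs 1-in-4 style contrasts), a TBI-like covariate associated with
case status (default 80% concordance, 20% recorded unknown), PMI drawn
uniformly on 5–48 hours independent of every signal, and an 18-target
protein panel across the four categories with planted standardized
effects bracketing the reported pathology/gliosis/synaptic contrasts.
Every modality uses its own deterministic substream of the master seed,
so adding a modality never perturbs another, and a fixed seed fixes
every byte of the serialized cohort.

What it does not emulate: amplification-level artifacts (Ct values,
plate effects, normalization residue), spatial structure in the
histology, heavy-tailed or donor-correlated noise, batch effects, and
any relationship between PMI and signal. Passing calibration tests on
these cohorts therefore demonstrates that the *statistical machinery* is
correct and calibrated under the stated model — not that real
postmortem data satisfy that model. The noise law itself (log2-normal)
is a modeling decision: it keeps quantities positive and makes the
planted fold change the exact expectation ratio on the log scale.

## Problem sizes and tolerances used in validation

The calibration suite checks the directional test's type-I error on a
null cohort of 2000 genes at five donors per group (band: four binomial
standard errors around 0.05), and its power against the noncentral-t
closed form ($ncp = d/\sqrt{1/n_1+1/n_2}$) at planted d ∈ {1, 2, 3}
with 500 genes each (band: ~3.5 Monte-Carlo standard errors plus a small
allowance for the Levene gate's occasional Welch switch). Module
recovery is checked with two *unequal-strength* modules (loadings
0.95/0.8, sizes 12/8): equal-strength, equal-size modules make the top
two eigenvalues coincide, and eigenvectors of a degenerate eigenspace
are rotationally unidentifiable — the dominant-plus-secondary structure
is both identifiable and the empirically typical case. The r-to-z edge
test is calibrated at thirty donors per group, where its normal
approximation is trustworthy. Exact tests, effect-size identities and
graph metrics are checked against brute-force oracles (full
enumeration, step-up by hand, BFS and path enumeration) on problems
small enough to enumerate.

## Known limitations

- Exact enumeration costs grow combinatorially; above the caps the
  package switches to Monte-Carlo (rank tests) or t-approximations
  (Spearman), both flagged in the output.
- The r-to-z edge test at five donors per group is approximate; treat
  edge-change p-values at study scale as descriptive.
- The Hodges–Lehmann interval under heavy ties is conservative and its
  endpoints cannot exceed the observed pairwise-difference range.
- Group labels are fixed to `"control"`/`"case"`; mapping other label
  pairs is the caller's responsibility at ingestion.
- The hierarchical-regression stage assumes a single binary covariate,
  mirroring the design it supports; richer covariate sets need a
  different tool.
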