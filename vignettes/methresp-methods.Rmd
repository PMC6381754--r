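---
title: "Methods and design notes for methresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for methresp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methresp)
```

`methresp` implements a two-cohort epigenetic biomarker workflow for
predicting pathological complete response (RCB = 0) to neoadjuvant
chemotherapy in triple-negative breast cancer: a five-filter
differential-methylation cascade on array β values, pyrosequencing-style
replication, an AIC-selected linear methylation score with a ROC/Youden
decision rule, and ΔΔCt expression analyses. This vignette records the
statistical model behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the design decisions taken where the workflow leaves
genuine freedom.

## The statistical model, stage by stage

### Per-probe testing and the cascade

β values (methylated fraction of signal at a CpG, in [0, 1]) are compared
between responders (R) and non-responders (NR) with the two-sided
Wilcoxon/Mann–Whitney rank-sum test, probe by probe. The test is
distribution-free, which matters because β values are bounded, skewed and
often bimodal; with ~10–14 patients per group a parametric alternative
would lean on assumptions the data cannot support. `rank_sum_test()`
delegates to `stats::wilcox.test()`: the exact permutation null is used
when the combined sample size is at most `exact_limit` (default 20) and
there are no ties; otherwise the normal approximation with tie-corrected
variance and continuity correction. The default switch point covers the
discovery comparison (10 vs 14 = 24 samples, which has ties in practice
anyway) while keeping small pyrosequencing comparisons exact.

The cascade then applies, in order: unadjusted p < 0.05; |Δβ| ≥ 0.20 with
Δβ = mean β(NR) − mean β(R); promoter island/shore annotation (island
relation in {Island, N_Shore, S_Shore} *and* at least one gene-group
annotation in {TSS1500, TSS200, 5UTR, 1stExon}); intragroup SD ≤ 0.20 in
*both* groups; and consecutive-CpG consistency. Each probe records the
first filter it failed, which makes the per-step counts an audit trail:
they are non-increasing by construction and reconcile with the input probe
count.

Three of these choices deserve comment:

- **No multiple-testing correction at step 1.** The procedure is a
  *screening* cascade whose specificity comes from the conjunction of five
  orthogonal filters, not from the p threshold alone. An optional
  Benjamini–Hochberg flag (`adjust_p`) exists for users who want FDR
  control, but it is off by default because the described procedure uses
  raw p values.
- **The effect-size filter is two-sided.** |Δβ| ≥ 0.20 admits genes
  hypermethylated in either group; the two directions are tracked
  explicitly (`hyper_in_NR` vs `hyper_in_R`) because both classes of
  marker are biologically meaningful (the responder-hypermethylated class
  is the one that ultimately feeds the signature).
- **"Consistent profile in consecutive CpGs" is quantified here.** The
  qualitative idea — a lone DMCpG is less trustworthy than one whose
  neighbours shift the same way — needs numbers to be an algorithm. The
  defaults are: neighbours are probes of the same gene on the same
  chromosome within ±1000 bp (`window`); a neighbour is concordant when
  its Δβ has the same sign and |Δβ| ≥ 0.10 (`concordance_delta`, half the
  headline effect threshold); a probe passes with ≥ 2 concordant
  neighbours (`min_concordant`), or all of them when fewer exist; isolated
  probes fail (`fail_if_no_neighbors = TRUE`). All four are configuration
  keys, because this quantification is the package's own reconstruction of
  an informally described step; the window matches the scale of promoter
  CpG islands, where assayed consecutive CpGs sit tens to hundreds of
  base pairs apart.

Probes annotated to several genes (semicolon-joined symbols) support every
named gene, so overlapping annotations surface as distinct candidate genes
sharing probes. A candidate gene's direction is the majority sign of its
surviving probes; discordant-minority probes are excluded from its support
rather than silently averaged.

### Replication

Gene-level pyrosequencing methylation is the unweighted mean percentage
over the assay's CpGs per sample (missing CpGs dropped per sample).
Replication in a cohort requires both p < α (default 0.05) *and* direction
concordance with the discovery candidate — a significant shift the wrong
way is treated as a failure, not a success, because the narrative logic of
a replication stage checks the sign throughout. Results with
α ≤ p < 0.20 and the right sign are annotated as a trend
(`trend_max = 0.20`); trend genes may enter the modelling stage when
`allow_trend` is on (the default), reflecting the judgement that a
direction-consistent near-miss in a 9-vs-21 comparison is worth carrying
forward, while keeping the flag explicit so the stricter policy is one
switch away.

Covariate checks (age, tumour size, nodal status, Ki67) use the rank-sum
test for dichotomous covariates and Kruskal–Wallis for three or more
levels. Numeric covariates are dichotomized at their median by default;
the cut is configurable because any choice here is a convention.

### Signature selection and the decision rule

Binomial logistic regression is the model family behind the AIC: it is the
standard AIC-bearing classifier whose linear predictor has exactly the
published rule's shape. All candidate subsets of size ≤ `max_genes`
(default 2) plus the intercept-only null are fitted and ranked by
AIC = 2k − 2ℓ. Two safeguards:

- **Separation handling.** With strong markers and n ≈ 40, quasi-complete
  separation is a real possibility. The likelihood then increases
  monotonically in the coefficient norm; the fit is flagged
  `converged = FALSE` and its AIC is reported at the iteration cap
  (25 IRLS steps). Selection still works — at the cap the AIC of a
  separating model is essentially 2k — and the flag travels with the
  model.
- **AIC margin against the null.** Minimizing AIC over many subsets is a
  multiple search: with five pure-noise candidates, the best of fifteen
  subsets beats the null by chance alarmingly often at margin 0. The
  design requirement adopted here is that pure-noise candidate sets should
  leave the null standing in at least 80% of runs; a one-off calibration
  simulation over margins {0, 2, 4, 6} under that null design picked 4 as
  the smallest margin meeting the requirement (also the conventional
  "considerably better support" gap in AIC practice). A planted
  two-gene signal dwarfs this margin, so the cost in sensitivity is
  negligible.

The published rule is an intercept-free weighted sum compared against a
constant, so `score_samples()` computes Σ coefficient × methylation(%)
with no intercept and the logistic intercept is absorbed into the cutoff:
shifting the score by a constant and shifting the threshold by the same
constant define the same classifier. The cutoff itself is the
Youden-optimal threshold (max sensitivity + specificity − 1) over the
empirical ROC with `-Inf` and every observed score as candidates;
prediction is *strictly* score > cutoff; ties in J are broken toward the
smallest cutoff for determinism, with a 1e-12 tolerance so that exact ties
computed along different floating-point paths still count as ties. The
AUC is always the pairwise-wins statistic U/(n_pos · n_neg) with ties
counted ½ — a single source of truth shared with the rank-sum machinery —
and its 95% CI is a percentile bootstrap over case resamples (default
1000; unstratified, because nothing in the design stratifies; resamples
that lose a class are redrawn and counted). Percentile rather than BCa or
normal-theory intervals is the simplest method consistent with
"bootstrapping with 1000 iterations", and is documented as such.

Classification performance is reported as the RCB = 0 rate among
score-positive and score-negative samples, always recomputed from the
integer counts and printed as "x out of n (p%)" with one decimal. The
cutoff value is data-dependent and never hard-coded; the model is fitted
on the pooled cohorts by default (mirroring a whole-cohort modelling
stage), and this in-sample character is a stated limitation below.

### Expression

ΔΔCt with amplification efficiency fixed at 2: triplicate Ct values are
averaged *on the Ct scale* (standard practice; averaging folds instead
would bias the estimate upward), ΔCt = Ct(target) − Ct(reference),
ΔΔCt = ΔCt − ΔCt(calibrator), fold = 2^−ΔΔCt. The calibrator is a required
argument with no default. Fold changes are compared between response
groups by rank-sum test; methylation–expression coupling uses Spearman's
rank correlation (midranks for ties, p from the t approximation
t = ρ√((n−2)/(1−ρ²)), adequate at the n ≥ 10 sizes used here and
documented as an approximation). The demethylating-treatment contrast
tests methylation and expression endpoints independently and insists on
≥ 3 replicates per arm, the minimum for the triplicate design to carry
any rank information.

### Study design

`two_proportion_sample_size()` uses the unpooled normal-approximation
formula without continuity correction,
n/group = ⌈(z₁₋α/₂ + z_power)² (p₁q₁ + p₂q₂) / (p₁ − p₂)²⌉, which is the
variant that reproduces the reference calculation this workflow is built
around (45% vs 10% at α = 0.05, power 0.80 → 22/group, 44 total).
Drop-out inflation is multiplicative, ⌈n(1 + d)⌉ (44 with 15% → 51);
dividing by (1 − d) would give 52 and is not what the reference
calculation did. Neither variant is offered as an option — mixing
conventions inside one design stage invites inconsistency.

## The synthetic-data generator

The generator exists so that every downstream stage can be exercised
against planted ground truth. Its central device is a *latent* per-sample,
per-gene methylation level: group means separated by the planted Δ
(`delta`), within-group biological SD `sd_within`, drawn once per cohort
seed. The array, pyrosequencing and qPCR generators all observe this same
latent biology through platform-specific noise — array probes add
probe-level noise (SD 0.02) on each of the gene's first
`n_consecutive_cpgs` promoter CpGs, pyrosequencing reads it on the
percentage scale with per-CpG assay noise (default SD 3 points), and
expression couples to it through a negative slope on the log2 scale
(default −4 per β unit, i.e. a fully methylated promoter silences ~16-fold)
before Ct-level technical noise (SD 0.15 cycles). This mimics technical
validation of one biology rather than independent biologies per platform;
a *validation cohort* is a fresh biological draw (new seed), mimicking
analytical replication.

Unplanted probes draw per-probe baselines from a bimodal Beta mixture
(half Beta(2,10), half Beta(10,2)) — the characteristic two-humped marginal
distribution of array β values — plus per-sample noise of SD `noise_sd`
(default 0.10) on the β scale, clamped to [0, 1]. Noise is added on the β
scale rather than the logit scale deliberately: it keeps the SD filter's
≤ 0.20 threshold interpretable exactly as the cascade applies it.

Default study conditions are the ones the pipeline is designed around:
discovery 10 R vs 14 NR, validation 9 R vs 21 NR, planted Δβ = 0.30 on
runs of 4 consecutive promoter-island CpGs with SD 0.10. For the
signature-recovery simulations a weaker regime is used — two predictive
genes at 25 percentage points with SD 15 among five candidates, n = 39
pooled with 11 responders — chosen as realistic pyrosequencing-scale
effects for that stage; at the discovery-scale effect sizes a single gene
often separates the classes completely, which makes two-gene recovery
meaningless rather than hard.

What the generator does **not** emulate, and hence what passing tests do
not show about real data: batch and chip effects, cell-type composition
and tumour purity, probe cross-reactivity and SNP-affected probes,
spatially correlated noise along the genome beyond the planted runs,
non-Gaussian assay error, and any relationship between covariates (age,
staging, Ki67) and methylation — covariates are generated independent of
response, so covariate-independence checks on synthetic data are
calibration checks, not biology. Recovering 100% of genes planted at
Δβ = 0.30/SD = 0.10 says the machinery is correct, not that real effects
of that size are typical.

## Numerical and degenerate-input conventions

- Constant pooled input to the rank test: p = 1 by convention, flagged
  `degenerate`; Spearman correlation on constant input signals an error
  rather than returning NaN.
- A probe missing in more than `max_missing` (default 20%) of either
  group, or with fewer than 2 observed values in a group, is excluded
  before testing and logged with a reason.
- Planted group means pushed outside [0, 1] are clamped with a warning;
  all β output is clamped to [0, 1] and all pyrosequencing output to
  [0, 100].
- An empty survivor set at any cascade step yields an empty candidate list
  with counts still reported; the pipeline completes with a warning rather
  than failing.
- All randomness flows through explicit integer seeds; identical
  configuration and seed reproduce every output file byte for byte,
  including bootstrap CIs.
- Manifest positions are 1-based; BED exports are 0-based half-open; the
  converters are exact inverses. Percentages and fractions convert exactly
  once, at the array→pyrosequencing boundary (×100).

## Problem sizes used in the test-suite simulations

Operating-characteristic tests run at the scale of the study they emulate:
cascade recovery on 40-gene (320-probe) manifests with 12 vs 12 cohorts
over 20 seeds; replication power at 9 vs 21 over 50 seeds; signature
recovery at n = 39 over 20 seeds; permutation AUC with 200 label
permutations. These sizes give stable rate estimates for thresholds of the
80–95% kind while keeping the suite quick to run routinely.

## Known limitations

- The signature's AUC, cutoff and rates are in-sample: the model is
  selected, fitted and evaluated on the pooled cohorts, as a whole-cohort
  modelling stage does. No cross-validation or external-cohort estimate is
  produced, so reported performance is optimistic for new patients.
- The consecutive-CpG consistency rule is this package's quantification of
  a qualitative criterion; different window/concordance settings change
  the survivor set, which is why they are all configuration keys.
- The exact rank test is skipped in the presence of ties (normal
  approximation with tie correction is used), which is standard but means
  heavily tied pyrosequencing percentages are handled approximately.
- The ΔΔCt implementation assumes perfect amplification efficiency; no
  standard-curve correction is offered.
- The pipeline starts at β values; array preprocessing (normalization,
  probe filtering, batch correction) and IDAT handling are out of scope.
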