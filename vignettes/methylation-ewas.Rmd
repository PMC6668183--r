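---
title: "Binomial-regression EWAS on bisulfite counts: models, DMRs, meQTLs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binomial-regression EWAS on bisulfite counts: models, DMRs, meQTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsewas)
```

## The statistical problem

Targeted bisulfite sequencing (e.g. methylC-capture sequencing, MCC-Seq)
measures DNA methylation at single-CpG resolution as a pair of counts per
CpG per sample: methylated reads $m_{ij}$ out of total reads $t_{ij}$.
`bsewas` implements an epigenome-wide association study (EWAS) on such
counts for a cohort design built around anti-citrullinated protein
antibody (ACPA) positivity — a serological risk marker for rheumatoid
arthritis (RA) measured in optical-density (OD) units and categorised as
negative ($\le 20$ OD), medium-positive (20–60 OD) and high-positive
($> 60$ OD) — together with a small self-reported-RA group.

## The per-CpG model

At each CpG the methylated count is modelled as binomial with a
logit-linear mean:

$$m_{ij} \sim \mathrm{Binomial}(t_{ij},\, p_{ij}), \qquad
\mathrm{logit}(p_{ij}) = \beta_0 + \beta_1 x_j + \gamma^\top z_j,$$

fitted by maximum likelihood (IRLS via `stats::glm.fit` on the
proportion response weighted by $t_{ij}$). Inference on the predictor of
interest $x_j$ uses the Wald statistic $z = \hat\beta_1/\widehat{se}$
with a two-sided normal reference; likelihood-ratio tests are not
offered. Five model specifications are provided (`model_spec()`):

| model | predictor | covariates |
|---|---|---|
| I  | ACPA-positive vs negative (RA excluded) | age, sex, smoking |
| II | as I | + five measured blood-cell proportions |
| III | RA vs all others | age, sex, smoking, cells |
| IV | ACPA ordinal dose 0/1/2 (numeric, one slope) | age, sex, smoking, cells |
| V  | case vs control | none (small validation cohorts) |

Coding choices the data cannot decide for themselves: smoking enters as
two indicators (current, past; never = reference); the five cell
proportions sum to one, so the basophil column (the smallest
compartment) is dropped to keep the design full rank; the ordinal dose
is a single numeric slope per the dose-effect design. Per-CpG fits that
fail (non-convergence, separation, a predictor left constant after
coverage masking) are kept as `converged = FALSE` rows and excluded from
the multiplicity computation; the scan never aborts on them.

For the two-group, no-covariate design the MLE has a closed form — the
difference of pooled logits with
$se = \sqrt{\sum_g (1/m_g + 1/(t_g - m_g))}$ — which the test suite uses
as an independent oracle at $10^{-8}$ precision. The IRLS convergence
tolerance is set to `epsilon = 1e-14` so that the standard errors reach
that agreement, not only the coefficients.

## Filtering

`filter_cpgs()` applies, in order: removal of sex-chromosome CpGs;
masking (setting to missing) of any observation with depth below 15
reads; removal of CpGs observed in fewer than 30 unmasked samples;
removal of non-variable CpGs (zero standard deviation of the methylation
ratio over unmasked samples; fewer than two unmasked samples counts as
undefined and is removed). Masking, rather than using low-coverage
observations for the model but not the sample count, is the stricter
reading of a rule motivated by measurement accuracy; both the depth and
sample-count thresholds are arguments. `filter_snps()` masks genotype
calls below 10 reads, drops non-bi-allelic records, and keeps SNPs with
call rate strictly above 70%.

## Multiplicity: Storey q-values and genomic control

`estimate_qvalues()` implements the Storey procedure directly:
$\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))$ on the grid
$\lambda = 0.05, \dots, 0.90$, smoothed by a natural cubic spline with
3 df and read off at $\lambda = 0.90$, clamped to $(0, 1]$; then
$q(p_{(i)}) = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$. With fewer than
100 tests the spline is unstable and $\pi_0 = 1$ (the conservative
Benjamini–Hochberg limit) is used instead; `pi0` can always be fixed by
argument. CpGs with $q < 0.01$ are called differentially methylated
(DMCs) by default. The genomic-control factor is
$\lambda_{GC} = \mathrm{median}\{F^{-1}_{\chi^2_1}(1-p)\} / 0.45494$.

## DMR calling

`call_dmrs()` reproduces a seed-and-merge definition: DMC seeds open
candidate windows of $\pm 200$ bp (closed at the boundary), overlapping
windows merge; inside a candidate region, maximal runs of *consecutive
tested* CpGs that all have nominal $p < 0.01$ and the same direction of
change are extracted, and runs with at least 3 members containing at
least one seed are reported. "Consecutive" means adjacent in the
post-filter analysis set — an untested CpG cannot break a run — and a
run may span the merged windows of several seeds but must contain one
(regions are built around significant sites). The per-region mean
methylation difference averages the per-CpG differences of
coverage-pooled group ratios (not the difference of per-region pooled
means; the alternative reading is noted in the documentation). The
caller is verified against an exhaustive brute-force enumerator of
maximal qualifying runs on a thousand random instances.

`directional_filter()` computes coverage-pooled group means
($\sum m / \sum t$) for the negative/medium/high/RA groups and calls a
CpG dose-directional when the three ACPA means are strictly monotone,
with RA consistency as a weak inequality beyond the high group (the RA
group may sit at or past the high-dose mean). Both comparators are
arguments.

## cis-meQTL mapping and genetic classification

`map_cis_meqtls()` reproduces a MatrixEQTL-style additive scan: for
every SNP–CpG pair within 250 kb (a 500-kb window), ordinary least
squares of the methylation ratio on alt-allele dosage with no
covariates; Benjamini–Hochberg q-values over all pairs and a
genome-wide subset at $p < 5\times10^{-8}$. CpG selection for this scan
(call rate above 50% of the cohort, ratio variance in the top half) is
deliberately separate from the EWAS filter, and the scan is intended to
be run on the *unmasked* count matrix: depth-masking belongs to the
count regression's accuracy argument, while the ratio regression here
uses its own call-rate rule. Pairs with constant dosage or methylation
are skipped and counted.

`adjust_and_classify()` appends the lead significant meQTL dosage
(smallest p; ties by distance, then position) to the original binomial
model and refits each DMC on samples with a genotype call, falling back
to the next meQTL when more than 30% of dosages are missing. A DMC
"remains significant" when its Bonferroni-adjusted p (raw refit p times
the number of refitted DMCs, capped at 1) is below 0.01 — the stricter
of the readings of a Bonferroni-threshold rule; a plain q-value rule is
available by argument. A DMR is `ngDMR` when its members re-satisfy the
DMR membership criteria after adjustment, `gDMR` when testable but not,
and `untestable` when no member has a significant meQTL in the window;
`rule = "any"` switches to the laxer any-member reading.

## Feature annotation, enrichment, replication

CpG-island classes follow edge distance: inside an island, shore within
2 kb outside, shelf within the next 2 kb, open sea beyond — a disjoint,
exhaustive partition. Promoter windows are TSS $\pm$ 1500 bp (the
transcription-end window is defined symmetrically), autoimmune-SNP
regions are SNP $\pm$ 200 bp, and a CpG is intergenic only if it touches
no gene body and no TSS/TES window. Enrichment uses one two-sided
Fisher's exact test per feature with all testable CpGs as background and
the CpG (not the region) as unit; fold change $(k/n)/(K/N)$, no
cross-feature multiplicity correction. Replication restricts both
cohorts to their common tested CpGs; a discovery DMC replicates at
validation $p < 0.05$ with matching direction, and the fold enrichment
compares the observed discovery–validation DMC overlap with its
independence expectation ($n_d\,n_v/n_{common}$, hypergeometric
upper-tail p) — the independence-expectation reading of a partially
specified construction, documented here as the package's choice.

## The synthetic study generator

`simulate_dataset()` emulates the full study with known ground truth.
Its defaults are the study conditions: 66/45/18 ACPA
negative/medium/high subjects plus 8 RA subjects (all female, 3/4
ACPA-positive), 50,000 CpGs on four autosomes plus a chrX that exists
solely to exercise the sex-chromosome filter, negative-binomial coverage
with mean 15 reads (size 5, reflecting the overdispersion of real
capture coverage), CpGs drawn in island clusters plus dispersed
background, and OD values log-normal within group, truncated at the
clinical cut-offs. Methylation probabilities are
$\mathrm{logit}^{-1}(\text{baseline} + \beta\,\text{dose} +
c\,(\text{neutrophil} - \bar{\text{neutrophil}}) + s\,G)$ with
binomial (or beta-binomial, `overdispersion_rho`) counts. Cell
proportions are Dirichlet draws around realistic blood means
(neutrophil 55%, lymphocyte 30%, monocyte 8%, eosinophil 5%, basophil
2%).

Planted regions come in two mechanisms. *Dose* regions shift by
`effect_logit` (default 1.0) per ordinal step, in a random direction,
and additionally carry a cis SNP (frequency independent of ACPA, slope
0.8 logit/allele) so that they have a real, phenotype-independent meQTL
— without one they would be untestable rather than non-genetic in the
classification. *Genotype-confounded* regions have no direct dose
effect; their SNP (slope 1.2 logit/allele) has allele frequency
0.2/0.35/0.5 across the dose groups, so unadjusted models see a dose
association that genotype adjustment removes — the test bed for gDMR
labelling. RA subjects are generated at an effective dose of 3 so the
RA group extends the monotone trend. Optional switches induce
neutrophil or smoking confounding with dose for covariate-adjustment
tests. `simulate_validation()` draws an independent 9-case/13-control
cohort over the same CpG map in which cases carry the dose-mechanism
effects (confounded regions deliberately do not replicate).

What the generator does *not* emulate: linkage disequilibrium (SNPs are
independent), read-level artefacts (bisulfite conversion error,
alignment bias, strand effects), spatial correlation of methylation
beyond the shared island baseline, and relatedness or population
structure. Passing tests therefore demonstrate correctness of the
statistical machinery under the declared generative model, not
robustness to those real-data complications.

## Problem sizes, margins and numerical choices

The test suite and the acceptance script run the full chain on the
default 50,000-CpG, 137-sample study (about two and a half minutes on
one core), plus a 5,000-CpG null study for calibration (type-I error,
$\lambda_{GC}$, Storey $\pi_0$, KS uniformity), a 5,000-CpG
50-region pair of cohorts for replication statistics, and
1,000-instance brute-force fuzzing of the DMR caller. One margin is
worth knowing: dose-mechanism regions are recovered essentially always,
but genotype-confounded regions are recovered only 70–90% per
realization — their marginal dose effect is the slope times the
allele-frequency step (about 0.36 logit per dose step), and because
every CpG sees a different random subset of samples at $\ge 15\times$
coverage, member p-values fluctuate and three-in-a-row runs sometimes
break. This is a property of the design conditions, not of the caller
(which is exact against brute force).

Other numerical choices: q-values are clamped to $[0, 1]$ and are exact
step-up enumerations given $\pi_0$; the candidate-window boundary is
closed (a CpG exactly at seed $\pm$ 200 bp is inside); lead-meQTL ties
break by distance then position; samples missing the lead dosage are
dropped only for that CpG's refit; Fisher p-values are validated against
exhaustive hypergeometric enumeration at $10^{-12}$.

## Limitations

No quasi-binomial or beta-binomial dispersion correction is applied in
the EWAS fits (binomial Wald tests are anti-conservative under residual
overdispersion; the null-calibration check guards the default
conditions only). No spatial smoothing, kernel/HMM DMR calling,
trans-meQTLs, imputation, mediation analysis, or reference-free
cell-type deconvolution: measured differential counts are required.
Pathway-style enrichment is supported only generically, by supplying
gene-set intervals as extra annotation tracks.
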