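---
title: "Methods: complement pQTL scanning and genotype-stratified subgrouping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complement pQTL scanning and genotype-stratified subgrouping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models, the assumptions they lean on, the tunable parameters, what the
synthetic cohort generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## The scientific setting

The complement system is the plasma arm of innate immunity. Its alternative
pathway turns over constitutively: Factor D cleaves Factor B into Bb, which
binds C3b to form the C3 convertase, while Factor H inhibits the pathway by
promoting convertase decay. Circulating levels of the precursors (C3,
Factor B), activation fragments (C3a, C5a, Bb, SC5b-9) and regulators
(Factor H) are therefore jointly informative about pathway tone, and the
log2 ratio `Bb/C3 = log2(Bb) - log2(C3)` indexes activation relative to
substrate abundance. The package asks whether common genetic variation
shifts these levels (pQTLs), whether those variants also track case status
in a fatigue-illness case–control design, and whether genotype-defined
strata sharpen the proteins' ability to discriminate cases — i.e. whether an
inflammation-skewed subgroup (high C3, low Bb) is genetically addressable.

## Preprocessing

All analyses run on `log2(max(raw, floor))` concentrations. The floor
(default 0.01 in each analyte's native unit, configurable per analyte)
exists only because log2 of a zero concentration is undefined; assay
detection limits vary by platform, so the package exposes the floor rather
than hard-coding a limit-of-detection rule. The Bb/C3 ratio is derived
after flooring and satisfies `BbC3ratio = log2Bb - log2C3` exactly.

Genotypes are recoded at read time so dosage counts the *in-sample* minor
allele — the less frequent allele among non-missing calls in the analysed
cohort, not a reference-panel allele. At an exact 0.5/0.5 tie the
lexicographically smaller nucleotide is declared minor; this is arbitrary
but deterministic, which matters more than the choice itself.
Multi-allelic VCF records are skipped with a warning (the immunochip-style
panels this targets are biallelic). Missing genotypes stay missing; every
model drops incomplete rows pairwise, per SNP–protein pair.

## Covariate screening

Each analyte is screened against age, sex and BMI with simple bivariate
OLS; a covariate enters the analyte's downstream adjustment set when its
p-value is below `alpha` (default 0.05), and a configuration-level override
list can force covariates in regardless (for adjustments supported by prior
literature rather than this sample). Sex is coded male = 1 / female = 0 —
female is the natural reference in a predominantly female illness — so a
negative sex coefficient means lower levels in males. The screen is
deliberately bivariate, not multivariable: its job is to decide adjustment
sets, and the same sets are reused by every downstream model, mirroring the
screen-then-adjust flow of the study design this package implements.

## Case–control and subgroup models

The linear model `log2(protein) ~ group + covariates` codes the group term
so the reported effect is adjusted mean(control) − mean(case); negative
values therefore mean higher levels in cases. The logistic model
`case ~ log2(protein) + covariates` reports the per-unit log-odds of being
a case, so the two models answer complementary questions and should agree
in direction for a real shift. No multiplicity adjustment is applied
across analytes in these models (the output metadata says so); the pQTL
scan, which fits hundreds of models, is where Bonferroni lives.

Logistic fits use IRLS with tolerance 1e-8 and at most 100 iterations.
Complete separation is detected both from R's fitted-probability warning
and from a residual deviance below 1e-6 (separation can drive the deviance
to zero without tripping the warning); separated fits are flagged
`converged = FALSE` rather than silently reported, because their Wald
statistics are meaningless.

Four-level subgroup outcomes use a multinomial logit with NFhet as the
reference (its coefficient block is identically zero in tidy output). The
protein's overall contribution is tested by a likelihood-ratio test against
the covariates-only model refitted on exactly the same rows;
`lrt(full, full)` degenerates cleanly to statistic 0, p = 1. Pairwise
group contrasts are estimated marginal means at covariate sample means via
emmeans, re-oriented so every contrast reads "A − B" with A
alphabetically first regardless of which level the model used as
reference; no multiplicity adjustment by default.

## The pQTL scan

For each SNP–protein pair the full model adds the additive dosage term to
the analyte's covariate set and is compared with the reduced model by the
F-test on identical rows; with one added term F = t² exactly, and the
package tests that identity to 1e-9. A pair is testable when the analysed
rows carry at least two distinct dosage values and at least three minor
allele copies — below that the dosage term is all leverage and the F
distribution is meaningless. The Bonferroni denominator is the number of
models actually fitted in the scan (skipped pairs excluded), and summary
counts are reported at the two tiers p < 0.05 and p < 0.01. The 2-df
genotypic coding is deliberately not implemented: the additive model is the
scan's estimand.

The per-analyte covariate sets for the scan come from the screening stage;
the package assumes the same sets apply to genetic and non-genetic models
(the model formulas are identical apart from the dosage term).

## Enrichment, overlap, directionality

Top hits are the scan records with raw FvR p strictly below the threshold
(default 0.01). For each analyte and each of the seven functional groups,
the enrichment score is the observed proportion of the analyte's hits in
the group divided by the group's expected proportion in the pool of all
analytes' hit lists; by construction the expectation-weighted mean of
scores is 1 for every analyte, an identity the tests assert at both SNP and
gene level (genes count once per analyte list). Whether the pool should
deduplicate SNPs shared across analyte lists is genuinely ambiguous; the
default pools with multiplicity and `dedupe = TRUE` gives the other
convention.

Cis/trans classification calls a variant cis when it is on the same
chromosome as, and within 1 Mb (inclusive — "within" is read as weak
inequality) of, the transcription start site of the gene encoding the
analyte. The analyte→TSS map is user-supplied; the shipped
`analyte_tss_synthetic.tsv` covers the nine analytes with synthetic
placeholder coordinates for testing and must be replaced with curated
coordinates for real analyses.

The directionality analysis regresses per-minor-allele protein effects (β)
on disease odds ratios, one point per SNP, after flipping any
major-allele-respect rows (OR → 1/OR, β → −β); the R² of that regression
measures how consistently genetic disease risk aligns with the protein
effect. Ordinary least squares without weights is used because the
quantity of interest is the R², not an efficient slope.

## Stratified ROC and subgrouping

Within a genotype stratum (subjects matching all dosage conditions), a
logistic model of case status on the analyte plus covariates produces
in-sample predicted probabilities; the AUC is their Mann–Whitney
concordance (ties ½), the SE is Hanley–McNeil, and the test against
AUC = 0.5 is a normal approximation on (AUC − 0.5)/SE. The Hanley–McNeil/
normal combination was chosen because it is closed-form, deterministic and
standard; it is isolated in `auc_mann_whitney()` so a DeLong or bootstrap
variant could be swapped in. Screens filter at AUC > 0.75 (strict by
default — the source convention uses both ≥ and > in different places, so
the operator is configurable), p < 0.05, and stratum size ≥ 15; the
filters are monotone by construction. The reported AUC is apparent
(in-sample): at stratum sizes of tens of subjects any resampling estimate
would be noisier than the optimism it removes, but users should read the
absolute AUCs as optimistic.

Two-marker subgrouping is a fixed rule, not a fit: a subject is `het` iff
heterozygous (dosage exactly 1) at either marker, and everyone else —
including carriers of two copies of a risk allele — is `rem`. The
homozygous-risk-to-rem behaviour is an explicit edge case, tested over the
full 3 × 3 dosage grid. Subjects missing either genotype are excluded by
default (configurable to `rem`). Labels cross het status with case status
and always partition the cohort.

## The synthetic cohort generator

The generator exists because the cohort this design targets is
access-restricted. Its defaults are the study conditions: 50 cases and 121
controls; BMI slopes per analyte on the log2 scale (0.169 for CRP, 0.033
for C3, …), an age slope for Factor D (0.011/year) and male offsets for
CRP and Factor B (negative, matching the reported direction of lower
levels in males); case–control shifts per analyte (C3 +0.215, Bb −0.022,
… — the Bb/C3 ratio shift emerges from its components); planted additive
pQTL effects at reported magnitudes (−0.36 on Bb and −0.23 on Factor B for
the C2 missense variant, −0.19 on Bb for the CFH V62I variant, +0.24 on
Factor B, and a strong C5a effect at the C5 internal-control locus); one
LD pair (r = 0.95) between the paralogous C2/CFB variants; per-analyte
residual SDs derived from reported total SDs minus the latent and
covariate contributions; and control-mean anchors so simulated levels sit
on the reported scale.

Three structural choices deserve explanation:

* **Fixed margins, not liability threshold.** Group labels are assigned
  first (exactly n_case/n_control) and protein shifts are conditional on
  group. This reproduces the case–control design directly and makes
  group-shift recovery exact in expectation; it does not model incidence.
* **Disease odds ratios via group-specific allele frequencies.** Each SNP
  in the `disease_or` table has its minor-allele frequency tilted in cases
  by the stated odds ratio (on allele odds), producing the case-enriched
  genotype strata the ROC stage needs and a disease table consistent with
  the genotypes. The female fraction (0.75) and case BMI offset
  (+2 kg/m²) are configurable placeholders, not reported values.
* **A heterozygote-specific interaction.** The defining phenomenon —
  protein biomarkers discriminating better inside genotype strata —
  cannot arise from purely additive effects plus a uniform group shift.
  The `het_interaction` block adds an extra case–control shift confined
  to heterozygous carriers of the two focal markers (default +0.35 on C3,
  +1.2 on CRP, +0.25 on Factor H), centred by the expected het probability
  so the *marginal* group shift stays at its configured value. This is the
  package's own modelling device for a genotype-dependent shift; its size
  was chosen to place the het-restricted and unstratified AUCs in the
  reported regimes (≈0.85 vs ≈0.7).

LD is induced by a Gaussian copula on the latent dosing normals. Because
discretising to 0/1/2 attenuates correlation, the latent correlation is
calibrated by bisection against the closed-form dosage correlation
(bivariate-normal rectangle probabilities over the 3 × 3 genotype grid), so
the requested r is achieved to well within ±0.1 at n ≥ 1000; infeasible
requests (extreme r with mismatched MAFs) fall back to the boundary with a
warning. Survey scores are linear in centred log2 protein levels plus
group offsets and noise, with MFI subscales rounded and clamped to their
4–20 range.

What the generator does **not** emulate: genome-wide LD beyond declared
pairs, population structure and relatedness, assay-specific error
(heteroscedastic, censored at detection limits), non-normal protein
distributions, and item-level survey structure. Passing tests therefore
demonstrate that the statistical machinery is correct and calibrated under
the stated generative model — not that the biological conclusions transfer
to any particular real cohort.

## Numerical choices

QR decompositions underlie the FvR fits (never explicit normal-equation
inverses); rank-deficient designs error rather than silently pivoting a
term away. Logistic tolerance 1e-8 / 100 iterations; multinomial reltol
1e-12 so two-level multinomial fits agree with binary logistic to 1e-5.
LRT statistics are clipped at zero with 1e-8 slack for rounding. CI95 for
AUCs is ±1.96 SE truncated to [0, 1]. Tie handling: mid-ranks with
variance correction in the Wilcoxon comparisons (exact distribution when
both groups ≤ 25 and tie-free), half-credit in AUC concordance, and strict
inequalities at every significance threshold.

## Problem sizes in the test suite

The suite exercises the pipeline at the study scale (n = 171, 50/121)
throughout: 2000 null SNP–protein pairs for type-I calibration, 500
replicates for parameter recovery and coverage at the planted effect sizes,
1000 null four-group cohorts for LRT calibration, 25 replicate cohorts for
top-hit recovery, and 200 replicates for the het-versus-unstratified ROC
comparison; scans in examples use 10–60 SNPs. These sizes give Monte-Carlo
standard errors comfortably inside the asserted bands while keeping the
default test run to a few minutes.

## Known limitations

Apparent (in-sample) AUC; no kinship or population-structure adjustment in
the scan; single-SNP models only (no conditional or joint analysis); the
additive coding cannot detect purely recessive or heterotic effects; the
enrichment expectation is the pooled top-hit distribution, so an analyte
contributing most of the pool drags every score toward 1; and the
two-marker subgroup rule is fixed rather than learned, by design.
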