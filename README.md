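# pqtlstrat

Protein quantitative trait locus (pQTL) scanning and genotype-stratified
subgroup discovery for circulating complement proteins in case–control
cohorts, motivated by the heterogeneity of Myalgic Encephalomyelitis /
Chronic Fatigue Syndrome (ME/CFS). The package is for analysts who have a
panel of plasma complement measurements (CRP, C3, C3a, C5a, Bb, Factor B,
Factor D, Factor H, SC5b-9), a SNP genotype matrix with functional
annotation, and subject covariates, and who want to ask three questions:

1. Which variants regulate circulating complement levels (pQTLs)?
2. Do those variants overlap variants associated with disease status, and
   with what directionality?
3. Can genotype-defined strata sharpen protein biomarkers into subgroups?

Because the cohort data this design targets are access-restricted, the
package ships a first-class synthetic cohort generator that reproduces the
study's statistical structure (fixed 50-case/121-control margins, additive
genotype effects on log2 protein levels, demographic covariate effects,
LD pairs, inter-protein correlation, genotype-dependent case–control
shifts) with planted ground truth, so every statistical property of the
pipeline is testable end to end.

## The models

All analyses use log2-transformed concentrations. The core scan fits, for
every SNP–protein pair, the nested ordinary-least-squares pair

```
full:     log2(protein) = b0 + b1 * dosage + b2 * covariates + e
reduced:  log2(protein) = b0 +               b2 * covariates + e
```

with `dosage` the additive count (0/1/2) of the in-sample minor allele, and
compares them with the full-versus-reduced (FvR) F-test

```
F = ((RSS_reduced - RSS_full) / 1) / (RSS_full / (n - p_full)),   F ~ F(1, n - p_full)
```

which for the single added term satisfies F = t² of the dosage coefficient.
Bonferroni correction uses m = number of models actually fitted. Around the
scan sit: bivariate covariate screening (age, sex, BMI per analyte);
case–control linear models (group effect reported as adjusted
mean(control) − mean(case)) and logistic models (odds of case per unit log2
protein); multinomial models over four genotype-defined subgroups with
likelihood-ratio tests; functional-group enrichment scores
(observed/expected proportion of an analyte's top hits per group, pooled
expectation across all analytes' lists); cis/trans classification (within
1 Mb of the encoding gene's TSS, inclusive); OR–β directionality
regression with all effects oriented to the minor allele; and stratified
ROC (Mann–Whitney AUC of in-sample logistic predictions, Hanley–McNeil SE,
filters AUC > 0.75, p < 0.05, n ≥ 15). Two-marker subgrouping labels a
subject `het` iff heterozygous (dosage exactly 1) at either marker —
homozygous-risk carriers are *not* het — crossed with case status into
CFShet/CFSrem/NFhet/NFrem.

## Worked example

```r
library(pqtlstrat)
library(dplyr)

sim      <- simulate_cohort(sim_config_default(n_snps = 40), seed = 7)
proteins <- log2_transform(sim$proteins_raw)
screen   <- screen_covariates(proteins, sim$subjects)
covmap   <- covariate_sets(screen)

tidy(case_control_linear(proteins, sim$subjects, "C3", covmap[["C3"]]))
#> # A tibble: 3 x 5
#>   term        estimate std_error statistic  p_value
#> 1 (Intercept)  -0.291    0.133       -2.19 3.02e- 2
#> 2 groupNF      -0.209    0.0469      -4.46 1.47e- 5
#> 3 bmi           0.0306   0.00422      7.24 1.51e-11
```

`groupNF = -0.209` is the BMI-adjusted difference mean(NF) − mean(ME/CFS)
in log2 C3: cases run about 0.21 log2 units (~15%) higher, echoing the
planted +0.215 shift, and the BMI slope recovers the planted 0.033-scale
effect.

```r
scan <- pqtl_scan(sim$dosages, proteins, sim$subjects, sim$snps,
                  covariate_map = covmap)
summary(scan)
#>   models_fitted snps_tested n_sig_05 n_sig_01 snps_sig_05 snps_sig_01
#> 1           400          40       34       12          20           7

as_tibble(scan) |> arrange(p_fvr) |> select(rsid, analyte, beta, se, p_fvr, gene) |> head(5)
#>   rsid       analyte     beta     se    p_fvr gene
#> 1 rs17611    C5a       -0.469 0.0405 4.13e-23 C5
#> 2 rs641153   FactorB    0.351 0.0595 1.93e- 8 CFB
#> 3 rs17759529 C3         0.164 0.0356 8.39e- 6 DPP4
#> 4 rs4151667  BbC3ratio -0.502 0.127  1.15e- 4 CFB
#> 5 rs9332739  BbC3ratio -0.495 0.127  1.39e- 4 C2
```

The planted pQTLs surface at the top of the scan with per-allele effects
near their planted values. Stratified ROC and two-marker subgrouping:

```r
stratum_roc(sim$dosages, proteins, sim$subjects, c(rs800292 = 1), "C3",
            covmap[["C3"]])
#>   stratum    analyte n_case n_control   auc     se  p_vs_half passes_filters
#> 1 rs800292=1 C3          23        46 0.798 0.0613 0.00000121 TRUE

table(assign_subgroups(sim$dosages, sim$subjects,
                       "rs9332739", "rs800292")$subgroup)
#> CFShet CFSrem  NFhet  NFrem
#>     28     22     49     72
```

Among rs800292 heterozygotes, C3 separates cases from controls with
AUC 0.80 versus about 0.72 unstratified: the genotype stratum concentrates
the biomarker signal. `run_pipeline(pipeline_config(out_dir = "out"))`
chains every stage (transform → screen → associate → pqtl → integrate →
stratify) and writes each result table as a TSV plus a manifest with
hashes, seed and thresholds.

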