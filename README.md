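# triogreml

Family-based GREML variance components for child phenotypes: direct
genetic effects, parental genetic nurture, and their covariance.

## The scientific problem

SNP-based heritability from samples of unrelated individuals conflates two
pathways by which genotypes reach a child's phenotype: the child's own
alleles acting directly, and the parents' alleles acting through the
environment they provide (*genetic nurture*, an indirect genetic effect).
In intact families the two are correlated — a passive gene–environment
correlation — because parents transmit trait-associated alleles and shape
the rearing environment with those same alleles.

With genotyped parent–offspring pairs the pathways can be separated. For
covariate-residualized, standardized child phenotypes `y` over `n` pairs,
the extended GREML model is

    Var(y) = V_o * A_c  +  V_m * A_p  +  V_om * (A_cp + A_cp')  +  V_e * I

where `A_c` is the GRM among children, `A_p` the GRM among the parents,
and `A_cp` the child × parent cross-relatedness matrix (own-pair entries
near 0.5). `V_o` is the direct-effect variance, `V_m` (or `V_f`) the
maternal (paternal) nurture variance, and `V_om` (`V_of`) the covariance
component; the combined genetic variance is `G = V_o + V_m + V_om`. The
model is fitted by average-information REML with boundary constraints on
the variance terms (the covariance is free in sign), and the full model is
compared to the offspring-only model `Var(y) = V_o A_c + V_e I` by a
2-df likelihood-ratio test.

The package covers the full analysis path — trio simulation with a known
direct/nurture architecture, Likert questionnaire generation and scoring
with missingness caps, post-imputation SNP QC (exact HWE test, call rate,
MAF, INFO, duplicates), within- and cross-generation GRM construction with
greedy relatedness pruning at 0.025, covariate residualization with
genotype PCs, and the REML fits — so every stage is testable without
access to restricted cohort data. See the methods vignette
(`vignettes/family-greml-methods.Rmd`) for the model, numerical choices
and validation design.

## Worked example

Simulate 1000 mother–child pairs over 2000 SNPs with direct-effect
variance 0.30, maternal nurture 0.15 and effect-vector correlation 0.5,
then fit the maternal model:

```r
library(triogreml)

cfg <- sim_config(n_families = 1000, n_snps = 2000, n_causal = 2000,
                  v_o = 0.3, v_m = 0.15, rho_m = 0.5, seed = 1)
cohort <- simulate_trio_genotypes(cfg)
pheno  <- simulate_phenotypes(cohort, cfg)

pooled <- (colSums(cohort$child_genotypes) +
           colSums(cohort$mother_genotypes)) / (4 * cfg$n_families)
set <- grm_set(
  compute_grm(cohort$child_genotypes,  freqs = pooled),
  compute_grm(cohort$mother_genotypes, freqs = pooled),
  compute_cross_grm(cohort$child_genotypes, cohort$mother_genotypes,
                    freqs = pooled),
  family_ids = cohort$family_ids)

fit_parent_model(scale(pheno$score)[, 1], set, "maternal")
#> <vc_result> maternal model, N = 1000
#>   v_o       0.342 (0.083)
#>   v_parent  0.191 (0.080)
#>   v_cross   0.096 (0.062)
#>   G         0.630 (0.093)
#>   logL -468.30, LRT p = 2.74e-05 (df 2)

expected_components(cfg)   # generative truth: v_o=0.300 v_m=0.150 v_om=0.106
```

Each estimate sits within one reported SE of its generative truth
(`v_om = 0.5 * sqrt(0.3 * 0.15) ≈ 0.106` in closed form), and `G` is
exactly the component sum. The LRT p-value rejects the offspring-only
model, as it should with real nurture in the architecture.

The end-to-end pipeline (simulate → score questionnaires → SNP QC → PCs →
residualize → GRMs → prune → fit all models) is driven by
`run_pipeline(pipeline_config(...))`; the numbered scripts under
`analysis/` walk the same stages narratively and write their tables under
`results/`.

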