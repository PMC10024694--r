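---
title: "Estimating direct genetic effects and genetic nurture with family-based GREML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating direct genetic effects and genetic nurture with family-based GREML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triogreml)
```

## The problem

A child's phenotype can be shaped by their own genotype (direct genetic
effects), but also by the genotypes of their parents acting through the
rearing environment — *genetic nurture* or indirect genetic effects. Because
parents transmit alleles *and* provide the environment, the two pathways are
correlated in intact families: a child who inherits trait-increasing alleles
typically also receives an environment shaped by those same alleles in the
parent. This covariance is the signature of passive gene–environment
correlation, and ignoring it biases SNP-based heritability estimates from
unrelated-population designs.

`triogreml` implements the estimation machinery for separating these sources
with genotyped parent–offspring pairs, together with a trio simulator that
makes every stage testable without access to restricted cohort data.

## The model

For $n$ parent–offspring pairs with covariate-residualized, standardized
child phenotypes $y$, the extended model places

$$
\mathrm{Var}(y) \;=\; V_o A_c \;+\; V_{m} A_p \;+\;
V_{om}\,(A_{cp} + A_{cp}^{\top}) \;+\; V_e I ,
$$

where

* $A_c$ is the genomic relatedness matrix (GRM) among children,
  $A_{jk} = \tfrac1M \sum_i (x_{ij}-2p_i)(x_{ik}-2p_i) / (2p_i(1-p_i))$;
* $A_p$ is the GRM among the parents (mothers or fathers), on the same
  pooled allele-frequency reference;
* $A_{cp}$ is the child × parent cross-relatedness matrix, whose own-pair
  diagonal concentrates at 0.5;
* $V_o$, $V_m$ (or $V_f$) and $V_{om}$ (or $V_{of}$) are the direct,
  nurture, and covariance components; $V_e$ is the residual.

The covariance enters once through the symmetrized cross structure. Its
diagonal contribution is $2 \times 0.5 \times V_{om} = V_{om}$, so the
phenotypic variance decomposes as $V_o + V_m + V_{om} + V_e$ and the
combined genetic variance is defined as the plain sum

$$ G \;=\; V_o + V_{m} + V_{om}, $$

which is the only convention under which the components and $G$ of a
results row are arithmetically consistent. `combined_g()` implements this
identity together with a delta-method standard error (sum of the component
variances plus twice every pairwise covariance). The offspring-only model
is the special case $V = V_o A_c + V_e I$, the standard SNP-heritability
model.

Model comparison uses the likelihood-ratio test of the full model against
the offspring-only model on the same pairs (2 degrees of freedom: the
parent and covariance components). Since one of the extra parameters is a
variance constrained to the boundary, the plain $\chi^2_2$ reference is
conservative; we report it unadjusted and verify by simulation that the
empirical size at $\alpha = 0.05$ stays at or below nominal (the boundary
mixture correction is deliberately not applied, because a single
unadjusted p-value per model is what the surrounding literature reports).

## REML estimation

`reml_fit()` maximizes the restricted likelihood

$$
\ell_R(\theta) = -\tfrac12\!\left[\log|V| + \log|X^{\top}V^{-1}X|
+ y^{\top}Py\right],
$$

with $X = \mathbf{1}$ (covariates are removed beforehand, see below) by
average-information (AI) iterations:

* the first step and any failed AI step use the EM update, which is slow
  but monotone;
* AI steps are halved until the likelihood does not decrease and
  $V(\theta)$ stays positive definite;
* variance components ($V_o$, $V_m$, $V_e$) are floored at zero when a
  step goes negative; the covariance component is free in sign. A
  component pinned at zero with an inward-pointing gradient is dropped
  from the Newton system (active set), which avoids the slow crawl that a
  truncated joint step otherwise causes;
* convergence is declared when the relative change in $\ell_R$ falls below
  $10^{-8}$ (at most 100 iterations, flagged otherwise); standard errors
  come from the inverse AI matrix at the optimum. $V_e$ keeps a floor of
  $10^{-6}\hat\sigma^2_y$ so $V$ cannot become singular.

Start values split the phenotypic variance equally across the nonnegative
terms with the covariance at zero. On fixtures small enough for dense
brute-force maximization ($n \le 50$) the engine's optimum matches an
independent grid-plus-quasi-Newton maximization of the explicitly computed
restricted likelihood to $10^{-4}$ in every parameter.

Phenotypes are standardized after residualization, so fitted components
are directly proportions of phenotypic variance. Fractions could
equivalently be defined on the raw-residual scale; the standardized scale
was chosen because the downstream quantities of interest are proportions
and it makes rows comparable across phenotypes.

## Covariates

Sex, genotyping batch and ten genotype principal components are regressed
out of the outcome by OLS before REML (`residualize()`), matching the
"regressed out of the outcomes" phrasing common in this literature, rather
than entering REML as fixed effects. At the sample sizes involved the two
choices differ negligibly (the REML projection removes exactly the fitted
fixed effects either way); pre-residualization keeps the mixed-model
kernel small and simple. PCs are the top left singular vectors of the
column-standardized child genotype matrix (`compute_pcs()`), optionally
after greedy LD pruning (window 50 SNPs, step 5, $r^2 > 0.2$ — ordinary
pruning defaults, exposed as options).

## SNP quality control

`filter_snps()` applies the standard post-imputation criteria: exact
Hardy–Weinberg p ≥ $10^{-6}$, call rate ≥ 0.90, MAF strictly > 0.05,
mean INFO > 0.9, biallelic, non-duplicated, with removals attributed to
the first failing criterion in that order. The HWE test is the exact
conditional (hypergeometric) test computed by the stable two-sided
recurrence; an exact test rather than the $\chi^2$ approximation because
rare genotype classes are exactly where the filter operates. HWE is tested
in the founder (parental) generation by default — children are a
nonrandom draw of parental alleles and testing them would double-count
families; this is configurable.

## Relatedness pruning

`prune_relatedness()` removes excess relatedness above a cutoff (default
0.025) by greedy most-connected-first removal, the behaviour of the
standard `--grm-cutoff` tooling: while any within-generation off-diagonal
or off-family cross entry exceeds the cutoff, the family with the most
over-threshold pairs is removed (ties to the larger family index); both
members of a removed family leave together because the pair model needs
complete pairs. Own child–parent cross entries are exempt — they are the
signal, not a violation. An exact post-prune scan is asserted in the
tests.

One practical consequence worth knowing: the cutoff is defined on the
*estimated* GRM, whose entries carry $O(1/\sqrt{M})$ noise. A 0.025 cutoff
is only meaningful when $3/\sqrt{M} \lesssim 0.025$, i.e. panels of
roughly 15k SNPs or more; on small simulated panels the default cutoff
would remove most of the sample for purely statistical reasons. The
analysis drivers therefore simulate 20,000-SNP panels.

## The simulator

`simulate_trio_genotypes()` draws, per SNP, an allele frequency
$p_j \sim U(\text{maf\_low}, \text{maf\_high})$, parental genotypes
$\mathrm{Bin}(2, p_j)$ under Hardy–Weinberg equilibrium, and each child
genotype by fair Mendelian transmission of one allele per parent.
Families are mutually unrelated; spouses pair independently by default
(an assortative-mating knob exists but is off, since assortment is a
confounder to be studied, not part of the base design). Sex is Bernoulli(½)
and batch uniform — batch structure beyond an additive offset is not
modelled.

`simulate_phenotypes()` builds
$y = g_o + g_m + g_f + \beta_{sex}\,\mathrm{sex} + \text{batch} + e$ with
per-SNP effects on *standardized* genotypes (the GCTA-consistent
architecture, so the simulated truth coincides with the GRM model's
estimand). The nurture effect vector is
$w_m = \sqrt{v_m}\,(\rho\, u_o + \sqrt{1-\rho^2}\, u_\perp)$ with $u_o$
the normalized direct-effect vector and $u_\perp$ an orthonormalized
independent draw — both exactly normalized, so the population fractions
hit the configured targets exactly. Because a child's standardized
genotype correlates 0.5 with each parent's, the phenotypic covariance
contribution is

$$ v_{om} = 2 \times 0.5 \times \rho_m \sqrt{v_o v_m}
         = \rho_m \sqrt{v_o v_m}, $$

which `expected_components()` returns in closed form (e.g.
$v_o = 0.3, v_m = 0.15, \rho_m = 0.5 \Rightarrow v_{om} \approx 0.106$).

`simulate_questionnaire()` turns the standardized latent score into
Likert items by adding unit-variance item noise and thresholding into
ordered categories with right-skewed default category probabilities
(cumulative 0.80/0.95 for 3-point items, 0.70/0.85/0.95 for 4-point), so
simulated totals pile up near the scale floor as community-sample symptom
scores do. Items go missing independently at a configurable rate.

What the generator does *not* emulate: linkage disequilibrium (SNPs are
independent), MAF-dependent architectures, X-chromosome transmission,
sibling or multi-generation structure, assortative mating (by default),
population stratification, rater bias, or real imputation uncertainty
(INFO is a constant stub). Passing tests therefore demonstrate the
estimator's behaviour under the idealized generative model it targets —
they do not certify robustness to stratification or assortment in real
cohorts, which is exactly the caveat attached to this design in the
literature.

## Questionnaire scoring

`score_scale()` totals the items after replacing each missing item with
the mean of that respondent's non-missing items, and invalidates
respondents missing more than the scale's cap (SMFQ: 13 three-point items,
cap 2; RS-DBD disruptive: 16 four-point items, cap 3; RS-DBD ADHD: 18
four-point items, cap 4). Item coding starts at 1, pinning the attainable
ranges to 13–39, 16–64 and 18–72; imputed totals are left non-integer.
Note that discretizing the latent score attenuates all genetic fractions
of the *scored* phenotype by the scale's reliability, so pipeline runs on
questionnaire scores recover proportionally smaller components than the
latent-scale truth; recovery tests against the configured truth use the
latent score.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle (scalar
per-SNP relatedness loops, log-gamma enumeration for the HWE test, dense
determinant-based restricted likelihoods, pseudoinverse residualization)
and the estimator end-to-end by simulation:

* single-seed recovery at 3000 pairs × 2000 SNPs against the closed-form
  truth (0.30, 0.15, 0.106), each component within 3 reported SEs;
* a 30-replicate run at 1000 pairs bounding the absolute mean bias of
  each component by 0.03;
* LRT size under the null ($v_m = v_{om} = 0$) from 200 phenotype
  replicates at 800 pairs, rejecting at $\alpha = 0.05$ between 1% and 8%.
  The 200 replicates redraw phenotypes on one fixed genotype cohort: the
  LRT's null distribution is conditional on the realized relatedness
  matrices, so conditional Monte Carlo answers the calibration question
  directly while keeping the run at desk scale;
* GRM sampling theory at 500 × 5000 (unit diagonal, null off-diagonals)
  and 2000 pairs × 2000 SNPs (own-pair cross relatedness 0.5).

These sizes are the package's validation conditions; they were chosen so
each property is measured with comfortable Monte-Carlo margin while the
whole suite runs in minutes.

## Known limitations

* Maternal and paternal effects are estimated in separate pair models, as
  in the reference design; a joint trio model and relatedness
  disequilibrium regression are out of scope.
* The LRT p-value ignores the boundary mixture (conservative for the
  2-df comparison).
* Pre-residualization assumes covariates are exogenous to the genetic
  components; with strong stratification the PCs absorb some genetic
  signal.
* The estimator is dense ($O(n^3)$ per iteration); pair datasets beyond a
  few tens of thousands would need out-of-core or sparse approaches.

## A worked example

```{r example, eval = FALSE}
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

fit <- fit_parent_model(scale(pheno$score)[, 1], set, "maternal")
fit
expected_components(cfg)   # the generative truth to compare against
```
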