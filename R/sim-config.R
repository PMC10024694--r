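#' Simulation configuration for a trio cohort
#'
#' Defines the generative architecture for a cohort of unrelated nuclear
#' families: genotype panel, polygenic direct and parental-nurture effects,
#' the correlation between direct and nurture per-SNP effect vectors, and
#' covariate (sex, genotyping batch) effects on the child phenotype.
#'
#' Variance fractions are defined on the scale of the phenotype before
#' covariate effects are added, so that
#' \code{v_o + v_m + v_f + v_om + v_of + v_e = 1}, where the covariance
#' fractions are implied: \code{v_om = rho_m * sqrt(v_o * v_m)} and
#' \code{v_of = rho_f * sqrt(v_o * v_f)}. The factor-of-one scaling follows
#' from parent-child genotypic correlation 0.5 entering twice
#' (2 x 0.5 = 1); see [expected_components()].
#'
#' @param n_families Number of independent families (one child, two parents).
#' @param n_snps Total number of biallelic SNPs.
#' @param n_causal Number of causal SNPs (drawn uniformly without
#'   replacement from the panel).
#' @param maf_low,maf_high Allele-frequency bounds, in (0, 0.5].
#' @param v_o True direct-effect variance fraction in [0, 1].
#' @param v_m,v_f True maternal / paternal nurture variance fractions.
#' @param rho_m,rho_f Correlation in [-1, 1] between the direct effect
#'   vector and the maternal / paternal nurture effect vector.
#' @param beta_sex Additive effect of sex (coded 0/1) on the phenotype.
#' @param beta_batch Numeric vector of per-batch offsets, length
#'   \code{n_batches} (recycled if length 1).
#' @param n_batches Number of genotyping batches.
#' @param spousal_cor Optional spousal phenotype-score correlation knob for
#'   assortative-mating experiments; 0 (the default) draws spouses
#'   independently.
#' @param seed Integer RNG seed; all simulation operations are
#'   deterministic given the config.
#'
#' @return An object of class \code{sim_config}.
#' @seealso [simulate_trio_genotypes()], [simulate_phenotypes()],
#'   [expected_components()]
#' @export
sim_config <- function(n_families = 1000L, n_snps = 1000L,
                       n_causal = n_snps,
                       maf_low = 0.05, maf_high = 0.5,
                       v_o = 0.3, v_m = 0, v_f = 0,
                       rho_m = 0, rho_f = 0,
                       beta_sex = 0, beta_batch = 0, n_batches = 1L,
                       spousal_cor = 0, seed = 1L) {
  n_families <- as.integer(n_families)
  n_snps <- as.integer(n_snps)
  n_causal <- as.integer(n_causal)
  n_batches <- as.integer(n_batches)
  stopifnot(n_families >= 1L, n_snps >= 1L, n_causal >= 1L, n_batches >= 1L)
  if (n_causal > n_snps)
    stop("n_causal (", n_causal, ") exceeds n_snps (", n_snps, ")")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("require 0 < maf_low <= maf_high <= 0.5")
  for (v in c(v_o = v_o, v_m = v_m, v_f = v_f))
    if (v < 0 || v > 1) stop("variance fractions must lie in [0, 1]")
  if (abs(rho_m) > 1 || abs(rho_f) > 1)
    stop("rho_m and rho_f must lie in [-1, 1]")
  if (abs(spousal_cor) > 1) stop("spousal_cor must lie in [-1, 1]")
  beta_batch <- rep_len(as.numeric(beta_batch), n_batches)

  cfg <- structure(
    list(n_families = n_families, n_snps = n_snps, n_causal = n_causal,
         maf_low = maf_low, maf_high = maf_high,
         v_o = v_o, v_m = v_m, v_f = v_f, rho_m = rho_m, rho_f = rho_f,
         beta_sex = as.numeric(beta_sex), beta_batch = beta_batch,
         n_batches = n_batches, spousal_cor = as.numeric(spousal_cor),
         seed = as.integer(seed)),
    class = "sim_config")

  truth <- expected_components(cfg, .validate = FALSE)
  if (truth$v_e < -1e-12)
    stop("invalid config: variance fractions plus implied covariances ",
         "exceed 1 (implied residual fraction v_e = ",
         signif(truth$v_e, 4), ")")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d families, %d SNPs (%d causal), MAF in [%g, %g]\n",
              x$n_families, x$n_snps, x$n_causal, x$maf_low, x$maf_high))
  tr <- expected_components(x)
  cat(sprintf("  v_o=%.3f v_m=%.3f v_f=%.3f v_om=%.3f v_of=%.3f v_e=%.3f\n",
              tr$v_o, tr$v_m, tr$v_f, tr$v_om, tr$v_of, tr$v_e))
  cat(sprintf("  beta_sex=%g, %d batch(es), seed=%d\n",
              x$beta_sex, x$n_batches, x$seed))
  invisible(x)
}

#' Population variance components implied by a simulation config
#'
#' Closed-form ground truth for the variance-component estimands. Direct and
#' nurture genetic scores are built on standardized genotypes, and a child's
#' standardized genotype correlates 0.5 with each parent's, so each
#' direct-nurture covariance contributes
#' \code{2 * 0.5 * rho * sqrt(v_o * v_parent)} to the phenotypic variance:
#' \deqn{v_{om} = \rho_m \sqrt{v_o v_m}, \qquad v_{of} = \rho_f \sqrt{v_o v_f},}
#' and \code{v_e} is the remainder so all fractions sum to 1.
#'
#' @param config A [sim_config()].
#' @param .validate Internal; skip re-validation during construction.
#' @return An object of class \code{vc_truth}: list with fields
#'   \code{v_o}, \code{v_m}, \code{v_f}, \code{v_om}, \code{v_of}, \code{v_e}.
#' @export
expected_components <- function(config, .validate = TRUE) {
  if (.validate) stopifnot(inherits(config, "sim_config"))
  v_om <- config$rho_m * sqrt(config$v_o * config$v_m)
  v_of <- config$rho_f * sqrt(config$v_o * config$v_f)
  v_e <- 1 - (config$v_o + config$v_m + config$v_f + v_om + v_of)
  structure(list(v_o = config$v_o, v_m = config$v_m, v_f = config$v_f,
                 v_om = v_om, v_of = v_of, v_e = v_e),
            class = "vc_truth")
}

# Derive a deterministic sub-seed for an internal RNG stream, kept inside
# 32-bit integer range.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647)
}
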