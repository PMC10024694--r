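# Shared study configuration for the analysis drivers.
#
# The cohort emulates a family-genotype study at desk scale: 1200 nuclear
# families, a 20,000-SNP panel (large enough that GRM estimator noise,
# ~1/sqrt(M) = 0.007, sits well below the 0.025 relatedness cutoff), and a
# moderate direct-effect / maternal-nurture architecture with correlated
# effect vectors.

library(triogreml)

study_sim_config <- function(seed = 2026) {
  sim_config(
    n_families = 1200,
    n_snps     = 20000,
    n_causal   = 2000,
    maf_low    = 0.05, maf_high = 0.5,
    v_o = 0.30,          # direct genetic effects
    v_m = 0.15,          # maternal genetic nurture
    v_f = 0.00,
    rho_m = 0.5,         # direct/nurture effect-vector correlation
    beta_sex = 0.2,
    beta_batch = c(0, 0.25, -0.1), n_batches = 3,
    seed = seed)
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
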