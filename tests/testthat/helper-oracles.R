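# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: scalar loops, explicit determinants and
# inverses, and closed-form enumeration.

# Brute-force GCTA relatedness for one pair of individuals: scalar loop
# over SNPs, pairwise-complete.
oracle_pair_relatedness <- function(x_j, x_k, p) {
  acc <- 0; m <- 0
  for (i in seq_along(p)) {
    if (is.na(x_j[i]) || is.na(x_k[i])) next
    acc <- acc + (x_j[i] - 2 * p[i]) * (x_k[i] - 2 * p[i]) /
      (2 * p[i] * (1 - p[i]))
    m <- m + 1
  }
  acc / m
}

# Full-enumeration exact HWE p-value via log-gamma factorials.
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  n_a <- 2 * n_aa + n_Aa
  n_rare <- min(n_A, n_a)
  if (n_rare == 0) return(1)
  hs <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(hs, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(n_A + 1) + lgamma(n_a + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

# Dense REML log-likelihood via explicit determinant and inverse
# (no Cholesky solves), for the oracle-equivalence checks.
oracle_restricted_loglik <- function(y, structures, theta) {
  n <- length(y)
  V <- Reduce(`+`, Map(`*`, structures, theta))
  dV <- det(V)
  if (!is.finite(dV) || dV <= 0) return(-Inf)
  Vi <- solve(V)
  X <- matrix(1, n, 1)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(-Inf)
  -0.5 * (sum(log(ev)) + log(det(XtViX)) + drop(t(y) %*% P %*% y))
}

# Constrained brute-force REML optimum: coarse grid seeding plus
# Nelder-Mead refinement on a softplus-free parameterization (nonnegative
# components optimized on the log scale).
oracle_reml_optimum <- function(y, structures, nonneg, n_grid = 5) {
  k <- length(structures)
  vp <- var(y)
  obj <- function(th) {
    ll <- oracle_restricted_loglik(y, structures, th)
    if (!is.finite(ll)) 1e10 else -ll
  }
  grid_axis <- lapply(seq_len(k), function(j) {
    if (nonneg[j]) seq(0.05, 1.2, length.out = n_grid) * vp
    else seq(-0.5, 0.5, length.out = n_grid) * vp
  })
  grid <- as.matrix(expand.grid(grid_axis))
  vals <- apply(grid, 1, obj)
  best <- grid[which.min(vals), ]
  lower <- ifelse(nonneg, 0, -Inf)
  fit <- optim(best, obj, method = "L-BFGS-B",
               lower = lower + ifelse(nonneg, 1e-9, 0),
               control = list(maxit = 2000, factr = 1e4))
  fit2 <- optim(fit$par, obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
  res <- if (fit2$value < fit$value) fit2 else fit
  res$par <- pmax(res$par, lower)
  res
}

# Small trio cohort + maternal-pair GRM set, shared by several tests.
make_pair_data <- function(n = 400, m = 400, v_o = 0.3, v_m = 0.15,
                           rho_m = 0.5, v_f = 0, rho_f = 0, seed = 42,
                           maf_low = 0.05) {
  cfg <- sim_config(n_families = n, n_snps = m, n_causal = m,
                    maf_low = maf_low, v_o = v_o, v_m = v_m, v_f = v_f,
                    rho_m = rho_m, rho_f = rho_f, seed = seed)
  cohort <- simulate_trio_genotypes(cfg)
  pheno <- simulate_phenotypes(cohort, cfg)
  pooled <- (colSums(cohort$child_genotypes) +
               colSums(cohort$mother_genotypes)) / (4 * n)
  set <- grm_set(
    compute_grm(cohort$child_genotypes, freqs = pooled),
    compute_grm(cohort$mother_genotypes, freqs = pooled),
    compute_cross_grm(cohort$child_genotypes, cohort$mother_genotypes,
                      freqs = pooled),
    family_ids = cohort$family_ids)
  list(cfg = cfg, cohort = cohort, pheno = pheno, set = set,
       y = as.numeric(scale(pheno$score)))
}
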