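test_that("restricted log-likelihood matches closed forms and the dense oracle", {
  set.seed(14)
  n <- 40
  y <- as.numeric(scale(rnorm(n)))
  spec_i <- model_spec(list(V_e = diag(n)))

  # spherical closed form: -0.5 (log|I| + log(n) + y'y - n ybar^2)
  closed <- -0.5 * (log(n) + sum(y^2) - n * mean(y)^2)
  expect_equal(restricted_loglik(y, spec_i, 1), closed, tolerance = 1e-10)

  # theta grid on an n = 6 toy model vs explicit determinant/inverse oracle
  set.seed(15)
  n6 <- 6
  G <- crossprod(matrix(rnorm(n6 * 20), 20)) / 20
  y6 <- rnorm(n6)
  spec6 <- model_spec(list(V_g = G, V_e = diag(n6)))
  for (a in c(0.2, 0.5, 1.0)) for (b in c(0.3, 0.8, 1.5)) {
    expect_equal(restricted_loglik(y6, spec6, c(a, b)),
                 oracle_restricted_loglik(y6, spec6$structures, c(a, b)),
                 tolerance = 1e-8)
  }

  # invariance to an intercept shift (fixed effect projected out)
  expect_equal(restricted_loglik(y6 + 5, spec6, c(0.5, 0.8)),
               restricted_loglik(y6, spec6, c(0.5, 0.8)), tolerance = 1e-9)

  # non-PD V is a distinct error condition
  expect_error(restricted_loglik(y6, spec6, c(1, -2)),
               class = "triogreml_nonpd")

  # cross structures must be symmetrized before entering a spec
  A_cp <- matrix(rnorm(36), 6, 6)
  expect_error(model_spec(list(V_x = A_cp)), "symmetric")
})

test_that("AI-REML optimum matches brute-force dense maximization on small fixtures", {
  # 2-parameter offspring model, n = 40
  d40 <- make_pair_data(n = 40, m = 120, v_o = 0.5, v_m = 0, rho_m = 0,
                        seed = 51)
  spec2 <- list(V_o = d40$set$child$A, V_e = diag(40))
  fit2 <- reml_fit(d40$y, model_spec(spec2), tol = 1e-10)
  or2 <- oracle_reml_optimum(d40$y, c(spec2[1], list(V_e = diag(40))),
                             nonneg = c(TRUE, TRUE))
  expect_lt(max(abs(fit2$estimates - or2$par)), 1e-4)
  expect_equal(restricted_loglik(d40$y, model_spec(spec2), fit2$estimates),
               -or2$value, tolerance = 1e-7)

  # 4-parameter maternal model, n = 50
  d50 <- make_pair_data(n = 50, m = 150, v_o = 0.4, v_m = 0.3, rho_m = 0.5,
                        seed = 52)
  structures <- list(V_o = d50$set$child$A, V_parent = d50$set$parent$A,
                     V_cross = d50$set$cross$A + t(d50$set$cross$A),
                     V_e = diag(50))
  nonneg <- c(TRUE, TRUE, FALSE, TRUE)
  fit4 <- reml_fit(d50$y, model_spec(structures, nonneg = nonneg),
                   tol = 1e-10)
  or4 <- oracle_reml_optimum(d50$y, structures, nonneg = nonneg, n_grid = 4)
  expect_lt(max(abs(fit4$estimates - or4$par)), 1e-4)
})

test_that("likelihood-ratio test follows the chi-square closed forms", {
  f <- list(logL = -100); r <- list(logL = -100)
  t0 <- lrt(f, r, df = 2)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)

  # logL difference 3, df 2: statistic 6, p = exp(-3)
  t1 <- lrt(list(logL = -97), r, df = 2)
  expect_equal(t1$statistic, 6)
  expect_equal(t1$p, exp(-3), tolerance = 1e-12)

  # chi-square(1) survival cross-check
  t2 <- lrt(list(logL = -98), r, df = 1)
  expect_equal(t2$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)

  # an optimizer fault (full below reduced) is an error
  expect_error(lrt(list(logL = -101), r, df = 2), "optimizer")
})

test_that("LRT statistic is invariant to phenotype rescaling", {
  d <- make_pair_data(n = 250, m = 250, v_o = 0.4, v_m = 0.2, rho_m = 0.4,
                      seed = 53)
  y1 <- d$pheno$score
  y2 <- 2.7 * y1
  stat_of <- function(y) {
    full <- reml_fit(y, model_spec(
      list(V_o = d$set$child$A, V_parent = d$set$parent$A,
           V_cross = d$set$cross$A + t(d$set$cross$A)),
      nonneg = c(TRUE, TRUE, FALSE, TRUE)))
    red <- reml_fit(y, model_spec(list(V_o = d$set$child$A)))
    lrt(full, red, df = 2)$statistic
  }
  expect_equal(stat_of(y1), stat_of(y2), tolerance = 1e-4)
})

test_that("combined G is exactly the component sum with a delta-method SE", {
  d <- make_pair_data(n = 300, m = 300, v_o = 0.35, v_m = 0.2, rho_m = 0.5,
                      seed = 54)
  res <- fit_parent_model(d$y, d$set, "maternal")
  # identity: G = V_o + V_parent + V_cross, exactly
  expect_identical(res$g, sum(res$components))
  # delta method from the parameter covariance
  ci <- 1:3
  expect_equal(res$g_se, sqrt(sum(res$fit$cov[ci, ci])), tolerance = 1e-12)

  expect_equal(combined_g(0, 0, 0, cov = matrix(0, 3, 3)),
               list(g = 0, g_se = 0))
  expect_true(is.na(combined_g(0.1, 0.2, 0.05)$g_se))
})

test_that("null nurture architectures drive the parent component to the boundary", {
  hits <- 0L
  n_rep <- 20L
  for (s in seq_len(n_rep)) {
    d <- make_pair_data(n = 250, m = 250, v_o = 0.3, v_m = 0, rho_m = 0,
                        seed = 300 + s)
    fit <- fit_parent_model(d$y, d$set, "maternal")
    if (fit$fit$boundary["V_parent"] || fit$components["v_parent"] < 0.01)
      hits <- hits + 1L
  }
  # a true-zero nonneg component pins to the 0 boundary about half the
  # time (the unconstrained estimate is centred at 0), mirroring the
  # exact-0.000 entries typical of published variance-component tables
  expect_gte(hits, 5L)
  expect_lte(hits, 15L)
})

test_that("maternal and paternal wrappers agree under a symmetric architecture", {
  diffs <- matrix(NA_real_, 5, 2)
  for (s in 1:5) {
    cfg <- sim_config(n_families = 400, n_snps = 300, v_o = 0.3,
                      v_m = 0.15, v_f = 0.15, rho_m = 0.4, rho_f = 0.4,
                      seed = 600 + s)
    co <- simulate_trio_genotypes(cfg)
    ph <- simulate_phenotypes(co, cfg)
    y <- as.numeric(scale(ph$score))
    mk_set <- function(g_par) {
      pooled <- (colSums(co$child_genotypes) + colSums(g_par)) / (4 * 400)
      grm_set(compute_grm(co$child_genotypes, freqs = pooled),
              compute_grm(g_par, freqs = pooled),
              compute_cross_grm(co$child_genotypes, g_par, freqs = pooled),
              family_ids = co$family_ids)
    }
    fm <- fit_parent_model(y, mk_set(co$mother_genotypes), "maternal")
    ff <- fit_parent_model(y, mk_set(co$father_genotypes), "paternal")
    diffs[s, ] <- c(fm$components["v_parent"] - ff$components["v_parent"],
                    fm$components["v_o"] - ff$components["v_o"])
    # each side recovers the shared truth within 3 reported SEs
    expect_lt(abs(fm$components["v_parent"] - 0.15), 3 * fm$se["v_parent"])
    expect_lt(abs(ff$components["v_parent"] - 0.15), 3 * ff$se["v_parent"])
  }
  # no systematic maternal/paternal asymmetry across seeds
  expect_lt(abs(mean(diffs[, 1])), 3 * sd(diffs[, 1]) / sqrt(5) + 0.02)
})

test_that("offspring model nests consistently in the extended model", {
  # true nurture absent: the extended model's v_o matches the offspring-only v
  d <- make_pair_data(n = 600, m = 500, v_o = 0.4, v_m = 0, rho_m = 0,
                      seed = 77)
  off <- fit_offspring_model(d$y, d$set)
  ext <- fit_parent_model(d$y, d$set, "maternal")
  expect_lt(abs(off$components["v_o"] - ext$components["v_o"]),
            3 * ext$se["v_o"])
  # bookkeeping: N equals the analyzed sample size
  expect_equal(off$n, 600)
  expect_equal(ext$n, 600)
  # the results table mirrors one row per model
  tab <- vc_result_table(list(off, ext), phenotype = "sim")
  expect_equal(nrow(tab), 2)
  expect_true(is.na(tab$v_parent[1]))
  expect_equal(tab$g[2], sum(ext$components))
})
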