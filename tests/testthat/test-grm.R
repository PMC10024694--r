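test_that("GRM estimator matches hand arithmetic and the per-SNP oracle", {
  # single SNP, p = 0.5, x = 2: A_jj = (2 - 1)^2 / (2 * 0.5 * 0.5) = 2
  g <- matrix(c(2, 0), 2, 1)
  A <- compute_grm(g, freqs = 0.5)$A
  expect_equal(A[1, 1], 2)
  expect_equal(A[2, 2], 2)
  expect_equal(A[1, 2], -2)

  # identical genotype vectors: off-diagonal equals the diagonal
  set.seed(4)
  g2 <- matrix(rbinom(30, 2, 0.3), 3, 10, byrow = TRUE)
  g2[2, ] <- g2[1, ]
  A2 <- compute_grm(g2, freqs = rep(0.3, 10))$A
  expect_equal(A2[1, 2], A2[1, 1])

  # random panel vs the scalar per-SNP covariance oracle, incl. missingness
  set.seed(5)
  p <- runif(25, 0.1, 0.45)
  g3 <- matrix(rbinom(8 * 25, 2, rep(p, each = 8)), 8, 25)
  g3[sample(length(g3), 15)] <- NA
  grm3 <- compute_grm(g3, freqs = p)
  for (j in 1:8) for (k in j:8)
    expect_equal(grm3$A[j, k],
                 oracle_pair_relatedness(g3[j, ], g3[k, ], p),
                 tolerance = 1e-12)

  expect_error(compute_grm(cbind(g3, 0), freqs = c(p, 0)), "monomorphic")
})

test_that("GRM sampling behaviour: unit diagonal, null off-diagonal, SNP-order invariance", {
  cfg <- sim_config(n_families = 500, n_snps = 5000, seed = 17)
  co <- simulate_trio_genotypes(cfg)
  grm <- compute_grm(co$child_genotypes)
  d <- diag(grm$A)
  off <- grm$A[upper.tri(grm$A)]
  expect_gt(mean(d), 0.98)
  expect_lt(mean(d), 1.02)
  expect_gt(mean(off), -0.005)
  expect_lt(mean(off), 0.005)
  expect_lt(sd(off), 3 / sqrt(5000))   # O(1/sqrt(M)) noise scale

  # invariant to SNP order
  perm <- sample(5000)
  grm_p <- compute_grm(co$child_genotypes[, perm],
                       freqs = colMeans(co$child_genotypes[, perm]) / 2)
  expect_equal(grm_p$A, grm$A, tolerance = 1e-10)
})

test_that("cross-GRM concentrates near 0.5 for true pairs and 0 otherwise", {
  n <- 2000; m <- 2000
  cfg <- sim_config(n_families = n, n_snps = m, seed = 23)
  co <- simulate_trio_genotypes(cfg)
  pooled <- (colSums(co$child_genotypes) + colSums(co$mother_genotypes)) /
    (4 * n)
  cx <- compute_cross_grm(co$child_genotypes, co$mother_genotypes,
                          freqs = pooled)
  # Mendelian expectation: mean own-pair relatedness 0.5
  expect_lt(abs(mean(diag(cx$A)) - 0.5), 3 / sqrt(m * n))
  # unrelated child x parent entries distributed around 0 (the pooled
  # frequency reference leaves a small O(1/n) negative centering offset)
  off <- cx$A[upper.tri(cx$A)]
  expect_lt(abs(mean(off)), 0.002)
  expect_lt(sd(off), 3 / sqrt(m))

  # estimator symmetry: an individual placed on both sides of the cross
  # matrix gets its within-GRM self-relatedness
  dup <- compute_cross_grm(co$mother_genotypes[1:5, ],
                           co$mother_genotypes[1:5, ], freqs = pooled)
  self <- compute_grm(co$mother_genotypes[1:5, ], freqs = pooled)
  expect_equal(diag(dup$A), diag(self$A), tolerance = 1e-12)

  # SNP panel mismatch is rejected naming the offender
  g_bad <- co$mother_genotypes
  colnames(g_bad)[1] <- "rogue_snp"
  expect_error(compute_cross_grm(co$child_genotypes, g_bad, freqs = pooled),
               "mismatch.*rogue|snp")
})

test_that("the joint child-parent relatedness matrix is PSD up to estimator noise", {
  n <- 300; m <- 5000
  cfg <- sim_config(n_families = n, n_snps = m, seed = 29)
  co <- simulate_trio_genotypes(cfg)
  pooled <- (colSums(co$child_genotypes) + colSums(co$mother_genotypes)) /
    (4 * n)
  A_c <- compute_grm(co$child_genotypes, freqs = pooled)$A
  A_p <- compute_grm(co$mother_genotypes, freqs = pooled)$A
  A_cp <- compute_cross_grm(co$child_genotypes, co$mother_genotypes,
                            freqs = pooled)$A
  joint <- rbind(cbind(A_c, A_cp), cbind(t(A_cp), A_p))
  ev <- eigen(joint, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -0.05)
})

test_that("greedy relatedness pruning removes the planted relatives and only them", {
  # three families, children 1-2 related at 0.5: exactly one of {1,2} leaves
  A_c <- diag(3)
  A_c[1, 2] <- A_c[2, 1] <- 0.5
  ids <- data.frame(fid = paste0("f", 1:3), iid = paste0("c", 1:3))
  gs <- grm_set(structure(list(ids = ids, A = A_c, N = matrix(100, 3, 3),
                               n_snps = 100), class = "grm"),
                family_ids = ids$fid)
  pr <- prune_relatedness(gs, cutoff = 0.025)
  expect_equal(length(pr$retained), 2)
  expect_true("f3" %in% pr$retained)
  expect_equal(pr$removed, "f2")    # tie broken toward the larger index

  # all below cutoff: nothing removed
  gs0 <- gs
  gs0$child$A <- diag(3) + 0.01
  expect_equal(length(prune_relatedness(gs0, 0.025)$retained), 3)
  expect_error(prune_relatedness(gs, cutoff = 0), "positive")

  # planted 4-sibling cluster among 100 families: 3 leave, 97 stay
  set.seed(8)
  n <- 100
  A <- diag(n) + matrix(rnorm(n * n, 0, 0.004), n, n)
  A <- (A + t(A)) / 2
  sib <- 11:14
  for (a in sib) for (b in sib) if (a != b) A[a, b] <- 0.5
  ids_n <- data.frame(fid = sprintf("f%03d", 1:n), iid = sprintf("c%03d", 1:n))
  gs_n <- grm_set(structure(list(ids = ids_n, A = A, N = matrix(1, n, n),
                                 n_snps = 1000), class = "grm"),
                  family_ids = ids_n$fid)
  pr_n <- prune_relatedness(gs_n, cutoff = 0.025)
  expect_equal(length(pr_n$retained), 97)
  expect_equal(sum(sprintf("f%03d", sib) %in% pr_n$removed), 3)

  # exhaustive post-prune scan: zero violations, exactly
  kept <- pr_n$retained_idx
  A_kept <- A[kept, kept]
  expect_identical(sum(A_kept[upper.tri(A_kept)] > 0.025), 0L)
})

test_that("cross-generation violations prune at the family level, own pairs exempt", {
  n <- 6
  A_c <- diag(n); A_p <- diag(n)
  A_cp <- matrix(0, n, n)
  diag(A_cp) <- 0.5                 # own child-parent pairs: exempt
  A_cp[2, 5] <- 0.3                 # child 2 related to parent of family 5
  ids <- data.frame(fid = paste0("f", 1:n), iid = paste0("x", 1:n))
  mk <- function(A) structure(list(ids = ids, A = A, N = matrix(1, n, n),
                                   n_snps = 10), class = "grm")
  cross <- structure(list(child_ids = ids, parent_ids = ids, A = A_cp,
                          N = matrix(1, n, n), n_snps = 10),
                     class = "cross_grm")
  gs <- grm_set(mk(A_c), mk(A_p), cross, family_ids = ids$fid)
  pr <- prune_relatedness(gs, 0.025)
  expect_equal(length(pr$retained), 5)
  expect_true(pr$removed %in% c("f2", "f5"))
  expect_equal(pr$removed, "f5")    # degree tie -> larger family index
})

test_that("GCTA GRM triplets and PLINK filesets round-trip", {
  tmp <- tempfile("grmio")
  # toy 3x3: six float32 values on disk
  set.seed(2)
  g <- matrix(rbinom(3 * 50, 2, 0.4), 3, 50,
              dimnames = list(paste0("i", 1:3), NULL))
  grm <- compute_grm(g, freqs = rep(0.4, 50))
  write_gcta_grm(grm, tmp)
  expect_equal(file.info(paste0(tmp, ".grm.bin"))$size, 6 * 4)
  back <- read_gcta_grm(tmp)
  expect_equal(back$A, grm$A, tolerance = 1e-6)
  expect_equal(back$ids$iid, grm$ids$iid)

  # wrong id count vs payload length errors out
  writeLines(c("i1 i1", "i2 i2"), paste0(tmp, ".grm.id"))
  expect_error(read_gcta_grm(tmp), "inconsistent")

  # 500 x 500 round-trip within float32 resolution
  n <- 500
  A <- crossprod(matrix(rnorm(n * n, sd = 0.2), n)) / n
  big <- structure(list(ids = data.frame(fid = paste0("f", 1:n),
                                         iid = paste0("i", 1:n)),
                        A = A, N = matrix(1000, n, n), n_snps = 1000L),
                   class = "grm")
  tmp2 <- tempfile("grmio2")
  write_gcta_grm(big, tmp2)
  back2 <- read_gcta_grm(tmp2)
  expect_lt(max(abs(back2$A - A)), 1e-6 * max(1, max(abs(A))))

  # PLINK bed/bim/fam round-trip with missing genotypes, n not divisible by 4
  set.seed(6)
  gp <- matrix(rbinom(11 * 7, 2, 0.5), 11, 7,
               dimnames = list(paste0("s", 1:11), paste0("snp", 1:7)))
  gp[sample(length(gp), 9)] <- NA
  tmp3 <- tempfile("plinkio")
  write_plink(gp, tmp3)
  back3 <- read_plink(tmp3)
  expect_identical(unname(back3$genotypes), unname(gp))
  expect_equal(back3$fam$iid, rownames(gp))
  expect_equal(back3$bim$id, colnames(gp))
})

test_that("a simulated cohort writes a complete fileset bundle", {
  cfg <- sim_config(n_families = 25, n_snps = 40, v_o = 0.3, seed = 13)
  co <- simulate_trio_genotypes(cfg)
  ph <- simulate_phenotypes(co, cfg)
  pre <- file.path(tempfile("cohort"), "sim")
  dir.create(dirname(pre))
  write_trio_cohort(co, pre, pheno = ph)
  for (suffix in c("_child.bed", "_child.bim", "_child.fam", "_mother.bed",
                   "_father.bed", ".pheno", ".covar", "_truth.json"))
    expect_true(file.exists(paste0(pre, suffix)))
  child <- read_plink(paste0(pre, "_child"))
  expect_identical(unname(child$genotypes), unname(co$child_genotypes))
  # family linkage: child FAM points at the parent IIDs
  expect_equal(child$fam$mat, paste0(co$family_ids, "_m"))
  truth <- jsonlite::read_json(paste0(pre, "_truth.json"))
  expect_equal(truth$truth$v_om,
               expected_components(cfg)$v_om, tolerance = 1e-12)
})
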