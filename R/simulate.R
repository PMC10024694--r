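#' Simulate genotypes for a cohort of unrelated trios
#'
#' Draws parental genotypes per SNP as Binomial(2, p_j) under Hardy-Weinberg
#' equilibrium, with p_j ~ Uniform(maf_low, maf_high), and each child
#' genotype by fair Mendelian transmission of one allele from each parent.
#' Families are mutually unrelated; the result is deterministic given
#' \code{config$seed}.
#'
#' @param config A [sim_config()].
#' @return An object of class \code{trio_cohort}: list with
#'   \describe{
#'     \item{family_ids}{character vector, one per family.}
#'     \item{child_genotypes, mother_genotypes, father_genotypes}{n x M
#'       integer matrices of additive-coded (0/1/2) genotypes; rows are
#'       families, columns SNPs.}
#'     \item{child_sex}{0/1 vector (0 = male, 1 = female).}
#'     \item{batch}{integer genotyping batch in 1..n_batches.}
#'     \item{snp_metadata}{data.frame: id, chromosome, position, a1, a2,
#'       frequency (the true generating frequency of a1).}
#'   }
#' @export
simulate_trio_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_families
  m <- config$n_snps
  set.seed(sub_seed(config$seed, 1L))

  p <- stats::runif(m, config$maf_low, config$maf_high)
  # parents: independent HWE draws, SNP-major fill so genotype matrices are
  # n x m with columns indexed like snp_metadata
  mother <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  father <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  # fair Mendelian transmission: one allele from each parent, transmitted
  # with probability genotype/2
  child <- matrix(stats::rbinom(n * m, 1L, mother / 2) +
                  stats::rbinom(n * m, 1L, father / 2), nrow = n)
  storage.mode(mother) <- "integer"
  storage.mode(father) <- "integer"
  storage.mode(child) <- "integer"

  ids <- sprintf("fam%05d", seq_len(n))
  snp_id <- sprintf("snp%06d", seq_len(m))
  dimnames(mother) <- dimnames(father) <- dimnames(child) <-
    list(ids, snp_id)

  structure(
    list(family_ids = ids,
         child_genotypes = child,
         mother_genotypes = mother,
         father_genotypes = father,
         child_sex = stats::rbinom(n, 1L, 0.5),
         batch = sample.int(config$n_batches, n, replace = TRUE),
         snp_metadata = data.frame(
           id = snp_id, chromosome = 1L, position = seq_len(m) * 1000L,
           a1 = "A", a2 = "B", frequency = p,
           stringsAsFactors = FALSE),
         config = config),
    class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("<trio_cohort> %d families x %d SNPs (%d batches)\n",
              length(x$family_ids), nrow(x$snp_metadata),
              length(unique(x$batch))))
  invisible(x)
}

# Standardize an additive genotype matrix by given allele frequencies:
# z = (x - 2p) / sqrt(2 p (1 - p)). Frequencies refer to the counted allele.
standardize_genotypes <- function(geno, freqs) {
  stopifnot(ncol(geno) == length(freqs))
  if (any(freqs <= 0 | freqs >= 1))
    stop("allele frequencies must lie strictly in (0, 1)")
  sweep(sweep(geno, 2L, 2 * freqs, "-"), 2L,
        sqrt(2 * freqs * (1 - freqs)), "/")
}

# Unit vector orthogonal to u, built from a raw Gaussian draw.
orthonormal_against <- function(raw, u) {
  w <- raw - sum(raw * u) * u
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("degenerate orthogonal draw; increase n_causal")
  w / nw
}

#' Simulate child phenotypes with direct and parental nurture effects
#'
#' Builds the child phenotype
#' \deqn{y = g_o + g_m + g_f + \beta_{sex} \cdot sex + batch + e,}
#' where \code{g_o} is the child's causal-SNP score on standardized
#' genotypes, \code{g_m} and \code{g_f} are the mother's and father's
#' nurture scores, and the per-SNP nurture effect vector correlates
#' \code{rho} with the direct vector. Effect vectors are scaled exactly so
#' the population variance fractions equal the config targets (see
#' [expected_components()]); \code{e} is Gaussian with the residual
#' fraction. Deterministic given \code{config$seed}.
#'
#' @param cohort A [simulate_trio_genotypes()] result.
#' @param config The matching [sim_config()].
#' @return A data.frame of class \code{pheno_table} with columns
#'   \code{fid}, \code{iid}, \code{score} (the simulated phenotype),
#'   \code{sex}, \code{batch}, and the latent truth columns \code{g_o},
#'   \code{g_m}, \code{g_f}. The causal SNP indices and effect vectors are
#'   attached as attributes \code{causal} and \code{effects}.
#' @export
simulate_phenotypes <- function(cohort, config) {
  stopifnot(inherits(cohort, "trio_cohort"), inherits(config, "sim_config"))
  n <- length(cohort$family_ids)
  if (n != config$n_families || nrow(cohort$snp_metadata) != config$n_snps)
    stop("cohort and config dimensions disagree")
  truth <- expected_components(config)
  if (truth$v_e < -1e-12) stop("implied residual variance is negative")
  set.seed(sub_seed(config$seed, 2L))

  causal <- sort(sample.int(config$n_snps, config$n_causal))
  k <- length(causal)
  if (k < 2 && ((config$v_m > 0 && abs(config$rho_m) < 1) ||
                (config$v_f > 0 && abs(config$rho_f) < 1)))
    stop("n_causal must be >= 2 for an effect correlation strictly inside (-1, 1)")

  # direct effects: Gaussian per standardized genotype, scaled to exact v_o
  u_o <- stats::rnorm(k)
  u_o <- u_o / sqrt(sum(u_o^2))
  w_o <- sqrt(config$v_o) * u_o

  nurture_effects <- function(v, rho) {
    if (v == 0) return(numeric(k))
    if (abs(rho) == 1) return(rho * sqrt(v) * u_o)
    u_perp <- orthonormal_against(stats::rnorm(k), u_o)
    sqrt(v) * (rho * u_o + sqrt(1 - rho^2) * u_perp)
  }
  w_m <- nurture_effects(config$v_m, config$rho_m)
  w_f <- nurture_effects(config$v_f, config$rho_f)

  p <- cohort$snp_metadata$frequency[causal]
  z_c <- standardize_genotypes(cohort$child_genotypes[, causal, drop = FALSE], p)
  z_m <- standardize_genotypes(cohort$mother_genotypes[, causal, drop = FALSE], p)
  z_f <- standardize_genotypes(cohort$father_genotypes[, causal, drop = FALSE], p)

  g_o <- drop(z_c %*% w_o)
  g_m <- drop(z_m %*% w_m)
  g_f <- drop(z_f %*% w_f)
  e <- stats::rnorm(n, sd = sqrt(max(truth$v_e, 0)))
  y <- g_o + g_m + g_f + config$beta_sex * cohort$child_sex +
    config$beta_batch[cohort$batch] + e

  out <- data.frame(fid = cohort$family_ids, iid = child_iids(cohort),
                    score = y, sex = cohort$child_sex, batch = cohort$batch,
                    g_o = g_o, g_m = g_m, g_f = g_f,
                    stringsAsFactors = FALSE)
  attr(out, "causal") <- causal
  attr(out, "effects") <- list(w_o = w_o, w_m = w_m, w_f = w_f)
  attr(out, "truth") <- truth
  class(out) <- c("pheno_table", "data.frame")
  out
}

child_iids <- function(cohort) paste0(cohort$family_ids, "_c")
mother_iids <- function(cohort) paste0(cohort$family_ids, "_m")
father_iids <- function(cohort) paste0(cohort$family_ids, "_f")

#' Generate Likert questionnaire item responses from latent scores
#'
#' Each of the scale's items is produced by adding item-specific Gaussian
#' noise to the standardized latent score and thresholding into
#' \code{n_categories} ordered categories coded
#' \code{min_code .. min_code + n_categories - 1}. Default thresholds are
#' right-skewed (most mass in the lowest category), as is typical of
#' community-sample symptom questionnaires. Items are masked missing
#' independently at \code{missing_rate}.
#'
#' @param scores A \code{pheno_table} (uses column \code{score}).
#' @param scale_def A [scale_definition()].
#' @param missing_rate Probability in [0, 1] that an item is missing.
#' @param seed Integer seed; the output is deterministic given it.
#' @param item_noise_sd Standard deviation of per-item noise on the
#'   standardized latent scale (default 1).
#' @param cum_probs Optional cumulative category probabilities (length
#'   \code{n_categories - 1}, increasing, in (0,1)); defaults depend on the
#'   number of categories.
#' @return A data.frame of class \code{item_table}: \code{fid}, \code{iid},
#'   then one integer column per item (\code{<name>_i01}, ...), \code{NA}
#'   for missing.
#' @export
simulate_questionnaire <- function(scores, scale_def, missing_rate = 0,
                                   seed = 1L, item_noise_sd = 1,
                                   cum_probs = NULL) {
  stopifnot(inherits(scale_def, "scale_definition"))
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  n <- nrow(scores)
  k <- scale_def$n_items
  c_ <- scale_def$n_categories
  if (is.null(cum_probs)) {
    cum_probs <- if (c_ == 3) c(0.80, 0.95)
    else if (c_ == 4) c(0.70, 0.85, 0.95)
    else cumsum(rep(1 / c_, c_ - 1))
  }
  stopifnot(length(cum_probs) == c_ - 1, all(diff(cum_probs) > 0),
            all(cum_probs > 0 & cum_probs < 1))
  set.seed(as.integer(seed))

  z <- as.numeric(scale(scores$score))
  # thresholds on the latent + item-noise scale
  thr <- stats::qnorm(cum_probs, sd = sqrt(1 + item_noise_sd^2))
  items <- matrix(NA_integer_, n, k)
  for (j in seq_len(k)) {
    latent_j <- z + stats::rnorm(n, sd = item_noise_sd)
    items[, j] <- findInterval(latent_j, thr) + scale_def$min_code
  }
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n * k) < missing_rate, n, k)
    items[miss] <- NA_integer_
  }
  colnames(items) <- sprintf("%s_i%02d", scale_def$name, seq_len(k))
  out <- cbind(data.frame(fid = scores$fid, iid = scores$iid,
                          stringsAsFactors = FALSE),
               as.data.frame(items))
  class(out) <- c("item_table", "data.frame")
  out
}
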