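#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test for a biallelic SNP from genotype counts
#' (\code{n_AA}, \code{n_Aa}, \code{n_aa}). Conditional on the observed
#' allele counts, the heterozygote count under HWE follows the
#' hypergeometric-type distribution
#' \deqn{P(h) = \frac{n!\,n_A!\,n_a!\,2^h}{h!\,((n_A-h)/2)!\,((n_a-h)/2)!\,(2n)!},}
#' over heterozygote counts \code{h} with the parity of the minor-allele
#' count. The p-value sums the probabilities of all configurations no more
#' probable than the observed one. Probabilities are accumulated by the
#' stable two-sided recurrence rather than factorials.
#'
#' @param n_AA,n_Aa,n_aa Nonnegative integer genotype counts (vectorized).
#' @return p-value(s) in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (length(n_AA) > 1 || length(n_Aa) > 1 || length(n_aa) > 1) {
    k <- max(length(n_AA), length(n_Aa), length(n_aa))
    return(mapply(hwe_exact_test, rep_len(n_AA, k), rep_len(n_Aa, k),
                  rep_len(n_aa, k)))
  }
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be nonnegative integers")
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")

  n_rare <- 2 * min(n_AA, n_aa) + n_Aa     # minor allele count
  h_obs <- n_Aa
  if (n_rare == 0) return(1)               # monomorphic: single configuration

  hs <- seq(n_rare %% 2, n_rare, by = 2)   # attainable het counts (parity)
  probs <- numeric(length(hs))
  # start at the (near-)modal het count and apply the recurrences
  # P(h+2)/P(h) = 4 * hom_r(h+2 side) ... expressed going both directions
  h_mid <- round(n_rare * (2 * n - n_rare) / (2 * n))
  if (h_mid %% 2 != n_rare %% 2) h_mid <- h_mid + 1L
  i_mid <- match(h_mid, hs)
  probs[i_mid] <- 1
  hom_r <- function(h) (n_rare - h) / 2
  hom_c <- function(h) n - h - (n_rare - h) / 2
  if (i_mid < length(hs)) {
    for (i in (i_mid + 1):length(hs)) {
      h <- hs[i - 1]
      probs[i] <- probs[i - 1] * 4 * hom_r(h) * hom_c(h) / ((h + 2) * (h + 1))
    }
  }
  if (i_mid > 1) {
    for (i in (i_mid - 1):1) {
      h <- hs[i + 1]
      probs[i] <- probs[i + 1] * h * (h - 1) / (4 * (hom_r(h) + 1) * (hom_c(h) + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(h_obs, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' Per-SNP summary statistics for quality control
#'
#' @param genotypes n x M additive genotype matrix, NA for missing.
#' @param metadata Optional data.frame aligned with columns: \code{id},
#'   \code{chromosome}, \code{position}, \code{a1}, \code{a2}, and
#'   optionally logical \code{is_multiallelic}.
#' @param info Optional per-SNP mean imputation INFO scores (averaged
#'   across batches upstream); defaults to 1 (directly genotyped stub).
#' @return data.frame of class \code{snp_stats}: id, n_AA, n_Aa, n_aa,
#'   call_rate, maf, hwe_p, info, is_multiallelic, is_duplicated.
#'   \code{is_duplicated} marks second and later occurrences of an
#'   identical chromosome + position + allele set.
#' @export
snp_stats <- function(genotypes, metadata = NULL, info = NULL) {
  m <- ncol(genotypes)
  if (is.null(metadata))
    metadata <- data.frame(id = colnames(genotypes) %||%
                             sprintf("snp%06d", seq_len(m)),
                           chromosome = 1L, position = seq_len(m),
                           a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  stopifnot(nrow(metadata) == m)
  n_AA <- colSums(genotypes == 2L, na.rm = TRUE)
  n_Aa <- colSums(genotypes == 1L, na.rm = TRUE)
  n_aa <- colSums(genotypes == 0L, na.rm = TRUE)
  n_obs <- n_AA + n_Aa + n_aa
  call_rate <- n_obs / nrow(genotypes)
  freq <- ifelse(n_obs > 0, (2 * n_AA + n_Aa) / (2 * n_obs), NA_real_)
  maf <- pmin(freq, 1 - freq)
  hwe_p <- hwe_exact_test(n_AA, n_Aa, n_aa)
  alleles <- t(apply(cbind(metadata$a1, metadata$a2), 1, sort))
  key <- paste(metadata$chromosome, metadata$position,
               alleles[, 1], alleles[, 2])
  out <- data.frame(
    id = metadata$id, n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa,
    call_rate = call_rate, maf = maf, hwe_p = hwe_p,
    info = if (is.null(info)) rep(1, m) else rep_len(info, m),
    is_multiallelic = metadata$is_multiallelic %||% rep(FALSE, m),
    is_duplicated = duplicated(key),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("snp_stats", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Post-imputation SNP filtering
#'
#' Keeps a SNP iff it passes all of: HWE exact p >= \code{hwe_p}, call rate
#' >= \code{call_rate}, minor allele frequency strictly > \code{maf}, mean
#' INFO > \code{info}, biallelic, and not a duplicate. The QC report
#' attributes each removed SNP to its first failing criterion, evaluated
#' in that order.
#'
#' @param stats A [snp_stats()] table.
#' @param thresholds Named list overriding any of \code{hwe_p} (1e-6),
#'   \code{call_rate} (0.90), \code{maf} (0.05), \code{info} (0.9).
#' @return List with \code{keep} (logical mask), \code{kept_ids}, and
#'   \code{report} (data.frame criterion/removed, plus rows for SNPs
#'   tested and kept).
#' @export
filter_snps <- function(stats, thresholds = list()) {
  th <- utils::modifyList(
    list(hwe_p = 1e-6, call_rate = 0.90, maf = 0.05, info = 0.9),
    thresholds)
  if (th$hwe_p < 0 || th$hwe_p > 1 || th$call_rate < 0 || th$call_rate > 1 ||
      th$maf < 0 || th$maf >= 0.5 || th$info < 0)
    stop("thresholds outside valid ranges")
  fail <- cbind(
    hwe = stats$hwe_p < th$hwe_p,
    call_rate = stats$call_rate < th$call_rate,
    maf = !(stats$maf > th$maf),
    info = !(stats$info > th$info),
    multiallelic = stats$is_multiallelic,
    duplicated = stats$is_duplicated)
  keep <- rowSums(fail) == 0
  first_fail <- apply(fail, 1, function(f) which(f)[1])  # NA when kept
  removed <- vapply(colnames(fail),
                    function(cr) sum(first_fail == match(cr, colnames(fail)),
                                     na.rm = TRUE),
                    integer(1))
  report <- data.frame(criterion = colnames(fail), removed = removed,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(keep = keep, kept_ids = stats$id[keep],
       report = rbind(report,
                      data.frame(criterion = c("tested", "kept"),
                                 removed = c(nrow(stats), sum(keep)))))
}
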