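#' Genomic relatedness matrix (GCTA estimator)
#'
#' For individuals j, k over M SNPs with counted-allele frequencies p_i:
#' \deqn{A_{jk} = \frac{1}{M_{jk}} \sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}
#'   {2 p_i (1 - p_i)},}
#' where missing genotypes are skipped pairwise and \code{M_jk} is the
#' per-pair count of SNPs observed in both individuals.
#'
#' @param genotypes n x M additive genotype matrix (NA = missing). Row
#'   names are used as sample ids.
#' @param freqs Counted-allele frequencies in (0, 1); defaults to the
#'   sample frequencies of \code{genotypes}.
#' @param ids Optional data.frame (fid, iid) overriding row names.
#' @return Object of class \code{grm}: list(ids, A, N, n_snps) with
#'   \code{A} the n x n relatedness matrix and \code{N} the per-pair SNP
#'   counts.
#' @export
compute_grm <- function(genotypes, freqs = NULL, ids = NULL) {
  if (is.null(freqs)) freqs <- colMeans(genotypes, na.rm = TRUE) / 2
  if (any(freqs <= 0 | freqs >= 1))
    stop("monomorphic SNP(s) present (p in {0,1}); filter before GRM")
  z <- standardize_genotypes(genotypes, freqs)
  obs <- !is.na(z)
  z[!obs] <- 0
  N <- tcrossprod(obs * 1)
  if (any(N == 0)) stop("some pair shares no observed SNPs")
  A <- tcrossprod(z) / N
  structure(list(ids = grm_ids(genotypes, ids), A = unname(A), N = unname(N),
                 n_snps = ncol(genotypes)),
            class = "grm")
}

grm_ids <- function(genotypes, ids) {
  if (!is.null(ids)) return(ids)
  iid <- rownames(genotypes) %||% paste0("ind", seq_len(nrow(genotypes)))
  data.frame(fid = iid, iid = iid, stringsAsFactors = FALSE)
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d samples, %d SNPs; mean diag %.3f\n",
              nrow(x$A), x$n_snps, mean(diag(x$A))))
  invisible(x)
}

#' Cross-generation relatedness matrix
#'
#' The standardized-covariance estimator of [compute_grm()] applied across
#' two genotype panels (children in rows, parents in columns), using one
#' shared allele-frequency reference so that within- and cross-generation
#' matrices live on the same scale. Entry (i, i) for aligned child-parent
#' pairs concentrates near 0.5.
#'
#' @param child_genotypes,parent_genotypes n_c x M and n_p x M matrices on
#'   the same SNP panel (matching column names) and allele orientation.
#' @param freqs Shared counted-allele frequencies; defaults to the pooled
#'   sample frequency over both panels.
#' @return Object of class \code{cross_grm}: list(child_ids, parent_ids,
#'   A, N, n_snps).
#' @export
compute_cross_grm <- function(child_genotypes, parent_genotypes,
                              freqs = NULL) {
  cn_c <- colnames(child_genotypes)
  cn_p <- colnames(parent_genotypes)
  if (!is.null(cn_c) && !is.null(cn_p) && !identical(cn_c, cn_p)) {
    off <- union(setdiff(cn_c, cn_p), setdiff(cn_p, cn_c))
    if (length(off) == 0) off <- "same set, different order"
    stop("SNP panel mismatch between generations: ",
         paste(utils::head(off, 5), collapse = ", "))
  }
  if (ncol(child_genotypes) != ncol(parent_genotypes))
    stop("SNP panel mismatch: differing SNP counts")
  if (is.null(freqs))
    freqs <- (colSums(child_genotypes, na.rm = TRUE) +
                colSums(parent_genotypes, na.rm = TRUE)) /
      (2 * (colSums(!is.na(child_genotypes)) +
              colSums(!is.na(parent_genotypes))))
  if (any(freqs <= 0 | freqs >= 1))
    stop("monomorphic SNP(s) present (p in {0,1}); filter before GRM")
  z_c <- standardize_genotypes(child_genotypes, freqs)
  z_p <- standardize_genotypes(parent_genotypes, freqs)
  obs_c <- !is.na(z_c); z_c[!obs_c] <- 0
  obs_p <- !is.na(z_p); z_p[!obs_p] <- 0
  N <- tcrossprod(obs_c * 1, obs_p * 1)
  if (any(N == 0)) stop("some cross pair shares no observed SNPs")
  A <- tcrossprod(z_c, z_p) / N
  structure(list(child_ids = grm_ids(child_genotypes, NULL),
                 parent_ids = grm_ids(parent_genotypes, NULL),
                 A = unname(A), N = unname(N),
                 n_snps = ncol(child_genotypes)),
            class = "cross_grm")
}

#' Aligned GRM set for a parent-offspring pair dataset
#'
#' Bundles the within-offspring GRM, the within-parent GRM and the
#' child x parent cross matrix, with row i of every matrix referring to the
#' same family.
#'
#' @param child_grm,parent_grm [compute_grm()] results of equal size.
#' @param cross [compute_cross_grm()] result (children x parents), or NULL
#'   for an offspring-only set.
#' @param family_ids Family identifier per aligned row.
#' @return Object of class \code{grm_set}.
#' @export
grm_set <- function(child_grm, parent_grm = NULL, cross = NULL,
                    family_ids = NULL) {
  n <- nrow(child_grm$A)
  if (!is.null(parent_grm) && nrow(parent_grm$A) != n)
    stop("child and parent GRMs are not aligned")
  if (!is.null(cross) && !all(dim(cross$A) == c(n, n)))
    stop("cross matrix is not aligned with the GRMs")
  if (is.null(family_ids)) family_ids <- child_grm$ids$fid
  stopifnot(length(family_ids) == n)
  structure(list(child = child_grm, parent = parent_grm, cross = cross,
                 family_ids = family_ids),
            class = "grm_set")
}

#' Greedy relatedness pruning at a correlation cutoff
#'
#' Scans for over-threshold relatedness: any off-diagonal within-offspring
#' or within-parent value, or any off-family cross value, strictly above
#' \code{cutoff} (child-with-own-parent entries are exempt). While
#' violations remain, the family whose members participate in the most
#' over-threshold pairs is removed (ties broken by removing the
#' larger-index family); removing a family removes both its members.
#'
#' @param set A [grm_set()]; parent/cross components may be NULL.
#' @param cutoff Relatedness threshold in (0, 1); default 0.025.
#' @return List with \code{retained} (family ids), \code{retained_idx},
#'   \code{removed} (family ids), \code{n_pairs_start} (violating pairs
#'   before pruning).
#' @export
prune_relatedness <- function(set, cutoff = 0.025) {
  stopifnot(inherits(set, "grm_set"))
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- length(set$family_ids)
  pair_list <- function(A, off_diag_only = TRUE) {
    hit <- which(A > cutoff, arr.ind = TRUE)
    hit <- hit[hit[, 1] != hit[, 2], , drop = FALSE]
    if (off_diag_only) hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit
  }
  pairs <- pair_list(set$child$A)
  if (!is.null(set$parent)) pairs <- rbind(pairs, pair_list(set$parent$A))
  if (!is.null(set$cross)) {
    # cross matrix is not symmetric: keep all off-family hits, as an
    # unordered family pair
    hit <- pair_list(set$cross$A, off_diag_only = FALSE)
    if (nrow(hit) > 0)
      pairs <- rbind(pairs, cbind(pmin(hit[, 1], hit[, 2]),
                                  pmax(hit[, 1], hit[, 2])))
  }
  n_pairs_start <- nrow(pairs)
  removed <- integer(0)
  while (nrow(pairs) > 0) {
    deg <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = n)
    worst <- max(deg)
    victim <- max(which(deg == worst))    # tie -> larger family index
    removed <- c(removed, victim)
    pairs <- pairs[pairs[, 1] != victim & pairs[, 2] != victim, ,
                   drop = FALSE]
  }
  keep_idx <- setdiff(seq_len(n), removed)
  list(retained = set$family_ids[keep_idx], retained_idx = keep_idx,
       removed = set$family_ids[removed], n_pairs_start = n_pairs_start)
}

#' Subset a GRM set to retained families
#'
#' @param set A [grm_set()].
#' @param idx Row indices to keep (e.g. \code{retained_idx} from
#'   [prune_relatedness()]).
#' @return A [grm_set()] over the retained families.
#' @export
subset_grm_set <- function(set, idx) {
  sub_grm <- function(g) {
    if (is.null(g)) return(NULL)
    g$A <- g$A[idx, idx, drop = FALSE]
    g$N <- g$N[idx, idx, drop = FALSE]
    if (!is.null(g$ids)) g$ids <- g$ids[idx, , drop = FALSE]
    if (!is.null(g$child_ids)) {
      g$child_ids <- g$child_ids[idx, , drop = FALSE]
      g$parent_ids <- g$parent_ids[idx, , drop = FALSE]
    }
    g
  }
  grm_set(sub_grm(set$child), sub_grm(set$parent), sub_grm(set$cross),
          family_ids = set$family_ids[idx])
}
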