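#' Read and write GCTA binary GRM triplets
#'
#' A GCTA GRM is stored as three files sharing a prefix: \code{.grm.bin}
#' (the lower triangle including the diagonal, row-wise, as little-endian
#' float32), \code{.grm.N.bin} (per-pair SNP counts in the same order and
#' encoding) and \code{.grm.id} (tab-separated FID / IID, one row per
#' sample). \code{read_gcta_grm(write_gcta_grm(g))} is exact to float32
#' precision.
#'
#' @param grm A [compute_grm()] result.
#' @param prefix File prefix (files get the three suffixes appended).
#' @return \code{write_gcta_grm} returns the prefix invisibly;
#'   \code{read_gcta_grm} returns a \code{grm} object.
#' @export
write_gcta_grm <- function(grm, prefix) {
  n <- nrow(grm$A)
  idx <- lower_tri_index(n)
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(grm$A[idx]), con, size = 4L, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  Nv <- if (is.matrix(grm$N)) grm$N[idx] else rep(grm$n_snps, nrow(idx))
  writeBin(as.numeric(Nv), con, size = 4L, endian = "little")
  close(con)
  utils::write.table(grm$ids, paste0(prefix, ".grm.id"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_gcta_grm
#' @export
read_gcta_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           col.names = c("fid", "iid"),
                           colClasses = "character")
  n <- nrow(ids)
  n_vals <- n * (n + 1) / 2
  f <- paste0(prefix, ".grm.bin")
  if (file.info(f)$size != 4 * n_vals)
    stop("GRM values file length (", file.info(f)$size / 4,
         " float32) inconsistent with ", n, " ids (need ", n_vals, ")")
  con <- file(f, "rb")
  vals <- readBin(con, "numeric", n_vals, size = 4L, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "rb")
  nv <- readBin(con, "numeric", n_vals, size = 4L, endian = "little")
  close(con)
  idx <- lower_tri_index(n)
  A <- matrix(0, n, n); Nm <- matrix(0, n, n)
  A[idx] <- vals; Nm[idx] <- nv
  A[idx[, 2:1, drop = FALSE]] <- vals
  Nm[idx[, 2:1, drop = FALSE]] <- nv
  structure(list(ids = ids, A = A, N = Nm,
                 n_snps = as.integer(round(max(nv)))),
            class = "grm")
}

# row-wise lower-triangle (incl. diagonal) index pairs: (1,1),(2,1),(2,2),...
lower_tri_index <- function(n) {
  i <- rep(seq_len(n), seq_len(n))
  j <- unlist(lapply(seq_len(n), seq_len))
  cbind(i, j)
}

#' Write and read PLINK bed/bim/fam filesets
#'
#' SNP-major PLINK 1 binary genotypes: the counted allele is \code{a1}, so
#' stored 2-bit codes map to dosages 0/1/2 of a1 with 01 = missing.
#' \code{write_plink} writes one fileset for an additive genotype matrix;
#' \code{read_plink} reads it back. Round-trips are exact.
#'
#' @param genotypes n x M matrix of a1 dosages (NA = missing).
#' @param prefix Path prefix for the .bed/.bim/.fam files.
#' @param fam data.frame with columns fid, iid, pat, mat, sex, phe (missing
#'   columns filled with 0 / -9).
#' @param bim data.frame with columns chromosome, id, cm, position, a1, a2
#'   (cm optional).
#' @return \code{write_plink} the prefix, invisibly; \code{read_plink} a
#'   list(genotypes, fam, bim).
#' @export
write_plink <- function(genotypes, prefix, fam = NULL, bim = NULL) {
  n <- nrow(genotypes); m <- ncol(genotypes)
  if (is.null(fam)) {
    iid <- rownames(genotypes) %||% paste0("ind", seq_len(n))
    fam <- data.frame(fid = iid, iid = iid, pat = 0, mat = 0, sex = 0,
                      phe = -9, stringsAsFactors = FALSE)
  }
  if (is.null(bim)) {
    id <- colnames(genotypes) %||% sprintf("snp%06d", seq_len(m))
    bim <- data.frame(chromosome = 1L, id = id, cm = 0,
                      position = seq_len(m), a1 = "A", a2 = "B",
                      stringsAsFactors = FALSE)
  }
  if (is.null(bim$cm)) bim$cm <- 0
  utils::write.table(fam[, c("fid", "iid", "pat", "mat", "sex", "phe")],
                     paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(bim[, c("chromosome", "id", "cm", "position", "a1", "a2")],
                     paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # 2-bit codes per individual, SNP-major: 00 = 2 copies of a1, 10 = het,
  # 11 = 0 copies, 01 = missing
  code <- matrix(3L, n, m)
  code[genotypes == 1] <- 2L
  code[genotypes == 2] <- 0L
  code[is.na(genotypes)] <- 1L
  bytes_per_snp <- ceiling(n / 4)
  pad <- 4 * bytes_per_snp - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  shifts <- c(1L, 4L, 16L, 64L)
  raw_mat <- matrix(0L, bytes_per_snp, m)
  for (k in 1:4)
    raw_mat <- raw_mat + code[seq(k, nrow(code), by = 4), , drop = FALSE] *
      shifts[k]
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(raw_mat), con)
  close(con)
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "phe"),
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "integer", "numeric"))
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chromosome", "id", "cm",
                                         "position", "a1", "a2"),
                           colClasses = c("character", "character",
                                          "numeric", "integer",
                                          "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file: ", prefix, ".bed")
  raw <- readBin(con, "raw", bytes_per_snp * m)
  if (length(raw) != bytes_per_snp * m)
    stop(".bed payload inconsistent with .fam/.bim dimensions")
  b <- as.integer(raw)
  two_bit <- rbind(b %% 4, (b %/% 4) %% 4, (b %/% 16) %% 4, (b %/% 64) %% 4)
  code <- matrix(as.vector(two_bit), nrow = 4 * bytes_per_snp, ncol = m)
  code <- code[seq_len(n), , drop = FALSE]
  geno <- matrix(NA_integer_, n, m,
                 dimnames = list(fam$iid, bim$id))
  geno[code == 0L] <- 2L
  geno[code == 2L] <- 1L
  geno[code == 3L] <- 0L
  list(genotypes = geno, fam = fam, bim = bim)
}

#' Write a trio cohort as PLINK filesets plus phenotype/covariate text
#'
#' Writes one bed/bim/fam fileset per generation (\code{<prefix>_child},
#' \code{<prefix>_mother}, \code{<prefix>_father}; family linkage through
#' the child FAM's parental-id fields), GCTA-dialect phenotype
#' (\code{FID IID value}), discrete covariate (\code{FID IID sex batch})
#' and quantitative covariate files, and a JSON sidecar holding the
#' simulation config and the implied true variance components.
#'
#' @param cohort A [simulate_trio_genotypes()] result.
#' @param pheno Optional \code{pheno_table} for the children.
#' @param prefix Output path prefix.
#' @param qcovar Optional data.frame (iid + quantitative columns).
#' @return The prefix, invisibly.
#' @export
write_trio_cohort <- function(cohort, prefix, pheno = NULL, qcovar = NULL) {
  bim <- data.frame(chromosome = cohort$snp_metadata$chromosome,
                    id = cohort$snp_metadata$id, cm = 0,
                    position = cohort$snp_metadata$position,
                    a1 = cohort$snp_metadata$a1, a2 = cohort$snp_metadata$a2,
                    stringsAsFactors = FALSE)
  fid <- cohort$family_ids
  fam_c <- data.frame(fid = fid, iid = child_iids(cohort),
                      pat = father_iids(cohort), mat = mother_iids(cohort),
                      sex = 2L - cohort$child_sex, phe = -9,
                      stringsAsFactors = FALSE)
  fam_m <- data.frame(fid = fid, iid = mother_iids(cohort), pat = 0, mat = 0,
                      sex = 2L, phe = -9, stringsAsFactors = FALSE)
  fam_f <- data.frame(fid = fid, iid = father_iids(cohort), pat = 0, mat = 0,
                      sex = 1L, phe = -9, stringsAsFactors = FALSE)
  write_plink(cohort$child_genotypes, paste0(prefix, "_child"), fam_c, bim)
  write_plink(cohort$mother_genotypes, paste0(prefix, "_mother"), fam_m, bim)
  write_plink(cohort$father_genotypes, paste0(prefix, "_father"), fam_f, bim)
  utils::write.table(data.frame(fid, child_iids(cohort), cohort$child_sex,
                                cohort$batch),
                     paste0(prefix, ".covar"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(pheno))
    utils::write.table(data.frame(pheno$fid, pheno$iid,
                                  signif(pheno$score, 10)),
                       paste0(prefix, ".pheno"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  if (!is.null(qcovar))
    utils::write.table(cbind(fid, qcovar), paste0(prefix, ".qcovar"),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth <- expected_components(cohort$config)
  jsonlite::write_json(list(config = unclass(cohort$config),
                            truth = unclass(truth)),
                       paste0(prefix, "_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
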