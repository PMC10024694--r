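#' Questionnaire scale definition
#'
#' Describes a Likert scale: number of items, number of ordered response
#' categories (coded \code{min_code} upward), and the maximum number of
#' missing items tolerated before a respondent's total is declared invalid.
#'
#' @param name Short scale name used to match item columns.
#' @param n_items Number of items.
#' @param n_categories Number of ordered categories per item.
#' @param max_missing Maximum allowed missing items per respondent.
#' @param min_code Lowest item code (default 1).
#' @return An object of class \code{scale_definition}.
#' @export
scale_definition <- function(name, n_items, n_categories, max_missing,
                             min_code = 1L) {
  n_items <- as.integer(n_items)
  n_categories <- as.integer(n_categories)
  max_missing <- as.integer(max_missing)
  stopifnot(n_items >= 1L, n_categories >= 2L, max_missing >= 0L)
  if (max_missing >= n_items)
    stop("max_missing must be smaller than n_items")
  structure(list(name = name, n_items = n_items,
                 n_categories = n_categories,
                 max_missing = max_missing,
                 min_code = as.integer(min_code)),
            class = "scale_definition")
}

#' Built-in scales: SMFQ and RS-DBD subscales
#'
#' The parent-rated Short Mood and Feelings Questionnaire (13 items on a
#' 3-point Likert scale, up to 2 missing items allowed), the combined
#' oppositional-defiant + conduct "disruptive" subscale of the RS-DBD
#' (16 items, 4-point, up to 3 missing) and the RS-DBD ADHD subscale
#' (18 items, 4-point, up to 4 missing). Items are coded from 1, so the
#' attainable totals are 13-39, 16-64 and 18-72 respectively.
#'
#' @return A [scale_definition()].
#' @export
smfq_scale <- function() scale_definition("smfq", 13L, 3L, 2L)

#' @rdname smfq_scale
#' @export
rsdbd_disruptive_scale <- function() scale_definition("disr", 16L, 4L, 3L)

#' @rdname smfq_scale
#' @export
rsdbd_adhd_scale <- function() scale_definition("adhd", 18L, 4L, 4L)

#' Score a questionnaire scale with mean imputation of missing items
#'
#' The total is the sum of item responses after replacing each missing item
#' with the mean of that respondent's non-missing items (equivalently,
#' \code{n_items} times the mean of observed items). Respondents missing
#' more than \code{max_missing} items are flagged invalid and receive no
#' score. Totals are left non-integer when imputation occurs.
#'
#' @param items An \code{item_table} (or data.frame) whose item columns
#'   start with \code{<scale name>_i}; \code{fid}/\code{iid} carried along.
#' @param scale A [scale_definition()].
#' @return A data.frame of class \code{pheno_table} with columns \code{fid},
#'   \code{iid}, \code{score} (NA when invalid), \code{n_missing},
#'   \code{valid}.
#' @export
score_scale <- function(items, scale) {
  stopifnot(inherits(scale, "scale_definition"))
  item_cols <- grep(paste0("^", scale$name, "_i"), names(items), value = TRUE)
  if (length(item_cols) != scale$n_items)
    stop("expected ", scale$n_items, " item columns matching '",
         scale$name, "_i*', found ", length(item_cols))
  x <- as.matrix(items[, item_cols])
  lo <- scale$min_code
  hi <- scale$min_code + scale$n_categories - 1L
  bad <- which(!is.na(x) & (x < lo | x > hi | x != round(x)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    row1 <- bad[1, 1]
    stop("out-of-range item code ", x[bad[1, 1], bad[1, 2]], " for ",
         items$iid[row1], " (", item_cols[bad[1, 2]], "); valid codes are ",
         lo, "..", hi)
  }
  n_missing <- rowSums(is.na(x))
  valid <- n_missing <= scale$max_missing
  score <- rowMeans(x, na.rm = TRUE) * scale$n_items
  score[!valid] <- NA_real_
  out <- data.frame(fid = items$fid, iid = items$iid, score = score,
                    n_missing = n_missing, valid = valid,
                    stringsAsFactors = FALSE)
  class(out) <- c("pheno_table", "data.frame")
  out
}

#' Regress covariates out of a phenotype and standardize the residual
#'
#' Ordinary least squares of the score on an intercept, sex, genotyping
#' batch (one-hot), and the genotype principal components, applied over
#' valid rows; the residual is returned both raw and scaled to unit
#' variance. Zero-variance covariate columns (e.g. a single batch) are
#' dropped silently — they are absorbed by the intercept; any remaining
#' collinearity is an error naming the offending columns.
#'
#' @param pheno A \code{pheno_table} with columns \code{iid} and
#'   \code{score}.
#' @param cov A data.frame with \code{iid} plus covariate columns: optional
#'   \code{sex}, optional \code{batch} (treated as categorical), and any
#'   number of quantitative columns (e.g. \code{pc_1..pc_10}).
#' @return The input with columns \code{residualized_score} and
#'   \code{standardized_score} added (NA for rows without a score or
#'   covariates).
#' @export
residualize <- function(pheno, cov) {
  stopifnot("iid" %in% names(pheno), "iid" %in% names(cov),
            "score" %in% names(pheno))
  idx <- match(pheno$iid, cov$iid)
  use <- !is.na(pheno$score) & !is.na(idx)
  cv <- cov[idx[use], setdiff(names(cov), c("fid", "iid")), drop = FALSE]
  if (any(!stats::complete.cases(cv)))
    stop("incomplete covariates for ", sum(!stats::complete.cases(cv)),
         " scored individuals")

  X <- matrix(1, nrow(cv), 1, dimnames = list(NULL, "intercept"))
  for (nm in names(cv)) {
    col <- cv[[nm]]
    if (nm == "batch" || is.factor(col) || is.character(col)) {
      f <- factor(col)
      if (nlevels(f) > 1) {
        d <- stats::model.matrix(~ f)[, -1, drop = FALSE]
        colnames(d) <- paste0(nm, levels(f)[-1])
        X <- cbind(X, d)
      }
    } else if (stats::sd(col) > 0) {
      X <- cbind(X, stats::setNames(data.frame(col), nm)[[1]])
      colnames(X)[ncol(X)] <- nm
    }
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qr_x, pheno$score[use])
  pheno$residualized_score <- NA_real_
  pheno$standardized_score <- NA_real_
  pheno$residualized_score[use] <- res
  pheno$standardized_score[use] <- res / stats::sd(res)
  pheno
}

#' Genotype principal components
#'
#' Top-k principal components of the column-standardized genotype matrix,
#' computed from the eigendecomposition of the sample covariance of
#' individuals, after optional LD pruning. Each component is unit-norm with
#' its sign fixed so the largest-magnitude loading is positive.
#'
#' @param genotypes n x M additive genotype matrix (no missing values).
#' @param k Number of components (default 10).
#' @param ld_prune If TRUE, greedy sliding-window LD pruning is applied
#'   first (window 50 SNPs, step 5, r^2 threshold 0.2 by default).
#' @param ld_window,ld_step,ld_r2 Pruning parameters.
#' @return A data.frame with \code{iid} (rownames of \code{genotypes}, or
#'   \code{ind<i>}) and columns \code{pc_1..pc_k}.
#' @export
compute_pcs <- function(genotypes, k = 10L, ld_prune = FALSE,
                        ld_window = 50L, ld_step = 5L, ld_r2 = 0.2) {
  if (anyNA(genotypes)) stop("genotype matrix must be complete")
  keep <- which(col_sds(genotypes) > 0)
  g <- genotypes[, keep, drop = FALSE]
  if (ld_prune) g <- g[, ld_prune_indices(g, ld_window, ld_step, ld_r2),
                       drop = FALSE]
  z <- scale(g)
  if (k > min(dim(z))) stop("k exceeds the rank bound min(n, M)")
  cv <- tcrossprod(z) / ncol(z)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[k] <= 1e-10 * eg$values[1])
    stop("k exceeds the numerical rank of the genotype matrix")
  pcs <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(pcs[, j]))
    if (pcs[i_max, j] < 0) pcs[, j] <- -pcs[, j]
  }
  colnames(pcs) <- paste0("pc_", seq_len(k))
  iid <- rownames(genotypes)
  if (is.null(iid)) iid <- paste0("ind", seq_len(nrow(genotypes)))
  cbind(data.frame(iid = iid, stringsAsFactors = FALSE),
        as.data.frame(pcs))
}

# column standard deviations without matrixStats
col_sds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt(pmax(colSums(x^2) / n - mu^2, 0) * n / max(n - 1, 1))
}

# Greedy sliding-window LD pruning (PLINK --indep-pairwise style): within
# each window, drop the later SNP of any pair with r^2 above the threshold.
ld_prune_indices <- function(g, window, step, r2_max) {
  m <- ncol(g)
  keep <- rep(TRUE, m)
  start <- 1L
  while (start <= m) {
    idx <- seq(start, min(start + window - 1L, m))
    idx <- idx[keep[idx]]
    if (length(idx) > 1) {
      r2 <- stats::cor(g[, idx, drop = FALSE])^2
      for (a in seq_along(idx)[-length(idx)]) {
        if (!keep[idx[a]]) next
        drop_b <- which(r2[a, ] > r2_max)
        drop_b <- drop_b[drop_b > a & keep[idx[drop_b]]]
        keep[idx[drop_b]] <- FALSE
      }
    }
    if (start + window - 1L >= m) break
    start <- start + step
  }
  which(keep)
}
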