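#' Fit the offspring-only GREML model
#'
#' Standard SNP-based heritability model for the child phenotype:
#' \code{V = V_o A_c + V_e I}. The p-value compares against a residual-only
#' model by likelihood-ratio test with 1 degree of freedom.
#'
#' @param y Residualized, standardized phenotype vector aligned with the
#'   GRM.
#' @param grm A [compute_grm()] result (or a \code{grm_set} whose child
#'   GRM is used).
#' @param ... Passed to [reml_fit()].
#' @return Object of class \code{vc_result} (one results-table row).
#' @export
fit_offspring_model <- function(y, grm, ...) {
  if (inherits(grm, "grm_set")) grm <- grm$child
  spec <- model_spec(list(V_o = grm$A))
  fit <- reml_fit(y, spec, ...)
  null_fit <- reml_fit(y, model_spec(list(V_e = diag(length(y)))), ...)
  test <- lrt(fit, null_fit, df = 1)
  gg <- combined_g(fit)
  new_vc_result(model = "offspring",
                components = c(v_o = unname(fit$estimates["V_o"])),
                se = c(v_o = unname(fit$se["V_o"])),
                v_e = unname(fit$estimates["V_e"]),
                v_e_se = unname(fit$se["V_e"]),
                g = gg$g, g_se = gg$g_se, logL = fit$logL,
                lrt_stat = test$statistic, lrt_p = test$p, lrt_df = 1,
                n = fit$n, fit = fit)
}

#' Fit an extended parent-offspring GREML model
#'
#' The maternal (or paternal) extension: the child phenotype's covariance
#' is modelled as
#' \code{V = V_o A_c + V_parent A_p + V_cross (A_cp + A_cp') + V_e I},
#' estimating the direct effect, the parental genetic-nurture effect, and
#' their covariance (passive gene-environment correlation). V_o and
#' V_parent are constrained nonnegative; V_cross is free in sign. The
#' p-value compares the full model to the offspring-only model on the same
#' data (likelihood-ratio test, 2 degrees of freedom).
#'
#' @param y Residualized, standardized phenotype vector aligned with the
#'   set.
#' @param set A [grm_set()] with child, parent and cross components.
#' @param parent_kind "maternal" or "paternal" (labels the output row).
#' @param ... Passed to [reml_fit()].
#' @return Object of class \code{vc_result}.
#' @export
fit_parent_model <- function(y, set, parent_kind = c("maternal", "paternal"),
                             ...) {
  parent_kind <- match.arg(parent_kind)
  stopifnot(inherits(set, "grm_set"))
  if (is.null(set$parent) || is.null(set$cross))
    stop("parent model needs parent and cross matrices in the grm_set")
  structures <- list(V_o = set$child$A,
                     V_parent = set$parent$A,
                     V_cross = set$cross$A + t(set$cross$A))
  spec <- model_spec(structures,
                     nonneg = c(V_o = TRUE, V_parent = TRUE,
                                V_cross = FALSE, V_e = TRUE))
  fit <- reml_fit(y, spec, ...)
  reduced <- reml_fit(y, model_spec(list(V_o = set$child$A)), ...)
  test <- lrt(fit, reduced, df = 2)
  gg <- combined_g(fit)
  comp <- c(v_o = unname(fit$estimates["V_o"]),
            v_parent = unname(fit$estimates["V_parent"]),
            v_cross = unname(fit$estimates["V_cross"]))
  se <- c(v_o = unname(fit$se["V_o"]),
          v_parent = unname(fit$se["V_parent"]),
          v_cross = unname(fit$se["V_cross"]))
  new_vc_result(model = parent_kind, components = comp, se = se,
                v_e = unname(fit$estimates["V_e"]),
                v_e_se = unname(fit$se["V_e"]),
                g = gg$g, g_se = gg$g_se, logL = fit$logL,
                lrt_stat = test$statistic, lrt_p = test$p, lrt_df = 2,
                n = fit$n, fit = fit)
}

new_vc_result <- function(model, components, se, v_e, v_e_se, g, g_se,
                          logL, lrt_stat, lrt_p, lrt_df, n, fit) {
  structure(list(model = model, components = components, se = se,
                 v_e = v_e, v_e_se = v_e_se, g = g, g_se = g_se,
                 logL = logL, lrt_stat = lrt_stat, lrt_p = lrt_p,
                 lrt_df = lrt_df, n = n, fit = fit),
            class = "vc_result")
}

#' @export
print.vc_result <- function(x, ...) {
  fmt <- function(v, s) sprintf("%.3f (%.3f)", v, s)
  cat(sprintf("<vc_result> %s model, N = %d\n", x$model, x$n))
  for (nm in names(x$components))
    cat(sprintf("  %-9s %s\n", nm, fmt(x$components[nm], x$se[nm])))
  cat(sprintf("  %-9s %s\n", "G", fmt(x$g, x$g_se)))
  cat(sprintf("  logL %.2f, LRT p = %.3g (df %d)\n",
              x$logL, x$lrt_p, x$lrt_df))
  invisible(x)
}

#' Flatten variance-component results into a results table
#'
#' One row per fitted model, mirroring the standard reporting layout
#' (components with SEs, combined G, logL, LRT p, N).
#'
#' @param results List of \code{vc_result} objects.
#' @param phenotype Optional phenotype label(s) recycled over rows.
#' @return data.frame with columns model, phenotype, v_o, v_o_se,
#'   v_parent, v_parent_se, v_cross, v_cross_se, g, g_se, logL, p, n.
#' @export
vc_result_table <- function(results, phenotype = NA_character_) {
  if (inherits(results, "vc_result")) results <- list(results)
  phenotype <- rep_len(phenotype, length(results))
  rows <- mapply(function(r, ph) {
    data.frame(model = r$model, phenotype = ph,
               v_o = r$components[["v_o"]], v_o_se = r$se[["v_o"]],
               v_parent = r$components["v_parent"][[1]] %na%
                 NA_real_,
               v_parent_se = r$se["v_parent"][[1]] %na% NA_real_,
               v_cross = r$components["v_cross"][[1]] %na% NA_real_,
               v_cross_se = r$se["v_cross"][[1]] %na% NA_real_,
               g = r$g, g_se = r$g_se, logL = r$logL, p = r$lrt_p,
               n = r$n, stringsAsFactors = FALSE)
  }, results, phenotype, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%na%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
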