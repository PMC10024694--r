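#' Pipeline configuration
#'
#' Declarative configuration for the end-to-end analysis: simulate (or
#' load) a trio cohort, generate and score questionnaire scales,
#' apply SNP QC, build and prune GRMs, and fit the offspring-only and
#' extended parent-offspring models for every phenotype. Defaults
#' reproduce the reference analysis settings: HWE exact p >= 1e-6, call
#' rate >= 0.90, MAF > 0.05, INFO > 0.9, relatedness cutoff 0.025, sex +
#' batch + 10 genotype PCs regressed out of the outcomes.
#'
#' @param input "simulate" (the default) or "files".
#' @param sim A [sim_config()] when simulating.
#' @param paths Named list of file prefixes when \code{input = "files"}:
#'   \code{child}, \code{mother}, \code{father} PLINK prefixes plus
#'   \code{pheno} and \code{covar} files (as written by
#'   [write_trio_cohort()]).
#' @param scales List of [scale_definition()]s to generate/score; NULL
#'   analyses the simulated latent score directly as one phenotype.
#' @param missing_rate Item missingness rate for the questionnaire stage.
#' @param qc_thresholds Named overrides for [filter_snps()].
#' @param cutoff Relatedness pruning cutoff (default 0.025).
#' @param models Character subset of c("offspring", "maternal",
#'   "paternal").
#' @param n_pcs Number of genotype principal components (default 10).
#' @param out_dir Output directory for intermediates and results.
#' @param seed Seed for the questionnaire stage (the cohort uses
#'   \code{sim$seed}).
#' @param verbose Print stage-by-stage progress with counts.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = c("simulate", "files"), sim = NULL,
                            paths = NULL, scales = default_scales(),
                            missing_rate = 0.02, qc_thresholds = list(),
                            cutoff = 0.025,
                            models = c("offspring", "maternal", "paternal"),
                            n_pcs = 10L, out_dir = tempfile("triogreml_run"),
                            seed = 1L, verbose = FALSE) {
  input <- match.arg(input)
  if (input == "simulate" && is.null(sim))
    stop("simulate mode needs a sim_config in 'sim'")
  if (input == "files" && is.null(paths))
    stop("files mode needs input paths")
  models <- match.arg(models, several.ok = TRUE)
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  structure(list(input = input, sim = sim, paths = paths, scales = scales,
                 missing_rate = missing_rate,
                 qc_thresholds = qc_thresholds, cutoff = cutoff,
                 models = models, n_pcs = as.integer(n_pcs),
                 out_dir = out_dir, seed = as.integer(seed),
                 verbose = verbose),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_scales <- function() {
  list(smfq_scale(), rsdbd_disruptive_scale(), rsdbd_adhd_scale())
}

#' Run the full family-GREML pipeline
#'
#' Executes simulate/load -> questionnaire scoring -> SNP QC -> PCs ->
#' residualization -> GRM construction -> relatedness pruning -> REML
#' fits, persisting intermediates under \code{config$out_dir}: the QC
#' report (\code{qc_report.tsv}), GCTA GRM triplets, retained-family id
#' lists, residualized phenotypes, a results table (\code{results.tsv})
#' and a JSON run manifest. Rerunning with the same config is
#' byte-identical for simulated inputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with \code{results} (data.frame),
#'   \code{manifest}, and the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  manifest <- list(package_version = as.character(utils::packageVersion("triogreml")),
                   seed = config$seed, cutoff = config$cutoff,
                   qc_thresholds = utils::modifyList(
                     list(hwe_p = 1e-6, call_rate = 0.90, maf = 0.05,
                          info = 0.9), config$qc_thresholds),
                   n_pcs = config$n_pcs, models = config$models,
                   stages = list())

  ## stage 1: cohort
  if (config$input == "simulate") {
    cohort <- simulate_trio_genotypes(config$sim)
    manifest$sim_config <- unclass(config$sim)
    manifest$truth <- unclass(expected_components(config$sim))
  } else {
    cohort <- load_trio_cohort(config$paths)
  }
  n_fam <- length(cohort$family_ids)
  m_all <- nrow(cohort$snp_metadata)
  say("cohort: %d families, %d SNPs", n_fam, m_all)
  manifest$stages$cohort <- list(n_families = n_fam, n_snps = m_all)

  ## stage 2: phenotypes (one per scale, or the latent score)
  phenos <- list()
  if (config$input == "simulate") {
    if (is.null(config$scales)) {
      phenos$latent <- simulate_phenotypes(cohort, config$sim)
    } else {
      for (i in seq_along(config$scales)) {
        sc <- config$scales[[i]]
        cfg_i <- config$sim
        cfg_i$seed <- sub_seed(config$sim$seed, 10L + i)
        latent <- simulate_phenotypes(cohort, cfg_i)
        items <- simulate_questionnaire(latent, sc,
                                        missing_rate = config$missing_rate,
                                        seed = sub_seed(config$seed, 20L + i))
        scored <- score_scale(items, sc)
        scored$sex <- latent$sex
        scored$batch <- latent$batch
        phenos[[sc$name]] <- scored
      }
    }
  } else {
    phenos$pheno <- cohort$pheno
  }
  manifest$stages$phenotypes <-
    lapply(phenos, function(p) list(n_scored = sum(!is.na(p$score))))

  ## stage 3: SNP QC (HWE tested in founders = parents)
  parents <- rbind(cohort$mother_genotypes, cohort$father_genotypes)
  stats <- snp_stats(parents, metadata = cohort$snp_metadata)
  qc <- filter_snps(stats, config$qc_thresholds)
  utils::write.table(qc$report, file.path(config$out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(qc$kept_ids, file.path(config$out_dir, "snps_kept.txt"))
  keep <- qc$keep
  say("QC: %d of %d SNPs kept", sum(keep), m_all)
  manifest$stages$qc <- list(n_tested = m_all, n_kept = sum(keep))
  g_child <- cohort$child_genotypes[, keep, drop = FALSE]
  g_mother <- cohort$mother_genotypes[, keep, drop = FALSE]
  g_father <- cohort$father_genotypes[, keep, drop = FALSE]

  ## stage 4: PCs and residualization
  rownames(g_child) <- child_iids(cohort)
  pcs <- compute_pcs(g_child, k = config$n_pcs)
  covar <- data.frame(iid = child_iids(cohort), sex = cohort$child_sex,
                      batch = cohort$batch, stringsAsFactors = FALSE)
  covar <- cbind(covar, pcs[match(covar$iid, pcs$iid), -1, drop = FALSE])
  phenos <- lapply(phenos, residualize, cov = covar)
  for (nm in names(phenos))
    utils::write.table(
      data.frame(phenos[[nm]]$fid, phenos[[nm]]$iid,
                 round(phenos[[nm]]$standardized_score, 8)),
      file.path(config$out_dir, paste0("pheno_", nm, ".txt")),
      quote = FALSE, row.names = FALSE, col.names = FALSE)

  ## stage 5: GRMs + pruning, per dataset
  datasets <- list()
  if ("offspring" %in% config$models) {
    grm_c <- compute_grm(g_child,
                         ids = data.frame(fid = cohort$family_ids,
                                          iid = child_iids(cohort)))
    set_c <- grm_set(grm_c, family_ids = cohort$family_ids)
    datasets$offspring <- list(set = set_c)
  }
  pair_set <- function(g_par, par_iids) {
    pooled <- (colSums(g_child) + colSums(g_par)) / (4 * n_fam)
    grm_c <- compute_grm(g_child, freqs = pooled,
                         ids = data.frame(fid = cohort$family_ids,
                                          iid = child_iids(cohort)))
    grm_p <- compute_grm(g_par, freqs = pooled,
                         ids = data.frame(fid = cohort$family_ids,
                                          iid = par_iids))
    cross <- compute_cross_grm(g_child, g_par, freqs = pooled)
    grm_set(grm_c, grm_p, cross, family_ids = cohort$family_ids)
  }
  if ("maternal" %in% config$models) {
    rownames(g_mother) <- mother_iids(cohort)
    datasets$maternal <- list(set = pair_set(g_mother, mother_iids(cohort)))
  }
  if ("paternal" %in% config$models) {
    rownames(g_father) <- father_iids(cohort)
    datasets$paternal <- list(set = pair_set(g_father, father_iids(cohort)))
  }
  for (nm in names(datasets)) {
    pr <- prune_relatedness(datasets[[nm]]$set, cutoff = config$cutoff)
    datasets[[nm]]$pruned <- subset_grm_set(datasets[[nm]]$set,
                                            pr$retained_idx)
    datasets[[nm]]$retained_idx <- pr$retained_idx
    writeLines(pr$retained,
               file.path(config$out_dir, paste0("retained_", nm, ".txt")))
    write_gcta_grm(datasets[[nm]]$pruned$child,
                   file.path(config$out_dir, paste0("grm_", nm, "_child")))
    say("%s dataset: %d of %d families retained at cutoff %.3f",
        nm, length(pr$retained), n_fam, config$cutoff)
    manifest$stages[[paste0("prune_", nm)]] <-
      list(n_retained = length(pr$retained),
           n_violating_pairs = pr$n_pairs_start)
  }

  ## stage 6: model fits
  results <- list(); labels <- character(0)
  for (ph in names(phenos)) {
    y_all <- phenos[[ph]]$standardized_score
    for (nm in names(datasets)) {
      idx <- datasets[[nm]]$retained_idx
      ok <- idx[!is.na(y_all[idx])]
      set_fit <- subset_grm_set(datasets[[nm]]$set, ok)
      y <- y_all[ok]
      y <- (y - mean(y)) / stats::sd(y)
      res <- if (nm == "offspring") fit_offspring_model(y, set_fit)
      else fit_parent_model(y, set_fit, parent_kind = nm)
      results[[paste(ph, nm)]] <- res
      labels <- c(labels, ph)
      say("%s / %s: G = %.3f (logL %.2f, p %.3g, N %d)",
          ph, nm, res$g, res$logL, res$lrt_p, res$n)
    }
  }
  tab <- vc_result_table(results, phenotype = labels)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) round(x, 8))
  utils::write.table(tab, file.path(config$out_dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest$stages$fits <- lapply(results, function(r)
    list(model = r$model, n = r$n, converged = r$fit$converged))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = tab, fits = results, manifest = manifest,
                 out_dir = config$out_dir))
}

# Load a cohort written by write_trio_cohort() (files input mode).
load_trio_cohort <- function(paths) {
  child <- read_plink(paths$child)
  mother <- read_plink(paths$mother)
  father <- read_plink(paths$father)
  fam <- child$fam
  cohort <- structure(
    list(family_ids = fam$fid,
         child_genotypes = child$genotypes,
         mother_genotypes = mother$genotypes,
         father_genotypes = father$genotypes,
         child_sex = 2L - fam$sex,
         batch = rep(1L, nrow(fam)),
         snp_metadata = data.frame(
           id = child$bim$id, chromosome = child$bim$chromosome,
           position = child$bim$position, a1 = child$bim$a1,
           a2 = child$bim$a2,
           frequency = colMeans(child$genotypes, na.rm = TRUE) / 2,
           stringsAsFactors = FALSE)),
    class = "trio_cohort")
  if (!is.null(paths$covar)) {
    cv <- utils::read.table(paths$covar,
                            col.names = c("fid", "iid", "sex", "batch"))
    ord <- match(child_iids(cohort), cv$iid)
    cohort$child_sex <- cv$sex[ord]
    cohort$batch <- cv$batch[ord]
  }
  if (!is.null(paths$pheno)) {
    ph <- utils::read.table(paths$pheno,
                            col.names = c("fid", "iid", "score"))
    ph <- ph[match(child_iids(cohort), ph$iid), ]
    ph$sex <- cohort$child_sex
    ph$batch <- cohort$batch
    class(ph) <- c("pheno_table", "data.frame")
    cohort$pheno <- ph
  }
  cohort
}
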