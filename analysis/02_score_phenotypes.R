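# Generate questionnaire item responses from the simulated latent
# phenotypes and score the three built-in scales with their missingness
# caps and mean imputation.
#
# Output: results/phenotypes/scores_<scale>.tsv and a summary table with
# observed ranges, means, SDs and validity counts.

source("analysis/00_config.R")

cfg <- study_sim_config()
cohort <- simulate_trio_genotypes(cfg)

out <- results_dir("phenotypes")
summary_rows <- list()
for (sc in default_scales()) {
  cfg_i <- cfg
  cfg_i$seed <- cfg$seed + match(sc$name, c("smfq", "disr", "adhd"))
  latent <- simulate_phenotypes(cohort, cfg_i)
  items <- simulate_questionnaire(latent, sc, missing_rate = 0.02,
                                  seed = cfg$seed)
  scored <- score_scale(items, sc)
  write.table(scored, file.path(out, paste0("scores_", sc$name, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  s <- scored$score[scored$valid]
  summary_rows[[sc$name]] <- data.frame(
    scale = sc$name, n_items = sc$n_items,
    floor = sc$n_items, ceiling = sc$n_items * sc$n_categories,
    n_valid = sum(scored$valid), n_invalid = sum(!scored$valid),
    min = min(s), max = max(s),
    mean = round(mean(s), 2), sd = round(sd(s), 2))
}
summary_tab <- do.call(rbind, summary_rows)
write.table(summary_tab, file.path(out, "scale_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(summary_tab, row.names = FALSE)
cat("\nScores sit near the scale floors (right-skewed community sample);\n",
    "respondents over the missingness cap are flagged invalid.\n")
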