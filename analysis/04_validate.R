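#!/usr/bin/env Rscript
# Step 4 — out-of-sample validation under the four resampling schemes.
#
# For each predictor set (5, 6 and 7 variables) and each scheme
# (bootstrap, hold-out 80:20 / 90:10 / 95:5): cycle train/test splits
# until every patient has been tested at least 30 times, average each
# patient's predicted relapse probabilities, and compute AUC with a
# DeLong 95% CI and the Youden-optimal cutoff on the averaged scores.

suppressPackageStartupMessages(library(bnaf))
dir.create("results", showWarnings = FALSE)
seed <- 20260922L

schema <- build_default_schema()
cohort <- read_cohort_csv("results/cohort_480.csv", schema)
st <- ground_truth_structure()

all_metrics <- list()
for (ps in c("atlas5", "easy6", "full7")) {
  res <- validate_all_schemes(cohort, st, ps, min_tests = 30L, seed = seed)
  tab <- res$table
  cat(sprintf("\n%s (%d predictors):\n", ps, length(predictor_set(ps))))
  for (i in seq_len(nrow(tab))) {
    if (is.na(tab$ci_low[i])) {
      cat(sprintf("  %-12s AUC %.3f\n", tab$scheme[i], tab$auc[i]))
    } else {
      cat(sprintf("  %-12s AUC %.3f (95%% CI %.3f-%.3f), %d cycles\n",
                  tab$scheme[i], tab$auc[i], tab$ci_low[i], tab$ci_high[i],
                  tab$n_cycles[i]))
    }
  }
  boot <- res$runs$bootstrap
  cat(sprintf("  bootstrap Youden cutoff %.3f (sens %.2f, spec %.2f)\n",
              boot$youden$cutoff, boot$youden$sensitivity,
              boot$youden$specificity))
  all_metrics[[ps]] <- list(
    predictor_set = predictor_set(ps),
    table = tab,
    youden_cutoff_bootstrap = boot$youden$cutoff,
    min_tests = min(vapply(res$runs,
                           function(r) min(r$per_patient_test_count),
                           numeric(1))))
  pts <- roc_points(boot$per_patient_mean_probability, boot$truth)
  utils::write.csv(pts, sprintf("results/roc_points_%s_bootstrap.csv", ps),
                   row.names = FALSE)
}
jsonlite::write_json(all_metrics, "results/validation_metrics.json",
                     auto_unbox = TRUE, digits = NA, dataframe = "rows")
cat("\nWrote results/validation_metrics.json and ROC point CSVs\n")
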