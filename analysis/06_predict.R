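#!/usr/bin/env Rscript
# Stage 6: brain-to-SES prediction. Stacked block ridge regression with
# five-fold cross-validation builds brain-wide GMV scores for each SES
# component; out-of-sample incremental R2 beyond the covariates is
# reported with percentile-bootstrap confidence intervals.

source("analysis/_common.R")

cohort <- read_cohort(data_file("cohort.tsv"))
volumes <- read_volumes(data_file("volumes"))
scores <- utils::read.delim(data_file("famd_scores.tsv"))
dat <- cbind(cohort$data, scores[, c("PC1", "PC2")])

rows <- lapply(c("PC1", "PC2"), function(tgt) {
  sr <- fit_stacked_ridge(volumes, dat, tgt, k_folds = 5L, seed = 61L)
  ev <- evaluate_delta_r2(sr$predictions, dat, tgt,
                          covariates = c("age", "sex", "site"),
                          n_boot = 500L, seed = 62L)
  message(sprintf("%s: out-of-sample delta R2 = %.1f%% (95%% CI [%.1f, %.1f])",
                  tgt, 100 * ev$delta_r2, 100 * ev$ci[1], 100 * ev$ci[2]))
  data.frame(target = tgt, delta_r2 = ev$delta_r2,
             ci_lo = ev$ci[1], ci_hi = ev$ci[2],
             r2_covariates = ev$r2_covars)
})
write_table(do.call(rbind, rows), result_file("06_prediction.tsv"))
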