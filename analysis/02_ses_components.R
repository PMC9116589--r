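#!/usr/bin/env Rscript
# Stage 2: summarize the mixed SES indicator battery into two components
# by factorial analysis of mixed data (FAMD) and check how well the
# component span recovers the generator's latent factors.

source("analysis/_common.R")

cohort <- read_cohort(data_file("cohort.tsv"))
fm <- fit_famd(cohort$data[, cohort$indicators, drop = FALSE], k = 2L)
scores <- famd_scores(fm)

message(sprintf("eigenvalues: %s (total inertia %.2f)",
                paste(round(fm$eigenvalues[1:4], 2), collapse = ", "),
                sum(fm$eigenvalues)))
message(sprintf("variance explained by the two components: %.1f%%",
                100 * sum(fm$eigenvalues[1:2]) / sum(fm$eigenvalues)))

if (!is.null(cohort$truth)) {
  cap_g <- summary(lm(cohort$truth$G ~ scores))$r.squared
  cap_e <- summary(lm(cohort$truth$E ~ scores))$r.squared
  message(sprintf("latent capture by the component span: G %.2f, E %.2f",
                  cap_g, cap_e))
}

write_table(data.frame(subject_id = cohort$data$subject_id, scores),
            data_file("famd_scores.tsv"))
write_table(data.frame(variable = rownames(fm$squared_loadings),
                       round(fm$squared_loadings, 4)),
            result_file("02_famd_loadings.tsv"))

assoc <- mixed_association_matrix(cohort$data[, cohort$indicators])
write_table(data.frame(variable = rownames(assoc), round(assoc, 3)),
            result_file("02_indicator_associations.tsv"))
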