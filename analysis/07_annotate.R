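#!/usr/bin/env Rscript
# Stage 7: functional annotation. Synthetic concept maps (one embedded
# positive control: a monotone transform of the observed F map) are scored
# by the mean-chi-square difference between nominally significant voxels
# and the rest, with pseudo-T statistics referred to a spatial-
# autocorrelation-preserving surrogate null and BH-FDR flags.

source("analysis/_common.R")

cohort <- read_cohort(data_file("cohort.tsv"))
volumes <- read_volumes(data_file("volumes"))
scores <- utils::read.delim(data_file("famd_scores.tsv"))
dat <- cbind(cohort$data, scores[, c("PC1", "PC2")])
cfg <- read_sim_config(data_file("sim_config.yaml"))

sm <- fit_voxelwise(volumes, dat, vbm_design(c("PC1", "PC2"),
                                             tiv_adjusted = TRUE))
concepts <- generate_concept_maps(cfg, n_concepts = 40L, match_map = sm$f)
en <- enrich(sm, concepts, nominal_alpha = 0.01, n_perm = 500L, seed = 71L)

tab <- en$table[order(en$table$p), ]
message(sprintf("%d/%d concepts significant at FDR 5%%; positive control p = %.4g",
                sum(tab$fdr_sig), nrow(tab), en$table$p[1]))
message("category ordering (mean of top-five concepts): ",
        paste(en$category_order, collapse = " > "))
write_table(tab, result_file("07_enrichment.tsv"))
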