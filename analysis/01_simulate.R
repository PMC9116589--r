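#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort and voxel volumes.
#
# The generator emulates the statistical structure the downstream stages
# assume: latent genetic (G) and environmental (E) factors behind a mixed
# battery of SES indicators, two split-sample polygenic indices at
# reliability 0.5, BMI as a partial mediator (share 0.4) of the
# environmental path, and gray matter volumes whose SES signal carries a
# region-varying genetic share over spatially autocorrelated noise.

source("analysis/_common.R")

cfg <- study_config()
cohort <- generate_cohort(cfg)
volumes <- generate_gmv(cfg, cohort)

write_cohort(cohort, data_file("cohort.tsv"))
write_volumes(volumes, data_file("volumes"))
write_sim_config(cfg, data_file("sim_config.yaml"))

message(sprintf("cohort: %d subjects, %d SES indicators, %d voxels in %d regions",
                cfg$n_subjects, length(cohort$indicators),
                sum(volumes$mask), cfg$n_regions))
message(sprintf("split-sample PGI correlation: %.3f (reliability %.2f)",
                estimate_reliability(cohort), cfg$pgi_reliability))

summary_tab <- data.frame(
  region = seq_len(cfg$n_regions),
  genetic_share = cfg$genetic_share_map,
  effect_size = cfg$effect_size,
  n_voxels = as.integer(table(volumes$region_labels)))
write_table(summary_tab, result_file("01_region_truth.tsv"))
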