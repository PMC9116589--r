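# Shared paths for the analysis drivers. Large intermediates (volumes,
# per-subject tables) live under scratch/; small result tables under
# results/.
library(sesbrain)

paths <- list(
  data = "scratch/analysis",
  results = "results"
)
dir.create(paths$data, recursive = TRUE, showWarnings = FALSE)
dir.create(paths$results, recursive = TRUE, showWarnings = FALSE)

data_file <- function(...) file.path(paths$data, ...)
result_file <- function(...) file.path(paths$results, ...)

write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
}

# the study world all drivers share: a population-imaging-like cohort on a
# 12^3 grid with eight parcels spanning genetic shares 0.05..0.9 and
# heterogeneous effect sizes (two null regions, so nominal-significance
# contrasts are non-degenerate)
study_config <- function() {
  sim_config(n_subjects = 2000L, grid_shape = c(12L, 12L, 12L),
             n_regions = 8L, pgi_reliability = 0.5,
             bmi_mediation_share = 0.4,
             effect_size = c(0.15, 0, 0.12, 0.04, 0, 0.18, 0.02, 0.10),
             noise_correlation_length = 2, seed = 20918L)
}
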