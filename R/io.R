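#' Cohort table I/O (TSV with a YAML schema sidecar)
#'
#' The cohort is written as one row per subject; categorical columns are
#' written as their string level codes, and a YAML sidecar
#' (`<path>.schema.yaml`) records each column's kind so the table round-
#' trips with correct types.
#'
#' @param cohort a `ses_cohort` (truth, if present, is written to
#'   `<path>.truth.tsv`).
#' @param path output TSV path.
#' @export
write_cohort <- function(cohort, path) {
  dat <- cohort_data(cohort)
  kinds <- vapply(dat, function(col)
    if (is.numeric(col)) "numeric" else "categorical", character(1))
  utils::write.table(dat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(columns = as.list(kinds),
                        indicators = cohort$indicators),
                   paste0(path, ".schema.yaml"))
  if (!is.null(cohort$truth))
    utils::write.table(cohort$truth, paste0(path, ".truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  schema <- yaml::read_yaml(paste0(path, ".schema.yaml"))
  dat <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (v in names(schema$columns))
    if (schema$columns[[v]] == "categorical") dat[[v]] <- factor(dat[[v]])
  truth_path <- paste0(path, ".truth.tsv")
  truth <- if (file.exists(truth_path)) utils::read.delim(truth_path) else NULL
  structure(list(data = dat, indicators = unlist(schema$indicators),
                 truth = truth, config = NULL),
            class = "ses_cohort")
}

#' Volume set I/O as NIfTI-1
#'
#' Writes the subjects-by-voxels data as a 4D float32 volume, the mask as
#' 3D uint8 and the region labels as 3D int16, sharing the affine.
#' @param volumes a `ses_volumes` object.
#' @param prefix path prefix; writes `<prefix>_gmv.nii.gz`,
#'   `<prefix>_mask.nii.gz`, `<prefix>_labels.nii.gz`.
#' @export
write_volumes <- function(volumes, prefix) {
  gs <- volumes$grid_shape
  arr4 <- array(t(volumes$data), dim = c(gs, nrow(volumes$data)))
  nii_write(arr4, paste0(prefix, "_gmv.nii.gz"), affine = volumes$affine,
            datatype = "float32")
  nii_write(array(as.integer(volumes$mask), gs), paste0(prefix, "_mask.nii.gz"),
            affine = volumes$affine, datatype = "uint8")
  nii_write(array(as.integer(volumes$region_labels), gs),
            paste0(prefix, "_labels.nii.gz"), affine = volumes$affine,
            datatype = "int16")
  invisible(prefix)
}

#' @rdname write_volumes
#' @export
read_volumes <- function(prefix) {
  g <- nii_read(paste0(prefix, "_gmv.nii.gz"))
  m <- nii_read(paste0(prefix, "_mask.nii.gz"))
  l <- nii_read(paste0(prefix, "_labels.nii.gz"))
  gs <- dim(g$data)[1:3]
  n <- dim(g$data)[4]
  structure(list(data = t(matrix(g$data, prod(gs), n)),
                 mask = array(m$data > 0, gs), affine = g$affine,
                 region_labels = array(as.integer(l$data), gs),
                 grid_shape = gs, truth = NULL),
            class = "ses_volumes")
}

#' Write per-voxel statistic vectors of a stat map as NIfTI volumes
#'
#' @param statmap a [fit_voxelwise()] result.
#' @param prefix output path prefix; one float32 volume per statistic
#'   (`f`, `p`, `partial_r2`, and one per standardized beta).
#' @export
write_stat_map <- function(statmap, prefix) {
  gs <- statmap$grid_shape
  aff <- diag(4)
  put <- function(v, name)
    nii_write(array(v, gs), paste0(prefix, "_", name, ".nii.gz"),
              affine = aff, datatype = "float32")
  put(statmap$f, "F")
  put(statmap$p, "p")
  put(statmap$partial_r2, "partialR2")
  for (j in seq_along(statmap$predictors))
    put(statmap$beta[, j], paste0("beta_", statmap$predictors[j]))
  invisible(prefix)
}

#' Per-region summary of a stat map
#'
#' Mean/max F and partial R-squared and significant-voxel share per region
#' label, at the supplied critical F.
#' @param statmap a [fit_voxelwise()] result.
#' @param f_crit critical F for the significant-voxel share.
#' @export
region_summary <- function(statmap, f_crit = Inf) {
  lab <- as.integer(statmap$region_labels)
  agg <- function(v, f) tapply(v, lab, f)
  data.frame(region = sort(unique(lab)),
             n_voxels = as.integer(table(lab)),
             mean_f = as.numeric(agg(statmap$f, mean)),
             max_f = as.numeric(agg(statmap$f, max)),
             mean_partial_r2 = as.numeric(agg(statmap$partial_r2, mean)),
             frac_significant = as.numeric(agg(statmap$f, function(x)
               mean(x >= f_crit))))
}

#' Simulation config YAML I/O
#' @param config a [sim_config()].
#' @param path YAML path.
#' @export
write_sim_config <- function(config, path) {
  lst <- unclass(config)
  lst$indicator_spec <- lapply(seq_len(nrow(config$indicator_spec)),
                               function(i) as.list(config$indicator_spec[i, ]))
  yaml::write_yaml(lst, path, precision = 12L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  spec <- do.call(rbind, lapply(lst$indicator_spec, function(row)
    as.data.frame(row, stringsAsFactors = FALSE)))
  do.call(sim_config, c(lst[setdiff(names(lst), "indicator_spec")],
                        list(indicator_spec = spec)))
}
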