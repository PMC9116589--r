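#' End-to-end pipeline runner
#'
#' Configuration-driven orchestration of the full inference chain:
#' simulate (optional) -> FAMD of the SES indicators -> VBM of the two SES
#' components (with and without TIV adjustment) -> GIV regression of TIV on
#' the polygenic index -> attenuation decomposition (PGI, then BMI) with
#' cluster shares -> brain-to-SES prediction -> functional annotation.
#' Every stage writes its outputs under `out_dir` and all inter-stage
#' traffic goes through those files; a JSON manifest lists every output
#' with its md5 checksum together with the parameters used.
#'
#' @param config a named list or the path of a YAML file. Recognised
#'   entries: `out_dir` (required), `stages` (named logical toggles:
#'   simulate, famd, vbm, giv, decompose, predict, annotate; default all
#'   TRUE), `sim` (arguments to [sim_config()]), `cohort_path` /
#'   `volumes_prefix` (external inputs when `simulate` is off), `vbm`
#'   (n_perm, alpha, seed, covariates, tiv_adjusted), `predict` (k_folds,
#'   seed, n_boot), `annotate` (n_concepts, nominal_alpha, n_perm, seed).
#' @return the manifest (invisibly), also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  stages <- utils::modifyList(
    list(simulate = TRUE, famd = TRUE, vbm = TRUE, giv = TRUE,
         decompose = TRUE, predict = TRUE, annotate = TRUE),
    config$stages %||% list())

  # validate referenced paths before any compute
  if (!isTRUE(stages$simulate)) {
    if (is.null(config$cohort_path) || !file.exists(config$cohort_path))
      stop("cohort_path missing or not found (simulate stage is off)")
    if (is.null(config$volumes_prefix) ||
        !file.exists(paste0(config$volumes_prefix, "_gmv.nii.gz")))
      stop("volumes_prefix missing or not found (simulate stage is off)")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", ...)
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  outputs <- character(0)
  emit <- function(...) outputs <<- c(outputs, ...)
  stage <- function(name, expr) {
    logmsg("stage ", name, " ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  op <- function(path) file.path(config$out_dir, path)

  cfg <- do.call(sim_config, config$sim %||% list())

  if (isTRUE(stages$simulate)) {
    cohort <- stage("simulate", {
      co <- generate_cohort(cfg)
      vo <- generate_gmv(cfg, co)
      write_cohort(co, op("cohort.tsv"))
      write_volumes(vo, op("volumes"))
      write_sim_config(cfg, op("sim_config.yaml"))
      emit(op("cohort.tsv"), op("cohort.tsv.schema.yaml"),
           op("cohort.tsv.truth.tsv"), op("sim_config.yaml"),
           paste0(op("volumes"), c("_gmv.nii.gz", "_mask.nii.gz",
                                   "_labels.nii.gz")))
      co
    })
    volumes <- read_volumes(op("volumes"))
  } else {
    cohort <- read_cohort(config$cohort_path)
    volumes <- read_volumes(config$volumes_prefix)
  }
  dat <- cohort$data

  if (isTRUE(stages$famd)) {
    dat <- stage("famd", {
      fm <- fit_famd(dat[, cohort$indicators, drop = FALSE], k = 2L)
      sc <- famd_scores(fm)
      utils::write.table(data.frame(subject_id = dat$subject_id, sc),
                         op("famd_scores.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(data.frame(variable = rownames(fm$squared_loadings),
                                    fm$squared_loadings),
                         op("famd_loadings.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit(op("famd_scores.tsv"), op("famd_loadings.tsv"))
      logmsg("famd eigenvalues: ",
             paste(round(fm$eigenvalues[1:2], 3), collapse = ", "))
      cbind(dat, sc)
    })
  }

  vbm_cfg <- utils::modifyList(
    list(n_perm = 500L, alpha = 0.05, seed = 1L,
         covariates = c("age", "sex", "site"), tiv_adjusted = TRUE),
    config$vbm %||% list())
  design <- vbm_design(c("PC1", "PC2"), covariates = vbm_cfg$covariates,
                       tiv_adjusted = vbm_cfg$tiv_adjusted)
  statmap <- NULL; fwe <- NULL; clus <- NULL

  if (isTRUE(stages$vbm)) {
    vbm_out <- stage("vbm", {
      sm <- fit_voxelwise(volumes, dat, design)
      fw <- permutation_fwe_threshold(volumes, dat, design,
                                      n_perm = vbm_cfg$n_perm,
                                      alpha = vbm_cfg$alpha,
                                      seed = vbm_cfg$seed)
      write_stat_map(sm, op("vbm"))
      utils::write.table(region_summary(sm, fw$f_crit), op("vbm_regions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(f_crit = fw$f_crit, p_crit = fw$p_crit,
                                n_perm = fw$n_perm, alpha = fw$alpha),
                           op("vbm_fwe.json"), auto_unbox = TRUE, digits = NA)
      emit(paste0(op("vbm"), c("_F.nii.gz", "_p.nii.gz", "_partialR2.nii.gz",
                               "_beta_PC1.nii.gz", "_beta_PC2.nii.gz")),
           op("vbm_regions.tsv"), op("vbm_fwe.json"))
      logmsg("vbm: ", sum(sm$f >= fw$f_crit), "/", length(sm$f),
             " voxels significant at FWE ", vbm_cfg$alpha)
      list(sm = sm, fw = fw)
    })
    statmap <- vbm_out$sm
    fwe <- vbm_out$fw
    clus <- form_clusters(statmap, fwe$f_crit)
  }

  if (isTRUE(stages$giv)) {
    stage("giv", {
      gv <- fit_giv(dat, "tiv", covariates = vbm_cfg$covariates)
      utils::write.table(
        data.frame(naive_beta = gv$naive_beta, naive_se = gv$naive_se,
                   giv_beta = gv$giv_beta, giv_se = gv$giv_se,
                   first_stage_f = gv$first_stage_f,
                   implied_reliability = gv$implied_reliability),
        op("giv_tiv.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      emit(op("giv_tiv.tsv"))
    })
  }

  if (isTRUE(stages$decompose) && !is.null(statmap)) {
    stage("decompose", {
      att <- bmi_residual_attribution(volumes, dat, design)
      gs <- volumes$grid_shape
      nii_write(array(att$pct_reduction_pgi, gs),
                op("pct_reduction_pgi.nii.gz"))
      nii_write(array(att$pct_reduction_bmi_residual, gs),
                op("pct_reduction_bmi.nii.gz"))
      wd <- wald_change_test(volumes, dat, design)
      nii_write(array(wd$min_p, gs), op("wald_min_p.nii.gz"))
      sig <- statmap$f >= fwe$f_crit
      summ <- attenuation_summary(att, voxels = sig & !att$undefined)
      utils::write.table(summ, op("attenuation_summary.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      if (length(clus$members)) {
        shares <- cluster_shares(volumes, dat, design, clus)
        utils::write.table(shares, op("cluster_shares.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        emit(op("cluster_shares.tsv"))
      }
      emit(op("pct_reduction_pgi.nii.gz"), op("pct_reduction_bmi.nii.gz"),
           op("wald_min_p.nii.gz"), op("attenuation_summary.tsv"))
    })
  }

  if (isTRUE(stages$predict)) {
    pred_cfg <- utils::modifyList(list(k_folds = 5L, seed = 1L, n_boot = 500L),
                                  config$predict %||% list())
    stage("predict", {
      sr <- fit_stacked_ridge(volumes, dat, "PC1", k_folds = pred_cfg$k_folds,
                              seed = pred_cfg$seed)
      ev <- evaluate_delta_r2(sr$predictions, dat, "PC1",
                              covariates = vbm_cfg$covariates,
                              n_boot = pred_cfg$n_boot, seed = pred_cfg$seed)
      utils::write.table(data.frame(subject_id = dat$subject_id,
                                    prediction = sr$predictions),
                         op("prediction_oof.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      jsonlite::write_json(list(delta_r2 = ev$delta_r2, ci = ev$ci,
                                n_boot = ev$n_boot),
                           op("prediction_delta_r2.json"), digits = NA,
                           auto_unbox = TRUE)
      emit(op("prediction_oof.tsv"), op("prediction_delta_r2.json"))
      logmsg("prediction delta R2 = ", round(ev$delta_r2, 4))
    })
  }

  if (isTRUE(stages$annotate) && !is.null(statmap)) {
    ann_cfg <- utils::modifyList(list(n_concepts = 20L, nominal_alpha = 0.01,
                                      n_perm = 200L, seed = 1L),
                                 config$annotate %||% list())
    stage("annotate", {
      cm <- generate_concept_maps(cfg, ann_cfg$n_concepts)
      en <- enrich(statmap, cm, nominal_alpha = ann_cfg$nominal_alpha,
                   n_perm = ann_cfg$n_perm, seed = ann_cfg$seed)
      utils::write.table(en$table, op("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit(op("enrichment.tsv"))
    })
  }

  manifest <- list(
    created = format(Sys.time()),
    package_version = as.character(utils::packageVersion("sesbrain")),
    parameters = list(sim = unclass(cfg)[setdiff(names(unclass(cfg)),
                                                 "indicator_spec")],
                      vbm = vbm_cfg, stages = stages),
    outputs = lapply(outputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg("pipeline complete: ", length(outputs), " outputs")
  invisible(manifest)
}
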