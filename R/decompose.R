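# Shared engine for the three-model attenuation decomposition.
#
# Models (per outcome column of Y):
#   before:    Y ~ covariates + SES components
#   after_pgi: Y ~ covariates + PGI + SES components
#   after_bmi: Y ~ covariates + PGI + BMI + SES components
# The association metric is the joint partial R^2 of the SES components in
# each model. With `use_giv`, the PGI enters as its first-stage fitted value
# (instrumented by the second split-sample index, first stage including the
# covariates and SES components), which is the 2SLS second stage: the SES
# coefficients conditional on the *true* genetic value are then estimated
# consistently, so the PGI-attributable share is disattenuated.
attenuation_core <- function(Y, data, design, use_giv = TRUE,
                             pgi = "pgi_1", instrument = "pgi_2",
                             bmi = "bmi", include_bmi = TRUE,
                             floor_r2 = 1e-6) {
  dm <- build_design(data, design)
  n <- nrow(Y)
  S <- dm$Xi; C <- dm$C
  x <- data[[pgi]]
  if (is.null(x)) stop("pgi column not found: ", pgi)
  if (use_giv) {
    z <- data[[instrument]]
    if (is.null(z)) stop("instrument column not found: ", instrument)
    x <- stats::lm.fit(cbind(C, S, z), x)$fitted.values
  }

  partial_r2_block <- function(base) {
    qrB <- qr(base)
    Yr <- qr.resid(qrB, Y)
    Sr <- qr.resid(qrB, S)
    Q <- qr.Q(qr(Sr))
    TSS <- colSums(Yr^2)
    SSR <- colSums((crossprod(Q, Yr))^2)
    ifelse(TSS > 0, pmin(SSR / TSS, 1), 0)
  }

  before <- partial_r2_block(C)
  after_pgi <- partial_r2_block(cbind(C, x))
  out <- list(assoc_before = before, assoc_after_pgi = after_pgi,
              undefined = before < floor_r2)
  out$pct_reduction_pgi <-
    ifelse(out$undefined, NA_real_, 100 * (before - after_pgi) / before)
  if (include_bmi) {
    b <- data[[bmi]]
    if (is.null(b)) stop("bmi column not found: ", bmi)
    after_bmi <- partial_r2_block(cbind(C, x, b))
    out$assoc_after_pgi_bmi <- after_bmi
    out$undefined_bmi <- after_pgi < floor_r2
    out$pct_reduction_bmi_residual <-
      ifelse(out$undefined_bmi, NA_real_,
             100 * (after_pgi - after_bmi) / after_pgi)
  }
  out
}

#' Attenuation of SES-GMV associations by polygenic-index control
#'
#' Compares the joint partial R-squared of the SES components per voxel
#' before and after a polygenic index is controlled for, reporting the
#' percent reduction. With `use_giv = TRUE` the index enters as its
#' instrumented (first-stage fitted) version, so the control is corrected
#' for measurement error; with `use_giv = FALSE` the raw index is used and
#' the attributable share attenuates by roughly the index reliability.
#' Percent reductions are reported raw (they can fall outside [0, 100] by
#' sampling noise); voxels whose before-association is below `floor_r2`
#' are flagged undefined and excluded from summaries.
#'
#' @inheritParams fit_voxelwise
#' @param use_giv correct PGI measurement error via the instrument.
#' @param pgi,instrument,bmi column names in the cohort table.
#' @param include_bmi also fit the third model adding BMI and report the
#'   percent of the residual (post-PGI) association removed.
#' @param floor_r2 undefined-denominator floor for percent reductions.
#' @return object of class `attenuation_result` with per-voxel vectors:
#'   `assoc_before`, `assoc_after_pgi`, `assoc_after_pgi_bmi`,
#'   `pct_reduction_pgi`, `pct_reduction_bmi_residual`, `undefined` flags.
#' @export
attenuation_by_pgi <- function(volumes, cohort, design, use_giv = TRUE,
                               pgi = "pgi_1", instrument = "pgi_2",
                               bmi = "bmi", include_bmi = FALSE,
                               floor_r2 = 1e-6) {
  data <- cohort_data(cohort)
  out <- attenuation_core(volumes$data, data, design, use_giv = use_giv,
                          pgi = pgi, instrument = instrument, bmi = bmi,
                          include_bmi = include_bmi, floor_r2 = floor_r2)
  out$grid_shape <- volumes$grid_shape
  out$region_labels <- volumes$region_labels
  class(out) <- "attenuation_result"
  out
}

#' BMI attribution in the residual (post-PGI) SES-GMV association
#'
#' Adds BMI to the PGI-controlled model and reports which percent of the
#' SES association remaining after polygenic control is removed.
#' @inheritParams attenuation_by_pgi
#' @export
bmi_residual_attribution <- function(volumes, cohort, design, use_giv = TRUE,
                                     pgi = "pgi_1", instrument = "pgi_2",
                                     bmi = "bmi", floor_r2 = 1e-6) {
  attenuation_by_pgi(volumes, cohort, design, use_giv = use_giv, pgi = pgi,
                     instrument = instrument, bmi = bmi, include_bmi = TRUE,
                     floor_r2 = floor_r2)
}

#' Summarize percent attributions over a voxel selection
#'
#' Mean / min / max of the percent reductions over the selected voxels
#' (default: all defined voxels), excluding flagged undefined entries —
#' the convention used when averaging attribution maps over voxels
#' significant in the before-model.
#'
#' @param att an [attenuation_by_pgi()] result.
#' @param voxels optional logical/integer voxel selection.
#' @export
attenuation_summary <- function(att, voxels = NULL) {
  sel <- if (is.null(voxels)) rep(TRUE, length(att$assoc_before)) else voxels
  row_for <- function(name, v) {
    v <- v[sel]
    v <- v[!is.na(v)]
    if (!length(v))
      return(data.frame(metric = name, mean = NA_real_, min = NA_real_,
                        max = NA_real_, n_voxels = 0L))
    data.frame(metric = name, mean = mean(v), min = min(v), max = max(v),
               n_voxels = length(v))
  }
  out <- row_for("pct_reduction_pgi", att$pct_reduction_pgi)
  if (!is.null(att$pct_reduction_bmi_residual))
    out <- rbind(out, row_for("pct_reduction_bmi_residual",
                              att$pct_reduction_bmi_residual))
  out
}

#' Wald test for the change in SES coefficients after adding controls
#'
#' Tests, per voxel and per SES component, whether the standardized
#' coefficient changes significantly when control columns (by default the
#' polygenic index) are added. Both coefficient vectors are linear
#' functionals of the same outcome, so the difference variance comes from
#' the joint coefficient covariance (homoskedastic plug-in with the
#' after-model residual variance; `robust = TRUE` switches to an HC0
#' sandwich). Two-sided normal p-values per component.
#'
#' @inheritParams fit_voxelwise
#' @param controls character vector of columns added in the after-model.
#' @param use_giv instrument the first control column (assumed to be the
#'   PGI) with `instrument` before adding it.
#' @param instrument instrument column used when `use_giv`.
#' @param robust use an HC0 sandwich for the difference variance.
#' @return list with matrices `delta` (voxels x components: beta_before -
#'   beta_after), `z`, `p`, and `min_p` per voxel.
#' @export
wald_change_test <- function(volumes, cohort, design, controls = "pgi_1",
                             use_giv = FALSE, instrument = "pgi_2",
                             robust = FALSE) {
  data <- cohort_data(cohort)
  Y <- volumes$data
  Yz <- scale(Y)
  dm <- build_design(data, design)
  n <- nrow(Y); S <- dm$Xi; C <- dm$C; q <- ncol(S)
  X_ctrl <- as.matrix(data[, controls, drop = FALSE])
  if (use_giv) {
    z <- data[[instrument]]
    X_ctrl[, 1] <- stats::lm.fit(cbind(C, S, z), X_ctrl[, 1])$fitted.values
  }
  Xb <- cbind(C, S)
  Xa <- cbind(C, X_ctrl, S)
  if (qr(Xa)$rank < ncol(Xa)) stop("singular joint design (after-model)")
  idx_b <- ncol(C) + seq_len(q)
  idx_a <- ncol(C) + ncol(X_ctrl) + seq_len(q)
  # hat rows a_j' such that beta_j = a_j' y
  Ab <- (chol2inv(chol(crossprod(Xb))) %*% t(Xb))[idx_b, , drop = FALSE]
  Aa <- (chol2inv(chol(crossprod(Xa))) %*% t(Xa))[idx_a, , drop = FALSE]
  D <- Ab - Aa                              # q x n contrast rows
  delta <- t(D %*% Yz)                      # voxels x q
  qrA <- qr(Xa)
  res_a <- qr.resid(qrA, Yz)
  if (robust) {
    se2 <- t((D^2) %*% (res_a^2))           # HC0: sum_i d_ji^2 e_i^2
  } else {
    sigma2 <- colSums(res_a^2) / (n - ncol(Xa))
    se2 <- outer(sigma2, rowSums(D^2))
  }
  zstat <- delta / sqrt(se2)
  pmat <- 2 * stats::pnorm(abs(zstat), lower.tail = FALSE)
  colnames(delta) <- colnames(zstat) <- colnames(pmat) <- design$predictors
  list(delta = delta, z = zstat, p = pmat,
       min_p = apply(pmat, 1, min))
}

#' Cluster-level genetic/environmental share table
#'
#' For each cluster, the per-subject mean GMV over member voxels is taken
#' as a scalar outcome and the three-model decomposition is rerun on it.
#' Reports the partial R-squared attributable to the PGI, to BMI partialled
#' out of the PGI, and the residual, plus their percent shares of the
#' before-association (the three parts sum to the before-association
#' identically).
#'
#' @inheritParams attenuation_by_pgi
#' @param clusters a [form_clusters()] result.
#' @return data frame, one row per cluster.
#' @export
cluster_shares <- function(volumes, cohort, design, clusters, use_giv = TRUE,
                           pgi = "pgi_1", instrument = "pgi_2", bmi = "bmi") {
  if (!length(clusters$members))
    return(data.frame())
  data <- cohort_data(cohort)
  Yc <- vapply(clusters$members, function(idx)
    rowMeans(volumes$data[, idx, drop = FALSE]), numeric(nrow(volumes$data)))
  att <- attenuation_core(Yc, data, design, use_giv = use_giv, pgi = pgi,
                          instrument = instrument, bmi = bmi,
                          include_bmi = TRUE)
  before <- att$assoc_before
  part_pgi <- before - att$assoc_after_pgi
  part_bmi <- att$assoc_after_pgi - att$assoc_after_pgi_bmi
  resid <- att$assoc_after_pgi_bmi
  data.frame(cluster = clusters$table$cluster,
             size = clusters$table$size,
             assoc_before = before,
             r2_pgi = part_pgi, r2_bmi = part_bmi, r2_residual = resid,
             share_pgi = 100 * part_pgi / before,
             share_bmi = 100 * part_bmi / before,
             share_residual = 100 * resid / before)
}
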