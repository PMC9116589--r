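#' Design specification for mass-univariate regressions
#'
#' Names the predictors-of-interest (tested jointly by F test) and the
#' covariates. Categorical covariates are expanded to dummies at fit time;
#' predictors-of-interest must be numeric and are z-scored before fitting
#' (standardized-beta convention; covariates are left unscaled).
#'
#' @param predictors character vector of predictor-of-interest column names
#'   (e.g. the two SES components, or a polygenic index).
#' @param covariates character vector of covariate column names.
#' @param tiv_adjusted if TRUE, `tiv` is appended to the covariates.
#' @return object of class `vbm_design`.
#' @export
vbm_design <- function(predictors, covariates = c("age", "sex", "site"),
                       tiv_adjusted = FALSE) {
  if (tiv_adjusted && !("tiv" %in% covariates)) covariates <- c(covariates, "tiv")
  if (length(intersect(predictors, covariates)))
    stop("predictor and covariate sets must be disjoint")
  structure(list(predictors = predictors, covariates = covariates,
                 tiv_adjusted = tiv_adjusted), class = "vbm_design")
}

cohort_data <- function(cohort) {
  if (inherits(cohort, "ses_cohort")) cohort$data else as.data.frame(cohort)
}

# Assemble covariate matrix (with intercept, factors expanded) and z-scored
# predictor-of-interest matrix; checks joint full rank.
build_design <- function(data, design) {
  miss <- setdiff(c(design$predictors, design$covariates), names(data))
  if (length(miss)) stop("columns not found: ", paste(miss, collapse = ", "))
  fml <- stats::as.formula(paste("~", paste(c("1", design$covariates),
                                            collapse = " + ")))
  C <- stats::model.matrix(fml, data = data)
  Xi <- as.matrix(data[, design$predictors, drop = FALSE])
  if (!is.numeric(Xi)) stop("predictors-of-interest must be numeric")
  Xi <- scale(Xi)
  X <- cbind(C, Xi)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  list(C = C, Xi = Xi)
}

#' Voxelwise OLS with joint F tests and partial R-squared
#'
#' Regresses each voxel's gray matter volume on the predictors-of-interest
#' plus covariates and tests the predictors jointly with a nested-model F
#' test: F = ((SSE_reduced - SSE_full)/q) / (SSE_full/(n - p)), where the
#' reduced model drops all predictors-of-interest. Partial R-squared is
#' (SSE_reduced - SSE_full)/SSE_reduced. Coefficients are standardized
#' (outcome and predictors z-scored).
#'
#' @param volumes a `ses_volumes` object (or list with `data` matrix and
#'   `region_labels`/`mask`/`grid_shape`).
#' @param cohort `ses_cohort` or data frame aligned to the volume rows.
#' @param design a [vbm_design()].
#' @param subset optional logical/integer subject subset (subgroup VBM).
#' @return object of class `stat_map`: per-voxel standardized coefficients,
#'   F, uncorrected p, partial R-squared; degrees of freedom, grid metadata
#'   and region labels.
#' @export
fit_voxelwise <- function(volumes, cohort, design, subset = NULL) {
  data <- cohort_data(cohort)
  Y <- volumes$data
  stopifnot(nrow(data) == nrow(Y))
  if (!is.null(subset)) {
    data <- data[subset, , drop = FALSE]
    Y <- Y[subset, , drop = FALSE]
    if (is.factor(data$site)) data$site <- droplevels(data$site)
  }
  n <- nrow(Y)
  dm <- build_design(data, design)
  q <- ncol(dm$Xi); p <- ncol(dm$C) + q
  if (n <= p + 1L) stop("too few subjects (n = ", n, ") for ", p, " parameters")

  qrC <- qr(dm$C)
  Yr <- qr.resid(qrC, Y)
  Yz <- scale(Y)
  Yzr <- qr.resid(qrC, Yz)
  Xr <- qr.resid(qrC, dm$Xi)
  qrX <- qr(Xr)
  Qx <- qr.Q(qrX)

  TSSr <- colSums(Yr^2)
  SSR <- colSums((crossprod(Qx, Yr))^2)
  SSE <- pmax(TSSr - SSR, 0)
  # voxels whose outcome lies (numerically) in the covariate span carry no
  # testable variation: report zero association rather than 0/0 noise
  tot <- colSums(sweep(Y, 2, colMeans(Y))^2)
  degen <- TSSr <= tot * 1e-12 | tot == 0
  partial_r2 <- ifelse(degen, 0, SSR / TSSr)
  df2 <- n - p
  Fstat <- ifelse(degen, 0, (SSR / q) / (SSE / df2))
  pval <- stats::pf(Fstat, q, df2, lower.tail = FALSE)
  beta <- qr.coef(qrX, Yzr)            # standardized betas via FWL
  rownames(beta) <- design$predictors

  structure(list(beta = t(beta), f = Fstat, p = pval,
                 partial_r2 = partial_r2, q = q, df2 = df2, n = n,
                 predictors = design$predictors, design = design,
                 grid_shape = volumes$grid_shape, mask = volumes$mask,
                 region_labels = volumes$region_labels),
            class = "stat_map")
}

#' Subgroup voxelwise regression
#'
#' [fit_voxelwise()] restricted to a subject subset (e.g. a low- or
#' high-SES stratum).
#' @inheritParams fit_voxelwise
#' @param subgroup logical or integer subject selector.
#' @export
subgroup_vbm <- function(volumes, cohort, design, subgroup) {
  n_sub <- if (is.logical(subgroup)) sum(subgroup) else length(subgroup)
  data <- cohort_data(cohort)
  dm <- tryCatch(build_design(data, design), error = function(e) NULL)
  p_guess <- if (is.null(dm)) length(design$predictors) + length(design$covariates) + 1L
             else ncol(dm$C) + ncol(dm$Xi)
  if (n_sub < p_guess + 2L)
    stop("subgroup too small (", n_sub, " subjects for ", p_guess, " parameters)")
  fit_voxelwise(volumes, cohort, design, subset = subgroup)
}

#' Max-statistic permutation threshold for family-wise error control
#'
#' Freedman-Lane scheme: the outcome and the predictors-of-interest are
#' residualized on the covariates; the residualized predictor rows are
#' permuted jointly, re-residualized, and the voxelwise joint F is refit;
#' the maximum F over voxels is recorded per permutation. The returned
#' critical F is the k-th largest max-F with k = floor(alpha * (n_perm+1)),
#' which controls the family-wise error rate at `alpha`; it is also
#' converted to the equivalent uncorrected p threshold.
#'
#' @inheritParams fit_voxelwise
#' @param n_perm number of permutations (>= 100).
#' @param alpha target family-wise error rate; must be >= 1/(n_perm + 1).
#' @param seed integer seed for the permutation stream.
#' @return list with `f_crit`, `p_crit` (uncorrected-p scale), `max_f`
#'   (null max-F draws), `n_perm`, `alpha`, and `fwe_p(f)` giving the
#'   FWE-corrected p for an observed max F.
#' @export
permutation_fwe_threshold <- function(volumes, cohort, design, n_perm = 1000L,
                                      alpha = 0.05, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (alpha < 1 / (n_perm + 1))
    stop("alpha below permutation resolution 1/(n_perm + 1)")
  data <- cohort_data(cohort)
  Y <- volumes$data
  n <- nrow(Y)
  dm <- build_design(data, design)
  q <- ncol(dm$Xi); p <- ncol(dm$C) + q; df2 <- n - p

  qrC <- qr(dm$C)
  Yr <- qr.resid(qrC, Y)
  Xr <- qr.resid(qrC, dm$Xi)
  TSSr <- colSums(Yr^2)

  max_f <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      Xp <- Xr[sample.int(n), , drop = FALSE]
      Xp <- qr.resid(qrC, Xp)
      Qp <- qr.Q(qr(Xp))
      SSR <- colSums((crossprod(Qp, Yr))^2)
      Fb <- (SSR / q) / (pmax(TSSr - SSR, 0) / df2)
      max(Fb)
    }, numeric(1))
  })
  k <- floor(alpha * (n_perm + 1))
  sorted <- sort(max_f, decreasing = TRUE)
  f_crit <- sorted[k]
  list(f_crit = f_crit,
       p_crit = stats::pf(f_crit, q, df2, lower.tail = FALSE),
       max_f = max_f, n_perm = n_perm, alpha = alpha, q = q, df2 = df2,
       fwe_p = function(f) (1 + sum(max_f >= f)) / (n_perm + 1))
}

#' Scalar-outcome regression with standardized coefficients
#'
#' Single-outcome analogue of [fit_voxelwise()] (e.g. total intracranial
#' volume regressed on the SES components): standardized betas with 95%
#' confidence intervals per predictor-of-interest, plus their joint F and
#' partial R-squared.
#'
#' @inheritParams fit_voxelwise
#' @param outcome name of the outcome column.
#' @export
scalar_outcome_regression <- function(cohort, outcome, design) {
  data <- cohort_data(cohort)
  if (!outcome %in% names(data)) stop("outcome column not found: ", outcome)
  y <- as.numeric(scale(data[[outcome]]))
  dm <- build_design(data, design)
  n <- length(y); q <- ncol(dm$Xi); p <- ncol(dm$C) + q
  if (n <= p + 1L) stop("too few subjects")
  X <- cbind(dm$C, dm$Xi)
  fit <- stats::lm.fit(X, y)
  sigma2 <- sum(fit$residuals^2) / (n - p)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtXinv))
  idx <- ncol(dm$C) + seq_len(q)
  est <- fit$coefficients[idx]; ses <- se[idx]
  tcrit <- stats::qt(0.975, n - p)

  qrC <- qr(dm$C)
  yr <- qr.resid(qrC, y)
  Qx <- qr.Q(qr(qr.resid(qrC, dm$Xi)))
  SSR <- sum((crossprod(Qx, yr))^2); TSSr <- sum(yr^2)
  Fj <- (SSR / q) / ((TSSr - SSR) / (n - p))

  data.frame(term = design$predictors, beta = unname(est), se = unname(ses),
             ci_lo = unname(est - tcrit * ses), ci_hi = unname(est + tcrit * ses),
             t = unname(est / ses),
             p = unname(2 * stats::pt(abs(est / ses), n - p, lower.tail = FALSE)),
             joint_f = Fj, joint_partial_r2 = SSR / TSSr,
             stringsAsFactors = FALSE)
}

#' Minimal detectable partial R-squared for a joint F test
#'
#' Smallest partial R-squared whose noncentral-F power at significance
#' `alpha` reaches `power`, for a joint test with `q` numerator degrees of
#' freedom in a model with `p_covariates` covariates (plus intercept).
#' The noncentrality is lambda = f^2 * (n - p) with f^2 = R2/(1 - R2) and
#' p = p_covariates + q + 1 (denominator-df convention; at cohort-scale n
#' the distinction from f^2 * n is below reporting precision). Solved by
#' bisection to 1e-8.
#'
#' @param n sample size.
#' @param q numerator degrees of freedom (number of jointly tested
#'   predictors).
#' @param p_covariates number of covariate columns beyond the intercept.
#' @param alpha significance level of the test.
#' @param power target power.
#' @return the minimal partial R-squared (fraction, not percent).
#' @export
minimal_detectable_r2 <- function(n, q, p_covariates = 0L, alpha, power) {
  stopifnot(n > p_covariates + q + 1L, alpha > 0, alpha < 1,
            power > 0, power < 1)
  df2 <- n - p_covariates - q - 1L
  fcrit <- stats::qf(1 - alpha, q, df2)
  pw <- function(r2) {
    f2 <- r2 / (1 - r2)
    stats::pf(fcrit, q, df2, ncp = f2 * df2, lower.tail = FALSE)
  }
  if (pw(0.999) < power) stop("requested power unattainable")
  lo <- 0; hi <- 0.999
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (pw(mid) < power) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Clusters of supra-threshold voxels (26-connectivity)
#'
#' Connected components of voxels with F at or above the threshold, using
#' 26-neighborhood connectivity; clusters are sorted by size (descending),
#' ties broken by peak F. Each cluster carries its member voxel indices,
#' peak coordinate, size and majority region label.
#'
#' @param statmap a [fit_voxelwise()] result.
#' @param f_threshold critical F (e.g. from [permutation_fwe_threshold()]).
#' @return object of class `cluster_set`: list with `table` (one row per
#'   cluster) and `members` (list of voxel index vectors).
#' @export
form_clusters <- function(statmap, f_threshold) {
  supra <- which(statmap$f >= f_threshold & as.vector(statmap$mask))
  if (!length(supra))
    return(structure(list(table = data.frame(), members = list()),
                     class = "cluster_set"))
  gs <- statmap$grid_shape
  coords <- arrayInd(supra, gs)
  key <- function(xyz) (xyz[, 3] - 1) * gs[1] * gs[2] + (xyz[, 2] - 1) * gs[1] + xyz[, 1]
  lookup <- new.env(hash = TRUE)
  for (i in seq_along(supra)) assign(as.character(supra[i]), i, envir = lookup)

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  edges <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= gs[1] & nb[, 2] >= 1 & nb[, 2] <= gs[2] &
      nb[, 3] >= 1 & nb[, 3] <= gs[3]
    if (!any(ok)) next
    nb_lin <- key(nb[ok, , drop = FALSE])
    src <- which(ok)
    hit <- vapply(as.character(nb_lin), function(s)
      if (exists(s, envir = lookup, inherits = FALSE))
        get(s, envir = lookup) else NA_integer_, integer(1))
    keep <- !is.na(hit)
    edges <- c(edges, rbind(src[keep], hit[keep]))
  }
  g <- igraph::make_graph(edges = edges, n = length(supra), directed = FALSE)
  comp <- igraph::components(g)

  tab <- do.call(rbind, lapply(seq_len(comp$no), function(cl) {
    idx <- supra[comp$membership == cl]
    fv <- statmap$f[idx]
    peak <- idx[which.max(fv)]
    lab <- if (!is.null(statmap$region_labels)) {
      labs <- statmap$region_labels[idx]
      as.integer(names(sort(table(labs), decreasing = TRUE))[1])
    } else NA_integer_
    data.frame(size = length(idx), peak_f = max(fv),
               peak_x = arrayInd(peak, gs)[1], peak_y = arrayInd(peak, gs)[2],
               peak_z = arrayInd(peak, gs)[3], region_label = lab)
  }))
  ord <- order(-tab$size, -tab$peak_f)
  members <- lapply(seq_len(comp$no), function(cl) supra[comp$membership == cl])
  tab <- tab[ord, , drop = FALSE]
  tab$cluster <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab[, c("cluster", "size", "peak_f", "peak_x",
                                 "peak_y", "peak_z", "region_label")],
                 members = members[ord]),
            class = "cluster_set")
}
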