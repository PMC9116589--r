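# Closed-form ridge solves along a penalty grid via one SVD of the
# (column-centered) training block. Returns a voxels x n_lambda coefficient
# matrix plus the centering needed to predict.
ridge_solve <- function(X, y, lambdas) {
  xc <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xc); yc <- y - ym
  sv <- svd(Xc, nu = min(dim(Xc)), nv = min(dim(Xc)))
  uty <- crossprod(sv$u, yc)
  B <- vapply(lambdas, function(l)
    as.numeric(sv$v %*% (sv$d / (sv$d^2 + l) * uty)), numeric(ncol(X)))
  list(beta = B, x_center = xc, y_mean = ym)
}

ridge_predict <- function(fit, X, j = NULL) {
  B <- if (is.null(j)) fit$beta else fit$beta[, j, drop = FALSE]
  sweep(X, 2, fit$x_center) %*% B + fit$y_mean
}

nnls_weights <- function(Z, y) {
  k <- ncol(Z)
  Zc <- scale(Z, scale = FALSE); yc <- y - mean(y)
  D <- crossprod(Zc) + diag(1e-8, k)
  d <- crossprod(Zc, yc)
  sol <- quadprog::solve.QP(D, d, diag(k), rep(0, k))$solution
  pmax(sol, 0)
}

#' Stacked block ridge regression with cross-validated out-of-sample scores
#'
#' Predicts a scalar target (an SES component) from brain-wide voxel
#' volumes: voxels are partitioned into blocks (by default the region
#' parcellation), a ridge regression is fit per block with its penalty
#' chosen by inner cross-validation over a log-spaced grid, block-level
#' predictions are generated cross-fitted within each outer training fold,
#' and a nonnegative-least-squares stacker combines them. Outer-fold
#' predictions are fully out-of-sample: no subject contributes to any model
#' that scores it.
#'
#' @inheritParams fit_voxelwise
#' @param target target column name in the cohort, or a numeric vector.
#' @param blocks list of voxel index vectors partitioning the in-mask
#'   voxels; default: the volumes' region labels.
#' @param k_folds number of outer folds (>= 2).
#' @param seed seed for fold assignment.
#' @param lambdas ridge penalty grid (default 10^-3..10^3, 13 points).
#' @param inner_folds folds for the within-training penalty selection.
#' @return object of class `stacked_ridge`: out-of-fold `predictions`,
#'   fold assignment, per-fold chosen penalties and stacker weights.
#' @export
fit_stacked_ridge <- function(volumes, cohort, target, blocks = NULL,
                              k_folds = 5L, seed = 1L,
                              lambdas = 10^seq(-3, 3, length.out = 13),
                              inner_folds = 5L) {
  data <- cohort_data(cohort)
  y <- if (is.character(target)) data[[target]] else as.numeric(target)
  if (is.null(y)) stop("target column not found")
  if (stats::sd(y) == 0) stop("degenerate target: zero variance")
  if (k_folds < 2L) stop("k_folds must be >= 2")
  Y <- volumes$data
  n <- nrow(Y)
  if (is.null(blocks)) {
    labs <- as.integer(volumes$region_labels)[as.vector(volumes$mask)]
    blocks <- split(seq_len(ncol(Y)), labs)
  }
  if (any(lengths(blocks) == 0L)) stop("block with zero voxels")
  nb <- length(blocks)

  with_seed(seed, {
    fold <- sample(rep_len(seq_len(k_folds), n))
    oof <- rep(NA_real_, n)
    fold_info <- vector("list", k_folds)
    for (f in seq_len(k_folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      y_tr <- y[tr]; n_tr <- length(tr)
      ifold <- sample(rep_len(seq_len(inner_folds), n_tr))
      P <- matrix(NA_real_, n_tr, nb)        # cross-fitted block predictions
      lam_star <- numeric(nb)
      block_fit <- vector("list", nb)
      for (b in seq_len(nb)) {
        Xb <- Y[tr, blocks[[b]], drop = FALSE]
        Pl <- matrix(NA_real_, n_tr, length(lambdas))
        for (g in seq_len(inner_folds)) {
          itr <- ifold != g
          fitg <- ridge_solve(Xb[itr, , drop = FALSE], y_tr[itr], lambdas)
          Pl[!itr, ] <- ridge_predict(fitg, Xb[!itr, , drop = FALSE])
        }
        mse <- colMeans((Pl - y_tr)^2)
        j <- which.min(mse)
        lam_star[b] <- lambdas[j]
        P[, b] <- Pl[, j]
        block_fit[[b]] <- ridge_solve(Xb, y_tr, lambdas[j])
      }
      w <- nnls_weights(P, y_tr)
      a <- mean(y_tr) - sum(w * colMeans(P))
      Pte <- vapply(seq_len(nb), function(b)
        as.numeric(ridge_predict(block_fit[[b]],
                                 Y[te, blocks[[b]], drop = FALSE])), numeric(length(te)))
      oof[te] <- a + as.numeric(Pte %*% w)
      fold_info[[f]] <- list(lambda = lam_star, weights = w, intercept = a)
    }
    structure(list(predictions = oof, fold = fold, blocks = blocks,
                   folds = fold_info, k_folds = k_folds, lambdas = lambdas,
                   target = if (is.character(target)) target else "target"),
              class = "stacked_ridge")
  })
}

#' Out-of-sample incremental R-squared with bootstrap confidence interval
#'
#' Delta R^2 = R^2(target ~ covariates + prediction) - R^2(target ~
#' covariates), both fit on the out-of-fold predictions, with a percentile
#' bootstrap over subjects for the 95% CI.
#'
#' @param predictions out-of-fold prediction vector (aligned to subjects).
#' @param cohort cohort table supplying target and covariates.
#' @param target target column name, or numeric vector.
#' @param covariates covariate column names (may be empty).
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return list with `delta_r2`, `ci` (2-vector), `r2_full`, `r2_covars`.
#' @export
evaluate_delta_r2 <- function(predictions, cohort, target,
                              covariates = character(0), n_boot = 1000L,
                              seed = 1L) {
  data <- cohort_data(cohort)
  y <- if (is.character(target)) data[[target]] else as.numeric(target)
  stopifnot(length(predictions) == length(y))
  C <- if (length(covariates)) {
    stats::model.matrix(stats::as.formula(
      paste("~", paste(covariates, collapse = "+"))), data = data)
  } else matrix(1, length(y), 1)
  X <- cbind(C, predictions)

  dr2 <- function(idx) {
    yy <- y[idx]
    r2 <- function(M) {
      fit <- stats::lm.fit(M[idx, , drop = FALSE], yy)
      1 - sum(fit$residuals^2) / sum((yy - mean(yy))^2)
    }
    r2(X) - r2(C)
  }
  all_idx <- seq_along(y)
  est <- dr2(all_idx)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b)
      dr2(sample(all_idx, replace = TRUE)), numeric(1))
  })
  fit_full <- stats::lm.fit(X, y); fit_cov <- stats::lm.fit(C, y)
  tss <- sum((y - mean(y))^2)
  list(delta_r2 = est,
       ci = unname(stats::quantile(boots, c(0.025, 0.975))),
       r2_full = 1 - sum(fit_full$residuals^2) / tss,
       r2_covars = 1 - sum(fit_cov$residuals^2) / tss,
       n_boot = n_boot)
}
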