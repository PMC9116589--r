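#' Genetic instrumental-variable (GIV) regression
#'
#' Corrects the attenuation bias that polygenic-index measurement error
#' induces in OLS: the index is a noisy proxy of the true genetic value, so
#' its OLS coefficient shrinks by the reliability. Two-stage least squares
#' with the second split-sample index as the instrument recovers the
#' disattenuated effect: stage 1 regresses `pgi_1` on `pgi_2` plus
#' covariates; stage 2 regresses the outcome on the stage-1 fitted values
#' plus covariates. Standard errors use the standard 2SLS form (residuals
#' computed with the original regressor, not the generated one).
#'
#' @param cohort `ses_cohort` or data frame with `pgi_1`, `pgi_2` columns.
#' @param outcome outcome column name, or a numeric vector (e.g. one
#'   voxel's volumes).
#' @param covariates character vector of covariate column names (factors
#'   are expanded to dummies).
#' @param pgi,instrument column names of the index and its instrument.
#' @param symmetrize if TRUE, also fits the reversed direction (pgi_2
#'   instrumented by pgi_1) and averages the two coefficient estimates
#'   (off by default; the canonical direction instruments pgi_1 with
#'   pgi_2).
#' @return object of class `giv_fit`: naive OLS and 2SLS coefficients for
#'   the index with standard errors, the first-stage F (instrument
#'   strength), and the implied reliability naive_beta / giv_beta.
#' @export
fit_giv <- function(cohort, outcome, covariates = character(0),
                    pgi = "pgi_1", instrument = "pgi_2", symmetrize = FALSE) {
  data <- cohort_data(cohort)
  y <- if (is.character(outcome)) data[[outcome]] else as.numeric(outcome)
  if (is.null(y)) stop("outcome column not found")
  x <- data[[pgi]]; z <- data[[instrument]]
  if (is.null(x) || is.null(z)) stop("pgi columns not found")
  if (stats::sd(z) == 0) stop("instrument is constant")
  C <- if (length(covariates)) {
    stats::model.matrix(stats::as.formula(
      paste("~", paste(covariates, collapse = "+"))), data = data)
  } else matrix(1, length(y), 1)
  n <- length(y); p <- ncol(C) + 1L
  if (n <= p + 1L) stop("too few observations")

  one_direction <- function(x, z) {
    # stage 1
    Z1 <- cbind(C, z)
    s1 <- stats::lm.fit(Z1, x)
    xhat <- s1$fitted.values
    rss1 <- sum(s1$residuals^2)
    # first-stage F for the excluded instrument
    s0 <- stats::lm.fit(C, x)
    f1 <- (sum(s0$residuals^2) - rss1) / (rss1 / (n - ncol(Z1)))
    # stage 2
    X2 <- cbind(C, xhat)
    s2 <- stats::lm.fit(X2, y)
    b <- s2$coefficients[ncol(X2)]
    # 2SLS sigma^2 from residuals with the *original* regressor
    res <- y - cbind(C, x) %*% s2$coefficients
    sigma2 <- sum(res^2) / (n - p)
    XtXinv <- chol2inv(chol(crossprod(X2)))
    se <- sqrt(sigma2 * diag(XtXinv)[ncol(X2)])
    list(beta = unname(b), se = unname(se), first_stage_f = f1)
  }

  g1 <- one_direction(x, z)
  if (symmetrize) {
    g2 <- one_direction(z, x)
    giv_beta <- (g1$beta + g2$beta) / 2
    giv_se <- sqrt((g1$se^2 + g2$se^2) / 4)  # ignores cross-covariance
  } else {
    giv_beta <- g1$beta; giv_se <- g1$se
  }

  Xn <- cbind(C, x)
  sn <- stats::lm.fit(Xn, y)
  nb <- sn$coefficients[ncol(Xn)]
  sigma2n <- sum(sn$residuals^2) / (n - p)
  nse <- sqrt(sigma2n * diag(chol2inv(chol(crossprod(Xn))))[ncol(Xn)])

  if (g1$first_stage_f < 10)
    warning("weak instrument: first-stage F = ", round(g1$first_stage_f, 2))

  structure(list(naive_beta = unname(nb), naive_se = unname(nse),
                 giv_beta = giv_beta, giv_se = giv_se,
                 first_stage_f = g1$first_stage_f,
                 implied_reliability = if (giv_beta != 0) unname(nb) / giv_beta
                                       else NA_real_,
                 n = n), class = "giv_fit")
}

#' @export
print.giv_fit <- function(x, ...) {
  cat("GIV regression (2SLS with split-sample polygenic instrument)\n")
  cat(sprintf("  naive OLS beta: %.4f (se %.4f)\n", x$naive_beta, x$naive_se))
  cat(sprintf("  GIV beta:       %.4f (se %.4f)\n", x$giv_beta, x$giv_se))
  cat(sprintf("  first-stage F:  %.1f\n", x$first_stage_f))
  cat(sprintf("  implied reliability: %.3f\n", x$implied_reliability))
  invisible(x)
}

#' Estimate polygenic-index reliability from the split-sample pair
#'
#' Under the assumption that the measurement noise in the two split-sample
#' indices is uncorrelated, their correlation is a consistent estimator of
#' the shared-signal (true genetic) variance fraction.
#'
#' @param cohort `ses_cohort` or data frame with `pgi_1`, `pgi_2`.
#' @export
estimate_reliability <- function(cohort) {
  data <- cohort_data(cohort)
  if (is.null(data$pgi_1) || is.null(data$pgi_2)) stop("pgi columns not found")
  stats::cor(data$pgi_1, data$pgi_2)
}
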