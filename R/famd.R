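#' Factorial analysis of mixed data (FAMD)
#'
#' Generalized PCA for tables mixing numeric and categorical columns:
#' numeric columns are standardized (population variance), categorical
#' columns are expanded to indicator columns centered and scaled by the
#' reciprocal square root of the level proportion, and the combined matrix
#' is decomposed by SVD. This combines ordinary PCA for the numeric part
#' with multiple correspondence analysis for the categorical part; the sum
#' of all eigenvalues equals (number of numeric variables) + (number of
#' categorical levels - number of categorical variables).
#'
#' Component signs are fixed deterministically: each component is flipped so
#' that it correlates nonnegatively with the first numeric variable (exact
#' zero correlations fall through to the next variable).
#'
#' @param table data frame of indicators; character columns are treated as
#'   categorical (factors), numeric columns as numeric.
#' @param k number of components to keep (default 2, the number of SES
#'   summary components used downstream).
#' @return object of class `famd`: list with `scores` (n x k, variance =
#'   eigenvalue convention), `eigenvalues` (all, nonincreasing),
#'   `squared_loadings` (variables x k; numeric: squared correlation with
#'   the component, categorical: correlation ratio; columns sum to the
#'   component eigenvalue), `loadings` (expanded-column x k right singular
#'   vectors), centering/scaling parameters, and column metadata.
#' @export
fit_famd <- function(table, k = 2L) {
  stopifnot(is.data.frame(table), ncol(table) >= 2L)
  n <- nrow(table)
  if (n < k + 1L) stop("need at least k + 1 rows")
  if (anyNA(table)) stop("missing values are not supported; complete cases only")

  kinds <- vapply(table, function(col) {
    if (is.numeric(col)) "numeric" else "categorical"
  }, character(1))

  centers <- list(); scales <- list(); levels_list <- list()
  blocks <- list(); block_var <- character(0)
  for (v in names(table)) {
    col <- table[[v]]
    if (kinds[v] == "numeric") {
      if (stats::sd(col) == 0) stop("constant column: ", v)
      mu <- mean(col); sdv <- sqrt(mean((col - mu)^2))
      centers[[v]] <- mu; scales[[v]] <- sdv
      blocks[[v]] <- matrix((col - mu) / sdv, ncol = 1,
                            dimnames = list(NULL, v))
      block_var <- c(block_var, v)
    } else {
      col <- factor(col)
      lev <- levels(droplevels(col))
      if (length(lev) < 2L) stop("constant column: ", v)
      col <- factor(col, levels = lev)
      ind <- outer(col, lev, `==`) * 1
      p <- colMeans(ind)
      Zc <- sweep(sweep(ind, 2, p), 2, sqrt(p), "/")
      colnames(Zc) <- paste(v, lev, sep = ".")
      centers[[v]] <- p; scales[[v]] <- sqrt(p); levels_list[[v]] <- lev
      blocks[[v]] <- Zc
      block_var <- c(block_var, rep(v, length(lev)))
    }
  }
  Z <- do.call(cbind, blocks)

  sv <- svd(Z / sqrt(n))
  eig <- sv$d^2
  kk <- min(k, sum(sv$d > 1e-12))
  scores <- sqrt(n) * sv$u[, seq_len(kk), drop = FALSE] %*%
    diag(sv$d[seq_len(kk)], kk)
  loadings <- sv$v[, seq_len(kk), drop = FALSE]

  # deterministic sign convention
  num_vars <- names(kinds)[kinds == "numeric"]
  for (j in seq_len(kk)) {
    for (v in num_vars) {
      cc <- stats::cov(table[[v]], scores[, j])
      if (abs(cc) > 1e-12) {
        if (cc < 0) { scores[, j] <- -scores[, j]; loadings[, j] <- -loadings[, j] }
        break
      }
    }
  }

  # per-variable squared loadings: sum of squared coordinates of the
  # variable's expanded columns; equals cor^2 (numeric) / correlation ratio
  # (categorical), and sums to the eigenvalue over variables
  coord <- loadings %*% diag(sv$d[seq_len(kk)], kk)
  sq <- rowsum(coord^2, group = block_var, reorder = FALSE)
  sq <- sq[names(table), , drop = FALSE]
  dimnames(sq) <- list(names(table), paste0("PC", seq_len(kk)))
  colnames(scores) <- paste0("PC", seq_len(kk))

  structure(list(scores = scores, eigenvalues = eig,
                 squared_loadings = sq, loadings = loadings,
                 kinds = kinds, centers = centers, scales = scales,
                 levels = levels_list, variables = names(table),
                 expanded_names = colnames(Z), k = kk, n = n),
            class = "famd")
}

#' Project new data onto fitted FAMD components
#'
#' Applies the stored centering/scaling and projection. Transforming the
#' training table returns the stored scores.
#'
#' @param model a [fit_famd()] result.
#' @param table data frame with the same columns as the fit table.
#' @param standardize if TRUE, scores are divided by the training-score
#'   standard deviation (unit-variance convention used by the downstream
#'   regressions); default FALSE returns raw principal coordinates.
#' @export
famd_transform <- function(model, table, standardize = FALSE) {
  if (!all(model$variables %in% names(table)))
    stop("schema mismatch: missing columns ",
         paste(setdiff(model$variables, names(table)), collapse = ", "))
  blocks <- list()
  for (v in model$variables) {
    col <- table[[v]]
    if (model$kinds[v] == "numeric") {
      if (!is.numeric(col)) stop("schema mismatch: ", v, " should be numeric")
      blocks[[v]] <- matrix((col - model$centers[[v]]) / model$scales[[v]], ncol = 1)
    } else {
      lev <- model$levels[[v]]
      col <- as.character(col)
      if (!all(col %in% lev))
        stop("unseen level in column ", v, ": ",
             paste(unique(setdiff(col, lev)), collapse = ", "))
      ind <- outer(factor(col, levels = lev), lev, `==`) * 1
      blocks[[v]] <- sweep(sweep(ind, 2, model$centers[[v]]), 2,
                           model$scales[[v]], "/")
    }
  }
  Z <- do.call(cbind, blocks)
  sc <- Z %*% model$loadings
  colnames(sc) <- paste0("PC", seq_len(model$k))
  if (standardize) {
    sdv <- sqrt(model$eigenvalues[seq_len(model$k)] * model$n / (model$n - 1))
    sc <- sweep(sc, 2, sdv, "/")
  }
  sc
}

#' Unit-variance component scores from a fitted FAMD model
#'
#' Convenience accessor: training scores standardized to unit (sample)
#' variance, the convention used when the components enter regressions.
#' @param model a [fit_famd()] result.
#' @export
famd_scores <- function(model) {
  sdv <- apply(model$scores, 2, stats::sd)
  sweep(model$scores, 2, sdv, "/")
}

#' Distance-correlation-free descriptive association matrix
#'
#' Descriptive extra: pairwise association between mixed columns, using
#' absolute Pearson correlation for numeric pairs, sqrt of the correlation
#' ratio for numeric/categorical pairs, and Cramer's V for categorical
#' pairs. Not used in fitting.
#' @param table mixed data frame.
#' @export
mixed_association_matrix <- function(table) {
  p <- ncol(table)
  out <- matrix(1, p, p, dimnames = list(names(table), names(table)))
  is_num <- vapply(table, is.numeric, logical(1))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    x <- table[[i]]; y <- table[[j]]
    val <- if (is_num[i] && is_num[j]) {
      abs(stats::cor(x, y))
    } else if (!is_num[i] && !is_num[j]) {
      tab <- table(x, y)
      chi <- suppressWarnings(stats::chisq.test(tab)$statistic)
      sqrt(as.numeric(chi) / (sum(tab) * (min(dim(tab)) - 1)))
    } else {
      num <- if (is_num[i]) x else y
      cat <- factor(if (is_num[i]) y else x)
      sqrt(summary(stats::lm(num ~ cat))$r.squared)
    }
    out[i, j] <- out[j, i] <- val
  }
  out
}
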