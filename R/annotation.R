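#' Spatial-autocorrelation-preserving surrogate sampler for a statistic map
#'
#' Calibrates, once, the smoothing scale of a Gaussian random field so that
#' a field rank-remapped onto the source map's value multiset reproduces
#' the source map's empirical variogram (circular axis-lag semivariogram,
#' up to `n_bins` integer lags); the scale is found by bisection in at
#' most `max_iter` iterations. Each
#' surrogate is then a fresh field at that scale whose values are replaced
#' by the original multiset in rank order — the surrogate has exactly the
#' original values, spatially rearranged with matched autocorrelation.
#' `mode = "naive"` skips the matching and permutes values uniformly
#' (for comparison only: it breaks the spatial null).
#'
#' @param values per-voxel statistic vector (e.g. the VBM F map).
#' @param grid_shape integer triple.
#' @param mode "variogram" (matched) or "naive" (pure permutation).
#' @param n_bins maximum number of variogram lags.
#' @param tol relative per-bin tolerance declared as matched.
#' @param max_iter bisection iterations for the scale search.
#' @param seed calibration seed.
#' @return object of class `surrogate_sampler`.
#' @export
surrogate_sampler <- function(values, grid_shape, mode = c("variogram", "naive"),
                              n_bins = 25L, tol = 0.15, max_iter = 50L,
                              seed = 1L) {
  mode <- match.arg(mode)
  V <- prod(grid_shape)
  stopifnot(length(values) == V, V >= 2L)
  out <- list(values = values, grid_shape = grid_shape, mode = mode,
              seed = seed)
  if (mode == "variogram") {
    # calibration statistic: circular axis-lag variogram of the full field
    # (deterministic, unlike sampled pairwise bins); matched on rank-
    # remapped trial fields so the remapping roughening is compensated
    lags <- seq_len(min(n_bins, floor(max(grid_shape) / 2)))
    target <- empirical_variogram(array(values, grid_shape), lags)
    sorted_vals <- sort(values)

    vario_at <- function(L, field_seed, n_fields = 4L) {
      f <- with_seed(field_seed, {
        z <- matrix(stats::rnorm(n_fields * V), n_fields, V)
        smooth_fields(z, grid_shape, L)
      })
      g <- vapply(seq_len(n_fields), function(i) {
        f_rm <- sorted_vals[rank(f[i, ], ties.method = "first")]
        empirical_variogram(array(f_rm, grid_shape), lags)
      }, numeric(length(lags)))
      rowMeans(g)
    }
    # every lag of the remapped-field variogram decreases in L, so the mean
    # signed relative error is monotone in L and bisection finds its root
    # (rank remapping leaves a small short-lag floor, which the signed-mean
    # objective trades off against the longer lags)
    lo <- 0.05; hi <- max(grid_shape) / 2
    best <- NULL; best_err <- Inf
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      g <- vario_at(mid, seed + it)
      rel <- (g - target) / pmax(target, 1e-12)
      err <- max(abs(rel))
      if (err < best_err) { best_err <- err; best <- mid }
      if (err <= tol) { best <- mid; best_err <- err; break }
      if (mean(rel) > 0) lo <- mid else hi <- mid
    }
    if (best_err > tol)
      warning("variogram tolerance not reached (best relative error ",
              round(best_err, 3), ")")
    out$smooth_scale <- best
    out$target_variogram <- target
    out$lags <- lags
  }
  structure(out, class = "surrogate_sampler")
}

#' Draw surrogate maps from a sampler
#'
#' @param sampler a [surrogate_sampler()].
#' @param n number of surrogate maps.
#' @param seed seed for the surrogate stream.
#' @return voxels x n matrix; every column holds exactly the original value
#'   multiset.
#' @export
make_surrogates <- function(sampler, n, seed = sampler$seed + 1L) {
  V <- prod(sampler$grid_shape)
  sorted_vals <- sort(sampler$values)
  with_seed(seed, {
    if (sampler$mode == "naive") {
      vapply(seq_len(n), function(i) sampler$values[sample.int(V)],
             numeric(V))
    } else {
      Z <- matrix(stats::rnorm(n * V), n, V)
      Z <- smooth_fields(Z, sampler$grid_shape, sampler$smooth_scale)
      apply(Z, 1, function(f) sorted_vals[rank(f, ties.method = "first")])
    }
  })
}

welch_t <- function(maps, sig) {
  n1 <- sum(sig); n0 <- sum(!sig)
  m1 <- colMeans(maps[sig, , drop = FALSE])
  m0 <- colMeans(maps[!sig, , drop = FALSE])
  v1 <- colMeans(maps[sig, , drop = FALSE]^2) - m1^2
  v0 <- colMeans(maps[!sig, , drop = FALSE]^2) - m0^2
  v1 <- v1 * n1 / max(n1 - 1, 1); v0 <- v0 * n0 / max(n0 - 1, 1)
  denom <- sqrt(v1 / n1 + v0 / n0)
  list(diff = m1 - m0, t = ifelse(denom == 0, 0, (m1 - m0) / denom))
}

#' Functional enrichment of a statistic map against concept maps
#'
#' For each concept map, computes the difference in mean concept value
#' between voxels nominally significant in the statistic map (uncorrected
#' p below `nominal_alpha`) and the rest, a Welch pseudo-T for that
#' difference, and a permutation p-value from spatial surrogates of the F
#' map: each surrogate's significant set is re-derived at the same quantile
#' (same set size), preserving the two-group structure under the null.
#' p = (1 + #{surrogate T >= observed T}) / (n_perm + 1), one-sided for
#' enrichment. FDR flags are Benjamini-Hochberg at `fdr_q`.
#'
#' @param statmap a [fit_voxelwise()] result.
#' @param concept_maps result of [generate_concept_maps()] or a voxels x
#'   concepts matrix.
#' @param nominal_alpha uncorrected-p cutoff defining the significant set.
#' @param n_perm number of spatial permutations.
#' @param seed seed for surrogate generation.
#' @param mode surrogate mode passed to [surrogate_sampler()].
#' @param fdr_q FDR level for the significance flags.
#' @return object of class `enrichment_result`: data frame with per-concept
#'   mean-chi-square difference, pseudo-T, permutation p, FDR flag, and
#'   category; plus the category ordering by the mean of each category's
#'   top-five concepts.
#' @export
enrich <- function(statmap, concept_maps, nominal_alpha = 0.01,
                   n_perm = 1000L, seed = 1L, mode = "variogram",
                   fdr_q = 0.05) {
  maps <- if (is.list(concept_maps) && !is.null(concept_maps$maps))
    concept_maps$maps else as.matrix(concept_maps)
  meta <- if (is.list(concept_maps) && !is.null(concept_maps$concepts))
    concept_maps$concepts
  else data.frame(concept = colnames(maps) %||% paste0("concept_", seq_len(ncol(maps))),
                  category = "uncategorized")
  V <- length(statmap$f)
  stopifnot(nrow(maps) == V)

  sig <- statmap$p < nominal_alpha
  k <- sum(sig)
  if (k == 0L || k == V) {
    res <- data.frame(meta, mean_sig = NA_real_, mean_rest = NA_real_,
                      difference = 0, pseudo_t = 0, p = 1, fdr_sig = FALSE)
    return(structure(list(table = res, no_signal = TRUE, n_perm = n_perm),
                     class = "enrichment_result"))
  }
  obs <- welch_t(maps, sig)

  sampler <- surrogate_sampler(statmap$f, statmap$grid_shape, mode = mode,
                               seed = seed)
  sur <- make_surrogates(sampler, n_perm, seed = seed + 1L)
  exceed <- integer(ncol(maps))
  for (b in seq_len(n_perm)) {
    fs <- sur[, b]
    sig_b <- fs >= sort(fs, decreasing = TRUE)[k]
    if (sum(sig_b) > k) {            # ties: trim to exactly k
      extra <- which(sig_b & fs == min(fs[sig_b]))
      sig_b[extra[seq_len(sum(sig_b) - k)]] <- FALSE
    }
    tb <- welch_t(maps, sig_b)$t
    exceed <- exceed + (tb >= obs$t)
  }
  p <- (1 + exceed) / (n_perm + 1)
  flags <- bh_fdr(p, fdr_q)
  res <- data.frame(meta,
                    mean_sig = colMeans(maps[sig, , drop = FALSE]),
                    mean_rest = colMeans(maps[!sig, , drop = FALSE]),
                    difference = obs$diff, pseudo_t = obs$t, p = p,
                    fdr_sig = flags, row.names = NULL)

  cat_order <- NULL
  if (length(unique(res$category)) > 1L) {
    sc <- -log10(res$p)
    cat_score <- tapply(seq_len(nrow(res)), res$category, function(i) {
      top <- sort(sc[i], decreasing = TRUE)
      mean(top[seq_len(min(5L, length(top)))])
    })
    cat_order <- names(sort(unlist(cat_score), decreasing = TRUE))
  }
  structure(list(table = res, category_order = cat_order, no_signal = FALSE,
                 n_perm = n_perm, nominal_alpha = nominal_alpha,
                 sampler = sampler),
            class = "enrichment_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg FDR flags
#'
#' Step-up procedure at level `q`, via adjusted p-values.
#' @param p_values vector of p-values in (0, 1].
#' @param q FDR level.
#' @return logical vector of significance flags.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(p_values > 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH") <= q
}
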