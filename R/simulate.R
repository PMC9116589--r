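#' Simulation configuration for the synthetic imaging cohort
#'
#' The generator emulates the statistical structure the downstream analyses
#' assume: a latent genetic value `G` and a latent environmental factor `E`
#' (iid standard normal), two split-sample polygenic indices that are noisy
#' copies of `G` at a stated reliability, mixed numeric/categorical SES
#' indicators loading on `G` and `E`, body-mass index as a partial mediator
#' of the environmental path, and voxel-level gray matter volumes whose
#' SES-related signal has a region-varying genetic share on top of spatially
#' autocorrelated Gaussian noise.
#'
#' @param n_subjects number of subjects.
#' @param grid_shape integer triple, voxels per axis.
#' @param pgi_reliability fraction in (0, 1]: var(G) / var(PGI), i.e. the
#'   share of polygenic-index variance carried by the true genetic value.
#'   Equals the expected correlation between the two split-sample indices.
#' @param genetic_share_map per-region fraction in [0, 1] of the SES-related
#'   GMV signal variance carried by `G` (recycled to `n_regions`).
#' @param bmi_mediation_share fraction in [0, 1] of the environmental path
#'   routed through BMI.
#' @param noise_correlation_length Gaussian-kernel length scale of the voxel
#'   noise field, in voxels. 0 gives spatially white noise.
#' @param n_regions number of contiguous parcels (axis-aligned blocks).
#' @param effect_size per-region signal coefficient beta_j (recycled); the
#'   default 0.1 puts single-voxel effects near partial R^2 of 1%, the order
#'   of magnitude reported for population-cohort SES-GMV associations.
#' @param tiv_loading coefficient of standardized total intracranial volume
#'   in each voxel.
#' @param noise_sd marginal standard deviation of the voxel noise field.
#' @param seed integer seed; same seed + same config give bit-identical
#'   cohorts and volumes.
#' @param indicator_spec data frame with columns `name`, `kind`
#'   ("numeric"/"categorical"), `n_levels`, `loading_on_G`, `loading_on_E`.
#'   The default set is symmetric in G and E (equal measurement quality for
#'   the genetic and environmental components).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 2000L,
                       grid_shape = c(12L, 12L, 12L),
                       pgi_reliability = 0.5,
                       genetic_share_map = NULL,
                       bmi_mediation_share = 0.4,
                       noise_correlation_length = 2,
                       n_regions = 8L,
                       effect_size = 0.1,
                       tiv_loading = 0.4,
                       noise_sd = 1,
                       seed = 1L,
                       indicator_spec = default_indicator_spec()) {
  grid_shape <- as.integer(grid_shape)
  n_regions <- as.integer(n_regions)
  if (is.null(genetic_share_map))
    genetic_share_map <- seq(0.05, 0.9, length.out = n_regions)
  genetic_share_map <- rep_len(genetic_share_map, n_regions)
  effect_size <- rep_len(effect_size, n_regions)

  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), grid_shape = grid_shape,
    pgi_reliability = pgi_reliability, genetic_share_map = genetic_share_map,
    bmi_mediation_share = bmi_mediation_share,
    noise_correlation_length = noise_correlation_length,
    n_regions = n_regions, effect_size = effect_size,
    tiv_loading = tiv_loading, noise_sd = noise_sd,
    seed = as.integer(seed),
    indicator_spec = as.data.frame(indicator_spec)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 2L, length(cfg$grid_shape) == 3L,
            all(cfg$grid_shape >= 1L))
  if (!(cfg$pgi_reliability > 0 && cfg$pgi_reliability <= 1))
    stop("pgi_reliability must be in (0, 1]")
  if (any(cfg$genetic_share_map < 0 | cfg$genetic_share_map > 1))
    stop("genetic_share_map fractions must be in [0, 1]")
  if (cfg$bmi_mediation_share < 0 || cfg$bmi_mediation_share > 1)
    stop("bmi_mediation_share must be in [0, 1]")
  if (cfg$n_regions > prod(cfg$grid_shape))
    stop("n_regions exceeds the number of voxels")
  spec <- cfg$indicator_spec
  req <- c("name", "kind", "n_levels", "loading_on_G", "loading_on_E")
  if (!all(req %in% names(spec))) stop("indicator_spec missing columns")
  if (all(spec$loading_on_G == 0 & spec$loading_on_E == 0))
    stop("non-invertible indicator_spec: all loadings are zero")
  comm <- spec$loading_on_G^2 + spec$loading_on_E^2
  if (any(comm > 1 + 1e-12))
    stop("indicator loadings imply communality > 1 for: ",
         paste(spec$name[comm > 1 + 1e-12], collapse = ", "))
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_indicator_spec <- function() {
  data.frame(
    name = c("occupational_wage", "household_income", "occupation_rank",
             "neighborhood_score", "housing_type", "occupation_class"),
    kind = c("numeric", "numeric", "numeric", "numeric",
             "categorical", "categorical"),
    n_levels = c(NA, NA, NA, NA, 3L, 4L),
    loading_on_G = c(0.97, 0.05, 0.93, 0.08, 0.90, 0.10),
    loading_on_E = c(0.05, 0.97, 0.08, 0.93, 0.10, 0.90),
    stringsAsFactors = FALSE)
}

# Evaluate expr with the global RNG set to `seed` and restored afterwards,
# so the generator has no side effect on the caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic cohort table
#'
#' Draws latent `G`, `E` iid standard normal; polygenic indices
#' `pgi_k = sqrt(r) G + sqrt(1-r) eps_k` with independent noise (so
#' `cor(pgi_1, pgi_2) = r`, the reliability); mixed SES indicators as
#' `loading_on_G * G + loading_on_E * E` plus an independent residual that
#' brings each latent index to unit variance (categorical indicators are the
#' latent index cut at equiprobable normal quantiles); covariates (age, sex,
#' scanner site, TIV with a small loading on both `G` and `E`, matching a
#' head-size/SES partial R^2 near 1.6%); and BMI
#' `= -sqrt(m) E + sqrt(1-m) u`, m = `bmi_mediation_share`, so that
#' controlling BMI removes the fraction `m` of the environmental path in the
#' weak-signal limit. The ground-truth latents are kept in `$truth`.
#'
#' @param config a [sim_config()].
#' @return object of class `ses_cohort`: list with `data` (data frame),
#'   `indicators` (names of SES indicator columns), `truth` (data frame with
#'   `G`, `E`, `bmi_u`), and `config`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_subjects
  r <- config$pgi_reliability
  m <- config$bmi_mediation_share
  spec <- config$indicator_spec

  with_seed(config$seed, {
    G <- rnorm(n); E <- rnorm(n)
    pgi_1 <- sqrt(r) * G + sqrt(1 - r) * rnorm(n)
    pgi_2 <- sqrt(r) * G + sqrt(1 - r) * rnorm(n)

    ind <- vector("list", nrow(spec))
    names(ind) <- spec$name
    for (j in seq_len(nrow(spec))) {
      lg <- spec$loading_on_G[j]; le <- spec$loading_on_E[j]
      res_sd <- sqrt(max(0, 1 - lg^2 - le^2))
      latent <- lg * G + le * E + res_sd * rnorm(n)
      if (spec$kind[j] == "numeric") {
        ind[[j]] <- latent
      } else {
        k <- spec$n_levels[j]
        cuts <- qnorm(seq_len(k - 1L) / k)
        ind[[j]] <- factor(paste0("L", findInterval(latent, cuts) + 1L),
                           levels = paste0("L", seq_len(k)))
      }
    }

    age <- rnorm(n, 62, 7.5)
    sex <- rbinom(n, 1L, 0.57)            # 1 = female
    site <- factor(sample(paste0("site", 1:3), n, replace = TRUE))
    tiv_std <- 0.09 * G + 0.09 * E + sqrt(1 - 2 * 0.09^2) * rnorm(n)
    tiv <- 1500 + 130 * tiv_std

    bmi_u <- rnorm(n)
    bmi <- -sqrt(m) * E + sqrt(1 - m) * bmi_u

    dat <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                      ind, age = age, sex = sex, site = site, tiv = tiv,
                      bmi = bmi, pgi_1 = pgi_1, pgi_2 = pgi_2,
                      stringsAsFactors = FALSE)
    structure(list(data = dat, indicators = spec$name,
                   truth = data.frame(G = G, E = E, bmi_u = bmi_u),
                   config = config),
              class = "ses_cohort")
  })
}

# Axis-aligned block partition of the grid into n_regions contiguous parcels:
# split the longest axis into near-equal slabs recursively.
block_parcellation <- function(grid_shape, n_regions) {
  if (n_regions > prod(grid_shape)) stop("grid too small for requested n_regions")
  labels <- array(1L, dim = grid_shape)
  # iterative bisection: maintain list of (ranges, n_wanted)
  queue <- list(list(rng = lapply(grid_shape, seq_len), k = n_regions))
  parts <- list()
  while (length(queue)) {
    item <- queue[[1]]; queue <- queue[-1]
    if (item$k == 1L) { parts[[length(parts) + 1L]] <- item$rng; next }
    sizes <- lengths(item$rng)
    ax <- which.max(sizes)
    k1 <- item$k %/% 2L; k2 <- item$k - k1
    cut <- round(sizes[ax] * k1 / item$k)
    cut <- max(1L, min(sizes[ax] - 1L, cut))
    r1 <- item$rng; r1[[ax]] <- item$rng[[ax]][seq_len(cut)]
    r2 <- item$rng; r2[[ax]] <- item$rng[[ax]][-seq_len(cut)]
    queue <- c(queue, list(list(rng = r1, k = k1), list(rng = r2, k = k2)))
  }
  for (i in seq_along(parts))
    labels[parts[[i]][[1]], parts[[i]][[2]], parts[[i]][[3]]] <- i
  labels
}

# Circulant Gaussian smoothing matrix for one axis (circular boundary).
circulant_kernel <- function(len, L) {
  d <- outer(seq_len(len), seq_len(len), function(i, j) {
    dd <- abs(i - j); pmin(dd, len - dd)
  })
  exp(-d^2 / (2 * L^2))
}

# Smooth white-noise fields (rows of Z, vectorized x-fastest over grid_shape)
# with a separable circular Gaussian kernel; renormalize to unit marginal
# variance. L = 0 returns Z unchanged.
smooth_fields <- function(Z, grid_shape, L) {
  if (L <= 0) return(Z)
  n <- nrow(Z)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  S <- lapply(grid_shape, circulant_kernel, L = L)
  A <- array(t(Z), dim = c(nx, ny, nz, n))
  A <- array(S[[1]] %*% matrix(A, nx), dim = c(nx, ny, nz, n))
  A <- aperm(A, c(2, 1, 3, 4))
  A <- array(S[[2]] %*% matrix(A, ny), dim = c(ny, nx, nz, n))
  A <- aperm(A, c(3, 2, 1, 4))              # -> z, x, y, n
  A <- array(S[[3]] %*% matrix(A, nz), dim = c(nz, nx, ny, n))
  A <- aperm(A, c(2, 3, 1, 4))              # -> x, y, z, n
  v0 <- prod(vapply(S, function(s) sum(s[1, ]^2), numeric(1)))
  t(matrix(A, nrow = prod(grid_shape), ncol = n)) / sqrt(v0)
}

#' Theoretical axis-lag variogram of the generator's noise field
#'
#' The noise field is Gaussian-kernel-smoothed white noise on a torus,
#' renormalized to unit marginal variance; its correlation at axis lag `h`
#' is the (discrete, circular) autocorrelation of the kernel, close to
#' `exp(-h^2 / (4 L^2))`. Returns the semivariogram `1 - rho(h)`.
#'
#' @param grid_shape integer triple.
#' @param L kernel length scale in voxels.
#' @param lags integer axis lags.
#' @param axis which axis (1-3).
#' @export
noise_variogram_theory <- function(grid_shape, L, lags, axis = 1L) {
  if (L <= 0) return(as.numeric(lags > 0))
  len <- grid_shape[axis]
  S <- circulant_kernel(len, L)
  w <- S[1, ]
  rho0 <- sum(w^2)
  rho <- vapply(lags, function(h) {
    sum(w * w[((seq_len(len) - 1L + h) %% len) + 1L]) / rho0
  }, numeric(1))
  1 - rho
}

#' Empirical axis-lag variogram of a 3D field
#'
#' Semivariance of circular-shift differences along grid axes, averaged over
#' the three axes, at the requested integer lags.
#'
#' @param field 3D array.
#' @param lags integer axis lags (>= 1).
#' @export
empirical_variogram <- function(field, lags) {
  stopifnot(length(dim(field)) == 3L)
  vapply(lags, function(h) {
    g <- 0
    for (ax in 1:3) {
      idx <- lapply(dim(field), seq_len)
      len <- dim(field)[ax]
      idx[[ax]] <- ((seq_len(len) - 1L + h) %% len) + 1L
      shifted <- field[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      g <- g + mean((field - shifted)^2) / 2
    }
    g / 3
  }, numeric(1))
}

#' Generate synthetic voxel volumes for a cohort
#'
#' Each voxel in region `j` (genetic share `s_j`, coefficient `beta_j`) gets
#' `beta_j (sqrt(s_j) G + sqrt(1 - s_j) E) + tiv_loading * tiv_std +
#' noise_sd * Z`, where `Z` is a unit-variance spatially autocorrelated
#' Gaussian field (independent across subjects). The environmental path `E`
#' decomposes exactly as `(1 - m) E + sqrt(m) (-bmi) + sqrt(m (1 - m)) u`
#' with `m` the BMI mediation share and `u` the BMI residual, i.e. the
#' generator routes the fraction `m` of the environmental effect through BMI
#' by construction.
#'
#' @param config a [sim_config()].
#' @param cohort the matching [generate_cohort()] output (truth required).
#' @return object of class `ses_volumes`: list with `data` (subjects x
#'   voxels matrix), `mask` (3D logical), `affine`, `region_labels` (3D
#'   integer), `grid_shape`, and `truth` (per-region shares/betas).
#' @export
generate_gmv <- function(config, cohort) {
  validate_sim_config(config)
  if (is.null(cohort$truth)) stop("cohort must carry ground truth (synthetic)")
  n <- config$n_subjects
  stopifnot(nrow(cohort$data) == n)
  labels <- block_parcellation(config$grid_shape, config$n_regions)
  V <- prod(config$grid_shape)
  lab_vec <- as.integer(labels)

  G <- cohort$truth$G; E <- cohort$truth$E
  tiv_std <- as.numeric(scale(cohort$data$tiv))
  s <- config$genetic_share_map[lab_vec]
  beta <- config$effect_size[lab_vec]

  # derive the noise seed from the config seed but offset it so cohort and
  # volumes use distinct streams
  dat <- with_seed(config$seed + 1000003L, {
    Z <- matrix(rnorm(n * V), n, V)
    Z <- smooth_fields(Z, config$grid_shape, config$noise_correlation_length)
    signal <- outer(G, beta * sqrt(s)) + outer(E, beta * sqrt(1 - s))
    signal + outer(tiv_std, rep(config$tiv_loading, V)) + config$noise_sd * Z
  })
  colnames(dat) <- NULL
  structure(list(data = dat, mask = array(TRUE, config$grid_shape),
                 affine = diag(c(1.5, 1.5, 1.5, 1)),
                 region_labels = labels, grid_shape = config$grid_shape,
                 truth = list(genetic_share = config$genetic_share_map,
                              effect_size = config$effect_size)),
            class = "ses_volumes")
}

#' Generate synthetic concept statistic maps
#'
#' Each concept map is the square of a smoothed unit-variance Gaussian field
#' (chi-square-like, nonnegative), standing in for meta-analytic activation
#' maps. If `match_map` is given, the first concept is a monotone transform
#' (rank quantile) of that statistic map, a positive control for enrichment.
#'
#' @param config a [sim_config()].
#' @param n_concepts number of maps.
#' @param match_map optional per-voxel statistic vector to embed as concept 1.
#' @param categories optional character vector of category names to assign
#'   cyclically.
#' @return list with `maps` (voxels x concepts matrix), `concepts` (data
#'   frame: concept, category, matched flag).
#' @export
generate_concept_maps <- function(config, n_concepts, match_map = NULL,
                                  categories = c("memory", "language", "emotion",
                                                 "attention", "perception",
                                                 "action", "executive", "social",
                                                 "reasoning", "reward")) {
  if (n_concepts < 1) stop("n_concepts must be >= 1")
  V <- prod(config$grid_shape)
  maps <- with_seed(config$seed + 2000003L, {
    Z <- matrix(rnorm(n_concepts * V), n_concepts, V)
    Z <- smooth_fields(Z, config$grid_shape, config$noise_correlation_length)
    t(Z^2)
  })
  matched <- rep(FALSE, n_concepts)
  if (!is.null(match_map)) {
    stopifnot(length(match_map) == V)
    maps[, 1] <- rank(match_map, ties.method = "average") / V
    matched[1] <- TRUE
  }
  concepts <- data.frame(
    concept = sprintf("concept_%03d", seq_len(n_concepts)),
    category = rep_len(categories, n_concepts),
    matched = matched, stringsAsFactors = FALSE)
  colnames(maps) <- concepts$concept
  list(maps = maps, concepts = concepts)
}
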