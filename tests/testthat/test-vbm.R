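test_that("voxelwise F and partial R2 match a normal-equations oracle", {
  # 10-row printed fixture, one voxel
  dat <- data.frame(
    y   = c(3.1, 2.4, 4.0, 3.3, 2.8, 3.9, 4.4, 2.2, 3.0, 3.6),
    pc1 = c(0.5, -1.2, 1.1, 0.3, -0.4, 0.9, 1.5, -1.0, -0.2, 0.1),
    pc2 = c(-0.3, 0.8, 0.2, -1.1, 0.6, -0.5, 0.4, 0.9, -0.7, 0.0),
    age = c(61, 55, 70, 64, 58, 67, 72, 52, 60, 63))
  vols <- structure(list(data = matrix(dat$y, ncol = 1),
                         mask = array(TRUE, c(1, 1, 1)),
                         region_labels = array(1L, c(1, 1, 1)),
                         grid_shape = c(1L, 1L, 1L)), class = "ses_volumes")
  des <- vbm_design(c("pc1", "pc2"), covariates = "age")
  sm <- fit_voxelwise(vols, dat, des)

  # brute-force nested-model fit via explicit normal equations
  Xf <- cbind(1, dat$age, scale(dat$pc1), scale(dat$pc2))
  Xr <- cbind(1, dat$age)
  bf <- solve(crossprod(Xf), crossprod(Xf, dat$y))
  br <- solve(crossprod(Xr), crossprod(Xr, dat$y))
  ssef <- sum((dat$y - Xf %*% bf)^2)
  sser <- sum((dat$y - Xr %*% br)^2)
  f_oracle <- ((sser - ssef) / 2) / (ssef / (10 - 4))
  expect_equal(sm$f[1], f_oracle, tolerance = 1e-10)
  expect_equal(sm$partial_r2[1], (sser - ssef) / sser, tolerance = 1e-10)
  expect_equal(sm$p[1], pf(f_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # standardized betas match lm on z-scored outcome and predictors
  bz <- coef(lm(scale(y) ~ age + scale(pc1) + scale(pc2), dat))
  expect_equal(unname(sm$beta[1, ]), unname(bz[3:4]), tolerance = 1e-10)
})

test_that("predictors orthogonalized out give exactly zero association", {
  cfg <- small_config(n_subjects = 80L)
  co <- generate_cohort(cfg)
  dat <- cohort_with_pcs(co)
  # outcome equals a covariate at every voxel
  V <- 12L
  vols <- structure(list(data = matrix(rep(dat$age, V), ncol = V),
                         mask = array(TRUE, c(V, 1, 1)),
                         region_labels = array(1L, c(V, 1, 1)),
                         grid_shape = c(V, 1L, 1L)), class = "ses_volumes")
  des <- vbm_design(c("PC1", "PC2"), covariates = c("age", "sex"))
  sm <- fit_voxelwise(vols, dat, des)
  expect_true(all(abs(sm$f) < 1e-16))
  expect_true(all(abs(sm$partial_r2) < 1e-18))
})

test_that("null voxels give uniform uncorrected p-values", {
  cfg <- sim_config(n_subjects = 300L, grid_shape = c(8L, 8L, 8L),
                    n_regions = 4L, effect_size = 0, tiv_loading = 0,
                    noise_correlation_length = 0, seed = 17L)
  co <- generate_cohort(cfg)
  vo <- generate_gmv(cfg, co)
  dat <- cohort_with_pcs(co)
  sm <- fit_voxelwise(vo, dat, vbm_design(c("PC1", "PC2"),
                                          tiv_adjusted = TRUE))
  expect_gt(ks.test(sm$p, "punif")$p.value, 0.01)
})

test_that("design handling: rank checks, rescaling invariance, disjointness", {
  cfg <- small_config(n_subjects = 60L)
  co <- generate_cohort(cfg); vo <- generate_gmv(cfg, co)
  dat <- cohort_with_pcs(co)
  dat$dup <- dat$age
  expect_error(
    fit_voxelwise(vo, dat, vbm_design(c("PC1", "PC2"),
                                      covariates = c("age", "dup"))),
    "rank deficient")
  expect_error(vbm_design("PC1", covariates = c("PC1", "age")), "disjoint")

  des1 <- vbm_design(c("PC1", "PC2"), covariates = c("age", "sex"))
  sm1 <- fit_voxelwise(vo, dat, des1)
  dat2 <- dat; dat2$age <- dat2$age * 1000 - 3
  sm2 <- fit_voxelwise(vo, dat2, des1)
  expect_equal(sm1$f, sm2$f, tolerance = 1e-8)
})

test_that("single-voxel permutation p agrees with the parametric F test", {
  set.seed(2)
  n <- 120L
  dat <- data.frame(PC1 = rnorm(n), PC2 = rnorm(n), age = rnorm(n))
  y <- 0.25 * dat$PC1 + rnorm(n)
  vols <- structure(list(data = matrix(y, ncol = 1),
                         mask = array(TRUE, c(1, 1, 1)),
                         region_labels = array(1L, c(1, 1, 1)),
                         grid_shape = c(1L, 1L, 1L)), class = "ses_volumes")
  des <- vbm_design(c("PC1", "PC2"), covariates = "age")
  sm <- fit_voxelwise(vols, dat, des)
  fw <- permutation_fwe_threshold(vols, dat, des, n_perm = 2000L, seed = 9L)
  expect_lt(abs(fw$fwe_p(sm$f[1]) - sm$p[1]),
            3 * sqrt(sm$p[1] * (1 - sm$p[1]) / 2000) + 2 / 2000)
})

test_that("perfectly correlated voxels collapse to single-voxel multiplicity", {
  set.seed(3)
  n <- 100L
  dat <- data.frame(PC1 = rnorm(n), PC2 = rnorm(n), age = rnorm(n))
  y <- rnorm(n)
  des <- vbm_design(c("PC1", "PC2"), covariates = "age")
  mk <- function(V) structure(list(data = matrix(rep(y, V), ncol = V),
                                   mask = array(TRUE, c(V, 1, 1)),
                                   region_labels = array(1L, c(V, 1, 1)),
                                   grid_shape = c(V, 1L, 1L)),
                              class = "ses_volumes")
  fw1 <- permutation_fwe_threshold(mk(1L), dat, des, n_perm = 300L, seed = 4L)
  fwV <- permutation_fwe_threshold(mk(8L), dat, des, n_perm = 300L, seed = 4L)
  expect_equal(fw1$f_crit, fwV$f_crit, tolerance = 1e-12)
  expect_error(permutation_fwe_threshold(mk(1L), dat, des, n_perm = 99L),
               "n_perm")
  expect_error(permutation_fwe_threshold(mk(1L), dat, des, n_perm = 100L,
                                         alpha = 0.001), "resolution")
})

test_that("seeded permutation runs are reproducible and converge", {
  cfg <- small_config(n_subjects = 150L)
  co <- generate_cohort(cfg); vo <- generate_gmv(cfg, co)
  dat <- cohort_with_pcs(co)
  des <- vbm_design(c("PC1", "PC2"), tiv_adjusted = TRUE)
  fa <- permutation_fwe_threshold(vo, dat, des, n_perm = 150L, seed = 5L)
  fb <- permutation_fwe_threshold(vo, dat, des, n_perm = 150L, seed = 5L)
  expect_identical(fa$max_f, fb$max_f)
  fc <- permutation_fwe_threshold(vo, dat, des, n_perm = 150L, seed = 6L)
  expect_false(identical(fa$max_f, fc$max_f))
})

test_that("scalar regression returns exact and calibrated coefficients", {
  cfg <- small_config(n_subjects = 400L)
  co <- generate_cohort(cfg)
  dat <- cohort_with_pcs(co)
  des <- vbm_design(c("PC1", "PC2"), covariates = c("age", "sex"))
  # outcome = PC1 itself: standardized beta exactly 1
  out <- scalar_outcome_regression(dat, "PC1", des)
  expect_equal(out$beta[out$term == "PC1"], 1, tolerance = 1e-10)
  expect_equal(out$beta[out$term == "PC2"], 0, tolerance = 1e-10)

  # TIV carries a genuine SES loading in the generator: joint association
  # detected, and each CI has positive width
  tv <- scalar_outcome_regression(dat, "tiv", des)
  expect_gt(tv$joint_f[1], 1)
  expect_true(all(tv$ci_hi > tv$ci_lo))

  # null outcome: CI covers zero at the nominal rate
  cover <- vapply(1:100, function(s) {
    set.seed(s + 400)
    d <- data.frame(PC1 = rnorm(120), PC2 = rnorm(120), age = rnorm(120),
                    sex = rbinom(120, 1, 0.5), y = rnorm(120))
    r <- scalar_outcome_regression(d, "y", des)
    r$ci_lo[1] <= 0 && r$ci_hi[1] >= 0
  }, logical(1))
  expect_gt(mean(cover), 0.88)
  expect_lt(mean(cover), 1)
})

test_that("minimal detectable R2 is self-consistent and well-behaved", {
  for (cs in list(list(n = 23931, q = 2, a = 2.19e-6, pw = 0.9),
                  list(n = 500, q = 2, a = 0.05, pw = 0.8),
                  list(n = 2000, q = 1, a = 0.001, pw = 0.95))) {
    r2 <- minimal_detectable_r2(cs$n, cs$q, 0, cs$a, cs$pw)
    df2 <- cs$n - cs$q - 1
    f2 <- r2 / (1 - r2)
    achieved <- pf(qf(1 - cs$a, cs$q, df2), cs$q, df2, ncp = f2 * df2,
                   lower.tail = FALSE)
    expect_lt(abs(achieved - cs$pw), 1e-6)
  }
  # power -> 0+ limit: detectable effect collapses toward zero
  expect_lt(minimal_detectable_r2(1000, 2, 0, 0.05, 1e-6), 1e-4)
  expect_error(minimal_detectable_r2(10, 2, 0, 1e-300, 0.999), "unattainable")
})

test_that("cluster formation matches a flood-fill oracle", {
  gs <- c(6L, 6L, 4L)
  # two disjoint blobs
  f <- rep(0, prod(gs))
  arr <- array(f, gs)
  arr[1:2, 1:2, 1] <- 5; arr[5:6, 5:6, 3:4] <- c(7, 6, 6, 6, 6, 6, 6, 8)
  sm <- manual_stat_map(as.numeric(arr), gs)
  cl <- form_clusters(sm, 4)
  expect_identical(nrow(cl$table), 2L)
  expect_identical(sort(cl$table$size), c(4L, 8L))
  # size-descending ordering with peak data
  expect_identical(cl$table$size, c(8L, 4L))
  expect_equal(cl$table$peak_f[1], 8)

  # random thresholded maps against the oracle
  for (seed in 1:4) {
    set.seed(seed)
    fv <- rnorm(prod(gs))
    smr <- manual_stat_map(fv, gs)
    clr <- form_clusters(smr, 0.8)
    oracle <- floodfill_clusters(array(fv >= 0.8, gs))
    expect_identical(nrow(clr$table), max(oracle))
    expect_identical(sort(clr$table$size),
                     sort(as.integer(table(oracle[oracle > 0]))))
  }
  # threshold above the maximum: empty set, not an error
  empty <- form_clusters(sm, 100)
  expect_identical(nrow(empty$table), 0L)
})

test_that("subgroup analysis restricts rows and flags undersized groups", {
  cfg <- small_config(n_subjects = 300L)
  co <- generate_cohort(cfg); vo <- generate_gmv(cfg, co)
  dat <- cohort_with_pcs(co)
  des <- vbm_design(c("PC1", "PC2"), covariates = c("age", "sex"))
  full <- fit_voxelwise(vo, dat, des)
  sub_all <- subgroup_vbm(vo, dat, des, rep(TRUE, 300L))
  expect_equal(sub_all$f, full$f)
  expect_error(subgroup_vbm(vo, dat, des, seq_len(5L)), "too small")

  # SES-effect heterogeneity: larger effects below the SES median show up
  # as larger partial R2 in the low-SES stratum
  set.seed(8)
  n <- 2000L
  d <- data.frame(PC1 = rnorm(n), PC2 = rnorm(n), age = rnorm(n),
                  sex = rbinom(n, 1, 0.5))
  low <- d$PC1 < quantile(d$PC1, 0.5)
  beta <- ifelse(low, 0.5, 0.1)
  Y <- vapply(1:6, function(v) beta * d$PC1 + rnorm(n), numeric(n))
  vols <- structure(list(data = Y, mask = array(TRUE, c(6, 1, 1)),
                         region_labels = array(1L, c(6, 1, 1)),
                         grid_shape = c(6L, 1L, 1L)), class = "ses_volumes")
  sm_lo <- subgroup_vbm(vols, d, des, low)
  sm_hi <- subgroup_vbm(vols, d, des, !low)
  expect_true(all(sm_lo$partial_r2 > sm_hi$partial_r2))
})

test_that("TIV adjustment reduces SES effect sizes when TIV is SES-linked", {
  cfg <- small_config(n_subjects = 800L, seed = 55L)
  co <- generate_cohort(cfg); vo <- generate_gmv(cfg, co)
  dat <- cohort_with_pcs(co)
  sm_no <- fit_voxelwise(vo, dat, vbm_design(c("PC1", "PC2"),
                                             tiv_adjusted = FALSE))
  sm_ti <- fit_voxelwise(vo, dat, vbm_design(c("PC1", "PC2"),
                                             tiv_adjusted = TRUE))
  expect_lt(mean(sm_ti$partial_r2), mean(sm_no$partial_r2))
})
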