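test_that("fold assignment partitions subjects with the stated sizes", {
  f <- make_folds(213, cv_scheme("kfold", k = 10, seed = 1))
  sizes <- sort(as.integer(table(f)))
  expect_equal(sizes, c(rep(21L, 9), 24L))      # nine of 21, one of 24

  expect_equal(make_folds(5, cv_scheme("loso")), 1:5)

  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:60, 1); k <- sample(2:min(9, n), 1)
    f <- make_folds(n, cv_scheme("kfold", k = k, seed = seed))
    expect_equal(sort(unique(f)), 1:k)
    expect_equal(length(f), n)                  # each subject exactly once
    expect_equal(as.integer(table(f))[1:(k - 1)],
                 rep(n %/% k, k - 1))
  }
  expect_error(make_folds(5, cv_scheme("kfold", k = 10)), "exceeds")
})

test_that("confound residualization is leakage-free OLS", {
  set.seed(40)
  n_tr <- 30; n_te <- 10; V <- 25
  C_tr <- cbind(1, matrix(rnorm(n_tr * 3), n_tr, 3))
  C_te <- cbind(1, matrix(rnorm(n_te * 3), n_te, 3))
  X_tr <- matrix(rnorm(n_tr * V), n_tr, V) + C_tr %*% matrix(rnorm(4 * V), 4, V)
  X_te <- matrix(rnorm(n_te * V), n_te, V)

  rz <- residualize_confounds(X_tr, C_tr, X_te, C_te)
  # training residuals orthogonal to every covariate column
  expect_lt(max(abs(crossprod(C_tr, rz$train))), 1e-8)
  # matches the per-voxel normal-equations oracle
  want <- oracle_residualize(X_tr, C_tr, X_te, C_te)
  expect_equal(rz$train, want$train, tolerance = 1e-9)
  expect_equal(rz$test, want$test, tolerance = 1e-9)

  # intercept-only: centering by the training means
  rz0 <- residualize_confounds(X_tr, matrix(1, n_tr), X_te, matrix(1, n_te))
  mu <- colMeans(X_tr)
  expect_equal(rz0$train, sweep(X_tr, 2, mu), tolerance = 1e-12)
  expect_equal(rz0$test, sweep(X_te, 2, mu), tolerance = 1e-12)

  expect_error(residualize_confounds(X_tr, cbind(C_tr, C_tr[, 2])),
               "rank deficient")
})

test_that("cross-validated RVR recovers an oracle feature and is deterministic", {
  set.seed(41)
  n <- 200
  cov <- fake_covariates(n)
  # target orthogonal to the confounds, so residualizing the features
  # cannot delete the signal; y itself is a feature, the rest is
  # low-amplitude noise
  y0 <- rnorm(n)
  y <- unname(resid(lm(y0 ~ covariate_design(cov) + 0)))
  y <- y / sd(y)
  X <- cbind(y, matrix(rnorm(n * 20, sd = 0.05), n, 20))
  sch <- cv_scheme("kfold", k = 5, seed = 3)
  cv1 <- suppressWarnings(run_cv(X, y, cov, sch))
  expect_gt(cv1$metrics$pearson_r, 0.99)
  cv2 <- suppressWarnings(run_cv(X, y, cov, sch))
  expect_identical(cv1$y_hat, cv2$y_hat)        # bit-identical rerun
  # every subject predicted exactly once, fold weights one row per fold
  expect_equal(sort(unique(cv1$folds)), 1:5)
  expect_equal(nrow(cv1$fold_weights), 5L)
})

test_that("out-of-fold predictions have no cross-fold leakage", {
  set.seed(42)
  n <- 24
  X <- matrix(rnorm(n * 15), n, 15)
  y <- X[, 1] + rnorm(n, 0, 0.3)
  cov <- fake_covariates(n)
  sch <- cv_scheme("kfold", k = 4, seed = 7)
  folds <- make_folds(n, sch)
  base <- suppressWarnings(run_cv(X, y, cov, sch))
  # relabel the subjects inside fold 2 (features, target and covariates
  # move together): other folds see the same training set, so their
  # out-of-fold predictions must be untouched, while fold 2's
  # predictions travel with their subjects
  idx <- which(folds == 2)
  perm <- rev(idx)
  X2 <- X; X2[idx, ] <- X[perm, ]
  y2 <- y; y2[idx] <- y[perm]
  cov2 <- cov; cov2[idx, ] <- cov[perm, ]
  mod <- suppressWarnings(run_cv(X2, y2, cov2, sch))
  expect_equal(mod$y_hat[folds != 2], base$y_hat[folds != 2],
               tolerance = 1e-8)
  expect_equal(mod$y_hat[idx], base$y_hat[perm], tolerance = 1e-8)
})

test_that("metrics match the two-pass oracle", {
  y <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(eval_metrics(y, y), list(pearson_r = 1, nmse = 0))
  yc <- y - mean(y)
  expect_equal(eval_metrics(yc, -yc)$pearson_r, -1, tolerance = 1e-12)

  set.seed(43)
  a <- rnorm(50); b <- a + rnorm(50)
  got <- eval_metrics(a, b)
  want <- oracle_metrics(a, b)
  expect_equal(got$pearson_r, want$r, tolerance = 1e-12)
  expect_equal(got$nmse, want$nmse, tolerance = 1e-12)

  # plain-range convention available as an option
  expect_equal(eval_metrics(a, b, range_power = 1)$nmse,
               mean((a - b)^2) / diff(range(a)), tolerance = 1e-12)
  expect_error(eval_metrics(rep(1, 5), rnorm(5)), "constant")
})

test_that("permutation p-values respect the 1/n_perm floor and determinism", {
  set.seed(44)
  n <- 30
  y <- rnorm(n)
  X <- cbind(y, matrix(rnorm(n * 10), n, 10))   # very strong signal
  cov <- fake_covariates(n)
  sch <- cv_scheme("kfold", k = 5, seed = 2)
  pt <- suppressWarnings(
    permutation_test(X, y, cov, sch, n_perm = 25, seed = 9))
  expect_equal(pt$p_r, 1 / 25)                  # observed beats all nulls
  expect_gte(pt$p_nmse, 1 / 25)
  expect_lte(pt$p_r, 1); expect_lte(pt$p_nmse, 1)
  expect_equal(length(pt$null_r), 25L)

  pt2 <- suppressWarnings(
    permutation_test(X, y, cov, sch, n_perm = 25, seed = 9))
  expect_identical(pt$null_r, pt2$null_r)       # same seed, same sequence
})

test_that("BH adjustment matches the exhaustive step-up oracle", {
  expect_equal(fdr_correct(0.03), 0.03)         # single p unchanged
  expect_equal(fdr_correct(rep(0.2, 5)), rep(0.2, 5))

  set.seed(45)
  for (rep in 1:25) {
    m <- sample(2:8, 1)
    p <- runif(m)
    expect_equal(fdr_correct(p), oracle_bh(p), tolerance = 1e-15)
    # order invariance: adjusted values travel with their p-values
    perm <- sample(m)
    expect_equal(fdr_correct(p[perm]), fdr_correct(p)[perm])
  }
  expect_error(fdr_correct(c(0.1, 0)), "0, 1")
  expect_error(fdr_correct(c(0.1, 1.2)), "0, 1")
})

test_that("region contributions normalize to 100 and rank deterministically", {
  dims <- c(4, 4, 2)
  mask <- array(TRUE, dims)
  w <- array(rnorm(prod(dims)), dims)

  one <- array(1L, dims)
  rc1 <- region_contributions(w, one, mask)
  expect_equal(rc1$percent_contribution, 100)

  half <- array(1L, dims); half[3:4, , ] <- 2L
  wq <- array(1, dims)
  rc2 <- region_contributions(wq, half, mask)
  expect_equal(rc2$percent_contribution, c(50, 50))
  expect_equal(rc2$actual_rank, c(1L, 2L))      # tie broken by region id

  set.seed(46)
  lab <- array(sample(0:3, prod(dims), TRUE), dims)  # includes unlabeled
  rc3 <- region_contributions(w, lab, mask)
  expect_equal(sum(rc3$percent_contribution), 100, tolerance = 1e-6)
  expect_true("unlabeled" %in% rc3$region_name)

  expect_error(region_contributions(w, one, array(TRUE, c(4, 4, 3))),
               "mismatch")
})

test_that("expected ranking averages per-fold competition ranks", {
  mk <- function(pct) {
    data.frame(region_id = 1:3, region_name = letters[1:3],
               percent_contribution = pct, stringsAsFactors = FALSE)
  }
  # identical rankings: expected equals actual
  er <- expected_ranking(list(mk(c(60, 30, 10)), mk(c(50, 35, 15))))
  expect_equal(er$expected_rank, c(1, 2, 3))
  # region 1 first in half the folds, second in the other half
  er2 <- expected_ranking(list(mk(c(60, 30, 10)), mk(c(30, 60, 10)),
                               mk(c(60, 30, 10)), mk(c(30, 60, 10))))
  expect_equal(er2$expected_rank[1:2], c(1.5, 1.5))
  expect_true(all(er2$expected_rank >= 1 & er2$expected_rank <= 3))

  bad <- mk(c(1, 2, 3)); bad$region_id <- 4:6
  expect_error(expected_ranking(list(mk(c(1, 2, 3)), bad)), "differ")
})
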