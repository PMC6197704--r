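test_that("cohort generation is a pure function of config and seed", {
  cfg <- smoke_config(seed = 5)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a$dosage, b$dosage)

  expect_identical(simulate_covariates(cfg), simulate_covariates(cfg))

  tm <- simulate_true_model(cfg)
  cv <- simulate_covariates(cfg)
  z <- rnorm(40); z <- (z - mean(z)) / sd(z)
  i1 <- simulate_brain_images(cfg, z, cv, tm)
  i2 <- simulate_brain_images(cfg, z, cv, tm)
  expect_identical(i1$data, i2$data)
})

test_that("genotype dosages respect MAF and block-LD structure", {
  # all MAFs at 0.5: empirical frequencies within 3 binomial SEs
  cfg <- smoke_config(seed = 2, maf_range = c(0.5, 0.5), n_snps = 20L,
                      n_blocks = 4L)
  panel <- simulate_genotypes(cfg, n_subjects = 500L)
  freq <- colMeans(panel$dosage) / 2
  se <- sqrt(0.5 * 0.5 / (2 * 500))
  expect_true(all(abs(freq - 0.5) <= 3 * se))
  expect_true(all(panel$dosage %in% 0:2))

  # independence case: near-zero pairwise dosage correlation; the max
  # over pairs is checked per block (5 SNPs each) where the |r| < 0.1
  # bound holds at n = 500 without multiplicity inflation
  cfg0 <- smoke_config(seed = 7, within_block_corr = 0, n_snps = 10L,
                       n_blocks = 2L)
  p0 <- simulate_genotypes(cfg0, n_subjects = 500L)
  C <- cor(p0$dosage)
  expect_lt(max(abs(C[upper.tri(C)])), 0.1)
  expect_lt(mean(abs(C[upper.tri(C)])), 0.05)

  # LD inside blocks strictly exceeds LD across blocks
  cfgL <- smoke_config(seed = 4, within_block_corr = 0.7)
  pL <- simulate_genotypes(cfgL, n_subjects = 300L)
  C2 <- cor(pL$dosage)^2
  blk <- pL$snp_meta$block
  same <- outer(blk, blk, `==`) & upper.tri(C2)
  diff <- !outer(blk, blk, `==`) & upper.tri(C2)
  expect_gt(mean(C2[same]), mean(C2[diff]))

  # block geometry: each block spans < 200 kb, gaps > 1 Mb
  spans <- tapply(pL$snp_meta$pos_bp, blk, function(x) diff(range(x)))
  expect_true(all(spans < 200000))
  starts <- tapply(pL$snp_meta$pos_bp, blk, min)
  ends <- tapply(pL$snp_meta$pos_bp, blk, max)
  expect_true(all(starts[-1] - ends[-length(ends)] > 1e6))

  expect_error(simulate_genotypes(smoke_config(n_snps = 61L, n_blocks = 12L)),
               "divisible")
})

test_that("summary statistics have calibrated nulls and exact noise-free limit", {
  cfg <- smoke_config(seed = 6, n_snps = 2000L, n_blocks = 400L)
  panel <- simulate_genotypes(cfg, n_subjects = 2L)

  # global null: p-values uniform (KS below the 1% critical value)
  ss0 <- simulate_summary_stats(rep(0, 2000), panel, cfg, seed = 42)
  D <- suppressWarnings(ks.test(ss0$pval, "punif"))$statistic
  expect_lt(D, 1.63 / sqrt(2000))

  # noise-free variant returns the true betas exactly
  tb <- rnorm(2000, 0, 0.05)
  ss_exact <- simulate_summary_stats(tb, panel, cfg, seed = 1, se_scale = 0)
  expect_equal(ss_exact$beta, tb, tolerance = 0)

  # consistency: huge discovery sample drives causal p to ~0
  cfg_big <- smoke_config(seed = 6, n_snps = 2000L, n_blocks = 400L,
                          discovery_n = 10000000L)
  tb2 <- rep(c(0.05, 0), 1000)
  ss_big <- simulate_summary_stats(tb2, panel, cfg_big, seed = 2)
  expect_lt(max(ss_big$pval[tb2 > 0]), 1e-10)
})

test_that("covariate tables match the cohort's demographic envelope", {
  cfg <- sim_config()   # full 213-subject default
  cov <- simulate_covariates(cfg)
  expect_equal(nrow(cov), 213L)
  expect_equal(sum(cov$status == "control"), 111L)
  expect_true(all(cov$age >= 18 & cov$age <= 68))
  expect_true(all(cov$sex %in% 0:1))
  expect_setequal(unique(cov$study), c("study1", "study2"))
  expect_identical(cov, simulate_covariates(cfg))
})

test_that("planted image signal scales with the score and hits its target correlation", {
  cfg <- smoke_config(seed = 7, noise_sd = 1e-8, signal_r = 0.5,
                      confound_effect_sizes = c(age = 0, sex = 0,
                                                icv = 0, study = 0))
  tm <- simulate_true_model(cfg)
  cov <- fake_covariates(40)
  z <- rnorm(40); z <- (z - mean(z)) / sd(z)
  img <- simulate_brain_images(cfg, z, cov, tm)
  # noise-free case: between-subject differences are proportional to the
  # score difference times the pattern
  d12 <- img$data[, , , 1] - img$data[, , , 2]
  expected <- (z[1] - z[2]) * img$signal_scale * tm$true_pattern
  expect_equal(d12, expected, tolerance = 1e-4)

  # realized correlation between score and pattern expression near target
  cfg2 <- sim_config(seed = 8)   # n = 213, signal_r = 0.5
  tm2 <- simulate_true_model(cfg2)
  cov2 <- simulate_covariates(cfg2)
  z2 <- rnorm(213); z2 <- (z2 - mean(z2)) / sd(z2)
  img2 <- simulate_brain_images(cfg2, z2, cov2, tm2)
  expr <- vapply(seq_len(213),
                 function(j) sum(img2$data[, , , j] * tm2$true_pattern), 0)
  expect_lt(abs(cor(z2, expr) - 0.5), 0.1)

  # standardization precondition enforced
  expect_error(simulate_brain_images(cfg2, z2 + 1, cov2, tm2), "standardized")
})

test_that("the atlas partitions the mask into labelled regions", {
  tm <- simulate_true_model(smoke_config(seed = 9))
  atlas <- simulate_atlas(tm)
  expect_true(all(atlas[tm$mask] >= 1))
  expect_true(all(atlas[!tm$mask] == 0))
  expect_gt(length(unique(atlas[tm$mask])), 1)
})
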