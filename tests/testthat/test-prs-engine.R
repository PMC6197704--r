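test_that("clumping keeps the most significant SNP of a correlated pair", {
  # single SNP: nothing to clump
  d1 <- matrix(c(0, 1, 2, 1, 0, 2), ncol = 1)
  p1 <- fake_panel(d1)
  s1 <- fake_sumstats(p1$snp_meta$id, 0.01)
  expect_equal(ld_clump(s1, p1, exclusions = NULL), p1$snp_meta$id)

  # two perfectly correlated SNPs 10 kb apart
  x <- c(0, 1, 2, 1, 0, 2, 1, 1)
  d2 <- cbind(x, x)
  p2 <- fake_panel(d2, pos_bp = c(100000L, 110000L))
  s2 <- fake_sumstats(p2$snp_meta$id, c(1e-4, 1e-8),
                      pos_bp = c(100000L, 110000L))
  kept <- ld_clump(s2, p2, exclusions = NULL)
  expect_equal(kept, p2$snp_meta$id[2])   # the 1e-8 SNP

  # default configuration: r2 = 0.25 within a 200 kb window
  expect_equal(eval(formals(ld_clump)$r2_threshold), 0.25)
  expect_equal(eval(formals(ld_clump)$window_kb), 200)
})

test_that("clumping matches the brute-force oracle and its invariants", {
  for (seed in 1:20) {
    inst <- random_clump_instance(seed)
    got <- suppressWarnings(ld_clump(inst$stats, inst$panel, 0.25, 100,
                                     exclusions = NULL))
    want <- oracle_clump(inst$stats, inst$panel$dosage, 0.25, 100000)
    expect_equal(sort(got), sort(want), info = paste("seed", seed))

    # retained-pair property: no retained in-window pair above threshold
    if (length(got) > 1) {
      meta <- inst$stats[match(got, inst$stats$id), ]
      for (i in seq_along(got)) {
        for (j in seq_along(got)) {
          if (j <= i) next
          if (abs(meta$pos_bp[i] - meta$pos_bp[j]) > 100000) next
          r2 <- cor(inst$panel$dosage[, got[i]],
                    inst$panel$dosage[, got[j]])^2
          expect_lte(r2, 0.25)
        }
      }
    }

    # invariance to input row order
    shuf <- inst$stats[sample(nrow(inst$stats)), ]
    expect_equal(suppressWarnings(
      ld_clump(shuf, inst$panel, 0.25, 100, exclusions = NULL)), got)
  }
})

test_that("clumping handles exclusion regions, zero variance and missing SNPs", {
  d <- cbind(c(0, 1, 2, 1, 0), c(1, 1, 1, 1, 1), c(2, 0, 1, 2, 0))
  panel <- fake_panel(d, chrom = c("6", "1", "1"),
                      pos_bp = c(30000000L, 1000L, 2000L))
  stats <- fake_sumstats(panel$snp_meta$id, c(1e-9, 0.01, 0.02),
                         chrom = c("6", "1", "1"),
                         pos_bp = c(30000000L, 1000L, 2000L))
  # MHC SNP removed despite having the best p; constant SNP warned away
  expect_warning(kept <- ld_clump(stats, panel), "zero-variance")
  expect_equal(kept, "snp003")

  expect_error(ld_clump(fake_sumstats("ghost", 0.1), panel), "missing")
})

test_that("p-value thresholding is strict", {
  d <- matrix(rep(c(0, 1, 2, 1), 3), ncol = 3)
  panel <- fake_panel(d)
  stats <- fake_sumstats(panel$snp_meta$id, c(0.05, 0.1, 0.2))
  sel <- threshold_select(stats, stats$id, 0.1)
  expect_equal(sel$id, "snp001")          # 0.1 itself excluded
  expect_equal(nrow(threshold_select(stats, stats$id, 1)), 3L)
  expect_error(threshold_select(stats, stats$id, 0.001), "no SNPs")
  expect_equal(eval(formals(threshold_select)$p_threshold), 0.1)
})

test_that("allele alignment fixes strand and counted-allele conventions", {
  dosage <- matrix(c(0, 1, 2, 2, 0, 1, 1, 2, 0, 0, 1, 2), ncol = 4)
  panel <- fake_panel(dosage,
                      counted = c("A", "G", "A", "A"),
                      other = c("G", "A", "T", "C"))
  stats <- fake_sumstats(panel$snp_meta$id, rep(0.01, 4),
                         beta = c(0.3, 0.3, 0.3, 0.3),
                         effect = c("A", "A", "A", "A"),
                         other = c("G", "G", "T", "G"))
  w <- capture_warnings(al <- allele_align(stats, panel))
  expect_match(w, "ambiguous", all = FALSE)
  expect_match(w, "unresolvable", all = FALSE)
  expect_equal(unname(al$effects["snp001"]), 0.3)     # identity
  expect_equal(unname(al$effects["snp002"]), -0.3)    # counted = other
  expect_equal(al$dropped_ambiguous, "snp003")        # A/T
  expect_equal(al$dropped_unresolved, "snp004")       # mismatched pair

  # dosage-complement identity: flipping the counted allele of every SNP
  # shifts the score by 2 * sum(beta)
  set.seed(1)
  D <- matrix(sample(0:2, 15, TRUE), 5, 3)
  pA <- fake_panel(D, counted = rep("A", 3), other = rep("G", 3))
  pB <- fake_panel(2 - D, counted = rep("G", 3), other = rep("A", 3))
  st <- fake_sumstats(pA$snp_meta$id, rep(0.01, 3), beta = c(0.2, -0.4, 0.1))
  sA <- compute_prs(pA, allele_align(st, pA)$effects)
  sB <- compute_prs(pB, allele_align(st, pB)$effects)
  expect_equal(as.vector(sB), as.vector(sA) - 2 * sum(st$beta), tolerance = 1e-12)
})

test_that("scoring matches the double-loop oracle and its algebra", {
  set.seed(42)
  D <- matrix(sample(0:2, 20, TRUE), 5, 4)
  panel <- fake_panel(D)
  eff <- setNames(rnorm(4), panel$snp_meta$id)
  s <- compute_prs(panel, eff, "sum")
  expect_equal(as.vector(s), oracle_prs(panel$dosage, as.list(eff)),
               tolerance = 1e-12)
  m <- compute_prs(panel, eff, "mean")
  expect_equal(as.vector(s), as.vector(m) * 4, tolerance = 0)

  expect_equal(as.vector(compute_prs(panel, setNames(rep(0, 4), names(eff)))),
               rep(0, 5))
  one <- fake_panel(matrix(c(2, 0, 1), ncol = 1))
  expect_equal(as.vector(compute_prs(one, setNames(1, "snp001")))[1], 2)

  # missing dosages are mean-imputed per SNP
  Dna <- D; Dna[1, 2] <- NA
  pna <- fake_panel(Dna)
  sna <- compute_prs(pna, eff)
  imput <- Dna; imput[1, 2] <- mean(Dna[-1, 2])
  expect_equal(as.vector(sna), as.vector(imput %*% eff), tolerance = 1e-12)
  Dall <- D; Dall[, 3] <- NA
  expect_error(compute_prs(fake_panel(Dall), eff), "no observed")
})

test_that("control standardization reproduces the hand-computed example", {
  scores <- c(1, 2, 3, 4, 10, 0)        # subjects 1-4 controls
  ctrl <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  z <- standardize_to_controls(scores, ctrl)
  mu <- mean(scores[1:4]); s <- sd(scores[1:4])
  expect_equal(z, (scores - mu) / s, tolerance = 1e-12)
  expect_lt(abs(mean(z[ctrl])), 1e-12)
  expect_equal(sd(z[ctrl]), 1, tolerance = 1e-12)
  # a patient sitting at the control mean scores exactly zero
  expect_equal(standardize_to_controls(c(1, 3, 2), c(TRUE, TRUE, FALSE))[3], 0)
  expect_error(standardize_to_controls(c(1, 1, 5), c(TRUE, TRUE, FALSE)),
               "variance")
})

test_that("group comparison has correct df, two-group identity and null rate", {
  # 3 groups, N = 213 -> F df (2, 210)
  set.seed(10)
  g <- rep(c("MDD", "BD", "HC"), c(69, 33, 111))
  z <- rnorm(213)
  gc <- group_compare(z, g)
  expect_equal(gc$df, c(2, 210))

  # two groups: F equals the squared pooled t
  set.seed(11)
  z2 <- rnorm(40); g2 <- rep(c("a", "b"), each = 20)
  gc2 <- group_compare(z2, g2)
  tt <- t.test(z2 ~ g2, var.equal = TRUE)
  expect_equal(gc2$F, unname(tt$statistic)^2, tolerance = 1e-10)

  # null calibration: equal means/variances rarely rejected
  set.seed(12)
  pvals <- replicate(100, group_compare(rnorm(60), rep(c("a", "b", "c"), 20))$p)
  expect_gte(mean(pvals > 0.05), 0.90)

  expect_error(group_compare(rnorm(3), c("a", "a", "b")), "n >= 2")
})

test_that("pairwise score correlations cover all pairs with sane nulls", {
  set.seed(13)
  prs <- matrix(rnorm(213 * 4), 213, 4,
                dimnames = list(NULL, c("ADHD", "AUT", "BD", "SCZ")))
  out <- score_correlations(prs)
  expect_equal(nrow(out), 6L)           # 4 disorders -> 6 pairs
  expect_true(all(out$p_fdr >= out$p))

  # a column correlated with itself
  prs2 <- cbind(prs[, 1:2], dup = prs[, 1])
  out2 <- score_correlations(prs2)
  self <- out2[out2$disorder1 == "ADHD" & out2$disorder2 == "dup", ]
  expect_equal(self$r, 1, tolerance = 1e-12)

  # independent scores: |r| < 0.2 in >= 90% of replicates at n = 213
  set.seed(14)
  rs <- replicate(100, cor(rnorm(213), rnorm(213)))
  expect_gte(mean(abs(rs) < 0.2), 0.9)

  expect_error(score_correlations(cbind(a = rep(1, 10), b = rnorm(10))),
               "constant")
})
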