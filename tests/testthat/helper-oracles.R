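# Independent brute-force oracles. Each is written as a direct, literal
# transcription of the definition (explicit loops, no shared code with
# the implementation under test).

# Greedy p-ranked clumping by exhaustive pairwise scanning.
oracle_clump <- function(stats, dosage, r2_threshold, window_bp) {
  ord <- order(stats$pval, stats$pos_bp, stats$id)
  stats <- stats[ord, , drop = FALSE]
  removed <- rep(FALSE, nrow(stats))
  kept <- character(0)
  for (i in seq_len(nrow(stats))) {
    if (removed[i]) next
    kept <- c(kept, stats$id[i])
    for (j in seq_len(nrow(stats))) {
      if (j <= i || removed[j]) next
      if (stats$chrom[j] != stats$chrom[i]) next
      if (abs(stats$pos_bp[j] - stats$pos_bp[i]) > window_bp) next
      r <- suppressWarnings(cor(dosage[, stats$id[i]], dosage[, stats$id[j]]))
      if (is.finite(r) && r^2 > r2_threshold) removed[j] <- TRUE
    }
  }
  kept
}

# Benjamini-Hochberg step-up adjusted p-values, literal definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, m * p[ord[j]] / j)
    adj[ord[i]] <- min(1, min(vals))
  }
  adj
}

# Double-loop allelic score accumulation.
oracle_prs <- function(dosage, effects) {
  n <- nrow(dosage)
  s <- numeric(n)
  for (i in seq_len(n)) {
    for (snp in names(effects)) {
      s[i] <- s[i] + effects[[snp]] * dosage[i, snp]
    }
  }
  s
}

# Double-loop inner products.
oracle_kernel <- function(A, B) {
  K <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      K[i, j] <- sum(A[i, ] * B[j, ])
    }
  }
  K
}

# Two-pass Pearson r and normalized MSE.
oracle_metrics <- function(y, y_hat) {
  my <- sum(y) / length(y)
  mh <- sum(y_hat) / length(y_hat)
  num <- sum((y - my) * (y_hat - mh))
  den <- sqrt(sum((y - my)^2) * sum((y_hat - mh)^2))
  mse <- sum((y - y_hat)^2) / length(y)
  list(r = num / den, nmse = mse / (max(y) - min(y))^2)
}

# Per-voxel normal-equations residualization.
oracle_residualize <- function(X, C, X_new = NULL, C_new = NULL) {
  B <- solve(t(C) %*% C) %*% t(C) %*% X
  out <- list(train = X - C %*% B)
  if (!is.null(X_new)) out$test <- X_new - C_new %*% B
  out
}

# Random clumping instance on <= max_snps SNPs with LD-correlated pairs.
random_clump_instance <- function(seed, max_snps = 10L, n_subj = 50L) {
  set.seed(seed)
  p <- sample(2:max_snps, 1)
  base <- matrix(rnorm(n_subj * p), n_subj, p)
  # force some highly correlated pairs
  for (k in seq_len(p %/% 2)) {
    j <- sample(p, 2)
    lambda <- runif(1)
    base[, j[2]] <- lambda * base[, j[1]] + (1 - lambda) * base[, j[2]]
  }
  dosage <- pmin(pmax(round(base + 1), 0), 2)   # matrix first: keeps dim
  # a couple of duplicated p-values to exercise the tie-break
  pv <- round(runif(p), 2)
  pos <- sort(sample(1:500000, p))
  panel <- fake_panel(dosage, pos_bp = pos)
  keep_var <- apply(panel$dosage, 2, sd) > 0
  stats <- fake_sumstats(panel$snp_meta$id[keep_var], pv[keep_var],
                         pos_bp = pos[keep_var])
  list(stats = stats, panel = panel)
}
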