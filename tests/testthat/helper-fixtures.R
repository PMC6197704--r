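# Shared fixtures: everything is generated in code at test time.

# Small cohort configuration for smoke-scale runs (40 subjects, 8^3 grid).
smoke_config <- function(seed = 1, signal_r = 0.5,
                         grid_dims = c(8L, 8L, 8L), n_snps = 60L,
                         n_blocks = 12L, discovery_n = 20000L, ...) {
  sim_config(group_sizes = c(MDD = 12L, HC1 = 12L, BD = 8L, HC2 = 8L),
             n_snps = n_snps, n_blocks = n_blocks, grid_dims = grid_dims,
             discovery_n = discovery_n, signal_r = signal_r, seed = seed, ...)
}

# Build a feature_matrix directly from a subjects x voxels matrix, laying
# the voxels out over a fully-true mask on a minimal 3D grid.
fake_features <- function(values, grid_dims = NULL, voxel_size_mm = c(2, 2, 2)) {
  V <- ncol(values)
  if (is.null(grid_dims)) {
    d1 <- V
    grid_dims <- c(d1, 1L, 1L)
  }
  stopifnot(prod(grid_dims) >= V)
  mask <- array(FALSE, grid_dims)
  mask[seq_len(V)] <- TRUE
  lin <- which(mask)
  structure(list(values = values, voxel_index = which(mask, arr.ind = TRUE),
                 linear_index = lin, grid_dims = as.integer(grid_dims),
                 voxel_size_mm = voxel_size_mm, mask = mask),
            class = "feature_matrix")
}

# Genotype panel fixture from an explicit dosage matrix.
fake_panel <- function(dosage, chrom = "1",
                       pos_bp = seq_len(ncol(dosage)) * 1000L,
                       counted = rep("A", ncol(dosage)),
                       other = rep("G", ncol(dosage)),
                       ids = sprintf("snp%03d", seq_len(ncol(dosage)))) {
  colnames(dosage) <- ids
  subjects <- sprintf("S%03d", seq_len(nrow(dosage)))
  rownames(dosage) <- subjects
  structure(list(subjects = subjects, dosage = dosage,
                 snp_meta = data.frame(id = ids, chrom = chrom,
                                       pos_bp = as.integer(pos_bp),
                                       counted_allele = counted,
                                       other_allele = other,
                                       stringsAsFactors = FALSE)),
            class = "genotype_panel")
}

fake_sumstats <- function(ids, pval, chrom = "1",
                          pos_bp = seq_along(ids) * 1000L,
                          beta = rep(0.1, length(ids)),
                          effect = rep("A", length(ids)),
                          other = rep("G", length(ids))) {
  out <- data.frame(id = ids, chrom = chrom, pos_bp = as.integer(pos_bp),
                    effect_allele = effect, other_allele = other,
                    beta = beta, pval = pval, stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

# Minimal covariate table with no built-in association to anything.
fake_covariates <- function(n, seed = 99) {
  set.seed(seed)
  data.frame(subject = sprintf("S%03d", seq_len(n)),
             group = rep(c("MDD", "HC1"), length.out = n),
             study = sample(rep(c("study1", "study2"), length.out = n)),
             status = sample(rep(c("patient", "control"), length.out = n)),
             age = runif(n, 20, 60), sex = rbinom(n, 1, 0.5),
             icv = rlnorm(n, log(1.5e6), 0.05), stringsAsFactors = FALSE)
}
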