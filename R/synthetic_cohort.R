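#' Simulate a block-LD genotype panel
#'
#' Draws subject-level effect-allele dosages in `{0, 1, 2}` for a panel of
#' SNPs partitioned into independent LD blocks. Within a block, every
#' pair of SNPs shares a latent Gaussian correlation of
#' `within_block_corr`; dosages arise from two independent latent
#' haplotypes thresholded at each SNP's Hardy-Weinberg quantile
#' `qnorm(maf)`, so single-SNP genotype frequencies follow
#' Hardy-Weinberg proportions. Minor allele frequencies are drawn
#' uniformly from `maf_range`. SNP coordinates place each block within a
#' 150 kb span with block starts 2.5 Mb apart, so clumping windows never
#' straddle blocks.
#'
#' @param config A [sim_config()].
#' @param n_subjects Number of subjects; defaults to the config's total.
#' @param seed Integer seed; defaults to a seed derived from the config.
#' @return A `genotype_panel`: list with `subjects` (labels), `dosage`
#'   (subject x SNP matrix), and `snp_meta` (data.frame with `id`,
#'   `chrom`, `pos_bp`, `counted_allele`, `other_allele`, `maf`).
#' @export
simulate_genotypes <- function(config, n_subjects = sum(config$group_sizes),
                               seed = derive_seed(config$seed, "genotypes")) {
  validate_sim_config(config)
  p <- config$n_snps
  nb <- config$n_blocks
  stop_if_not(p %% nb == 0L,
              "simulate_genotypes: n_snps (%d) is not divisible into %d blocks",
              p, nb)
  m <- p %/% nb
  rho <- config$within_block_corr
  set.seed(seed)

  maf <- runif(p, config$maf_range[1], config$maf_range[2])
  thr <- qnorm(maf)

  dosage <- matrix(0L, n_subjects, p)
  for (b in seq_len(nb)) {
    cols <- ((b - 1L) * m + 1L):(b * m)
    for (hap in 1:2) {
      common <- rnorm(n_subjects)
      z <- sqrt(rho) * common +
        sqrt(1 - rho) * matrix(rnorm(n_subjects * m), n_subjects, m)
      dosage[, cols] <- dosage[, cols] +
        (z < rep(thr[cols], each = n_subjects))
    }
  }

  # non-strand-ambiguous allele pairs so synthetic scoring never drops SNPs
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2, byrow = TRUE)
  pick <- sample.int(nrow(pairs), p, replace = TRUE)

  block_of <- rep(seq_len(nb), each = m)
  within <- if (m > 1) round(seq(0, 150000, length.out = m)) else 0
  pos <- 1000000 + (block_of - 1L) * 2500000 + rep(within, nb)
  ids <- sprintf("rs%06d", seq_len(p))

  snp_meta <- data.frame(
    id = ids, chrom = "1", pos_bp = as.integer(pos),
    counted_allele = pairs[pick, 1], other_allele = pairs[pick, 2],
    maf = maf, block = block_of, stringsAsFactors = FALSE
  )
  subjects <- sprintf("S%04d", seq_len(n_subjects))
  dimnames(dosage) <- list(subjects, ids)
  structure(list(subjects = subjects, dosage = dosage, snp_meta = snp_meta),
            class = "genotype_panel")
}

#' Simulate ground-truth effects and spatial patterns
#'
#' Draws per-disorder true SNP effects (a `causal_fraction` of SNPs get
#' nonzero betas), a brain mask and grey-matter template on the config's
#' grid, a smooth sparse-support voxel pattern (zero outside the mask)
#' that the target disorder's genetic score will express, and one smooth
#' confound map per covariate in `confound_effect_sizes`.
#'
#' @inheritParams simulate_genotypes
#' @return A `true_model` list: `true_betas` (SNP x disorder matrix),
#'   `mask`, `template`, `true_pattern` (3D arrays), `confound_maps`
#'   (named list of 3D arrays).
#' @export
simulate_true_model <- function(config,
                                seed = derive_seed(config$seed, "truth")) {
  validate_sim_config(config)
  set.seed(seed)
  p <- config$n_snps
  n_causal <- max(1L, round(config$causal_fraction * p))
  betas <- sapply(config$disorders, function(d) {
    b <- numeric(p)
    b[sample.int(p, n_causal)] <- rnorm(n_causal, 0, 0.05)
    b
  })
  rownames(betas) <- sprintf("rs%06d", seq_len(p))

  dims <- config$grid_dims
  # ellipsoidal "brain" mask centred in the grid
  ax <- lapply(dims, function(d) (seq_len(d) - (d + 1) / 2) / (d / 2))
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  mask <- r2 <= 0.9^2
  template <- array(0, dims)
  template[mask] <- 0.6 * exp(-r2[mask])

  # smooth sparse-support pattern: a few signed Gaussian blobs inside the mask
  in_idx <- which(mask, arr.ind = TRUE)
  n_blob <- 4L
  centers <- in_idx[sample.int(nrow(in_idx), n_blob), , drop = FALSE]
  signs <- rep(c(1, -1), length.out = n_blob)
  pat <- array(0, dims)
  coords <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                        z = seq_len(dims[3]))
  for (k in seq_len(n_blob)) {
    d2 <- (coords$x - centers[k, 1])^2 + (coords$y - centers[k, 2])^2 +
      (coords$z - centers[k, 3])^2
    pat <- pat + array(signs[k] * exp(-d2 / (2 * 2^2)), dims)
  }
  pat[!mask] <- 0
  pat[abs(pat) < 0.05] <- 0        # sparse support
  stop_if_not(any(pat != 0), "simulate_true_model: empty pattern support")

  # Confound fields are orthogonalized against the planted pattern so a
  # covariate effect never masquerades as the PRS-linked signal: signal_r
  # then indexes the effective signal strength of the confound-adjusted
  # analysis, not a quantity that residualization can inflate.
  P2 <- sum(pat^2)
  confound_maps <- lapply(names(config$confound_effect_sizes), function(cv) {
    f <- smooth_field(array(rnorm(prod(dims)), dims), config)
    f <- f - (sum(f * pat) / P2) * pat
    f <- f / sd(f[mask])
    f[!mask] <- 0
    f
  })
  names(confound_maps) <- names(config$confound_effect_sizes)

  structure(list(true_betas = betas, mask = mask, template = template,
                 true_pattern = pat, confound_maps = confound_maps),
            class = "true_model")
}

# white-noise array -> smoothed field at the config's FWHM (unit-sum kernel)
smooth_field <- function(arr, config) {
  gaussian_smooth_array(arr, config$fwhm_mm, config$voxel_size_mm)
}

#' Simulate discovery-GWAS summary statistics
#'
#' Produces per-SNP association records analytically: the estimated
#' effect is the true beta plus Gaussian noise with standard error
#' `1 / sqrt(2 * discovery_n * maf * (1 - maf))`; the p-value comes from
#' the two-sided Wald statistic. Effect and other alleles are copied from
#' the panel's counted/other alleles.
#'
#' @param true_betas Numeric vector of true per-allele effects, one per
#'   panel SNP (a single disorder's column of a `true_model`).
#' @param panel A `genotype_panel` supplying SNP metadata and MAFs.
#' @param config A [sim_config()] (for `discovery_n`).
#' @param seed Integer seed.
#' @param se_scale Multiplier on the standard error; 0 gives noise-free
#'   estimates equal to the true betas (p-values then computed with the
#'   unscaled SE).
#' @return A `summary_stats` data.frame: `id`, `chrom`, `pos_bp`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval`.
#' @export
simulate_summary_stats <- function(true_betas, panel, config,
                                   seed = derive_seed(config$seed, "sumstats"),
                                   se_scale = 1) {
  meta <- panel$snp_meta
  stop_if_not(length(true_betas) == nrow(meta),
              "simulate_summary_stats: true_betas must cover all %d panel SNPs",
              nrow(meta))
  maf <- meta$maf
  stop_if_not(all(maf > 0 & maf < 1),
              "simulate_summary_stats: MAF of 0 or 1 gives an undefined SE")
  set.seed(seed)
  se <- 1 / sqrt(2 * config$discovery_n * maf * (1 - maf))
  beta_hat <- true_betas + rnorm(length(maf), 0, se * se_scale)
  z <- beta_hat / se
  pval <- 2 * pnorm(-abs(z))
  pval <- pmax(pval, .Machine$double.xmin)   # pval strictly > 0
  out <- data.frame(
    id = meta$id, chrom = meta$chrom, pos_bp = meta$pos_bp,
    effect_allele = meta$counted_allele, other_allele = meta$other_allele,
    beta = beta_hat, se = se, pval = pval, stringsAsFactors = FALSE
  )
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Simulate a covariate table for the two-study cohort
#'
#' Per subject: group label, study (derived from the group), diagnostic
#' status (patient/control), age (group-specific normal clipped to
#' 18-68 years), sex (group-specific Bernoulli, 1 = female), and
#' intracranial volume (lognormal around 1.5e6 mm^3).
#'
#' @inheritParams simulate_genotypes
#' @return A data.frame with one row per subject: `subject`, `group`,
#'   `study`, `status`, `age`, `sex`, `icv`.
#' @export
simulate_covariates <- function(config,
                                seed = derive_seed(config$seed, "covariates")) {
  validate_sim_config(config)
  set.seed(seed)
  gs <- config$group_sizes
  groups <- rep(names(gs), times = gs)
  n <- length(groups)

  # group-level demographics: mean age, sd, fraction female
  demo <- list(MDD = c(48.8, 8.3, 0.71), HC1 = c(51.1, 7.6, 0.56),
               BD = c(43.4, 11.3, 0.48), HC2 = c(44.2, 13.1, 0.46))
  par_for <- function(g) demo[[g]] %||% c(45, 11, 0.5)

  age <- sex <- numeric(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    pp <- par_for(g)
    age[idx] <- pmin(68, pmax(18, rnorm(length(idx), pp[1], pp[2])))
    sex[idx] <- rbinom(length(idx), 1, pp[3])
  }
  status <- ifelse(is_control_group(groups), "control", "patient")
  # first two group labels belong to study 1, the rest to study 2
  study_of <- setNames(rep(c("study1", "study2"),
                           length.out = length(gs)),
                       names(gs))
  # conventional split: MDD/HC1 -> study1, BD/HC2 -> study2 when present
  if (all(c("MDD", "HC1", "BD", "HC2") %in% names(gs))) {
    study_of[c("MDD", "HC1")] <- "study1"
    study_of[c("BD", "HC2")] <- "study2"
  }
  icv <- rlnorm(n, log(1.5e6), 0.08)
  data.frame(subject = sprintf("S%04d", seq_len(n)), group = groups,
             study = unname(study_of[groups]), status = status,
             age = age, sex = sex, icv = icv, stringsAsFactors = FALSE)
}

#' Simulate grey-matter maps carrying a planted multivariate signal
#'
#' Each subject's map is `template + smoothed noise + prs_z * scale *
#' true_pattern + covariate confounds`. The noise is white noise smoothed
#' at the config's FWHM and rescaled to `noise_sd` within the mask. The
#' signal scale is calibrated so the correlation between `prs_z` and the
#' pattern's inner product with the maps equals `signal_r` in
#' expectation: with `v` the variance of the nuisance part's projection
#' on the pattern and `P2` the pattern's squared norm, `scale =
#' sqrt(v * r^2 / (1 - r^2)) / P2`.
#'
#' @param config A [sim_config()].
#' @param prs_z Numeric vector, one standardized score per subject
#'   (mean 0, sd 1).
#' @param covariates Covariate table from [simulate_covariates()].
#' @param true_model A `true_model` from [simulate_true_model()].
#' @param seed Integer seed.
#' @return A `voxel_image_set`: `data` (4D array, grid x subject),
#'   `grid_dims`, `voxel_size_mm`, `mask`, `modulated` flag, `subjects`.
#' @export
simulate_brain_images <- function(config, prs_z, covariates, true_model,
                                  seed = derive_seed(config$seed, "images")) {
  validate_sim_config(config)
  n <- length(prs_z)
  stop_if_not(nrow(covariates) == n,
              "simulate_brain_images: covariates (%d rows) do not match %d scores",
              nrow(covariates), n)
  stop_if_not(abs(mean(prs_z)) < 1e-6 && abs(sd(prs_z) - 1) < 1e-6,
              "simulate_brain_images: prs_z must be standardized (mean 0, sd 1)")
  dims <- config$grid_dims
  stop_if_not(identical(dim(true_model$true_pattern), as.integer(dims)),
              "simulate_brain_images: pattern grid does not match config grid")
  set.seed(seed)

  mask <- true_model$mask
  pat <- true_model$true_pattern
  P2 <- sum(pat^2)

  # standardized covariate values entering the confound fields
  zstd <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  cov_z <- list(age = zstd(covariates$age), sex = zstd(covariates$sex),
                icv = zstd(covariates$icv),
                study = zstd(as.numeric(covariates$study ==
                                          sort(unique(covariates$study))[1])),
                status = zstd(as.numeric(covariates$status == "patient")))

  nuisance <- array(0, c(dims, n))
  for (j in seq_len(n)) {
    noise <- smooth_field(array(rnorm(prod(dims)), dims), config)
    noise <- noise / sd(noise[mask]) * config$noise_sd
    vol <- noise
    for (cv in names(config$confound_effect_sizes)) {
      if (!is.null(cov_z[[cv]])) {
        vol <- vol + config$confound_effect_sizes[[cv]] * cov_z[[cv]][j] *
          true_model$confound_maps[[cv]]
      }
    }
    nuisance[, , , j] <- vol
  }

  proj <- vapply(seq_len(n), function(j) sum(nuisance[, , , j] * pat), 0)
  v_nuis <- var(proj)
  r <- config$signal_r
  scale <- if (r > 0) sqrt(v_nuis * r^2 / (1 - r^2)) / P2 else 0

  data <- array(0, c(dims, n))
  for (j in seq_len(n)) {
    data[, , , j] <- true_model$template + nuisance[, , , j] +
      prs_z[j] * scale * pat
  }
  structure(list(data = data, grid_dims = as.integer(dims),
                 voxel_size_mm = config$voxel_size_mm, mask = mask,
                 modulated = FALSE,
                 subjects = covariates$subject, signal_scale = scale),
            class = "voxel_image_set")
}

#' Partition the mask into contiguous atlas regions
#'
#' Labels in-mask voxels by grid octant, producing up to eight compact
#' pseudo-anatomical regions for weight-map summarization.
#'
#' @param true_model A `true_model` (for mask and grid).
#' @return Integer 3D array of region labels (0 outside the mask), with
#'   a `region_names` attribute.
#' @export
simulate_atlas <- function(true_model) {
  mask <- true_model$mask
  dims <- dim(mask)
  half <- ceiling(dims / 2)
  idx <- which(mask, arr.ind = TRUE)
  oct <- 1L + (idx[, 1] > half[1]) + 2L * (idx[, 2] > half[2]) +
    4L * (idx[, 3] > half[3])
  atlas <- array(0L, dims)
  atlas[mask] <- oct
  attr(atlas, "region_names") <-
    setNames(sprintf("octant_%d", 1:8), 1:8)
  atlas
}

#' Generate a complete synthetic imaging-genetics cohort
#'
#' Orchestrates the generator: covariates, genotype panel, ground-truth
#' model, per-disorder discovery summary statistics, and grey-matter
#' maps whose planted pattern tracks the target disorder's standardized
#' true genetic score. Pure function of the config (including its seed).
#'
#' @param config A [sim_config()].
#' @return A `sim_cohort` list: `config`, `covariates`, `panel`,
#'   `true_model`, `sumstats` (named list per disorder), `images`,
#'   `atlas`, `prs_z_true` (standardized target score driving the maps).
#' @export
#' @examples
#' cfg <- sim_config(group_sizes = c(MDD = 6, HC1 = 6, BD = 4, HC2 = 4),
#'                   n_snps = 20, n_blocks = 5, grid_dims = c(6, 6, 6),
#'                   discovery_n = 10000, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' nrow(cohort$covariates)
simulate_cohort <- function(config) {
  validate_sim_config(config)
  covariates <- simulate_covariates(config)
  panel <- simulate_genotypes(config)
  truth <- simulate_true_model(config)
  sumstats <- lapply(seq_along(config$disorders), function(k) {
    simulate_summary_stats(truth$true_betas[, k], panel, config,
                           seed = derive_seed(config$seed,
                                              paste0("sumstats_", k)))
  })
  names(sumstats) <- config$disorders

  g <- as.vector(panel$dosage %*% truth$true_betas[, config$target_disorder])
  prs_z <- if (sd(g) > 0) (g - mean(g)) / sd(g) else {
    set.seed(derive_seed(config$seed, "score_fallback"))
    z <- rnorm(length(g))
    (z - mean(z)) / sd(z)
  }
  images <- simulate_brain_images(config, prs_z, covariates, truth)
  atlas <- simulate_atlas(truth)
  structure(list(config = config, covariates = covariates, panel = panel,
                 true_model = truth, sumstats = sumstats, images = images,
                 atlas = atlas, prs_z_true = prs_z),
            class = "sim_cohort")
}
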