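#' Simulation configuration for a synthetic imaging-genetics cohort
#'
#' Bundles every knob of the cohort generator: group sizes, genotype panel
#' structure (LD blocks, allele frequencies), discovery-GWAS sample size,
#' image grid geometry and smoothing, the strength of the planted
#' PRS-linked grey-matter pattern, and covariate confounding.
#'
#' The defaults describe a two-study case-control cohort of 213 subjects
#' (69 depression patients + 70 controls from one study; 33 bipolar
#' patients + 41 controls from a second study), genotyped on a small
#' block-structured panel, imaged on a coarse isotropic grid.
#'
#' @param group_sizes Named integer vector of subjects per group. Groups
#'   ending in a digit-suffixed "HC" label are controls; others patients.
#' @param n_snps Number of SNPs in the panel; must be divisible by
#'   `n_blocks`.
#' @param n_blocks Number of independent LD blocks.
#' @param within_block_corr Latent pairwise correlation of SNPs within a
#'   block, in `[0, 1)`.
#' @param maf_range Length-2 numeric in `(0, 0.5]`: minor allele
#'   frequencies are drawn uniformly in this range.
#' @param discovery_n Discovery-GWAS sample size governing summary-stat
#'   noise.
#' @param causal_fraction Fraction of SNPs with nonzero true effect.
#' @param grid_dims Integer triple of voxel-grid dimensions, all >= 4.
#' @param voxel_size_mm Numeric triple, voxel edge lengths in mm.
#' @param fwhm_mm Full-width-half-maximum of the Gaussian smoothing
#'   kernel applied to image noise, in mm (>= 0).
#' @param signal_r Target correlation in `[0, 1)` between the standardized
#'   PRS and the planted pattern's expression in the images.
#' @param noise_sd Standard deviation of the smoothed image noise (> 0).
#' @param confound_effect_sizes Named numeric vector: per-covariate
#'   effect sizes planting covariate-linked spatial confounds.
#' @param disorders Character vector of disorder labels for which
#'   discovery summary statistics and scores are simulated.
#' @param target_disorder Which disorder's genetic score drives the
#'   planted grey-matter pattern.
#' @param seed Integer master seed; identical config + seed gives a
#'   bit-identical cohort.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(grid_dims = c(8, 8, 8), n_snps = 60, n_blocks = 12)
#' sum(cfg$group_sizes)  # 213
sim_config <- function(group_sizes = c(MDD = 69L, HC1 = 70L, BD = 33L, HC2 = 41L),
                       n_snps = 300L,
                       n_blocks = 60L,
                       within_block_corr = 0.7,
                       maf_range = c(0.05, 0.5),
                       discovery_n = 50000L,
                       causal_fraction = 0.2,
                       grid_dims = c(12L, 12L, 12L),
                       voxel_size_mm = c(2, 2, 2),
                       fwhm_mm = 8,
                       signal_r = 0.5,
                       noise_sd = 1,
                       confound_effect_sizes = c(age = 0.3, sex = 0.2,
                                                 icv = 0.3, study = 0.2),
                       disorders = c("ADHD", "AUT", "BD", "SCZ"),
                       target_disorder = "AUT",
                       seed = 1L) {
  cfg <- list(
    group_sizes = group_sizes, n_snps = as.integer(n_snps),
    n_blocks = as.integer(n_blocks),
    within_block_corr = within_block_corr, maf_range = maf_range,
    discovery_n = as.integer(discovery_n),
    causal_fraction = causal_fraction,
    grid_dims = as.integer(grid_dims), voxel_size_mm = voxel_size_mm,
    fwhm_mm = fwhm_mm, signal_r = signal_r, noise_sd = noise_sd,
    confound_effect_sizes = confound_effect_sizes,
    disorders = disorders, target_disorder = target_disorder,
    seed = as.integer(seed)
  )
  stop_if_not(target_disorder %in% disorders,
              "sim_config: target_disorder must be one of the disorders")
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  req <- c("group_sizes", "n_snps", "n_blocks", "within_block_corr",
           "maf_range", "discovery_n", "causal_fraction", "grid_dims",
           "voxel_size_mm", "fwhm_mm", "signal_r", "noise_sd", "seed")
  missing <- setdiff(req, names(cfg))
  stop_if_not(length(missing) == 0L,
              "sim_config: missing required field(s): %s",
              paste(missing, collapse = ", "))
  stop_if_not(sum(cfg$group_sizes) > 0, "sim_config: sum of group_sizes must be > 0")
  stop_if_not(!is.null(names(cfg$group_sizes)) && all(nzchar(names(cfg$group_sizes))),
              "sim_config: group_sizes must be named")
  stop_if_not(cfg$n_blocks <= cfg$n_snps, "sim_config: n_blocks must be <= n_snps")
  stop_if_not(cfg$within_block_corr >= 0 && cfg$within_block_corr < 1,
              "sim_config: within_block_corr must be in [0, 1)")
  stop_if_not(length(cfg$maf_range) == 2L && all(cfg$maf_range > 0) &&
                all(cfg$maf_range <= 0.5) && cfg$maf_range[1] <= cfg$maf_range[2],
              "sim_config: maf_range must be an ordered pair in (0, 0.5]")
  stop_if_not(cfg$causal_fraction > 0 && cfg$causal_fraction <= 1,
              "sim_config: causal_fraction must be in (0, 1]")
  stop_if_not(length(cfg$grid_dims) == 3L && all(cfg$grid_dims >= 4L),
              "sim_config: grid_dims must be an integer triple, all >= 4")
  stop_if_not(cfg$fwhm_mm >= 0, "sim_config: fwhm_mm must be >= 0")
  stop_if_not(cfg$signal_r >= 0 && cfg$signal_r < 1,
              "sim_config: signal_r must be in [0, 1)")
  stop_if_not(cfg$noise_sd > 0, "sim_config: noise_sd must be > 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  subjects:", sum(x$group_sizes), "(",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes), collapse = ", "),
      ")\n")
  cat("  panel:", x$n_snps, "SNPs in", x$n_blocks, "LD blocks (r =",
      x$within_block_corr, ")\n")
  cat("  grid:", paste(x$grid_dims, collapse = "x"), "voxels at",
      paste(x$voxel_size_mm, collapse = "x"), "mm\n")
  cat("  signal_r:", x$signal_r, " noise_sd:", x$noise_sd,
      " seed:", x$seed, "\n")
  invisible(x)
}

# Control groups: labels starting with "HC".
is_control_group <- function(labels) grepl("^HC", labels)
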