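#' @name pipeline
#' @title Stage-level pipeline runners
#' @description
#' File-based pipeline stages mirroring the analysis chain:
#' [run_simulate()] writes a full synthetic cohort to disk;
#' [run_prs()] builds polygenic scores from the on-disk summary
#' statistics and dosages; [run_univariate()] runs the voxelwise GLM
#' with permutation FWE; [run_mvpa()] runs cross-validated RVR with
#' permutation significance and FDR; [run_report()] collates the score
#' and prediction tables into delimited text. Every stage writes a
#' `manifest.json` recording the configuration, seeds, package version
#' and input checksums. The thin command-line entry point at
#' `inst/cli/prsmvpa.R` dispatches to these functions.
NULL

write_manifest <- function(dir, stage, config = NULL, seed = NULL,
                           inputs = character(0), extra = list()) {
  files <- inputs[file.exists(inputs)]
  doc <- c(list(stage = stage,
                package = "prsmvpa",
                version = as.character(utils::packageVersion("prsmvpa")),
                timestamp = format(Sys.time(), tz = "UTC"),
                seed = seed,
                config = if (!is.null(config)) unclass(config),
                input_checksums = as.list(tools::md5sum(files))),
           extra)
  jsonlite::write_json(doc, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(doc)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Simulate a cohort and write every input the analysis consumes
#'
#' Writes dosages (`dosages.tsv` + `snps.tsv` map), per-disorder
#' summary statistics (`sumstats_<disorder>.tsv`), covariates, NIfTI
#' grey-matter maps with mask and atlas, ground-truth files
#' (`true_pattern.nii`, `true_betas.tsv`, `prs_z_true.tsv`), and a
#' manifest.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the in-memory `sim_cohort`.
#' @export
run_simulate <- function(config, out_dir) {
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)

  write_tsv(cohort$covariates, file.path(out_dir, "covariates.tsv"))
  dos <- data.frame(subject = cohort$panel$subjects,
                    cohort$panel$dosage, check.names = FALSE)
  write_tsv(dos, file.path(out_dir, "dosages.tsv"))
  write_tsv(cohort$panel$snp_meta, file.path(out_dir, "snps.tsv"))
  for (d in names(cohort$sumstats)) {
    ss <- cohort$sumstats[[d]]
    write_tsv(data.frame(SNP = ss$id, CHR = ss$chrom, BP = ss$pos_bp,
                         A1 = ss$effect_allele, A2 = ss$other_allele,
                         BETA = ss$beta, P = ss$pval),
              file.path(out_dir, sprintf("sumstats_%s.tsv", d)))
  }
  write_image_set(cohort$images, file.path(out_dir, "images"))
  write_nifti_volume(cohort$atlas, file.path(out_dir, "atlas.nii"),
                     config$voxel_size_mm)
  write_nifti_volume(cohort$true_model$true_pattern,
                     file.path(out_dir, "true_pattern.nii"),
                     config$voxel_size_mm)
  tb <- cohort$true_model$true_betas
  write_tsv(data.frame(id = rownames(tb), tb, check.names = FALSE),
            file.path(out_dir, "true_betas.tsv"))
  write_tsv(data.frame(subject = cohort$covariates$subject,
                       prs_z_true = cohort$prs_z_true),
            file.path(out_dir, "prs_z_true.tsv"))
  write_manifest(out_dir, "simulate", config = config, seed = config$seed)
  invisible(cohort)
}

read_cohort_panel <- function(dir) {
  snps <- read.table(file.path(dir, "snps.tsv"), header = TRUE,
                     colClasses = c(chrom = "character"),
                     stringsAsFactors = FALSE)
  dos <- read.table(file.path(dir, "dosages.tsv"), header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
  D <- as.matrix(dos[, -1, drop = FALSE])
  rownames(D) <- dos$subject
  structure(list(subjects = dos$subject, dosage = D,
                 snp_meta = snps), class = "genotype_panel")
}

#' Build PRS tables from an on-disk cohort
#'
#' Clump + threshold + align + score each disorder, standardize to the
#' pooled controls, and report group F tests and pairwise score
#' correlations.
#'
#' @param cohort_dir Directory written by [run_simulate()] (or with the
#'   same layout).
#' @param out_dir Output directory.
#' @param r2_threshold,window_kb,p_threshold,mode,exclusions Scoring
#'   parameters (defaults: r^2 0.25, 200 kb, p < 0.1, sum).
#' @return Invisibly, a list with the score matrix, z-scores, group
#'   statistics and correlation table.
#' @export
run_prs <- function(cohort_dir, out_dir, r2_threshold = 0.25,
                    window_kb = 200, p_threshold = 0.1, mode = "sum",
                    exclusions = mhc_region()) {
  need <- file.path(cohort_dir, c("covariates.tsv", "dosages.tsv", "snps.tsv"))
  for (f in need) stop_if_not(file.exists(f), "run_prs: missing input: %s", f)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  covariates <- read.table(file.path(cohort_dir, "covariates.tsv"),
                           header = TRUE, stringsAsFactors = FALSE)
  panel <- read_cohort_panel(cohort_dir)
  ss_files <- list.files(cohort_dir, "^sumstats_.*\\.tsv$", full.names = TRUE)
  stop_if_not(length(ss_files) > 0, "run_prs: no sumstats_*.tsv in %s", cohort_dir)
  sumstats <- lapply(ss_files, read_summary_stats)
  names(sumstats) <- sub("^sumstats_(.*)\\.tsv$", "\\1", basename(ss_files))

  tab <- build_prs_table(sumstats, panel, r2_threshold, window_kb,
                         exclusions, p_threshold, mode)
  is_ctrl <- covariates$status == "control"
  z <- apply(tab$scores, 2, standardize_to_controls, is_control = is_ctrl)
  # pool controls across studies: three diagnostic groups
  groups <- ifelse(is_ctrl, "HC", covariates$group)
  group_stats <- lapply(colnames(z), function(d) {
    gc <- group_compare(z[, d], groups)
    data.frame(disorder = d, F = gc$F, df1 = gc$df[1], df2 = gc$df[2],
               p = gc$p, stringsAsFactors = FALSE)
  })
  group_stats <- do.call(rbind, group_stats)
  correlations <- score_correlations(tab$scores)

  write_tsv(data.frame(subject = panel$subjects, tab$scores,
                       check.names = FALSE),
            file.path(out_dir, "prs.tsv"))
  write_tsv(data.frame(subject = panel$subjects, z, check.names = FALSE),
            file.path(out_dir, "prs_z.tsv"))
  write_tsv(group_stats, file.path(out_dir, "group_stats.tsv"))
  write_tsv(correlations, file.path(out_dir, "score_correlations.tsv"))
  write_manifest(out_dir, "prs", inputs = need,
                 extra = list(n_snps_used = as.list(tab$n_snps_used),
                              mode = mode, p_threshold = p_threshold,
                              r2_threshold = r2_threshold,
                              window_kb = window_kb))
  invisible(list(scores = tab$scores, z = z, group_stats = group_stats,
                 correlations = correlations, n_snps_used = tab$n_snps_used))
}

read_cohort_features <- function(cohort_dir, fwhm_mm = 0) {
  covariates <- read.table(file.path(cohort_dir, "covariates.tsv"),
                           header = TRUE, stringsAsFactors = FALSE)
  files <- file.path(cohort_dir, "images",
                     paste0(covariates$subject, ".nii"))
  images <- read_image_set(files, file.path(cohort_dir, "images", "mask.nii"),
                           subjects = covariates$subject)
  if (fwhm_mm > 0) images <- gaussian_smooth(images, fwhm_mm)
  list(covariates = covariates, images = images,
       features = vectorize(images))
}

#' Voxelwise GLM stage with permutation FWE
#'
#' @param cohort_dir Cohort directory (images + covariates).
#' @param prs_file Path to a score table (`subject` column + one column
#'   per disorder).
#' @param disorder Which score column to regress on.
#' @param out_dir Output directory.
#' @param n_perm,alpha,cluster_forming_p,k_min,seed Passed to
#'   [fwe_correct()].
#' @return Invisibly, the `stat_map`.
#' @export
run_univariate <- function(cohort_dir, prs_file, disorder, out_dir,
                           n_perm = 1000L, alpha = 0.05,
                           cluster_forming_p = 0.001, k_min = 20L,
                           seed = 1L) {
  stop_if_not(file.exists(prs_file), "run_univariate: missing input: %s", prs_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ch <- read_cohort_features(cohort_dir)
  prs <- read.table(prs_file, header = TRUE, stringsAsFactors = FALSE)
  stop_if_not(disorder %in% names(prs),
              "run_univariate: no column '%s' in %s", disorder, prs_file)
  stopifnot(identical(prs$subject, ch$covariates$subject))
  X <- vbm_design(ch$covariates, prs[[disorder]])
  stat <- fwe_correct(ch$features, X, n_perm = n_perm, alpha = alpha,
                      cluster_forming_p = cluster_forming_p,
                      k_min = k_min, seed = seed)
  write_stat_map(stat, out_dir, prefix = paste0("vbm_", disorder))
  write_manifest(out_dir, "univariate", seed = seed,
                 inputs = prs_file,
                 extra = list(disorder = disorder, n_perm = n_perm,
                              alpha = alpha,
                              cluster_forming_p = cluster_forming_p,
                              k_min = k_min))
  invisible(stat)
}

#' Multivariate stage: cross-validated RVR with permutation + FDR
#'
#' For each disorder column of the score table: confound-residualized
#' cross-validated RVR, Pearson r and normalized MSE, permutation
#' p-values, and Benjamini-Hochberg adjustment per metric across the
#' disorders. Writes a JSON results document, mean weight maps as
#' NIfTI, and per-disorder region summary tables when an atlas is
#' present. `n_perm = 0` skips significance testing with a warning.
#'
#' @param cohort_dir Cohort directory.
#' @param prs_file Score table path (`subject` + disorder columns).
#' @param out_dir Output directory.
#' @param scheme A [cv_scheme()].
#' @param opts An [rvr_opts()].
#' @param n_perm Number of permutations (0 = metrics only).
#' @param seed Permutation seed.
#' @param disorders Subset of score columns; default all.
#' @return Invisibly, the per-disorder results list.
#' @export
run_mvpa <- function(cohort_dir, prs_file, out_dir,
                     scheme = cv_scheme("loso"), opts = rvr_opts(),
                     n_perm = 1000L, seed = 1L, disorders = NULL) {
  stop_if_not(file.exists(prs_file), "run_mvpa: missing input: %s", prs_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ch <- read_cohort_features(cohort_dir)
  prs <- read.table(prs_file, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(identical(prs$subject, ch$covariates$subject))
  disorders <- disorders %||% setdiff(names(prs), "subject")

  atlas <- NULL
  atlas_file <- file.path(cohort_dir, "atlas.nii")
  if (file.exists(atlas_file)) {
    a <- RNifti::readNifti(atlas_file)
    atlas <- array(as.integer(round(as.vector(a))), dim(a)[1:3])
  }
  if (n_perm == 0) {
    warning("run_mvpa: n_perm = 0; reporting metrics without p-values")
  }

  results <- list()
  for (d in disorders) {
    y <- prs[[d]]
    cv <- run_cv(ch$features, y, ch$covariates, scheme, opts)
    res <- list(disorder = d, pearson_r = cv$metrics$pearson_r,
                nmse = cv$metrics$nmse,
                fold_sizes = as.integer(table(cv$folds)))
    if (n_perm > 0) {
      pt <- permutation_test(ch$features, y, ch$covariates, scheme, opts,
                             n_perm = n_perm,
                             seed = derive_seed(seed, paste0("perm_", d)))
      res$p_r <- pt$p_r
      res$p_nmse <- pt$p_nmse
    }
    wmap <- devectorize(cv$mean_weights, ch$features)
    write_nifti_volume(wmap, file.path(out_dir, sprintf("weights_%s.nii", d)),
                       ch$features$voxel_size_mm)
    if (!is.null(atlas)) {
      rc <- region_contributions(wmap, atlas, ch$features$mask)
      fold_rc <- lapply(seq_len(nrow(cv$fold_weights)), function(i) {
        region_contributions(devectorize(cv$fold_weights[i, ], ch$features),
                             atlas, ch$features$mask)
      })
      er <- expected_ranking(fold_rc)
      rc$expected_rank <- er$expected_rank[match(rc$region_id, er$region_id)]
      write_tsv(rc, file.path(out_dir, sprintf("regions_%s.tsv", d)))
      res$regions = rc
    }
    results[[d]] <- res
  }
  if (n_perm > 0) {
    p_r <- vapply(results, `[[`, 0, "p_r")
    p_nmse <- vapply(results, `[[`, 0, "p_nmse")
    p_r_fdr <- fdr_correct(p_r)
    p_nmse_fdr <- fdr_correct(p_nmse)
    for (i in seq_along(results)) {
      results[[i]]$p_r_fdr <- p_r_fdr[i]
      results[[i]]$p_nmse_fdr <- p_nmse_fdr[i]
    }
  }
  doc <- lapply(results, function(r) r[setdiff(names(r), "regions")])
  jsonlite::write_json(doc, file.path(out_dir, "mvpa_results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "mvpa", seed = seed, inputs = prs_file,
                 extra = list(scheme = unclass(scheme), n_perm = n_perm,
                              disorders = disorders))
  invisible(results)
}

#' Collate score and prediction summaries into a plain-text report
#'
#' Reproduces the numbers from the upstream result files verbatim: the
#' per-disorder group statistics (score stage) and the per-disorder
#' prediction metrics with uncorrected and FDR-adjusted p-values (MVPA
#' stage).
#'
#' @param prs_dir Directory written by [run_prs()] (optional).
#' @param mvpa_dir Directory written by [run_mvpa()].
#' @param out_dir Output directory.
#' @return Invisibly, the collated tables.
#' @export
run_report <- function(prs_dir = NULL, mvpa_dir, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mv_file <- file.path(mvpa_dir, "mvpa_results.json")
  stop_if_not(file.exists(mv_file), "run_report: missing input: %s", mv_file)
  mv <- jsonlite::read_json(mv_file, simplifyVector = FALSE)
  pred <- do.call(rbind, lapply(mv, function(r) {
    data.frame(disorder = r$disorder, pearson_r = r$pearson_r,
               nmse = r$nmse, p_r = r$p_r %||% NA_real_,
               p_r_fdr = r$p_r_fdr %||% NA_real_,
               p_nmse = r$p_nmse %||% NA_real_,
               p_nmse_fdr = r$p_nmse_fdr %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
  write_tsv(pred, file.path(out_dir, "prediction_summary.tsv"))

  grp <- NULL
  if (!is.null(prs_dir) && file.exists(file.path(prs_dir, "group_stats.tsv"))) {
    grp <- read.table(file.path(prs_dir, "group_stats.tsv"), header = TRUE,
                      stringsAsFactors = FALSE)
    file.copy(file.path(prs_dir, "group_stats.tsv"),
              file.path(out_dir, "score_group_summary.tsv"), overwrite = TRUE)
  }
  txt <- c("Prediction of polygenic scores from grey-matter patterns",
           "========================================================", "",
           utils::capture.output(print(pred, row.names = FALSE)))
  if (!is.null(grp)) {
    txt <- c(txt, "", "Score group comparisons", "-----------------------",
             utils::capture.output(print(grp, row.names = FALSE)))
  }
  writeLines(txt, file.path(out_dir, "report.txt"))
  write_manifest(out_dir, "report", inputs = mv_file)
  invisible(list(prediction = pred, group_stats = grp))
}
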