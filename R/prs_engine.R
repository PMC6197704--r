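#' Default MHC exclusion region
#'
#' The extended major histocompatibility complex on chromosome 6 is
#' excluded from PRS construction because of its long-range linkage
#' disequilibrium. The default is deliberately wide
#' (chr6:25,000,000-35,000,000, half-open).
#'
#' @param chrom,start_bp,end_bp Region coordinates (half-open interval).
#' @return A one-row `exclusion_region` data.frame.
#' @export
mhc_region <- function(chrom = "6", start_bp = 25000000L, end_bp = 35000000L) {
  stop_if_not(start_bp < end_bp, "mhc_region: start_bp must be < end_bp")
  data.frame(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
             stringsAsFactors = FALSE)
}

in_exclusion <- function(stats, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0L) {
    return(rep(FALSE, nrow(stats)))
  }
  hit <- rep(FALSE, nrow(stats))
  for (k in seq_len(nrow(exclusions))) {
    hit <- hit | (stats$chrom == exclusions$chrom[k] &
                    stats$pos_bp >= exclusions$start_bp[k] &
                    stats$pos_bp < exclusions$end_bp[k])
  }
  hit
}

#' P-value-informed LD clumping
#'
#' Greedy clumping against the analysis panel's own dosages: SNPs in the
#' exclusion regions are removed first; the remainder are processed in
#' ascending p-value (ties broken by `(pval, pos_bp, id)`); each index
#' SNP is retained and every unprocessed SNP on the same chromosome
#' within `window_kb` kb (either side) whose squared Pearson dosage
#' correlation with the index exceeds `r2_threshold` is removed.
#' Zero-variance SNPs are excluded with a warning (their r^2 is
#' undefined). Defaults follow the common PRS configuration of r^2 =
#' 0.25 within a 200 kb window.
#'
#' @param stats A `summary_stats` data.frame.
#' @param panel A `genotype_panel` containing every SNP in `stats`.
#' @param r2_threshold Squared-correlation cut-off in (0, 1).
#' @param window_kb Window half-width in kb.
#' @param exclusions Exclusion regions (data.frame with `chrom`,
#'   `start_bp`, `end_bp`); default the MHC region.
#' @return Character vector of retained SNP ids.
#' @export
ld_clump <- function(stats, panel, r2_threshold = 0.25, window_kb = 200,
                     exclusions = mhc_region()) {
  stop_if_not(r2_threshold > 0 && r2_threshold < 1,
              "ld_clump: r2_threshold must be in (0, 1)")
  missing <- setdiff(stats$id, colnames(panel$dosage))
  stop_if_not(length(missing) == 0L,
              "ld_clump: SNPs missing from the panel: %s",
              paste(head(missing, 10), collapse = ", "))

  stats <- stats[!in_exclusion(stats, exclusions), , drop = FALSE]
  if (nrow(stats) == 0L) return(character(0))

  sds <- apply(panel$dosage[, stats$id, drop = FALSE], 2, sd)
  if (any(sds == 0)) {
    warning(sprintf("ld_clump: excluding %d zero-variance SNP(s): %s",
                    sum(sds == 0),
                    paste(head(stats$id[sds == 0], 5), collapse = ", ")))
    stats <- stats[sds > 0, , drop = FALSE]
  }
  if (nrow(stats) == 0L) return(character(0))

  ord <- order(stats$pval, stats$pos_bp, stats$id)
  stats <- stats[ord, , drop = FALSE]
  window_bp <- window_kb * 1000

  alive <- rep(TRUE, nrow(stats))
  retained <- character(0)
  for (i in seq_len(nrow(stats))) {
    if (!alive[i]) next
    retained <- c(retained, stats$id[i])
    later <- which(alive & seq_len(nrow(stats)) > i &
                     stats$chrom == stats$chrom[i] &
                     abs(stats$pos_bp - stats$pos_bp[i]) <= window_bp)
    if (length(later)) {
      r <- as.vector(cor(panel$dosage[, stats$id[i]],
                         panel$dosage[, stats$id[later], drop = FALSE]))
      alive[later[r^2 > r2_threshold]] <- FALSE
    }
  }
  retained
}

#' Select clumped SNPs below a p-value threshold
#'
#' Keeps exactly the retained SNPs with `pval < p_threshold` (strict:
#' ties at the boundary are excluded). The conventional default
#' threshold is 0.1.
#'
#' @param stats A `summary_stats` data.frame.
#' @param retained Character vector of SNP ids surviving clumping.
#' @param p_threshold Threshold in (0, 1].
#' @return The subset of `stats` passing the threshold.
#' @export
threshold_select <- function(stats, retained, p_threshold = 0.1) {
  stop_if_not(p_threshold > 0 && p_threshold <= 1,
              "threshold_select: p_threshold must be in (0, 1]")
  out <- stats[stats$id %in% retained & stats$pval < p_threshold, ,
               drop = FALSE]
  stop_if_not(nrow(out) > 0L,
              "threshold_select: no SNPs pass p < %g; a score over 0 SNPs is undefined",
              p_threshold)
  out
}

#' Align summary-statistic effects to the panel's counted alleles
#'
#' For each shared SNP: if the panel's counted allele equals the effect
#' allele the beta is kept; if it equals the other allele the beta is
#' negated (the dosage counts the opposite allele); strand-ambiguous
#' pairs (A/T, C/G) and unresolvable allele pairs are dropped with a
#' warning.
#'
#' @param stats A `summary_stats` subset (post-threshold).
#' @param panel A `genotype_panel`.
#' @return A list: `effects` (named numeric vector of aligned betas, by
#'   SNP id), `dropped_ambiguous`, `dropped_unresolved` (id vectors).
#' @export
allele_align <- function(stats, panel) {
  meta <- panel$snp_meta
  rownames(meta) <- meta$id
  stop_if_not(all(stats$id %in% meta$id),
              "allele_align: stats contain SNPs absent from the panel")
  m <- meta[stats$id, , drop = FALSE]

  ambiguous <- (stats$effect_allele == "A" & stats$other_allele == "T") |
    (stats$effect_allele == "T" & stats$other_allele == "A") |
    (stats$effect_allele == "C" & stats$other_allele == "G") |
    (stats$effect_allele == "G" & stats$other_allele == "C")

  same <- m$counted_allele == stats$effect_allele &
    m$other_allele == stats$other_allele
  flipped <- m$counted_allele == stats$other_allele &
    m$other_allele == stats$effect_allele
  unresolved <- !ambiguous & !same & !flipped

  if (any(ambiguous)) {
    warning(sprintf("allele_align: dropping %d strand-ambiguous SNP(s)",
                    sum(ambiguous)))
  }
  if (any(unresolved)) {
    warning(sprintf("allele_align: dropping %d SNP(s) with unresolvable alleles",
                    sum(unresolved)))
  }
  keep <- !ambiguous & !unresolved
  eff <- ifelse(flipped, -stats$beta, stats$beta)[keep]
  names(eff) <- stats$id[keep]
  list(effects = eff,
       dropped_ambiguous = stats$id[ambiguous],
       dropped_unresolved = stats$id[unresolved & !ambiguous])
}

#' Compute polygenic scores from aligned effects
#'
#' `score_j = sum_i beta_i * dosage_ij` (sum mode) or that divided by
#' the SNP count (mean mode). Missing dosages are mean-imputed per SNP
#' before scoring; a SNP with no observed dosages is rejected.
#'
#' @param panel A `genotype_panel`.
#' @param effects Named numeric vector of aligned per-allele effects.
#' @param mode `"sum"` (default) or `"mean"`.
#' @return Named numeric vector of scores, one per subject, with
#'   attribute `n_snps_used`.
#' @export
compute_prs <- function(panel, effects, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  stop_if_not(length(effects) >= 1L, "compute_prs: need at least one SNP")
  ids <- names(effects)
  stop_if_not(all(ids %in% colnames(panel$dosage)),
              "compute_prs: effects reference SNPs absent from the panel")
  D <- panel$dosage[, ids, drop = FALSE]
  if (anyNA(D)) {
    for (k in seq_len(ncol(D))) {
      col <- D[, k]
      if (anyNA(col)) {
        stop_if_not(!all(is.na(col)),
                    "compute_prs: SNP %s has no observed dosages", ids[k])
        col[is.na(col)] <- mean(col, na.rm = TRUE)
        D[, k] <- col
      }
    }
  }
  s <- as.vector(D %*% effects)
  if (mode == "mean") s <- s / length(effects)
  names(s) <- panel$subjects
  attr(s, "n_snps_used") <- length(effects)
  s
}

#' Standardize scores to the control distribution
#'
#' `z = (score - mean(controls)) / sd(controls)` with the sample SD
#' (n - 1), applied to every subject; controls are pooled across
#' studies.
#'
#' @param scores Numeric vector (or one-column per-disorder matrix) of
#'   raw scores, one per subject.
#' @param is_control Logical vector flagging control subjects.
#' @return Numeric vector of z-scores.
#' @export
standardize_to_controls <- function(scores, is_control) {
  stop_if_not(length(scores) == length(is_control),
              "standardize_to_controls: length mismatch")
  stop_if_not(sum(is_control) >= 2L,
              "standardize_to_controls: need at least 2 controls")
  mu <- mean(scores[is_control])
  s <- sd(scores[is_control])
  stop_if_not(s > 0, "standardize_to_controls: zero control variance")
  (scores - mu) / s
}

#' Group comparison of scores: one-way ANOVA plus pairwise Welch tests
#'
#' One-way ANOVA F with (k - 1, N - k) degrees of freedom across
#' diagnostic groups; when the F test is significant at `alpha`, all
#' pairwise two-sample Welch t-tests are reported uncorrected.
#'
#' @param z Numeric vector of (typically control-standardized) scores.
#' @param groups Factor or character vector of group labels.
#' @param alpha Significance level gating the pairwise tests.
#' @return A list: `F` statistic, `df` (length 2), `p`, and `pairwise`
#'   (data.frame of group pairs with Welch t and p, or NULL).
#' @export
group_compare <- function(z, groups, alpha = 0.05) {
  groups <- factor(groups)
  stop_if_not(nlevels(groups) >= 2L, "group_compare: need >= 2 groups")
  stop_if_not(all(table(groups) >= 2L),
              "group_compare: every group needs n >= 2")
  fit <- lm(z ~ groups)
  an <- anova(fit)
  Fv <- an$`F value`[1]
  df <- c(an$Df[1], an$Df[2])
  p <- an$`Pr(>F)`[1]

  pairwise <- NULL
  if (p < alpha) {
    combs <- utils::combn(levels(groups), 2)
    pairwise <- data.frame(
      group1 = combs[1, ], group2 = combs[2, ],
      t = NA_real_, p = NA_real_, stringsAsFactors = FALSE
    )
    for (k in seq_len(ncol(combs))) {
      tt <- t.test(z[groups == combs[1, k]], z[groups == combs[2, k]])
      pairwise$t[k] <- unname(tt$statistic)
      pairwise$p[k] <- tt$p.value
    }
  }
  list(F = Fv, df = df, p = p, pairwise = pairwise)
}

#' Pairwise correlations between disorder scores with BH-FDR
#'
#' All unordered pairs of score columns: Pearson r, two-sided p from the
#' t transform of r, and Benjamini-Hochberg adjusted p across the pairs.
#'
#' @param prs Numeric matrix or data.frame, one column per disorder.
#' @return A data.frame: `disorder1`, `disorder2`, `r`, `p`, `p_fdr`.
#' @export
score_correlations <- function(prs) {
  prs <- as.matrix(prs)
  stop_if_not(nrow(prs) >= 3L, "score_correlations: need >= 3 subjects")
  stop_if_not(all(apply(prs, 2, sd) > 0),
              "score_correlations: constant score column")
  combs <- utils::combn(colnames(prs), 2)
  out <- data.frame(disorder1 = combs[1, ], disorder2 = combs[2, ],
                    r = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(combs))) {
    ct <- cor.test(prs[, combs[1, k]], prs[, combs[2, k]])
    out$r[k] <- unname(ct$estimate)
    # a perfect correlation underflows to p = 0; keep p in (0, 1]
    out$p[k] <- max(ct$p.value, .Machine$double.xmin)
  }
  out$p_fdr <- fdr_correct(out$p)
  out
}

#' Build a PRS table for several disorders through the full engine
#'
#' Runs clump -> threshold -> align -> score for each disorder's summary
#' statistics against one genotype panel.
#'
#' @param sumstats_list Named list of `summary_stats`, one per disorder.
#' @param panel A `genotype_panel`.
#' @param r2_threshold,window_kb,exclusions,p_threshold,mode Passed to
#'   the component operations.
#' @return A list: `scores` (subject x disorder matrix), `n_snps_used`
#'   (named integer), `mode`, `dropped` (per-disorder drop records).
#' @export
build_prs_table <- function(sumstats_list, panel, r2_threshold = 0.25,
                            window_kb = 200, exclusions = mhc_region(),
                            p_threshold = 0.1, mode = "sum") {
  stopifnot(length(sumstats_list) >= 1L, !is.null(names(sumstats_list)))
  scores <- NULL
  n_used <- integer(0)
  dropped <- list()
  for (d in names(sumstats_list)) {
    st <- sumstats_list[[d]]
    kept <- ld_clump(st, panel, r2_threshold, window_kb, exclusions)
    sel <- threshold_select(st, kept, p_threshold)
    al <- allele_align(sel, panel)
    s <- compute_prs(panel, al$effects, mode)
    scores <- cbind(scores, s)
    n_used <- c(n_used, setNames(attr(s, "n_snps_used"), d))
    dropped[[d]] <- al[c("dropped_ambiguous", "dropped_unresolved")]
  }
  colnames(scores) <- names(sumstats_list)
  list(scores = scores, n_snps_used = n_used, mode = mode, dropped = dropped)
}

#' Read GWAS summary statistics from delimited text
#'
#' Whitespace- or tab-delimited with a header; column names are
#' configurable.
#'
#' @param path File path.
#' @param columns Named character vector mapping the canonical fields
#'   (`id`, `chrom`, `pos_bp`, `effect_allele`, `other_allele`, `beta`,
#'   `pval`) to the file's column names.
#' @return A `summary_stats` data.frame.
#' @export
read_summary_stats <- function(path,
                               columns = c(id = "SNP", chrom = "CHR",
                                           pos_bp = "BP", effect_allele = "A1",
                                           other_allele = "A2", beta = "BETA",
                                           pval = "P")) {
  raw <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  missing <- setdiff(unname(columns), names(raw))
  stop_if_not(length(missing) == 0L,
              "read_summary_stats: missing column(s): %s",
              paste(missing, collapse = ", "))
  out <- data.frame(
    id = as.character(raw[[columns["id"]]]),
    chrom = as.character(raw[[columns["chrom"]]]),
    pos_bp = as.integer(raw[[columns["pos_bp"]]]),
    effect_allele = as.character(raw[[columns["effect_allele"]]]),
    other_allele = as.character(raw[[columns["other_allele"]]]),
    beta = as.numeric(raw[[columns["beta"]]]),
    pval = as.numeric(raw[[columns["pval"]]]),
    stringsAsFactors = FALSE
  )
  stop_if_not(!anyDuplicated(out$id), "read_summary_stats: duplicate SNP ids")
  stop_if_not(all(out$pval > 0), "read_summary_stats: p-values must be > 0")
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Read a dosage matrix from a PLINK .raw-style export
#'
#' Expects a header line with `FID IID ...` followed by one column per
#' SNP named `<id>_<counted allele>`; remaining standard PLINK columns
#' (PAT, MAT, SEX, PHENOTYPE) are ignored if present. SNP positions are
#' taken from a companion map (data.frame with `id`, `chrom`, `pos_bp`,
#' `other_allele`).
#'
#' @param path File path to the delimited export.
#' @param snp_map Data.frame with `id`, `chrom`, `pos_bp`,
#'   `other_allele` for every SNP column.
#' @return A `genotype_panel`.
#' @export
read_dosage_raw <- function(path, snp_map) {
  raw <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  drop <- intersect(c("FID", "PAT", "MAT", "SEX", "PHENOTYPE"), names(raw))
  subjects <- as.character(raw$IID)
  geno <- raw[, setdiff(names(raw), c(drop, "IID")), drop = FALSE]
  ids <- sub("_[ACGT]$", "", names(geno))
  counted <- sub("^.*_", "", names(geno))
  stop_if_not(!anyDuplicated(ids), "read_dosage_raw: duplicate SNP columns")
  stop_if_not(all(ids %in% snp_map$id),
              "read_dosage_raw: SNPs missing from snp_map: %s",
              paste(head(setdiff(ids, snp_map$id), 5), collapse = ", "))
  D <- as.matrix(geno)
  stop_if_not(all(is.na(D) | (D >= 0 & D <= 2)),
              "read_dosage_raw: dosages must lie in [0, 2]")
  rownames(snp_map) <- snp_map$id
  meta <- data.frame(id = ids, chrom = as.character(snp_map[ids, "chrom"]),
                     pos_bp = as.integer(snp_map[ids, "pos_bp"]),
                     counted_allele = counted,
                     other_allele = as.character(snp_map[ids, "other_allele"]),
                     stringsAsFactors = FALSE)
  dimnames(D) <- list(subjects, ids)
  structure(list(subjects = subjects, dosage = D, snp_meta = meta),
            class = "genotype_panel")
}
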