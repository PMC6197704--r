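#' Design matrix for a voxelwise PRS regression
#'
#' Nuisance covariates (intercept, age, sex, status, study, ICV) plus
#' the effect of interest as the last column.
#'
#' @param covariates Covariate table (see [covariate_design()]).
#' @param effect Numeric vector, the predictor of interest (e.g. a
#'   PRS), one value per subject.
#' @param effect_name Column name for the effect of interest.
#' @return Numeric design matrix; the effect of interest is the last
#'   column.
#' @export
vbm_design <- function(covariates, effect, effect_name = "prs") {
  X <- cbind(covariate_design(covariates), effect)
  colnames(X)[ncol(X)] <- effect_name
  X
}

# Batched OLS t-statistics for one contrast column across all voxels.
# Returns t per voxel; se == 0 voxels get +-t_cap and are flagged.
glm_tstats <- function(Y, X, interest, t_cap = 1e10) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("voxelwise GLM: design is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  # unit-norm column scaling for conditioning; t is scale-invariant
  sc <- sqrt(colSums(X^2))
  Xs <- sweep(X, 2, sc, `/`)
  XtXinv_s <- solve(crossprod(Xs))
  XtXinv <- sweep(sweep(XtXinv_s, 1, sc, `/`), 2, sc, `/`)
  B <- XtXinv %*% crossprod(X, Y)
  resid <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  cvar <- XtXinv[interest, interest]
  se <- sqrt(sigma2 * cvar)
  est <- B[interest, ]
  t_raw <- ifelse(se > 0, est / se, sign(est) * Inf)
  over <- !is.finite(t_raw) | abs(t_raw) > t_cap   # perfect/near-perfect fits
  t <- ifelse(over, sign(est) * t_cap, t_raw)
  list(t = t, df = df, capped = any(over))
}

#' Voxelwise GLM of grey matter on a predictor of interest
#'
#' Ordinary least squares per voxel; the t statistic is the contrast
#' estimate over its standard error for the effect-of-interest column.
#' Both signs are testable (negate the effect column to flip the map).
#' A perfect fit (zero residual) yields a capped t of `1e10` and sets
#' the `capped` flag.
#'
#' @param features A `feature_matrix` (or subjects x voxels matrix).
#' @param design Full-rank design matrix including an intercept; rows
#'   align with the feature rows.
#' @param interest Name or index of the effect-of-interest column;
#'   default the last column.
#' @return A `stat_map`: `t` (per masked voxel), `df`, `interest`,
#'   `capped`, plus the feature geometry for back-projection.
#' @export
fit_voxelwise_glm <- function(features, design,
                              interest = ncol(as.matrix(design))) {
  Y <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  X <- as.matrix(design)
  stop_if_not(nrow(Y) == nrow(X),
              "fit_voxelwise_glm: feature rows (%d) do not match design rows (%d)",
              nrow(Y), nrow(X))
  if (is.character(interest)) interest <- match(interest, colnames(X))
  stop_if_not(!is.na(interest) && interest >= 1 && interest <= ncol(X),
              "fit_voxelwise_glm: unknown effect-of-interest column")
  fit <- glm_tstats(Y, X, interest)
  structure(list(t = fit$t, df = fit$df, interest = interest,
                 capped = fit$capped,
                 features = if (inherits(features, "feature_matrix")) features),
            class = "stat_map")
}

# 26-connectivity connected components over suprathreshold voxels.
# coords: m x 3 voxel coordinates. Returns integer component labels.
label_clusters_26 <- function(coords, grid_dims) {
  m <- nrow(coords)
  if (m == 0L) return(integer(0))
  vox_id <- array(0L, grid_dims)
  vox_id[coords] <- seq_len(m)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  labels <- integer(m)
  comp <- 0L
  for (s in seq_len(m)) {
    if (labels[s] != 0L) next
    comp <- comp + 1L
    stack <- s
    labels[s] <- comp
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- sweep(off, 2, coords[v, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= grid_dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= grid_dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= grid_dims[3]
      ids <- vox_id[nb[ok, , drop = FALSE]]
      ids <- ids[ids > 0L]
      new <- ids[labels[ids] == 0L]
      if (length(new)) {
        labels[new] <- comp
        stack <- c(stack, new)
      }
    }
  }
  labels
}

# max suprathreshold |t| cluster size (26-connectivity) for a t-map
max_cluster_size <- function(t, u, voxel_index, grid_dims) {
  supra <- which(abs(t) > u)
  if (!length(supra)) return(0L)
  lab <- label_clusters_26(voxel_index[supra, , drop = FALSE], grid_dims)
  max(tabulate(lab))
}

#' Permutation family-wise-error correction for a voxelwise GLM
#'
#' Freedman-Lane scheme: the data are residualized against the nuisance
#' regressors, the residual rows are permuted, the reduced-model fit is
#' added back, and the full model is refit. Voxel-level corrected
#' p-values come from the null distribution of the maximum |t| across
#' voxels; cluster-level corrected p-values from the null of the
#' largest suprathreshold cluster (|t| above the two-sided
#' cluster-forming threshold, 26-connectivity). Clusters smaller than
#' the reporting floor `k_min` are omitted from the table. Defaults:
#' `alpha = 0.05`, `cluster_forming_p = 0.001`, `k_min = 20`.
#'
#' @param features A `feature_matrix` (must carry grid geometry).
#' @param design Full-rank design matrix including an intercept.
#' @param interest Effect-of-interest column (name or index; default
#'   last).
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Family-wise significance level (reported, not used to
#'   truncate output).
#' @param cluster_forming_p Two-sided per-voxel p defining
#'   suprathreshold voxels for cluster formation.
#' @param k_min Minimum cluster size reported.
#' @param seed Permutation seed.
#' @return A `stat_map` with `t`, `df`, `p_fwe_voxel` (per voxel),
#'   `clusters` (data.frame: `cluster_id`, `size`, `peak_voxel` x/y/z,
#'   `peak_t`, `p_fwe_cluster`), `threshold_t`, `n_perm`, `alpha`.
#' @export
fwe_correct <- function(features, design, interest = ncol(as.matrix(design)),
                        n_perm = 1000L, alpha = 0.05,
                        cluster_forming_p = 0.001, k_min = 20L, seed = 1L) {
  stop_if_not(n_perm >= 100, "fwe_correct: n_perm must be >= 100")
  stop_if_not(inherits(features, "feature_matrix"),
              "fwe_correct: features must be a feature_matrix (grid needed for clusters)")
  Y <- features$values
  X <- as.matrix(design)
  if (is.character(interest)) interest <- match(interest, colnames(X))
  n <- nrow(Y)

  obs <- glm_tstats(Y, X, interest)
  df <- obs$df
  u <- qt(1 - cluster_forming_p / 2, df)
  vi <- features$voxel_index
  dims <- features$grid_dims

  # reduced model: nuisance only
  Z <- X[, -interest, drop = FALSE]
  Zs <- sweep(Z, 2, sqrt(colSums(Z^2)), `/`)   # fitted values are scale-free
  Gz <- Zs %*% solve(crossprod(Zs), crossprod(Zs, Y))
  Rz <- Y - Gz

  max_t_null <- numeric(n_perm)
  max_sz_null <- integer(n_perm)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    Yp <- Gz + Rz[sample.int(n), , drop = FALSE]
    tb <- glm_tstats(Yp, X, interest)$t
    max_t_null[b] <- max(abs(tb))
    max_sz_null[b] <- max_cluster_size(tb, u, vi, dims)
  }

  p_fwe_voxel <- vapply(abs(obs$t), function(tv) {
    max(1, sum(max_t_null >= tv)) / n_perm
  }, 0)

  supra <- which(abs(obs$t) > u)
  clusters <- data.frame(cluster_id = integer(0), size = integer(0),
                         peak_x = integer(0), peak_y = integer(0),
                         peak_z = integer(0), peak_t = numeric(0),
                         p_fwe_cluster = numeric(0))
  if (length(supra)) {
    lab <- label_clusters_26(vi[supra, , drop = FALSE], dims)
    for (cid in seq_len(max(lab))) {
      members <- supra[lab == cid]
      size <- length(members)
      if (size < k_min) next
      peak <- members[which.max(abs(obs$t[members]))]
      clusters <- rbind(clusters, data.frame(
        cluster_id = cid, size = size,
        peak_x = vi[peak, 1], peak_y = vi[peak, 2], peak_z = vi[peak, 3],
        peak_t = obs$t[peak],
        p_fwe_cluster = max(1, sum(max_sz_null >= size)) / n_perm
      ))
    }
    if (nrow(clusters)) {
      clusters <- clusters[order(-clusters$size), , drop = FALSE]
      rownames(clusters) <- NULL
    }
  }

  structure(list(t = obs$t, df = df, interest = interest,
                 capped = obs$capped, p_fwe_voxel = p_fwe_voxel,
                 clusters = clusters, threshold_t = u,
                 max_t_null = max_t_null, max_size_null = max_sz_null,
                 n_perm = n_perm, alpha = alpha, features = features),
            class = "stat_map")
}

#' Two-sample group comparison within the VBM machinery
#'
#' The group-difference contrast as a 0/1 indicator column in the same
#' GLM + permutation-FWE framework.
#'
#' @param features A `feature_matrix`.
#' @param groups Two-level factor or character vector.
#' @param nuisance Optional nuisance matrix (columns beyond the
#'   intercept, e.g. age/sex/ICV); an intercept is always added.
#' @param ... Passed to [fwe_correct()] (`n_perm`, `alpha`, ...).
#' @return A `stat_map` (see [fwe_correct()]).
#' @export
two_sample_vbm <- function(features, groups, nuisance = NULL, ...) {
  groups <- factor(groups)
  stop_if_not(nlevels(groups) == 2L, "two_sample_vbm: need exactly 2 groups")
  stop_if_not(all(table(groups) >= 2L), "two_sample_vbm: both groups need n >= 2")
  ind <- as.numeric(groups == levels(groups)[2])
  X <- cbind(intercept = 1, nuisance, group = ind)
  fwe_correct(features, X, interest = "group", ...)
}

#' Write a statistic map and cluster table to disk
#'
#' The t map (and voxelwise corrected p map, when present) as NIfTI-1
#' volumes on the original grid; the cluster table as tab-delimited
#' text with voxel coordinates (1-based grid indices) and mm
#' coordinates.
#'
#' @param stat A `stat_map` carrying its `feature_matrix`.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Invisibly, the written paths.
#' @export
write_stat_map <- function(stat, dir, prefix = "statmap") {
  stop_if_not(!is.null(stat$features), "write_stat_map: stat map has no geometry")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fm <- stat$features
  paths <- file.path(dir, paste0(prefix, "_t.nii"))
  write_nifti_volume(devectorize(stat$t, fm), paths, fm$voxel_size_mm)
  if (!is.null(stat$p_fwe_voxel)) {
    p <- file.path(dir, paste0(prefix, "_pfwe.nii"))
    write_nifti_volume(devectorize(stat$p_fwe_voxel, fm), p, fm$voxel_size_mm)
    paths <- c(paths, p)
  }
  if (!is.null(stat$clusters)) {
    ct <- stat$clusters
    if (nrow(ct)) {
      vs <- fm$voxel_size_mm
      ct$peak_x_mm <- (ct$peak_x - 1) * vs[1]
      ct$peak_y_mm <- (ct$peak_y - 1) * vs[2]
      ct$peak_z_mm <- (ct$peak_z - 1) * vs[3]
    }
    cp <- file.path(dir, paste0(prefix, "_clusters.tsv"))
    write.table(ct, cp, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, cp)
  }
  invisible(paths)
}
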