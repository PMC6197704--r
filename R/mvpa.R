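#' Cross-validation scheme
#'
#' @param kind `"loso"` (leave-one-subject-out) or `"kfold"`.
#' @param k Number of folds (k-fold only, >= 2).
#' @param seed Seed for the k-fold shuffle.
#' @return A `cv_scheme` list.
#' @export
cv_scheme <- function(kind = c("loso", "kfold"), k = 10L, seed = 1L) {
  kind <- match.arg(kind)
  stop_if_not(kind == "loso" || k >= 2L, "cv_scheme: k must be >= 2")
  structure(list(kind = kind, k = as.integer(k), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Assign subjects to cross-validation folds
#'
#' Leave-one-subject-out gives n singleton folds. K-fold shuffles the
#' subjects by the scheme's seed, then the first k - 1 folds take
#' `floor(n/k)` subjects each and the last fold absorbs the remainder
#' (213 subjects in 10 folds: nine folds of 21 and one of 24).
#'
#' @param n Number of subjects.
#' @param scheme A [cv_scheme()].
#' @return Integer vector of fold ids, one per subject.
#' @export
make_folds <- function(n, scheme) {
  if (scheme$kind == "loso") return(seq_len(n))
  k <- scheme$k
  stop_if_not(k <= n, "make_folds: k = %d exceeds n = %d", k, n)
  base <- n %/% k
  sizes <- c(rep(base, k - 1L), n - base * (k - 1L))
  set.seed(scheme$seed)
  perm <- sample.int(n)
  assignment <- integer(n)
  assignment[perm] <- rep(seq_len(k), times = sizes)
  assignment
}

#' Build the confound design matrix from a covariate table
#'
#' Intercept, age, sex (0/1), status (patient = 1), study (0/1), and
#' intracranial volume, in a fixed column order.
#'
#' @param covariates Covariate table as produced by
#'   [simulate_covariates()] (columns `age`, `sex`, `status`, `study`,
#'   `icv`).
#' @return Numeric design matrix with named columns.
#' @export
covariate_design <- function(covariates) {
  studies <- sort(unique(covariates$study))
  stop_if_not(length(studies) <= 2L,
              "covariate_design: expected at most two studies")
  cbind(intercept = 1,
        age = covariates$age,
        sex = as.numeric(covariates$sex),
        status = as.numeric(covariates$status == "patient"),
        study = as.numeric(covariates$study == studies[length(studies)]),
        icv = covariates$icv)
}

#' Residualize features against confounds, training fit only
#'
#' Ordinary least squares of each training-set feature column on the
#' training covariates; the training residuals are `train - fit`, and
#' test rows are residualized with the training coefficients (no refit
#' on test data, so no leakage into the folds).
#'
#' @param X_train,X_test Feature matrices (subjects x voxels); `X_test`
#'   may be `NULL`.
#' @param C_train,C_test Covariate design matrices with intercept.
#' @return A list: `train`, `test` (residualized blocks), `coef`.
#' @export
residualize_confounds <- function(X_train, C_train, X_test = NULL,
                                  C_test = NULL) {
  C_train <- as.matrix(C_train)
  stop_if_not(qr(C_train)$rank == ncol(C_train),
              "residualize_confounds: covariate matrix is rank deficient")
  B <- solve(crossprod(C_train), crossprod(C_train, X_train))
  out <- list(train = X_train - C_train %*% B, coef = B)
  if (!is.null(X_test)) {
    stop_if_not(!is.null(C_test) && ncol(C_test) == ncol(C_train),
                "residualize_confounds: test covariates missing or misaligned")
    out$test <- X_test - as.matrix(C_test) %*% B
  }
  out
}

# Precompute per-fold residualized features and kernels. These depend
# only on (features, covariates, folds), never on the target, so they
# are shared across all permutations of y.
prepare_fold_contexts <- function(values, C, folds) {
  lapply(sort(unique(folds)), function(f) {
    te <- which(folds == f)
    tr <- which(folds != f)
    rz <- residualize_confounds(values[tr, , drop = FALSE],
                                C[tr, , drop = FALSE],
                                values[te, , drop = FALSE],
                                C[te, , drop = FALSE])
    K_tr <- linear_kernel(rz$train)
    K_te <- rz$test %*% t(rz$train)
    list(fold = f, test_idx = te, train_idx = tr,
         X_train = rz$train, K_tr = K_tr, K_te = K_te)
  })
}

# Fit/predict across folds for one target vector using prepared contexts.
cv_predict_contexts <- function(contexts, y, opts, want_weights = FALSE) {
  n <- length(y)
  y_hat <- numeric(n)
  weights <- if (want_weights) {
    matrix(NA_real_, length(contexts), ncol(contexts[[1]]$X_train))
  }
  conv <- logical(length(contexts))
  for (i in seq_along(contexts)) {
    ctx <- contexts[[i]]
    model <- rvr_fit(ctx$K_tr, y[ctx$train_idx], opts)
    conv[i] <- model$converged
    y_hat[ctx$test_idx] <- rvr_predict(model, ctx$K_te)
    if (want_weights) {
      weights[i, ] <- backproject_weights(model, ctx$X_train)$w
    }
  }
  list(y_hat = y_hat, fold_weights = weights, converged = conv)
}

#' Cross-validated RVR with in-fold confound residualization
#'
#' Per fold: residualize the confounds (training fit applied to the
#' test rows), build the linear kernel on residualized features, fit
#' the RVR, predict the held-out subjects, and back-project the fold's
#' voxel weight map. Deterministic given the data, scheme seed and
#' options.
#'
#' @param features A `feature_matrix` (or plain subjects x voxels
#'   matrix).
#' @param y Numeric target (e.g. one disorder's PRS), one per subject.
#' @param covariates Covariate table aligned with the feature rows.
#' @param scheme A [cv_scheme()].
#' @param opts An [rvr_opts()].
#' @return A `cv_result`: `y`, `y_hat` (out-of-fold predictions),
#'   `folds`, `fold_weights` (fold x voxel matrix), `mean_weights`,
#'   `metrics` (`pearson_r`, `nmse`), `folds_converged`.
#' @export
run_cv <- function(features, y, covariates, scheme = cv_scheme("loso"),
                   opts = rvr_opts()) {
  values <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  n <- length(y)
  stop_if_not(nrow(values) == n, "run_cv: feature rows do not match y")
  stop_if_not(nrow(covariates) == n, "run_cv: covariate rows do not match y")
  C <- covariate_design(covariates)
  folds <- make_folds(n, scheme)
  contexts <- prepare_fold_contexts(values, C, folds)
  fit <- cv_predict_contexts(contexts, y, opts, want_weights = TRUE)
  if (any(!fit$converged)) {
    warning(sprintf("run_cv: %d of %d folds did not converge",
                    sum(!fit$converged), length(fit$converged)))
  }
  metrics <- eval_metrics(y, fit$y_hat)
  structure(list(y = y, y_hat = fit$y_hat, folds = folds,
                 fold_weights = fit$fold_weights,
                 mean_weights = colMeans(fit$fold_weights),
                 metrics = metrics, folds_converged = fit$converged,
                 scheme = scheme),
            class = "cv_result")
}

#' Prediction metrics: Pearson r and normalized MSE
#'
#' `pearson_r` is the sample correlation of actual and predicted
#' targets. `nmse` is the mean squared error divided by the squared
#' range of the actual target by default (`range_power = 2`), making it
#' dimensionless; `range_power = 1` divides by the plain range.
#'
#' @param y Actual target (length >= 3, non-constant).
#' @param y_hat Predictions.
#' @param range_power 2 (default, squared range) or 1 (plain range).
#' @return A list: `pearson_r`, `nmse`.
#' @export
eval_metrics <- function(y, y_hat, range_power = 2) {
  stop_if_not(length(y) >= 3L, "eval_metrics: need n >= 3")
  stop_if_not(sd(y) > 0, "eval_metrics: y is constant")
  stop_if_not(length(y) == length(y_hat), "eval_metrics: length mismatch")
  r <- if (sd(y_hat) > 0) cor(y, y_hat) else 0
  nmse <- mean((y - y_hat)^2) / diff(range(y))^range_power
  list(pearson_r = r, nmse = nmse)
}

#' Permutation test for the cross-validated metrics
#'
#' The target is shuffled and the full cross-validation re-run
#' `n_perm` times; confound residualization is computed once per fold
#' and reused, since it never involves the target. One-sided p-values:
#' `p_r = max(1, #\{null r >= observed r\}) / n_perm` and `p_nmse =
#' max(1, #\{null nmse <= observed nmse\}) / n_perm`, so the smallest
#' attainable p is `1/n_perm` (0.001 at 1000 permutations).
#'
#' @inheritParams run_cv
#' @param n_perm Number of permutations (>= 1).
#' @param seed Seed for the permutation sequence.
#' @param range_power Passed to [eval_metrics()].
#' @return A list: `observed` (metrics), `p_r`, `p_nmse`, `null_r`,
#'   `null_nmse`, `n_perm`.
#' @export
permutation_test <- function(features, y, covariates,
                             scheme = cv_scheme("loso"), opts = rvr_opts(),
                             n_perm = 1000L, seed = 1L, range_power = 2) {
  stop_if_not(n_perm >= 1, "permutation_test: n_perm must be >= 1")
  values <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  n <- length(y)
  C <- covariate_design(covariates)
  folds <- make_folds(n, scheme)
  contexts <- prepare_fold_contexts(values, C, folds)

  obs_fit <- cv_predict_contexts(contexts, y, opts)
  observed <- eval_metrics(y, obs_fit$y_hat, range_power)

  null_r <- null_nmse <- numeric(n_perm)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    yp <- y[sample.int(n)]
    fit <- cv_predict_contexts(contexts, yp, opts)
    m <- eval_metrics(yp, fit$y_hat, range_power)
    null_r[b] <- m$pearson_r
    null_nmse[b] <- m$nmse
  }
  list(observed = observed,
       p_r = max(1, sum(null_r >= observed$pearson_r)) / n_perm,
       p_nmse = max(1, sum(null_nmse <= observed$nmse)) / n_perm,
       null_r = null_r, null_nmse = null_nmse, n_perm = n_perm)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: sort ascending, `adj_i = min_{j >= i}
#' (m p_j / j)` capped at 1, returned in the original order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
fdr_correct <- function(p) {
  stop_if_not(all(is.finite(p)) && all(p > 0) && all(p <= 1),
              "fdr_correct: p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Atlas-region contributions of a voxel weight map
#'
#' A region's contribution is `100 * sum |w| over its voxels / sum |w|
#' over all in-mask voxels`; in-mask voxels with no atlas label form an
#' `"unlabeled"` pseudo-region, so percents sum to 100. Regions are
#' ranked by descending contribution, ties broken by region id.
#'
#' @param w 3D weight array on the image grid (see [devectorize()]).
#' @param atlas Integer 3D label array on the same grid (0 = no label),
#'   optionally with a `region_names` attribute.
#' @param mask Logical 3D array.
#' @return A `region_summary` data.frame: `region_id`, `region_name`,
#'   `percent_contribution`, `actual_rank`.
#' @export
region_contributions <- function(w, atlas, mask) {
  stop_if_not(identical(dim(w), dim(atlas)) && identical(dim(w), dim(mask)),
              "region_contributions: grid mismatch between weights, atlas, mask")
  aw <- abs(w[mask])
  labels <- as.vector(atlas)[as.vector(mask)]
  total <- sum(aw)
  stop_if_not(total > 0, "region_contributions: all-zero weight map")
  ids <- sort(unique(labels))
  nm <- attr(atlas, "region_names")
  name_of <- function(id) {
    if (id == 0) "unlabeled"
    else if (!is.null(nm) && as.character(id) %in% names(nm)) nm[[as.character(id)]]
    else sprintf("region_%d", id)
  }
  pct <- vapply(ids, function(id) 100 * sum(aw[labels == id]) / total, 0)
  out <- data.frame(region_id = ids,
                    region_name = vapply(ids, name_of, ""),
                    percent_contribution = pct, stringsAsFactors = FALSE)
  ord <- order(-out$percent_contribution, out$region_id)
  out$actual_rank <- NA_integer_
  out$actual_rank[ord] <- seq_len(nrow(out))
  class(out) <- c("region_summary", "data.frame")
  out
}

#' Expected region ranking across cross-validation folds
#'
#' Within each fold, regions are ranked by descending percent
#' contribution (ties broken by region id); the expected rank is the
#' mean of a region's rank across folds. Expected ranks close to the
#' overall (actual) ranks indicate a stable weight map.
#'
#' @param fold_contribs List (one element per fold) of
#'   `region_summary` data.frames over identical region sets.
#' @return A data.frame: `region_id`, `region_name`, `expected_rank`.
#' @export
expected_ranking <- function(fold_contribs) {
  stop_if_not(length(fold_contribs) >= 2L,
              "expected_ranking: need >= 2 folds")
  ref <- sort(fold_contribs[[1]]$region_id)
  for (fc in fold_contribs) {
    stop_if_not(identical(sort(fc$region_id), ref),
                "expected_ranking: region lists differ across folds")
  }
  ranks <- sapply(fold_contribs, function(fc) {
    fc <- fc[order(fc$region_id), ]
    r <- integer(nrow(fc))
    ord <- order(-fc$percent_contribution, fc$region_id)
    r[ord] <- seq_len(nrow(fc))
    r
  })
  first <- fold_contribs[[1]][order(fold_contribs[[1]]$region_id), ]
  data.frame(region_id = first$region_id,
             region_name = first$region_name,
             expected_rank = rowMeans(ranks),
             stringsAsFactors = FALSE)
}
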