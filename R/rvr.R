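#' Options controlling the relevance vector regression fit
#'
#' Defaults follow the classic sparse Bayesian learning recipe:
#' uniform initial prior precisions `alpha_init = 1/n^2` (scale-free in
#' the sample size), initial noise variance `sigma2_init_fraction *
#' var(y)`, bases pruned once their precision exceeds `alpha_prune`,
#' convergence on the largest absolute change in `log(alpha)`.
#'
#' @param max_iter Maximum number of re-estimation iterations.
#' @param tol Convergence threshold on `max |delta log alpha|`.
#' @param alpha_prune Precision above which a basis is removed (the bias
#'   is never pruned). `Inf` disables pruning.
#' @param alpha_init Initial precision for every basis; `NULL` means
#'   `1/n^2` at fit time.
#' @param sigma2_init_fraction Initial noise variance as a fraction of
#'   the target variance.
#' @param update_alpha Set `FALSE` to freeze the precisions (used by the
#'   ridge-equivalence checks).
#' @param update_sigma2 Set `FALSE` to freeze the noise variance.
#' @param jitter_rel Relative diagonal jitter on a failed factorization.
#' @return An `rvr_opts` list.
#' @export
rvr_opts <- function(max_iter = 2000L, tol = 1e-6, alpha_prune = 1e9,
                     alpha_init = NULL, sigma2_init_fraction = 0.1,
                     update_alpha = TRUE, update_sigma2 = TRUE,
                     jitter_rel = 1e-10) {
  stop_if_not(max_iter >= 1, "rvr_opts: max_iter must be >= 1")
  stop_if_not(tol > 0, "rvr_opts: tol must be > 0")
  stop_if_not(alpha_prune > 0, "rvr_opts: alpha_prune must be > 0")
  stop_if_not(is.null(alpha_init) || alpha_init > 0,
              "rvr_opts: alpha_init must be > 0")
  stop_if_not(sigma2_init_fraction > 0,
              "rvr_opts: sigma2_init_fraction must be > 0")
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 alpha_prune = alpha_prune, alpha_init = alpha_init,
                 sigma2_init_fraction = sigma2_init_fraction,
                 update_alpha = update_alpha, update_sigma2 = update_sigma2,
                 jitter_rel = jitter_rel),
            class = "rvr_opts")
}

#' Linear kernel between feature sets
#'
#' Entry `(i, j)` is the inner product of subject i's and subject j's
#' feature vectors. The train-by-train block is symmetric positive
#' semi-definite.
#'
#' @param a A `feature_matrix` or plain numeric matrix (rows =
#'   subjects).
#' @param b Second feature set (same column count); default `a`.
#' @return A numeric kernel matrix with attribute `kernel = "linear"`.
#' @export
linear_kernel <- function(a, b = a) {
  A <- if (inherits(a, "feature_matrix")) a$values else as.matrix(a)
  B <- if (inherits(b, "feature_matrix")) b$values else as.matrix(b)
  stop_if_not(ncol(A) == ncol(B),
              "linear_kernel: feature column counts differ (%d vs %d)",
              ncol(A), ncol(B))
  K <- A %*% t(B)
  attr(K, "kernel") <- "linear"
  K
}

#' Fit a relevance vector regression on a precomputed kernel
#'
#' Sparse Bayesian regression over the design `[bias | K]`: each basis
#' carries an independent zero-mean Gaussian prior whose precision is
#' re-estimated from the data; most precisions diverge, pruning their
#' bases, and the surviving training samples are the relevance vectors.
#'
#' @param K n x n training kernel matrix.
#' @param y Numeric target, length n (finite, n >= 3).
#' @param opts An [rvr_opts()].
#' @return An `rvr_model`: `active_set` (1-based indices into the
#'   `n + 1`-column design; 1 is the bias), `mu` (posterior means),
#'   `alpha`, `sigma2`, `n_iter`, `converged`, `flagged`, `ml`
#'   (marginal log-likelihood trace), `n_train`, `kernel_tag`.
#' @export
rvr_fit <- function(K, y, opts = rvr_opts()) {
  K <- as.matrix(K)
  n <- length(y)
  stop_if_not(all(is.finite(y)), "rvr_fit: y must be finite")
  stop_if_not(n >= 3L, "rvr_fit: need n >= 3")
  stop_if_not(nrow(K) == n && ncol(K) == n,
              "rvr_fit: K must be %d x %d", n, n)
  Phi <- cbind(1, unname(K))
  a0 <- opts$alpha_init %||% (1 / n^2)
  vy <- var(y)
  s2 <- opts$sigma2_init_fraction * if (vy > 0) vy else 1e-6
  fit <- rvr_fit_arma(Phi, as.numeric(y), rep(a0, n + 1L), s2,
                      opts$alpha_prune, opts$tol, opts$max_iter,
                      opts$update_alpha, opts$update_sigma2,
                      opts$jitter_rel)
  structure(list(active_set = fit$active + 1L, mu = as.numeric(fit$mu),
                 alpha = as.numeric(fit$alpha), gamma = as.numeric(fit$gamma),
                 sigma2 = fit$sigma2, n_iter = fit$n_iter,
                 converged = fit$converged, flagged = fit$flagged,
                 ml = as.numeric(fit$ml), n_train = n,
                 kernel_tag = attr(K, "kernel") %||% "linear",
                 opts = opts),
            class = "rvr_model")
}

#' Predict from a fitted RVR model
#'
#' `yhat = mu_bias + sum_j mu_j K_test_train[, j]` over the active
#' kernel bases.
#'
#' @param model An `rvr_model`.
#' @param K_test_train Test-by-train kernel block; columns must align
#'   with the model's training subjects.
#' @return Numeric vector of point predictions.
#' @export
rvr_predict <- function(model, K_test_train) {
  K_test_train <- matrix(as.numeric(K_test_train),
                         ncol = NCOL(K_test_train),
                         nrow = NROW(K_test_train))
  stop_if_not(ncol(K_test_train) == model$n_train,
              "rvr_predict: kernel block has %d columns; model trained on %d subjects",
              ncol(K_test_train), model$n_train)
  act <- model$active_set
  bias <- model$mu[act == 1L]
  kern_idx <- act[act > 1L] - 1L
  yhat <- rep(if (length(bias)) bias else 0, nrow(K_test_train))
  if (length(kern_idx)) {
    yhat <- yhat + as.vector(K_test_train[, kern_idx, drop = FALSE] %*%
                               model$mu[act > 1L])
  }
  yhat
}

#' Back-project a linear-kernel RVR model into voxel space
#'
#' For a linear kernel the model's decision function is linear in the
#' features: `w = sum_j mu_j x_j` over the active training samples, so
#' that `yhat(x) = <w, x> + mu_bias` for any feature vector `x`.
#'
#' @param model An `rvr_model` fitted on the linear kernel of
#'   `train_features`.
#' @param train_features The training `feature_matrix` (or plain
#'   matrix) the kernel was built from.
#' @return A list: `w` (voxel weight vector) and `bias`.
#' @export
backproject_weights <- function(model, train_features) {
  stop_if_not(identical(model$kernel_tag, "linear"),
              "backproject_weights: defined for linear kernels only (tag: %s)",
              model$kernel_tag)
  X <- if (inherits(train_features, "feature_matrix")) {
    train_features$values
  } else {
    as.matrix(train_features)
  }
  stop_if_not(nrow(X) == model$n_train,
              "backproject_weights: feature rows do not match the training set")
  act <- model$active_set
  kern_idx <- act[act > 1L] - 1L
  w <- if (length(kern_idx)) {
    as.vector(t(X[kern_idx, , drop = FALSE]) %*% model$mu[act > 1L])
  } else {
    numeric(ncol(X))
  }
  bias <- model$mu[act == 1L]
  list(w = w, bias = if (length(bias)) bias else 0)
}

#' @export
print.rvr_model <- function(x, ...) {
  cat("Relevance vector regression model\n")
  cat(sprintf("  n_train: %d  relevance vectors: %d  bias retained: %s\n",
              x$n_train, sum(x$active_set > 1L), 1L %in% x$active_set))
  cat(sprintf("  sigma2: %.4g  iterations: %d  converged: %s\n",
              x$sigma2, x$n_iter, x$converged))
  invisible(x)
}

#' Serialize an RVR model to JSON
#'
#' Records the active set, posterior means, precisions, noise variance,
#' fit options and a fingerprint of the training feature order.
#'
#' @param model An `rvr_model`.
#' @param path Output file path.
#' @param feature_fingerprint Optional string identifying the training
#'   feature ordering (e.g. an md5 of the voxel index).
#' @return Invisibly, `path`.
#' @export
write_rvr_model <- function(model, path, feature_fingerprint = NULL) {
  doc <- list(active_set = model$active_set, mu = model$mu,
              alpha = model$alpha, sigma2 = model$sigma2,
              n_train = model$n_train, kernel_tag = model$kernel_tag,
              converged = model$converged, n_iter = model$n_iter,
              opts = unclass(model$opts),
              feature_fingerprint = feature_fingerprint)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
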