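#' @useDynLib prsmvpa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor cor.test lm median pnorm pt qnorm qt quantile
#'   rbinom rlnorm rnorm runif sd t.test var p.adjust anova setNames
#' @importFrom utils read.table write.table head
NULL

# Derive a reproducible sub-seed from a master seed and a stage tag.
# Keeps results < 2^31 so they remain valid R integer seeds.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

# Symmetric positive-definite solve with relative jitter fallback.
# Returns list(inv = A^{-1}, logdet = log|A|).
sym_solve <- function(A, jitter_rel = 1e-10) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- chol(A + diag(jitter_rel * sum(diag(A)), nrow(A)))
  }
  list(inv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
}
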