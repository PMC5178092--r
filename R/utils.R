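# Internal helpers: seed substreams, guarded correlation, assertions.

#' Derive a reproducible sub-seed from a base seed and stream indices
#'
#' Every stochastic stage (imputation, permutation, splits, spectral k-means)
#' draws its seed from the run seed through this function, so stages are
#' decoupled: changing the number of draws in one stage does not perturb
#' another.
#'
#' @param seed integer base seed.
#' @param ... integer stream indices identifying the stage.
#' @return an integer seed in [0, 2^31 - 2].
#' @keywords internal
substream_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

# Pearson correlation that returns 0 instead of NA when either argument is
# (numerically) constant; both score paths require this degenerate-case rule.
safe_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch in correlation")
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(0)
  r <- stats::cor(x, y)
  if (is.na(r)) 0 else r
}

is_symmetric_matrix <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
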