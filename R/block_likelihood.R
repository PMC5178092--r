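# Block predictive likelihoods against a permutation null.
#
# Per trial the subjects are split into training and testing halves (shared
# across all blocks of the chromosome). Each block's model predicts the
# held-out log phenotypes; its Pearson correlation r with the truth is
# compared to n_p correlations obtained after permuting the training
# phenotypes, via the ratio R = exp(r) / sum_p exp(r_p). The likelihood
# L_k of block k is the fraction of trials in which it attains the maximal
# ratio (ties all count as winners).

# One-hot design: 3 indicator columns per marker (states 0, 1, 2); the
# missing state contributes an all-zero row for that marker, so it carries
# no information rather than a fabricated genotype.
.one_hot <- function(block_states) {
  x <- as.matrix(block_states)
  n <- nrow(x)
  p <- ncol(x)
  X <- matrix(0, n, 3L * p)
  for (j in seq_len(p)) {
    for (a in 0:2) X[, 3L * (j - 1L) + a + 1L] <- (x[, j] == a) * 1
  }
  X
}

# SVD ridge core shared by fit_block_model and the fast trial loop.
# Returns a closure basis so permuted responses reuse the decomposition.
.ridge_basis <- function(X_train, lambda) {
  xbar <- colMeans(X_train)
  Xc <- sweep(X_train, 2, xbar)
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d[1], 1) * 1e-12
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  shrink <- d / (d^2 + lambda)
  list(
    xbar = xbar,
    coef = function(y) {
      ybar <- mean(y)
      beta <- V %*% (shrink * crossprod(U, y - ybar))
      list(beta = beta, ybar = ybar)
    })
}

#' Fit the default block prediction model
#'
#' Ridge-penalized least squares of the log phenotype on per-marker one-hot
#' state indicators (three per marker), solved in closed form via the SVD.
#' The one-hot encoding lets each genotype class have its own mean, so
#' non-additive (non-linear in dosage) genotype effects are representable.
#' With the tiny default penalty the fit is the minimum-norm least-squares
#' solution up to numerical regularization, so a realizable phenotype is
#' reproduced on the training set.
#'
#' @param block_states subjects x markers integer state matrix for one
#'   block.
#' @param log_phenotypes numeric response on the log scale, one per
#'   training subject.
#' @param lambda ridge penalty (default `1e-8`).
#' @return object of class `block_model`; use [predict()] with a
#'   `newdata` state matrix to obtain predicted log phenotypes.
#' @export
fit_block_model <- function(block_states, log_phenotypes, lambda = 1e-8) {
  block_states <- as.matrix(block_states)
  if (nrow(block_states) < 4) stop("need at least 4 training subjects")
  if (ncol(block_states) < 1) stop("block must contain at least one marker")
  if (length(log_phenotypes) != nrow(block_states)) {
    stop("phenotype length must match training subjects")
  }
  basis <- .ridge_basis(.one_hot(block_states), lambda)
  fit <- basis$coef(log_phenotypes)
  structure(list(xbar = basis$xbar, beta = fit$beta, ybar = fit$ybar,
                 n_markers = ncol(block_states), lambda = lambda),
            class = "block_model")
}

#' @param object a `block_model`.
#' @param newdata subjects x markers state matrix.
#' @param ... unused.
#' @rdname fit_block_model
#' @export
predict.block_model <- function(object, newdata, ...) {
  X <- .one_hot(as.matrix(newdata))
  if (ncol(X) != length(object$xbar)) stop("marker count mismatch")
  drop(sweep(X, 2, object$xbar) %*% object$beta) + object$ybar
}

#' Predictive-power ratio of one block in one trial
#'
#' `R = exp(r_obs) / sum_p exp(r_null_p)`: the exponentiated observed
#' test-set correlation over the summed exponentiated permutation-null
#' correlations. Exponentiation maps negative correlations to small
#' positive contributions.
#'
#' @param r_obs observed Pearson correlation.
#' @param r_null numeric vector of null correlations (non-empty).
#' @return positive scalar.
#' @export
trial_ratio <- function(r_obs, r_null) {
  if (length(r_null) == 0) stop("r_null must be non-empty")
  exp(r_obs) / sum(exp(r_null))
}

#' Block likelihoods from repeated train/test trials
#'
#' For each of `n_trial` trials the subjects are split at random into a
#' training half (the larger half when N is odd) and a testing half, shared
#' by all blocks. Per block, the observed test correlation and `n_p`
#' permutation-null correlations (the same permutations for every block)
#' are combined by [trial_ratio()]; `L_k` is the fraction of trials in
#' which block k attains the maximal ratio, ties counting for all tied
#' blocks, so `sum(L) = 1` exactly when winners are unique and
#' `sum(L) >= 1` otherwise.
#'
#' @param g a [genotype_matrix()] for the chromosome.
#' @param blocks a `block_partition` from
#'   [hierarchical_block_decomposition()].
#' @param phen a `phenotype_vector` (the `raw` log-scale values are used).
#' @param n_trial number of train/test trials (default 1000).
#' @param n_p permutation-null trials per split (default 20).
#' @param seed integer seed.
#' @param lambda ridge penalty passed to the block model.
#' @param model_fun optional custom model: `function(states_train, y_train)`
#'   returning `function(states_new) -> predictions`; replaces the default
#'   ridge model (slower path).
#' @return object of class `block_likelihoods` with elements `l` (per-block
#'   likelihoods) and `n_trial`.
#' @export
block_likelihoods <- function(g, blocks, phen, n_trial = 1000, n_p = 20,
                              seed = 1, lambda = 1e-8, model_fun = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), n_trial >= 1, n_p >= 1)
  N <- n_subjects(g)
  if (N < 8) stop("need at least 8 subjects")
  y <- if (inherits(phen, "phenotype_vector")) phen$raw else as.numeric(phen)
  if (length(y) != N) stop("phenotype length must match subjects")
  K <- nrow(blocks)
  if (K == 1) {
    return(structure(list(l = 1, n_trial = as.integer(n_trial)),
                     class = "block_likelihoods"))
  }
  st <- t(g$states)                    # subjects x markers
  block_idx <- mapply(seq, blocks$start, blocks$end, SIMPLIFY = FALSE)
  n_train <- ceiling(N / 2)            # odd N: training gets the extra subject
  wins <- numeric(K)
  withr::with_seed(as.integer(seed), {
    Xfull <- if (is.null(model_fun)) {
      lapply(block_idx, function(idx) .one_hot(st[, idx, drop = FALSE]))
    } else NULL
    for (t in seq_len(n_trial)) {
      ord <- sample.int(N)
      tr <- ord[seq_len(n_train)]
      te <- ord[(n_train + 1):N]
      y_tr <- y[tr]
      y_te <- y[te]
      perms <- lapply(seq_len(n_p), function(p) sample(y_tr))
      R <- numeric(K)
      for (k in seq_len(K)) {
        if (is.null(model_fun)) {
          basis <- .ridge_basis(Xfull[[k]][tr, , drop = FALSE], lambda)
          Xte <- sweep(Xfull[[k]][te, , drop = FALSE], 2, basis$xbar)
          pred_of <- function(yy) {
            fit <- basis$coef(yy)
            drop(Xte %*% fit$beta) + fit$ybar
          }
        } else {
          states_tr <- st[tr, block_idx[[k]], drop = FALSE]
          states_te <- st[te, block_idx[[k]], drop = FALSE]
          pred_of <- function(yy) model_fun(states_tr, yy)(states_te)
        }
        r_obs <- safe_cor(pred_of(y_tr), y_te)
        r_null <- vapply(perms, function(yp) safe_cor(pred_of(yp), y_te), 0)
        R[k] <- trial_ratio(r_obs, r_null)
      }
      winners <- which(R == max(R))
      wins[winners] <- wins[winners] + 1
    }
  })
  l <- wins / n_trial
  if (sum(l) < 1 - 1e-9) stop("internal error: likelihoods sum below 1")
  structure(list(l = l, n_trial = as.integer(n_trial)),
            class = "block_likelihoods")
}

#' @export
print.block_likelihoods <- function(x, ...) {
  cat(sprintf("block_likelihoods over %d trials: %s\n", x$n_trial,
              paste(sprintf("%.3f", x$l), collapse = " ")))
  invisible(x)
}
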