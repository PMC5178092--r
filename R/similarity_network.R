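# Per-chromosome SNP similarity networks and their fusion.
#
# Two views of the same markers are fused: the genetic-distance matrix
# D_ss' = |cM_s - cM_s'| and the permutation-averaged, phenotype-weighted
# mutual information I_ss'. The fused matrix M is produced by Similarity
# Network Fusion (cross-diffusion of row-normalized kernels restricted to
# kappa nearest neighbours).

#' Genetic-distance matrix of a chromosome
#'
#' @param map a genetic map (data.frame with columns `marker_id`,
#'   `chromosome`, `cm`) or a [genotype_matrix()].
#' @return S x S matrix with entries `|cM_s - cM_s'|`, marker ids as
#'   dimnames.
#' @export
genetic_distance_matrix <- function(map) {
  if (inherits(map, "genotype_matrix")) map <- map$map
  if (length(unique(map$chromosome)) != 1) {
    stop("markers from multiple chromosomes")
  }
  if (nrow(map) < 2) stop("need at least two markers")
  d <- abs(outer(map$cm, map$cm, "-"))
  dimnames(d) <- list(map$marker_id, map$marker_id)
  d
}

# Impute missing states (3) of each marker by sampling from its empirical
# state distribution over subjects with data. Draws come from the current
# RNG stream; callers seed it.
.impute_states <- function(states) {
  miss <- states == 3L
  if (!any(miss)) return(states)
  for (j in which(rowSums(miss) > 0)) {
    obs <- states[j, !miss[j, ]]
    if (length(obs) == 0) {
      stop(sprintf("marker '%s' has all states missing",
                   rownames(states)[j] %||% j))
    }
    freq <- tabulate(obs + 1L, nbins = 3L) / length(obs)
    states[j, miss[j, ]] <- sample(0:2, sum(miss[j, ]), replace = TRUE,
                                   prob = freq)
  }
  states
}

#' Phenotype-weighted mutual information between all marker pairs
#'
#' For markers s, s' with states alpha, beta in `{0,1,2}`, computes
#' `I_ss' = sum_ab P_sas'b log(P_sas'b / (P_sa P_s'b))` where the joint
#' cell probability `P_sas'b = sum_m rho_m [state(m,s)=a][state(m,s')=b]`
#' weights each subject by its normalized phenotype `rho`. Missing states
#' are imputed from each marker's empirical state distribution before the
#' computation; `0 log 0` terms contribute 0. The normalization
#' `sum_ab P_sas'b = 1` is asserted for every pair.
#'
#' @param g a [genotype_matrix()] or raw integer state matrix (markers x
#'   subjects).
#' @param rho normalized phenotype weights (a `phenotype_vector` or a
#'   numeric vector summing to 1).
#' @param imputation_seed optional integer; if given, missing-state
#'   imputation is seeded (otherwise it draws from the current RNG stream).
#' @return symmetric S x S matrix; the diagonal holds each marker's
#'   weighted entropy.
#' @export
weighted_mutual_information <- function(g, rho, imputation_seed = NULL) {
  states <- if (inherits(g, "genotype_matrix")) g$states else g
  rho <- .as_rho(rho)
  if (length(rho) != ncol(states)) stop("rho length must equal subjects")
  if (!is.null(imputation_seed)) {
    states <- withr::with_seed(as.integer(imputation_seed),
                               .impute_states(states))
  } else {
    states <- .impute_states(states)
  }
  .wmi_imputed(states, rho)
}

# Core of Eq. for I_ss' on fully observed (imputed) states.
.wmi_imputed <- function(states, rho) {
  S <- nrow(states)
  A <- lapply(0:2, function(a) {
    m <- (states == a) * 1
    m
  })
  # marginals P_sa = sum_m rho_m [state(m,s)=a]
  p <- lapply(A, function(m) as.vector(m %*% rho))
  floor_ <- 1e-300
  I <- matrix(0, S, S)
  total <- matrix(0, S, S)
  for (a in 1:3) {
    Aw <- A[[a]] * rep(rho, each = S)    # rows scaled? no: columns are subjects
    for (b in 1:3) {
      J <- tcrossprod(Aw, A[[b]])        # J_ss' = sum_m rho_m sig sig
      total <- total + J
      lg <- log(pmax(J, floor_)) -
        log(pmax(outer(p[[a]], p[[b]]), floor_))
      I <- I + J * lg
    }
  }
  if (max(abs(total - 1)) > 1e-8) {
    stop("internal error: joint state probabilities do not sum to 1")
  }
  I <- (I + t(I)) / 2
  dimnames(I) <- list(rownames(states), rownames(states))
  I
}

#' Permutation-averaged mutual information matrix
#'
#' Averages [weighted_mutual_information()] over `n_perm` random
#' permutations of the phenotype weights, with missing states freshly
#' imputed at every permutation, yielding a mutual-information matrix that
#' is independent of which subject carries which phenotype (it retains only
#' the phenotype value distribution). The weights are sorted before the
#' seeded permutations are applied, so any two phenotypes with the same
#' value multiset give bit-identical output under the same seed.
#'
#' @inheritParams weighted_mutual_information
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed driving both the permutations and the
#'   per-permutation imputations.
#' @return symmetric S x S matrix with attribute `n_perm`.
#' @export
permutation_mutual_information <- function(g, rho, n_perm = 100, seed = 1) {
  states <- if (inherits(g, "genotype_matrix")) g$states else g
  rho <- .as_rho(rho)
  stopifnot(n_perm >= 1)
  rho_sorted <- sort(rho)
  acc <- withr::with_seed(as.integer(seed), {
    a <- 0
    for (p in seq_len(n_perm)) {
      rho_p <- sample(rho_sorted)
      st_p <- .impute_states(states)
      a <- a + .wmi_imputed(st_p, rho_p)
    }
    a
  })
  out <- acc / n_perm
  attr(out, "n_perm") <- n_perm
  out
}

# Local-scale exponential kernel (Wang et al. affinity):
# W_ij = exp(-d_ij^2 / (eta * eps_ij)),
# eps_ij = (mu_i + mu_j + d_ij) / 3 with mu_i the mean dissimilarity of i
# to its kappa nearest neighbours (self excluded).
.affinity_kernel <- function(diss, kappa, eta) {
  S <- nrow(diss)
  mu <- vapply(seq_len(S), function(i) {
    v <- sort(diss[i, -i])[seq_len(kappa)]
    mean(v)
  }, 0)
  eps <- (outer(mu, mu, "+") + diss) / 3
  eps <- pmax(eps, .Machine$double.eps)
  exp(-diss^2 / (eta * eps))
}

# Full transition kernel: off-diagonal rows sum to 1/2, diagonal 1/2.
.full_kernel <- function(W) {
  P <- W
  diag(P) <- 0
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- P / (2 * rs)
  diag(P) <- 0.5
  P
}

# Sparse kernel: each row keeps self and its kappa nearest neighbours (by
# dissimilarity), renormalized to sum 1.
.sparse_kernel <- function(W, diss, kappa) {
  S <- nrow(W)
  Sp <- matrix(0, S, S)
  for (i in seq_len(S)) {
    nn <- order(diss[i, -i])[seq_len(kappa)]
    nn <- seq_len(S)[-i][nn]
    keep <- c(i, nn)
    Sp[i, keep] <- W[i, keep]
  }
  Sp / rowSums(Sp)
}

#' Fuse the distance and mutual-information views with SNF
#'
#' The distance matrix is used as a dissimilarity directly; the
#' mutual-information matrix is converted by the affine inversion
#' `max(I) - I` with zero self-dissimilarity. Each view becomes a
#' locally-scaled exponential kernel, row-normalized into a full kernel and
#' a kappa-nearest-neighbour sparse kernel, and the two full kernels are
#' updated by cross-diffusion (`P_v <- S_v P_other t(S_v)`, renormalized and
#' symmetrized) for `iterations` steps. With `iterations = 0` the average
#' of the two initial full kernels is returned.
#'
#' @param d genetic-distance matrix (symmetric, zero diagonal).
#' @param i mutual-information matrix over the same markers.
#' @param kappa neighbourhood size, `2 <= kappa < S`.
#' @param eta kernel bandwidth hyperparameter, positive.
#' @param iterations number of cross-diffusion steps (default 20).
#' @return symmetric non-negative S x S fused similarity matrix with
#'   attributes `kappa`, `eta`, `iterations`.
#' @export
snf_fuse <- function(d, i, kappa, eta, iterations = 20) {
  if (!is_symmetric_matrix(d) || !is_symmetric_matrix(i)) {
    stop("inputs must be symmetric matrices")
  }
  S <- nrow(d)
  if (!all(dim(i) == dim(d))) stop("views must cover the same markers")
  if (kappa < 1 || kappa >= S) stop("kappa must satisfy 1 <= kappa < S")
  if (eta <= 0) stop("eta must be positive")
  if (iterations < 0) stop("iterations must be >= 0")
  di <- max(i) - i
  diag(di) <- 0
  views <- list(d, di)
  W <- lapply(views, .affinity_kernel, kappa = kappa, eta = eta)
  P <- lapply(W, .full_kernel)
  Sp <- mapply(function(w, v) .sparse_kernel(w, v, kappa),
               W, views, SIMPLIFY = FALSE)
  if (iterations > 0) {
    for (it in seq_len(iterations)) {
      P_new <- list(
        Sp[[1]] %*% P[[2]] %*% t(Sp[[1]]),
        Sp[[2]] %*% P[[1]] %*% t(Sp[[2]]))
      P <- lapply(P_new, function(m) {
        m <- .full_kernel((m + t(m)) / 2)
        (m + t(m)) / 2
      })
    }
  }
  M <- (P[[1]] + P[[2]]) / 2
  M <- (M + t(M)) / 2
  dimnames(M) <- dimnames(d)
  structure(M, kappa = kappa, eta = eta, iterations = iterations)
}
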