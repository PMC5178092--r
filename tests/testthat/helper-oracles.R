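# Independent straight-line oracles used to cross-check the implementation.
# These deliberately use naive loops and textbook formulas, not the package's
# vectorized code paths.

# Textbook Pearson correlation from raw sums.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Weighted mutual information by explicit loops over pairs and state cells
# (states must be fully observed, i.e. in {0,1,2}).
mi_oracle <- function(states, rho) {
  S <- nrow(states)
  out <- matrix(0, S, S)
  for (s1 in 1:S) for (s2 in 1:S) {
    acc <- 0
    for (a in 0:2) for (b in 0:2) {
      j <- sum(rho[states[s1, ] == a & states[s2, ] == b])
      pa <- sum(rho[states[s1, ] == a])
      pb <- sum(rho[states[s2, ] == b])
      if (j > 0) acc <- acc + j * log(j / (pa * pb))
    }
    out[s1, s2] <- acc
  }
  out
}

# Literal re-implementation of the SNF recurrence: local-scale kernel,
# row-stochastic full/sparse kernels, cross-diffusion, averaging.
snf_oracle <- function(d, i, kappa, eta, iterations) {
  S <- nrow(d)
  di <- max(i) - i
  diag(di) <- 0
  kernel_of <- function(diss) {
    mu <- numeric(S)
    for (r in 1:S) mu[r] <- mean(sort(diss[r, -r])[1:kappa])
    W <- matrix(0, S, S)
    for (r in 1:S) for (c in 1:S) {
      eps <- max((mu[r] + mu[c] + diss[r, c]) / 3, .Machine$double.eps)
      W[r, c] <- exp(-diss[r, c]^2 / (eta * eps))
    }
    W
  }
  full_of <- function(W) {
    P <- matrix(0, S, S)
    for (r in 1:S) {
      rs <- sum(W[r, -r])
      if (rs == 0) rs <- 1
      for (c in 1:S) if (c != r) P[r, c] <- W[r, c] / (2 * rs)
      P[r, r] <- 0.5
    }
    P
  }
  sparse_of <- function(W, diss) {
    Sp <- matrix(0, S, S)
    for (r in 1:S) {
      others <- setdiff(1:S, r)
      nn <- others[order(diss[r, others])][1:kappa]
      keep <- c(r, nn)
      Sp[r, keep] <- W[r, keep]
      Sp[r, ] <- Sp[r, ] / sum(Sp[r, ])
    }
    Sp
  }
  W1 <- kernel_of(d);  W2 <- kernel_of(di)
  P1 <- full_of(W1);   P2 <- full_of(W2)
  S1 <- sparse_of(W1, d); S2 <- sparse_of(W2, di)
  if (iterations > 0) {
    for (t in 1:iterations) {
      N1 <- S1 %*% P2 %*% t(S1)
      N2 <- S2 %*% P1 %*% t(S2)
      P1 <- full_of((N1 + t(N1)) / 2); P1 <- (P1 + t(P1)) / 2
      P2 <- full_of((N2 + t(N2)) / 2); P2 <- (P2 + t(P2)) / 2
    }
  }
  M <- (P1 + P2) / 2
  (M + t(M)) / 2
}

# AUROC as the Mann-Whitney concordance probability: fraction of
# (true, false) pairs where the true point has the smaller score, ties
# counting one half.
auroc_mw_oracle <- function(points) {
  ts <- points$score[points$is_true]
  fs <- points$score[!points$is_true]
  acc <- 0
  for (a in ts) for (b in fs) {
    acc <- acc + (a < b) + 0.5 * (a == b)
  }
  acc / (length(ts) * length(fs))
}

# Small random genotype fixture (fully observed unless missing_rate > 0).
random_states <- function(S, N, missing_rate = 0, seed = 1) {
  withr::with_seed(seed, {
    st <- matrix(sample(0:2, S * N, replace = TRUE), S, N)
    if (missing_rate > 0) st[runif(S * N) < missing_rate] <- 3L
    rownames(st) <- paste0("m", seq_len(S))
    st
  })
}

# Planted block-diagonal similarity matrix with additive noise.
planted_similarity <- function(sizes, within = 1, between = 0.05,
                               noise = 0.01, seed = 1) {
  S <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  m <- matrix(between, S, S)
  m[outer(lab, lab, "==")] <- within
  withr::with_seed(seed, {
    e <- matrix(stats::runif(S * S, 0, noise), S, S)
    m <- m + (e + t(e)) / 2
  })
  diag(m) <- within
  (m + t(m)) / 2
}

# Tiny two-chromosome genotype/phenotype bundle for pipeline-level tests.
toy_dataset <- function(seed = 42, n_subjects = 60, markers = 20) {
  g <- simulate_genotypes(n_subjects = n_subjects, n_chromosomes = 2,
                          markers_per_chromosome = markers, cm_length = 50,
                          missing_rate = 0.02, seed = seed)
  ph <- simulate_phenotypes(g, seed = seed + 1)
  list(g = g, phenotype = ph$phenotype, truth = ph$truth,
       phen = normalize_phenotype(ph$phenotype))
}
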