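# Distance matrix, weighted mutual information, permutation averaging, SNF.

test_that("genetic distance matrix is the absolute cM difference", {
  map <- data.frame(marker_id = c("a", "b", "c"), chromosome = "1",
                    cm = c(0, 1.5, 3.0), mb = c(0, 1, 2))
  d <- genetic_distance_matrix(map)
  expect_equal(unname(d), rbind(c(0, 1.5, 3), c(1.5, 0, 1.5), c(3, 1.5, 0)))
  # degenerate: all markers at one position
  map$cm <- rep(2, 3)
  expect_equal(unname(genetic_distance_matrix(map)), matrix(0, 3, 3))
  map$chromosome <- c("1", "1", "2")
  expect_error(genetic_distance_matrix(map), "multiple chromosomes")
  # random positions vs brute-force elementwise differences
  cm <- withr::with_seed(3, stats::runif(12, 0, 80))
  map2 <- data.frame(marker_id = paste0("m", 1:12), chromosome = "1",
                     cm = sort(cm), mb = sort(cm) / 2)
  d2 <- genetic_distance_matrix(map2)
  for (i in 1:12) for (j in 1:12) {
    expect_identical(d2[i, j], abs(map2$cm[i] - map2$cm[j]))
  }
})

test_that("mutual information of duplicated two-state markers is log 2", {
  # two identical markers, states split 50/50, uniform weights
  st <- rbind(rep(c(0L, 1L), each = 10), rep(c(0L, 1L), each = 10))
  rho <- rep(1 / 20, 20)
  I <- weighted_mutual_information(st, rho)
  expect_equal(I[1, 2], log(2), tolerance = 1e-12)
  # diagonal = weighted entropy, checked by direct summation
  p <- c(sum(rho[st[1, ] == 0]), sum(rho[st[1, ] == 1]))
  expect_equal(I[1, 1], -sum(p * log(p)), tolerance = 1e-12)
})

test_that("independent markers have near-zero mutual information", {
  st <- random_states(2, 20000, seed = 5)
  I <- weighted_mutual_information(st, rep(1 / 20000, 20000))
  expect_lt(I[1, 2], 0.005)
  expect_gte(I[1, 2], 0)       # MI of an empirical joint is non-negative
})

test_that("weighted MI matches the straight-line oracle on random fixtures", {
  for (seed in 1:4) {
    st <- random_states(6, 40, seed = seed)
    rho <- withr::with_seed(seed + 100, {
      w <- stats::rexp(40)
      w / sum(w)
    })
    I <- weighted_mutual_information(st, rho)
    expect_equal(unname(I), mi_oracle(st, rho), tolerance = 1e-10)
    # subject relabeling invariance
    perm <- withr::with_seed(seed + 200, sample(40))
    I2 <- weighted_mutual_information(st[, perm], rho[perm])
    expect_equal(I2, I, tolerance = 1e-12)
  }
})

test_that("joint state probabilities sum to one for every marker pair", {
  st <- random_states(5, 30, seed = 9)
  rho <- withr::with_seed(9, { w <- stats::runif(30); w / sum(w) })
  for (s1 in 1:5) for (s2 in 1:5) {
    tot <- 0
    for (a in 0:2) for (b in 0:2) {
      tot <- tot + sum(rho[st[s1, ] == a & st[s2, ] == b])
    }
    expect_equal(tot, 1, tolerance = 1e-10)
  }
  # a marker with no observed states cannot be imputed
  st[2, ] <- 3L
  expect_error(weighted_mutual_information(st, rho), "all states missing")
})

test_that("permutation averaging is exact for uniform weights and converges", {
  st <- random_states(5, 30, seed = 21)
  rho_u <- rep(1 / 30, 30)
  I1 <- weighted_mutual_information(st, rho_u)
  # permuting uniform weights changes nothing: average equals one evaluation
  Ip <- permutation_mutual_information(st, rho_u, n_perm = 7, seed = 1)
  expect_equal(unname(Ip), unname(I1), tolerance = 1e-12, ignore_attr = TRUE)
  # skewed weights: two disjoint 100-permutation halves agree within
  # Monte-Carlo error
  rho_s <- withr::with_seed(22, { w <- stats::rexp(30)^2; w / sum(w) })
  Ia <- permutation_mutual_information(st, rho_s, n_perm = 100, seed = 31)
  Ib <- permutation_mutual_information(st, rho_s, n_perm = 100, seed = 32)
  expect_lt(max(abs(Ia - Ib)), 0.1)
  expect_gt(stats::cor(as.vector(Ia), as.vector(Ib)), 0.98)
})

test_that("fusing two copies of the same view is a fixed point", {
  cm <- sort(withr::with_seed(41, stats::runif(12, 0, 50)))
  d <- abs(outer(cm, cm, "-"))
  i <- max(d) - d                 # information view encoding the same geometry
  M <- snf_fuse(d, i, kappa = 4, eta = 0.5, iterations = 8)
  oracle <- snf_oracle(d, i, kappa = 4, eta = 0.5, iterations = 8)
  expect_equal(unname(M), oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(M)))
})

test_that("SNF output matches the literal recurrence oracle and its base case", {
  withr::with_seed(55, {
    cm <- sort(stats::runif(9, 0, 60))
    st <- random_states(9, 50, seed = 56)
  })
  d <- abs(outer(cm, cm, "-"))
  i <- weighted_mutual_information(st, rep(1 / 50, 50))
  for (iters in c(0, 1, 5, 20)) {
    M <- snf_fuse(d, i, kappa = 3, eta = 0.4, iterations = iters)
    expect_equal(unname(M), snf_oracle(d, i, 3, 0.4, iters),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # contract: symmetric, non-negative, finite
  M <- snf_fuse(d, i, kappa = 3, eta = 0.4)
  expect_true(all(is.finite(M)) && all(M >= 0))
  expect_true(isSymmetric(unclass(M)))
  expect_error(snf_fuse(d, i, kappa = 9, eta = 0.4), "kappa")
  expect_error(snf_fuse(d, i[1:8, 1:8], kappa = 3, eta = 0.4), "symmetric|markers")
})

test_that("fused similarity separates far-apart marker groups", {
  # two tight groups separated by a large cM gap
  cm <- c(seq(0, 4, by = 1), seq(60, 64, by = 1))
  d <- abs(outer(cm, cm, "-"))
  st <- random_states(10, 80, seed = 77)
  # make within-group genotypes correlated: copy a template per group
  st[2:5, ] <- rep(st[1, ], each = 4); st[7:10, ] <- rep(st[6, ], each = 4)
  i <- weighted_mutual_information(st, rep(1 / 80, 80))
  M <- snf_fuse(d, i, kappa = 3, eta = 0.5)
  grp <- rep(1:2, each = 5)
  off <- M
  diag(off) <- NA
  within <- mean(off[outer(grp, grp, "==")], na.rm = TRUE)
  between <- mean(off[outer(grp, grp, "!=")])
  expect_gt(within, between)
})
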