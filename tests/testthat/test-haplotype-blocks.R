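# Spectral splitting, the open/closed-branch decomposition, grid selection.

test_that("spectral split recovers planted blocks and honors n", {
  m <- planted_similarity(c(4, 4), seed = 1)
  lab <- spectral_split(m, 2, seed = 1)
  expect_equal(length(unique(lab)), 2)
  # exhaustive bipartition maximizing within-block similarity agrees
  best <- NULL
  off <- m; diag(off) <- 0
  for (code in 1:(2^7)) {            # all non-trivial bipartitions of 8
    assign_ <- c(0, as.integer(intToBits(code))[1:7])
    if (all(assign_ == 0)) next
    w <- sum(off[outer(assign_, assign_, "==")])
    if (is.null(best) || w > best$w) best <- list(w = w, lab = assign_)
  }
  expect_true(all(best$lab[lab == lab[1]] == best$lab[1]))
  expect_true(all(best$lab[lab != lab[1]] != best$lab[1]))
  # n equal to the submatrix size forces singletons
  expect_equal(sort(spectral_split(m, 8, seed = 1)), 1:8)
  expect_error(spectral_split(m, 9, seed = 1), "cannot split")
})

test_that("spectral split is invariant to marker relabeling", {
  m <- planted_similarity(c(5, 6), noise = 0.02, seed = 3)
  lab <- spectral_split(m, 2, seed = 9)
  perm <- withr::with_seed(4, sample(11))
  lab_p <- spectral_split(m[perm, perm], 2, seed = 9)
  unperm <- integer(11)
  unperm[perm] <- lab_p
  # same partition up to label names
  expect_equal(outer(unperm, unperm, "=="), outer(lab, lab, "=="))
})

test_that("chromosomes smaller than kappa stay a single block", {
  m <- planted_similarity(c(3, 3), seed = 5)
  part <- hierarchical_block_decomposition(m, clustering_config(), kappa = 10)
  expect_equal(nrow(part), 1)
  expect_equal(c(part$start, part$end), c(1, 6))
})

test_that("two well-separated groups become exactly two blocks", {
  m <- planted_similarity(c(3, 3), between = 0.01, noise = 0.005, seed = 6)
  part <- hierarchical_block_decomposition(m, clustering_config(), kappa = 3,
                                           seed = 2)
  expect_equal(nrow(part), 2)
  expect_equal(part$start, c(1L, 4L))
  expect_equal(part$end, c(3L, 6L))
})

test_that("the split arity escalates past non-contiguous proposals", {
  # pairs A=(1,2), B=(3,4), C=(5,6); A and C mutually similar, B apart:
  # the binary split proposes the non-contiguous {A,C} vs {B} and must be
  # rejected; n = 3 yields contiguous pairs and is accepted
  m <- matrix(0.02, 6, 6)
  pairs <- list(1:2, 3:4, 5:6)
  for (p in pairs) m[p, p] <- 1
  m[1:2, 5:6] <- 0.6; m[5:6, 1:2] <- 0.6
  diag(m) <- 1
  lab2 <- spectral_split(m, 2, seed = 1)
  expect_true(lab2[1] == lab2[5] && lab2[1] != lab2[3])  # fixture as intended
  part <- hierarchical_block_decomposition(m, clustering_config(), kappa = 2,
                                           seed = 1)
  expect_equal(nrow(part), 3)
  expect_equal(part$start, c(1L, 3L, 5L))
  expect_equal(part$n_markers, c(2L, 2L, 2L))
})

test_that("blocks always partition the chromosome and are reproducible", {
  for (seed in 1:5) {
    sizes <- withr::with_seed(seed, sample(2:6, 3, replace = TRUE))
    m <- planted_similarity(sizes, noise = 0.1, seed = seed)
    part <- hierarchical_block_decomposition(m, clustering_config(),
                                             kappa = 4, seed = seed)
    covered <- unlist(mapply(seq, part$start, part$end, SIMPLIFY = FALSE))
    expect_identical(sort(covered), seq_len(sum(sizes)))   # cover + disjoint
    expect_true(all(part$n_markers >= 1))
    part2 <- hierarchical_block_decomposition(m, clustering_config(),
                                              kappa = 4, seed = seed)
    expect_identical(part, part2)                           # deterministic
  }
})

test_that("block-diagonal similarity yields blocks no coarser than the groups", {
  sizes <- c(4, 5, 4)
  m <- planted_similarity(sizes, between = 0.01, noise = 0.005, seed = 8)
  part <- hierarchical_block_decomposition(m, clustering_config(), kappa = 4,
                                           seed = 1)
  bounds <- cumsum(sizes)
  group_of <- function(j) findInterval(j - 1, bounds) + 1
  for (b in seq_len(nrow(part))) {
    expect_equal(group_of(part$start[b]), group_of(part$end[b]))
  }
})

test_that("grid selection applies the minimax criterion and its tie-breaks", {
  cfg <- clustering_config(kappa_grid = c(4, 6), eta_grid = c(0.4, 0.6))
  withr::with_seed(12, {
    cm <- sort(stats::runif(18, 0, 70))
    st <- random_states(18, 60, seed = 13)
  })
  d <- abs(outer(cm, cm, "-"))
  i <- weighted_mutual_information(st, rep(1 / 60, 60))
  sel <- select_kappa_eta(d, i, cfg, snf_iterations = 10, seed = 3)
  # enumerate the full grid independently and check the selection rule
  stats_of <- list()
  for (kappa in cfg$kappa_grid) for (eta in cfg$eta_grid) {
    M <- snf_fuse(d, i, kappa, eta, iterations = 10)
    p <- hierarchical_block_decomposition(
      M, cfg, kappa, seed = bnm:::substream_seed(3, kappa, round(eta * 1000)))
    stats_of[[sprintf("%d_%.1f", kappa, eta)]] <-
      c(kappa, eta, max(p$n_markers), sum(p$n_markers == max(p$n_markers)),
        nrow(p))
  }
  tab <- do.call(rbind, stats_of)
  sel_max <- max(sel$partition$n_markers)
  expect_equal(sel_max, min(tab[, 3]))                      # minimax
  cand <- tab[tab[, 3] == sel_max, , drop = FALSE]
  expect_equal(sum(sel$partition$n_markers == sel_max), min(cand[, 4]))
  cand <- cand[cand[, 4] == min(cand[, 4]), , drop = FALSE]
  expect_equal(nrow(sel$partition), max(cand[, 5]))
  cand <- cand[cand[, 5] == max(cand[, 5]), , drop = FALSE]
  expect_equal(unname(c(sel$kappa, sel$eta)),
               unname(cand[order(cand[, 1], cand[, 2])[1], 1:2]))
  # one-element grids return that pair
  cfg1 <- clustering_config(kappa_grid = 5, eta_grid = 0.5)
  sel1 <- select_kappa_eta(d, i, cfg1, snf_iterations = 5, seed = 3)
  expect_equal(c(sel1$kappa, sel1$eta), c(5, 0.5))
})
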