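# Sliding windows, power/FDR, ROC, Mb-block tolerance, threshold matching.

test_that("sliding windows reproduce the published group counts", {
  expect_equal(nrow(sliding_windows(19000, 4000, 200)), 76)
  expect_equal(nrow(sliding_windows(9500, 2000, 100)), 76)
  w <- sliding_windows(10, 5, 5)
  expect_equal(nrow(w), 2)
  expect_equal(w$start, c(1L, 6L))
  expect_error(sliding_windows(10, 11, 1), "exceeds")
  w2 <- sliding_windows(1000, 100, 30)
  expect_true(all(w2$end - w2$start + 1 == 100))
  expect_true(all(diff(w2$start) == 30))
})

test_that("power and FDR match hand counts", {
  # perfect separation
  pts <- data.frame(effect_size = 1:20,
                    score = rep(c(1, 0), 10)[order(rep(c(FALSE, TRUE), 10))],
                    is_true = rep(c(FALSE, TRUE), 10))
  pts$score <- ifelse(pts$is_true, 0, 1)
  pf <- power_fdr(pts, 0.5, window = 10, offset = 5)
  expect_true(all(pf$power == 1))
  expect_true(all(pf$fdr == 0))
  # hand-labelled window of six points
  pts2 <- data.frame(effect_size = 1:6,
                     score = c(0.1, 0.9, 0.2, 0.8, 0.05, 0.5),
                     is_true = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  pf2 <- power_fdr(pts2, 0.3, window = 6, offset = 6)
  # calls: points 1, 3, 5 -> true calls 1 and 5, false call 3
  expect_equal(pf2$power, 2 / 3)
  expect_equal(pf2$fdr, 1 / 3)
  expect_equal(pf2$n_calls, 3L)
  # threshold 1 calls everything
  pf3 <- power_fdr(pts2, 1, window = 6, offset = 6)
  expect_equal(pf3$power, 1)
  expect_equal(pf3$fdr, 0.5)
  # raising the threshold never reduces the number of calls
  ns <- vapply(seq(0, 1, 0.1),
               function(t) power_fdr(pts2, t, 6, 6)$n_calls, 0L)
  expect_true(all(diff(ns) >= 0))
  expect_error(power_fdr(pts2[order(-pts2$effect_size), ], 0.5, 6, 6),
               "sorted")
})

test_that("ROC and AUROC match the Mann-Whitney oracle", {
  # perfect separation
  pts <- data.frame(score = c(0, 0.1, 0.8, 0.9),
                    is_true = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc_curve(pts)$auroc, 1)
  # label-independent scores at large n
  pts2 <- withr::with_seed(5, data.frame(
    score = stats::runif(4000), is_true = rep(c(TRUE, FALSE), 2000)))
  expect_lt(abs(roc_curve(pts2)$auroc - 0.5), 0.05)
  # eight-point toy with ties vs exhaustive pair counting
  pts3 <- data.frame(score = c(0.1, 0.3, 0.3, 0.7, 0.2, 0.3, 0.8, 0.9),
                     is_true = c(TRUE, TRUE, TRUE, TRUE,
                                 FALSE, FALSE, FALSE, FALSE))
  expect_equal(roc_curve(pts3)$auroc, auroc_mw_oracle(pts3))
  # random fixtures
  for (seed in 1:10) {
    p <- withr::with_seed(seed, data.frame(
      score = round(stats::runif(30), 1),
      is_true = stats::runif(30) < 0.4))
    if (sum(p$is_true) == 0 || all(p$is_true)) next
    expect_equal(roc_curve(p)$auroc, auroc_mw_oracle(p), tolerance = 1e-12)
  }
  expect_error(roc_curve(data.frame(score = 1:3, is_true = TRUE)),
               "true and one false")
})

test_that("Mb bins collapse calls and carry the truth flag", {
  map <- data.frame(marker_id = paste0("m", 1:4), chromosome = "1",
                    mb = c(0.5, 1.9, 2.1, 3.8))
  lab <- mb_block_truth(map, data.frame(chromosome = "1", marker_id = "m3"),
                        d = 2)
  expect_equal(lab$bin, c(0L, 0L, 1L, 1L))
  expect_equal(lab$is_true_block, c(FALSE, FALSE, TRUE, TRUE))
  # d larger than the chromosome: a single bin, true because it holds m3
  lab2 <- mb_block_truth(map, data.frame(chromosome = "1", marker_id = "m3"),
                         d = 100)
  expect_true(all(lab2$bin == 0L) && all(lab2$is_true_block))
  # collapse vs hand-collapsed calls at d = 3
  pts <- data.frame(effect_size = rep(2, 4), score = c(0.9, 0.1, 0.7, 0.4),
                    is_true = c(FALSE, FALSE, TRUE, FALSE),
                    chromosome = "1", mb = map$mb, instance = 1)
  blk <- collapse_mb_blocks(pts, d = 3)
  # bins at d=3: {0.5, 1.9, 2.1} and {3.8}
  expect_equal(nrow(blk), 2)
  expect_equal(sort(blk$score), c(0.1, 0.4))
  expect_equal(blk$is_true[order(blk$score)], c(TRUE, FALSE))
})

test_that("threshold matching recovers FDR-comparable thresholds", {
  withr::with_seed(9, {
    n <- 400
    ref <- data.frame(effect_size = sort(stats::runif(n, 0, 3)),
                      score = stats::runif(n),
                      is_true = stats::runif(n) < 0.3)
  })
  thr <- sort(ref$score)[120]
  # self-match: the reference threshold reproduces its own mean FDR
  m <- match_threshold(ref, thr, ref, window = 100, offset = 50)
  expect_equal(m$alt_fdr, m$ref_fdr)
  expect_equal(m$threshold, thr)
  # monotone rescaling: matched threshold is the rescaled one
  alt <- ref
  alt$score <- ref$score^2
  m2 <- match_threshold(ref, thr, alt, window = 100, offset = 50)
  expect_equal(m2$threshold, thr^2)
  # exhaustive grid oracle on a small instance
  withr::with_seed(10, {
    alt2 <- data.frame(effect_size = sort(stats::runif(60, 0, 3)),
                       score = stats::runif(60),
                       is_true = stats::runif(60) < 0.4)
  })
  m3 <- match_threshold(ref, thr, alt2, window = 30, offset = 15)
  gaps <- vapply(sort(unique(alt2$score)), function(t) {
    pf <- power_fdr(alt2, t, 30, 15)
    v <- pf$fdr[!is.na(pf$fdr)]
    if (!length(v)) return(Inf)
    abs(mean(v) - m3$ref_fdr)
  }, 0)
  expect_equal(m3$threshold,
               sort(unique(alt2$score))[which.min(gaps)])
})
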