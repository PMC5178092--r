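# Evaluation harness: sliding effect-size windows, power/FDR at a
# threshold, ROC/AUROC, Mb-block tolerance, and FDR-matched threshold
# pairing between two score sets.
#
# A "point" is one scored candidate: its score (R-value or P-value; small
# means significant), a truth flag, and the effect size of the causative
# locus of its (phenotype, chromosome) instance. Points are sorted by
# effect size and analysed in overlapping windows so that power and FDR
# can be read as functions of effect size.

#' Sliding index windows over sorted points
#'
#' Windows are `[k*offset + 1, k*offset + window]` for k = 0, 1, ... as
#' long as the window fits; partial trailing windows are dropped.
#'
#' @param n_points total number of points.
#' @param window window width (points per group).
#' @param offset start-to-start spacing, `1 <= offset <= window`.
#' @return data.frame with columns `start`, `end` (1-based, inclusive).
#' @export
sliding_windows <- function(n_points, window, offset) {
  stopifnot(window >= 1, offset >= 1, offset <= window)
  if (window > n_points) stop("window exceeds the number of points")
  starts <- seq(0L, n_points - window, by = offset)
  data.frame(start = starts + 1L, end = starts + window)
}

.check_points <- function(points) {
  need <- c("effect_size", "score", "is_true")
  if (!all(need %in% names(points))) {
    stop("points need columns effect_size, score, is_true")
  }
  if (is.unsorted(points$effect_size)) {
    stop("points must be sorted by increasing effect size")
  }
  points
}

#' Power and FDR per effect-size window
#'
#' Within each window, calls are the points with `score <= threshold`;
#' power is true calls over true points and FDR is false calls over all
#' calls (`NA` when the window makes no calls).
#'
#' @param points data.frame with columns `effect_size` (sorted ascending),
#'   `score`, `is_true`.
#' @param threshold calling threshold (calls are `score <= threshold`).
#' @param window,offset window geometry, see [sliding_windows()].
#' @return data.frame per window: `start`, `end`, `mean_effect`, `power`,
#'   `fdr`, `n_calls`.
#' @export
power_fdr <- function(points, threshold, window, offset) {
  points <- .check_points(points)
  w <- sliding_windows(nrow(points), window, offset)
  res <- lapply(seq_len(nrow(w)), function(k) {
    sel <- w$start[k]:w$end[k]
    sc <- points$score[sel]
    tr <- points$is_true[sel]
    called <- sc <= threshold
    n_true <- sum(tr)
    n_calls <- sum(called)
    data.frame(
      start = w$start[k], end = w$end[k],
      mean_effect = mean(points$effect_size[sel]),
      power = if (n_true > 0) sum(called & tr) / n_true else NA_real_,
      fdr = if (n_calls > 0) sum(called & !tr) / n_calls else NA_real_,
      n_calls = n_calls)
  })
  do.call(rbind, res)
}

#' ROC curve and AUROC
#'
#' Sweeps the calling threshold over the distinct scores (small score =
#' significant); tied scores move together. AUROC by the trapezoid rule,
#' which equals the Mann-Whitney concordance probability with ties counted
#' half.
#'
#' @param points data.frame with columns `score`, `is_true` (at least one
#'   true and one false point).
#' @return list with `curve` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auroc`.
#' @export
roc_curve <- function(points) {
  if (!all(c("score", "is_true") %in% names(points))) {
    stop("points need columns score, is_true")
  }
  n_true <- sum(points$is_true)
  n_false <- sum(!points$is_true)
  if (n_true == 0 || n_false == 0) {
    stop("ROC needs at least one true and one false point")
  }
  thr <- sort(unique(points$score))
  tpr <- vapply(thr, function(t) sum(points$is_true & points$score <= t), 0) /
    n_true
  fpr <- vapply(thr, function(t) sum(!points$is_true & points$score <= t), 0) /
    n_false
  fpr_full <- c(0, fpr)
  tpr_full <- c(0, tpr)
  auroc <- sum(diff(fpr_full) * (utils::head(tpr_full, -1) +
                                   utils::tail(tpr_full, -1)) / 2)
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auroc = auroc)
}

#' Mb-block truth labels
#'
#' Partitions each chromosome into fixed half-open bins of width `d` Mb
#' anchored at 0 and flags the bin that contains a true locus. Used for
#' the tolerance mode in which any call within `d` Mb of the true locus
#' counts as a single true positive.
#'
#' @param map data.frame with columns `marker_id`, `chromosome`, `mb`.
#' @param true_loci data.frame with columns `chromosome`, `marker_id` of
#'   the causative markers.
#' @param d bin width in Mb, positive.
#' @return data.frame per marker: `marker_id`, `chromosome`, `mb`, `bin`
#'   (integer bin index), `block` (chromosome:bin label), `is_true_block`.
#' @export
mb_block_truth <- function(map, true_loci, d) {
  stopifnot(d > 0)
  bin <- as.integer(floor(map$mb / d))
  block <- paste(map$chromosome, bin, sep = ":")
  truth_idx <- match(true_loci$marker_id, map$marker_id)
  if (anyNA(truth_idx)) stop("true locus absent from map")
  truth_key <- block[truth_idx]
  data.frame(marker_id = map$marker_id, chromosome = map$chromosome,
             mb = map$mb, bin = bin, block = block,
             is_true_block = block %in% truth_key,
             stringsAsFactors = FALSE)
}

#' Collapse marker-level points to Mb-block points
#'
#' One point per (instance, block): the block's score is the minimum
#' marker score (so the block is called iff any of its markers is), its
#' truth flag says whether it contains the instance's true locus, and it
#' inherits the instance's effect size.
#'
#' @param points marker-level points with columns `effect_size`, `score`,
#'   `is_true` (flagging each instance's causative marker) plus
#'   `chromosome`, `mb`, and `instance` (identifier of the
#'   phenotype-chromosome pair; a constant works for a single scan).
#' @param d bin width in Mb.
#' @return block-level points sorted by effect size.
#' @export
collapse_mb_blocks <- function(points, d) {
  stopifnot(d > 0)
  bin <- as.integer(floor(points$mb / d))
  key <- paste(points$instance, points$chromosome, bin)
  agg <- lapply(split(seq_len(nrow(points)), key), function(idx) {
    data.frame(effect_size = points$effect_size[idx[1]],
               score = min(points$score[idx]),
               is_true = any(points$is_true[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$effect_size), ]
  rownames(out) <- NULL
  out
}

#' Match a threshold between two score sets by average FDR
#'
#' Computes the reference score set's FDR averaged over windows that make
#' at least one call, then searches the alternative set's distinct score
#' values for the threshold whose average FDR is closest; ties prefer the
#' smaller threshold.
#'
#' @param ref_points,alt_points point tables as in [power_fdr()], each
#'   sorted by effect size.
#' @param threshold_ref calling threshold for the reference set.
#' @param window,offset window geometry (shared).
#' @return list with `threshold` (matched alternative threshold),
#'   `ref_fdr` and `alt_fdr` (the paired average FDRs).
#' @export
match_threshold <- function(ref_points, threshold_ref, alt_points,
                            window, offset) {
  mean_fdr <- function(points, thr) {
    pf <- power_fdr(points, thr, window, offset)
    v <- pf$fdr[!is.na(pf$fdr)]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  ref <- mean_fdr(ref_points, threshold_ref)
  if (is.na(ref)) stop("reference threshold makes no calls in any window")
  cand <- sort(unique(alt_points$score))
  best <- NULL
  for (thr in cand) {
    fdr <- mean_fdr(alt_points, thr)
    if (is.na(fdr)) next
    gap <- abs(fdr - ref)
    if (is.null(best) || gap < best$gap - 1e-15) {
      best <- list(threshold = thr, gap = gap, alt_fdr = fdr)
    }
  }
  if (is.null(best)) stop("alternative score set makes no calls")
  list(threshold = best$threshold, ref_fdr = ref, alt_fdr = best$alt_fdr)
}
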