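# Per-SNP pseudo-probabilities from inter-block correlations.
#
# For SNP s, Q_sb is the strongest fused-network similarity between s and
# block b (excluding s itself); the inter-block odds are
# L0_sb = Q_sb / sum_{b' != b} Q_sb'. The pseudo-probability r_s is the
# Pearson correlation between the phenotype-independent odds sequence
# (L0_s1, ..., L0_sNc) and the phenotype-dependent block likelihoods
# (L_1, ..., L_Nc), clamped below at zero; the reported R-value is
# R(s) = 1 - max(0, r_s), so small R-values mark strong candidates.

#' Inter-block odds of one SNP
#'
#' @param m fused similarity matrix of the chromosome.
#' @param blocks a `block_partition`.
#' @param s marker index (row of `m`).
#' @param statistic `"max"` (default) or `"mean"`: how block-level
#'   similarity Q is summarized over the block's markers.
#' @return numeric vector `L0_sb` over the blocks, in block order. For a
#'   singleton block containing only `s` itself the exclusion is waived and
#'   its own similarity is used.
#' @export
interblock_odds <- function(m, blocks, s, statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  K <- nrow(blocks)
  if (K < 2) stop("need at least 2 blocks for inter-block odds")
  if (s < 1 || s > nrow(m)) stop("marker index out of range")
  q <- vapply(seq_len(K), function(b) {
    idx <- setdiff(seq(blocks$start[b], blocks$end[b]), s)
    if (length(idx) == 0) idx <- s          # singleton block = {s}
    if (statistic == "max") max(m[s, idx]) else mean(m[s, idx])
  }, 0)
  denom <- sum(q) - q
  ifelse(denom > 0, q / denom, Inf)
}

#' Pseudo-probability of one SNP
#'
#' Pearson correlation between the inter-block odds and the block
#' likelihoods, clamped below at 0; degenerate (zero-variance) sequences
#' score 0.
#'
#' @param l0 numeric vector from [interblock_odds()].
#' @param l per-block likelihoods (a `block_likelihoods` or numeric).
#' @return scalar in `[0, 1]`.
#' @export
snp_pseudo_probability <- function(l0, l) {
  if (inherits(l, "block_likelihoods")) l <- l$l
  if (length(l0) != length(l)) stop("sequence lengths differ")
  if (length(l0) < 2) stop("need at least 2 blocks")
  max(0, safe_cor(l0, l))
}

#' Build the phenotype-independent network stage of the scan
#'
#' Per chromosome: missingness filter, genetic-distance matrix,
#' permutation-averaged mutual information, (kappa, eta) selection, fusion,
#' block decomposition. The result depends on the phenotype only through
#' the multiset of its values (the permutation averaging destroys the
#' subject pairing), so it can be reused across phenotypes that share a
#' value distribution, and across arbitrary phenotypes when scoring speed
#' matters more than re-estimating the weighting.
#'
#' @param g a [genotype_matrix()] or per-chromosome list of them.
#' @param phen a `phenotype_vector` (weights for the mutual information).
#' @param config a [bnm_config()].
#' @param seed integer seed.
#' @param verbose print per-chromosome progress (default FALSE).
#' @return object of class `bnm_network`: per-chromosome list with elements
#'   `genotype` (filtered), `distance`, `mutual_info`, `kappa`, `eta`,
#'   `fused`, `blocks`.
#' @export
bnm_network <- function(g, phen, config = bnm_config(), seed = 1,
                        verbose = FALSE) {
  gl <- as_genotype_list(g)
  cfg <- clustering_config(s_min = config$s_min, t_max = config$t_max,
                           kappa_grid = config$kappa_grid,
                           eta_grid = config$eta_grid)
  out <- vector("list", length(gl))
  names(out) <- names(gl)
  for (ci in seq_along(gl)) {
    t0 <- proc.time()[["elapsed"]]
    gf <- filter_missing(gl[[ci]], config$max_missing_fraction)
    d <- genetic_distance_matrix(gf$map)
    i <- permutation_mutual_information(gf, phen$rho,
                                        n_perm = config$n_perm,
                                        seed = substream_seed(seed, ci, 1))
    sel <- select_kappa_eta(d, i, cfg,
                            snf_iterations = config$snf_iterations,
                            seed = substream_seed(seed, ci, 2))
    out[[ci]] <- list(genotype = gf, distance = d, mutual_info = i,
                      kappa = sel$kappa, eta = sel$eta,
                      fused = sel$fused, blocks = sel$partition)
    if (verbose) {
      message(sprintf(
        "chromosome %s: %d markers, kappa=%d eta=%.1f, %d blocks [%.1fs]",
        names(gl)[ci], n_markers(gf), sel$kappa, sel$eta,
        nrow(sel$partition), proc.time()[["elapsed"]] - t0))
    }
  }
  structure(out, class = "bnm_network")
}

#' Score every SNP given a prepared network
#'
#' Runs the phenotype-dependent stage (block likelihoods, then per-SNP
#' pseudo-probabilities) on an existing [bnm_network()].
#'
#' @param network a `bnm_network`.
#' @param phen a `phenotype_vector`.
#' @param config a [bnm_config()].
#' @param seed integer seed.
#' @return data.frame with one row per SNP: `chromosome`, `marker_id`,
#'   `mb`, `r_s`, `r_value`, sorted by chromosome then Mb.
#' @export
bnm_score <- function(network, phen, config = bnm_config(), seed = 1) {
  stopifnot(inherits(network, "bnm_network"))
  rows <- vector("list", length(network))
  for (ci in seq_along(network)) {
    nw <- network[[ci]]
    gf <- nw$genotype
    K <- nrow(nw$blocks)
    S <- n_markers(gf)
    if (K < 2) {
      warning(sprintf(
        "chromosome %s collapsed to a single block; its SNPs score 0",
        gf$map$chromosome[1]))
      r_s <- rep(0, S)
    } else {
      L <- block_likelihoods(gf, nw$blocks, phen,
                             n_trial = config$n_trial, n_p = config$n_p,
                             seed = substream_seed(seed, ci, 3),
                             lambda = config$ridge_lambda)
      r_s <- vapply(seq_len(S), function(s) {
        l0 <- interblock_odds(nw$fused, nw$blocks, s,
                              statistic = config$q_statistic)
        snp_pseudo_probability(l0, L)
      }, 0)
    }
    rows[[ci]] <- data.frame(chromosome = gf$map$chromosome,
                             marker_id = gf$map$marker_id,
                             mb = gf$map$mb,
                             r_s = r_s,
                             r_value = 1 - r_s,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$chromosome, names(network)), out$mb), ]
  rownames(out) <- NULL
  out
}

#' End-to-end Block Network Mapping scan
#'
#' Per chromosome: missingness filter, distance and mutual-information
#' networks, (kappa, eta) selection and fusion, contiguous block
#' decomposition, block likelihoods against the permutation null, per-SNP
#' pseudo-probabilities. Deterministic for a fixed seed.
#'
#' @inheritParams bnm_network
#' @return data.frame as in [bnm_score()].
#' @export
bnm_scan <- function(g, phen, config = bnm_config(), seed = 1,
                     verbose = FALSE) {
  nw <- bnm_network(g, phen, config = config, seed = seed, verbose = verbose)
  bnm_score(nw, phen, config = config, seed = seed)
}
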