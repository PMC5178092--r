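# Contiguous haplotype-block decomposition of the fused similarity matrix.
#
# The chromosome is split top-down: every open branch smaller than kappa
# closes; otherwise the branch is split into n = 2, 3, ... clusters by
# normalized spectral clustering of its similarity submatrix, accepting the
# first n whose clusters are all contiguous in map order and all at least
# s_min markers; if no n up to n_max = min(floor(S_k / s_min), t_max) is
# accepted the branch closes. Leaves, in map order, are the blocks.

#' Clustering configuration for the block decomposition
#'
#' @param s_min minimum cluster size (default 2).
#' @param t_max maximum number of iterations / split arity cap (default 50).
#' @param kappa_grid candidate SNF neighbourhood sizes (default `10:15`).
#' @param eta_grid candidate kernel bandwidths (default `seq(0.3, 0.7, 0.1)`).
#' @return a `clustering_config` list.
#' @export
clustering_config <- function(s_min = 2, t_max = 50, kappa_grid = 10:15,
                              eta_grid = seq(0.3, 0.7, by = 0.1)) {
  stopifnot(s_min >= 1, t_max >= 1,
            length(kappa_grid) >= 1, length(eta_grid) >= 1,
            all(kappa_grid >= 2), all(eta_grid > 0))
  structure(list(s_min = as.integer(s_min), t_max = as.integer(t_max),
                 kappa_grid = as.integer(kappa_grid),
                 eta_grid = as.numeric(eta_grid)),
            class = "clustering_config")
}

#' Split a similarity submatrix into n clusters by spectral clustering
#'
#' Normalized spectral clustering with the submatrix used directly as the
#' affinity: the symmetric normalized Laplacian's n smallest eigenvectors
#' are row-normalized and clustered by k-means (seeded, multiple restarts).
#'
#' @param m_sub symmetric similarity submatrix.
#' @param n number of clusters, `2 <= n <= nrow(m_sub)`.
#' @param seed integer seed for the k-means stage.
#' @return integer vector of cluster labels in `1:n`.
#' @export
spectral_split <- function(m_sub, n, seed = 1) {
  S <- nrow(m_sub)
  if (n > S) stop("cannot split ", S, " markers into ", n, " clusters")
  if (n < 2) stop("n must be at least 2")
  if (n == S) return(seq_len(S))
  A <- (m_sub + t(m_sub)) / 2
  diag(A) <- 0
  deg <- rowSums(A)
  deg[deg <= 0] <- .Machine$double.eps
  dh <- 1 / sqrt(deg)
  Lsym <- diag(S) - (dh * A) * rep(dh, each = S)   # I - D^-1/2 A D^-1/2
  ev <- eigen(Lsym, symmetric = TRUE)
  U <- ev$vectors[, S:(S - n + 1), drop = FALSE]   # n smallest eigenvalues
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  km <- withr::with_seed(as.integer(seed),
    stats::kmeans(U, centers = n, nstart = 20, iter.max = 100))
  km$cluster
}

.contiguous_groups <- function(labels) {
  # returns list of index vectors per label; NULL if some label's members
  # are not contiguous
  out <- list()
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    if (max(idx) - min(idx) + 1 != length(idx)) return(NULL)
    out[[length(out) + 1]] <- idx
  }
  out[order(vapply(out, min, 0L))]
}

#' Decompose a chromosome into contiguous blocks
#'
#' Runs the open/closed-branch loop described above on the fused similarity
#' matrix `m` (markers in map order).
#'
#' @param m fused similarity matrix (from [snf_fuse()]).
#' @param cfg a [clustering_config()].
#' @param kappa the branch-closing size threshold (the SNF neighbourhood
#'   size of the fusion that produced `m`).
#' @param seed integer seed for the spectral splits.
#' @return a `block_partition`: data.frame with columns `block_id`,
#'   `start`, `end`, `n_markers` (marker index intervals in map order),
#'   with attributes `kappa` and `s_min`.
#' @export
hierarchical_block_decomposition <- function(m, cfg = clustering_config(),
                                             kappa, seed = 1) {
  if (!is_symmetric_matrix(m, tol = 1e-6)) stop("m must be symmetric")
  stopifnot(kappa >= 2)
  S <- nrow(m)
  open <- list(seq_len(S))
  closed <- list()
  iter <- 0L
  while (length(open) > 0 && iter < cfg$t_max) {
    iter <- iter + 1L
    next_open <- list()
    for (b in seq_along(open)) {
      idx <- open[[b]]
      Sk <- length(idx)
      if (Sk < kappa) {
        closed[[length(closed) + 1]] <- idx
        next
      }
      n_max <- min(Sk %/% cfg$s_min, cfg$t_max)
      accepted <- NULL
      if (n_max >= 2) {
        for (n in 2:n_max) {
          labels <- spectral_split(m[idx, idx, drop = FALSE], n,
                                   seed = substream_seed(seed, iter, b, n))
          groups <- .contiguous_groups(labels)
          if (!is.null(groups) &&
              all(vapply(groups, length, 0L) >= cfg$s_min)) {
            accepted <- lapply(groups, function(gidx) idx[gidx])
            break
          }
        }
      }
      if (is.null(accepted)) {
        closed[[length(closed) + 1]] <- idx
      } else {
        next_open <- c(next_open, accepted)
      }
    }
    open <- next_open
  }
  closed <- c(closed, open)            # t_max reached: remaining leaves close
  starts <- vapply(closed, min, 0L)
  o <- order(starts)
  part <- data.frame(
    block_id = seq_along(closed),
    start = starts[o],
    end = vapply(closed, max, 0L)[o],
    n_markers = vapply(closed, length, 0L)[o])
  # coverage / disjointness / contiguity asserted on every run
  covered <- unlist(mapply(seq, part$start, part$end, SIMPLIFY = FALSE))
  if (!identical(sort(covered), seq_len(S)) ||
      any(part$end - part$start + 1 != part$n_markers)) {
    stop("internal error: blocks do not partition the chromosome")
  }
  structure(part, class = c("block_partition", "data.frame"),
            kappa = kappa, s_min = cfg$s_min)
}

#' Select (kappa, eta) by the minimax largest-block criterion
#'
#' Fuses and decomposes for every pair on the grid and keeps the pair whose
#' largest leaf block is smallest (highest mapping resolution). Ties are
#' broken by fewer blocks at the maximal size, then by more total blocks,
#' then by the lexicographically smallest (kappa, eta).
#'
#' @param d genetic-distance matrix.
#' @param i mutual-information matrix.
#' @param cfg a [clustering_config()] (provides the grids).
#' @param snf_iterations cross-diffusion steps per fusion (default 20).
#' @param seed integer seed.
#' @return list with elements `kappa`, `eta`, `partition`
#'   (`block_partition`), and `fused` (the winning similarity matrix).
#' @export
select_kappa_eta <- function(d, i, cfg = clustering_config(),
                             snf_iterations = 20, seed = 1) {
  S <- nrow(d)
  kappas <- cfg$kappa_grid[cfg$kappa_grid < S]
  if (length(kappas) == 0) {
    stop("no kappa on the grid is smaller than the number of markers (",
         S, ")")
  }
  best <- NULL
  for (kappa in sort(kappas)) {
    for (eta in sort(cfg$eta_grid)) {
      M <- snf_fuse(d, i, kappa = kappa, eta = eta,
                    iterations = snf_iterations)
      part <- hierarchical_block_decomposition(
        M, cfg, kappa = kappa, seed = substream_seed(seed, kappa, round(eta * 1000)))
      max_size <- max(part$n_markers)
      n_at_max <- sum(part$n_markers == max_size)
      n_blocks <- nrow(part)
      cand <- list(kappa = kappa, eta = eta, partition = part, fused = M,
                   key = c(max_size, n_at_max, -n_blocks))
      if (is.null(best)) {
        best <- cand
      } else {
        for (j in 1:3) {
          if (cand$key[j] < best$key[j]) { best <- cand; break }
          if (cand$key[j] > best$key[j]) break
        }
      }
    }
  }
  best$key <- NULL
  best
}
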