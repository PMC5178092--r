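# Genotype/phenotype simulator.
#
# Genotypes follow a first-order Markov chain along each chromosome with
# Hardy-Weinberg-like stationary state frequencies; the chance that the
# state is redrawn between adjacent markers is calibrated so that the
# unconditional switch frequency between them equals the Haldane
# recombination fraction r = (1 - exp(-2 d / 100)) / 2 for d cM.
# Phenotypes are one causative marker per chromosome with exponential
# effect sizes; the summed dosage effect is scaled to sample variance 1 and
# N(0,1) noise is added.

#' Simulate genotypes with distance-decaying linkage
#'
#' Marker cM positions are equally spaced on `[0, cm_length]`; physical
#' positions default to `mb = cm / 2`. Each subject's state sequence is a
#' Markov chain on `{0,1,2}` with stationary distribution `state_freqs`:
#' between adjacent markers d cM apart the state is redrawn from the
#' stationary distribution with probability `theta = r / (1 - sum(p^2))`
#' (and copied otherwise), where `r` is Haldane's map function, so the
#' marginal probability that the two states differ equals `r`. Each emitted
#' state is independently replaced by the missing code 3 with probability
#' `missing_rate`.
#'
#' @param n_subjects,n_chromosomes,markers_per_chromosome positive integers.
#' @param cm_length genetic length of each chromosome in cM (default 100).
#' @param missing_rate per-entry missing probability in `[0, 1)`.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param state_freqs stationary probabilities of states 0, 1, 2; default
#'   `c(0.25, 0.5, 0.25)` (Hardy-Weinberg at allele frequency 1/2).
#' @return named list of [genotype_matrix()] objects, one per chromosome
#'   (chromosomes labelled `"1" ... "n_chromosomes"`).
#' @export
simulate_genotypes <- function(n_subjects = 200, n_chromosomes = 19,
                               markers_per_chromosome = 60,
                               cm_length = 100, missing_rate = 0.02,
                               seed = 1,
                               state_freqs = c(0.25, 0.5, 0.25)) {
  stopifnot(n_subjects >= 1, n_chromosomes >= 1, markers_per_chromosome >= 1,
            cm_length >= 0)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  p <- as.numeric(state_freqs)
  if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("state_freqs must be 3 probabilities summing to 1")
  }
  het <- 1 - sum(p^2)                  # P(two independent draws differ)
  if (het <= 0) stop("degenerate chain: a single state has probability 1")
  S <- markers_per_chromosome
  N <- n_subjects
  cm <- if (S == 1) 0 else seq(0, cm_length, length.out = S)
  d <- diff(cm)
  r <- (1 - exp(-2 * d / 100)) / 2     # Haldane map function
  theta <- r / het                     # redraw probability per step
  if (any(theta > 1)) stop("degenerate chain: redraw probability exceeds 1")
  out <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_chromosomes), function(chr) {
      states <- matrix(0L, nrow = S, ncol = N)
      states[1, ] <- sample(0:2, N, replace = TRUE, prob = p)
      if (S > 1) {
        for (j in 2:S) {
          redraw <- stats::runif(N) < theta[j - 1]
          row <- states[j - 1, ]
          if (any(redraw)) {
            row[redraw] <- sample(0:2, sum(redraw), replace = TRUE, prob = p)
          }
          states[j, ] <- row
        }
      }
      if (missing_rate > 0) {
        states[stats::runif(S * N) < missing_rate] <- 3L
      }
      map <- data.frame(
        marker_id = sprintf("c%02d_m%03d", chr, seq_len(S)),
        chromosome = as.character(chr),
        cm = cm, mb = cm / 2, stringsAsFactors = FALSE)
      genotype_matrix(states, map,
                      subject_ids = sprintf("subj%04d", seq_len(N)))
    })
  })
  names(out) <- as.character(seq_len(n_chromosomes))
  out
}

.dosage <- function(states_row) {
  # additive dosage 0/1/2; missing entries get the marker's mean observed
  # dosage (the expectation under its empirical state distribution)
  x <- as.numeric(states_row)
  miss <- x == 3
  if (all(miss)) stop("marker with all states missing")
  if (any(miss)) x[miss] <- mean(x[!miss])
  x
}

#' Simulate phenotypes with one causative marker per chromosome
#'
#' One causative marker is drawn uniformly on each chromosome and assigned
#' an effect size from an exponential distribution (or taken from
#' `effect_sizes`). The per-subject genetic effect is the sum over
#' chromosomes of effect size times centered additive dosage at the
#' causative marker; this sum is scaled to sample variance exactly 1, and
#' independent `N(0,1)` noise is added.
#'
#' @param g list of [genotype_matrix()] (one per chromosome).
#' @param rate rate of the exponential effect-size distribution
#'   (default 0.5, chosen so that 19 draws span the same order of magnitude
#'   as effect sizes observed in Diversity Outbred simulation studies).
#' @param seed integer seed.
#' @param effect_sizes optional numeric vector (one per chromosome) of
#'   effect sizes to use instead of exponential draws.
#' @param causative optional integer vector of causative marker row indices
#'   (one per chromosome) instead of uniform draws.
#' @return list with elements `phenotype` (raw, log-scale values, length N)
#'   and `truth`, a `simulation_truth` object holding `causative`
#'   (data.frame: chromosome, marker_id, effect_size, effect_size_scaled),
#'   `qtl_component` (sample variance 1 unless degenerate), `noise`, and
#'   `noise_sd`; `phenotype == qtl_component + noise` exactly.
#' @export
simulate_phenotypes <- function(g, rate = 0.5, seed = 1,
                                effect_sizes = NULL, causative = NULL) {
  gl <- as_genotype_list(g)
  if (!is.null(effect_sizes) && length(effect_sizes) != length(gl)) {
    stop("effect_sizes must have one value per chromosome")
  }
  if (!is.null(causative) && length(causative) != length(gl)) {
    stop("causative must have one marker index per chromosome")
  }
  if (is.null(effect_sizes) && (!is.finite(rate) || rate <= 0)) {
    stop("rate must be positive")
  }
  N <- n_subjects(gl[[1]])
  withr::with_seed(as.integer(seed), {
    loci <- if (is.null(causative)) {
      vapply(gl, function(x) sample.int(n_markers(x), 1L), 1L)
    } else as.integer(causative)
    beta <- if (is.null(effect_sizes)) {
      stats::rexp(length(gl), rate = rate)
    } else as.numeric(effect_sizes)
    genetic <- numeric(N)
    for (i in seq_along(gl)) {
      dos <- .dosage(gl[[i]]$states[loci[i], ])
      genetic <- genetic + beta[i] * (dos - mean(dos))
    }
    s <- stats::sd(genetic)
    noise <- stats::rnorm(N)
    if (!is.finite(s) || s == 0) {
      warning("zero-variance genetic effect; falling back to pure noise")
      qtl <- numeric(N)
      beta_scaled <- rep(0, length(gl))
      beta <- rep(0, length(gl))
    } else {
      qtl <- genetic / s
      beta_scaled <- beta / s
    }
    truth <- structure(list(
      causative = data.frame(
        chromosome = vapply(gl, function(x) x$map$chromosome[1], ""),
        marker_id = mapply(function(x, j) x$map$marker_id[j], gl, loci),
        effect_size = beta,
        effect_size_scaled = beta_scaled,
        stringsAsFactors = FALSE, row.names = NULL),
      qtl_component = qtl,
      noise = noise,
      noise_sd = 1), class = "simulation_truth")
    list(phenotype = qtl + noise, truth = truth)
  })
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("simulation_truth: %d causative loci, var(qtl) = %.6f\n",
              nrow(x$causative), stats::var(x$qtl_component)))
  invisible(x)
}

#' Write a simulated dataset to the genotype/map/phenotype/truth file set
#'
#' @param g list of genotype matrices.
#' @param phenotype raw phenotype values (log scale).
#' @param truth a `simulation_truth`.
#' @param dir output directory (created if absent).
#' @return invisibly, the four file paths.
#' @export
write_simulation <- function(g, phenotype, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gl <- as_genotype_list(g)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             map = file.path(dir, "map.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_genotypes(gl, paths[["genotypes"]], paths[["map"]])
  utils::write.table(
    data.frame(subject_id = gl[[1]]$subject_ids, value = phenotype),
    paths[["phenotypes"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$causative, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
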