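---
title: "Block Network Mapping: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block Network Mapping: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The mapping model

Block Network Mapping treats QTL detection as a two-stage inference on
each chromosome. The first stage is phenotype-independent: it asks how
the sampled genotypes are organized. The second stage is
phenotype-dependent: it asks which part of that organization predicts
the trait.

**Stage 1 — haplotype blocks.** Markers are encoded 0/1/2 (homozygous
dominant, heterozygous, homozygous recessive) with 3 for missing.
Markers missing on more than half the subjects are removed (the filter
runs after phenotype/subject intersection, so the missingness fractions
refer to the analyzed subjects). Two marker-by-marker similarity views
are built:

* the genetic distance `D[s, s'] = |cM_s - cM_s'|` — sample-independent,
  enforcing that blocks are chromosomal intervals;
* the phenotype-weighted mutual information
  `I[s, s'] = sum_ab P_ab log(P_ab / (P_a P_b))`, where
  `P_ab = sum_m rho_m [state(m,s)=a][state(m,s')=b]` weights subject m by
  its normalized phenotype `rho_m = exp(y_m) / sum exp(y)` — purely
  sample-driven.

Weighting by `rho` rather than uniformly keeps the estimator faithful to
the sampling distribution that produced the cohort; to remove the
*pairing* of phenotypes with subjects (which would leak trait information
into the blocks), `I` is averaged over random permutations of `rho`, with
missing states freshly imputed from each marker's empirical state
distribution at every permutation. The permutations are applied to the
*sorted* weight vector, so the result depends on the phenotype only
through its value multiset: two phenotypes that are subject-permutations
of one another give bit-identical networks under the same seed, which is
also how the suite asserts phenotype-independence exactly.

The two views are fused by Similarity Network Fusion: each view becomes
a locally-scaled exponential kernel
`W[i, j] = exp(-d_ij^2 / (eta * eps_ij))` with
`eps_ij = (mu_i + mu_j + d_ij)/3` and `mu_i` the mean dissimilarity of i
to its kappa nearest neighbours; full (row-stochastic, diagonal 1/2) and
kappa-nearest-neighbour sparse kernels are formed, and the full kernels
are cross-diffused (`P_v <- S_v P_other t(S_v)`, renormalized,
symmetrized) for a fixed number of iterations. The mutual-information
view enters as the dissimilarity `max(I) - I` — a monotone,
parameter-free inversion — with the self-dissimilarity zeroed, as the
kernel requires. With zero iterations the fusion degenerates to the
average of the two initial kernels, which the tests use as the base case.

The fused matrix is decomposed into contiguous blocks top-down: a branch
of size `S_k < kappa` closes; otherwise it is split into n = 2, 3, ...
clusters by normalized spectral clustering of its similarity submatrix
(used directly as the affinity, no re-kernelization), accepting the first
n whose clusters are all contiguous in map order and all of size at least
`s_min`, up to `n_max = min(floor(S_k / s_min), t_max)`. `(kappa, eta)`
are chosen over a grid by minimizing the largest leaf block — resolution
is the goal — with ties broken by fewer maximal blocks, then more total
blocks, then the lexicographically smallest pair. The tie rule "compare
the number of big versus small clusters" admits several readings; this
three-level order is the package's deterministic choice. The grid search
re-fuses per pair, since kappa enters the fusion itself, not only the
decomposition.

**Stage 2 — block likelihoods and SNP scores.** Per trial, subjects are
split into a training half (the larger half when N is odd) and a test
half, shared across all blocks for fairness. Each block's model — a
closed-form ridge regression of the log phenotype on per-marker one-hot
state indicators, able to represent non-additive genotype-class effects —
predicts the held-out log phenotypes, and the observed Pearson
correlation is compared to `n_p` permutation-null correlations through
`R = exp(r_obs) / sum_p exp(r_null)`. Exponentiation maps negative
correlations to small positive contributions; negative values are kept
as-is. Undefined correlations (constant predictions) are set to 0. The
likelihood `L_k` is the fraction of trials block k attains the maximal
ratio, ties counting for all tied blocks, so `sum(L) = 1` exactly under
unique winners.

Each SNP's inter-block odds `L0_{s,b} = Q_{s,b} / sum_{b' != b} Q_{s,b'}`
(with `Q` the maximal — optionally mean — fused similarity between s and
block b, excluding s itself; the exclusion is waived only for a singleton
block consisting of s) are correlated with the block likelihood sequence;
the correlation, clamped below at 0, is the pseudo-probability `r_s`, and
`R(s) = 1 - r_s` is reported. The SNP's own block is included in both
sequences (excluding it is not offered: with few blocks per chromosome
the correlation would often become degenerate). A chromosome that
collapses to a single block carries no inter-block information and its
SNPs score 0 with a warning.

## Parameters

| parameter | default | role |
|---|---|---|
| `n_perm` | 100 | permutations averaged in `I`; the average converges quickly and split-half agreement is part of the test suite |
| `kappa_grid` | 10..15 | SNF neighbourhood sizes searched |
| `eta_grid` | 0.3..0.7 (step 0.1) | kernel bandwidth scalings searched |
| `snf_iterations` | 20 | cross-diffusion steps; the update is contractive and 20 steps are ample at these matrix sizes |
| `s_min` | 2 | minimum block size |
| `t_max` | 50 | iteration/arity cap of the decomposition |
| `n_trial` | 1000 | train/test trials per chromosome |
| `n_p` | 20 | permutation-null trials per split; the denominator scale cancels in the winner comparison when `n_p` is constant across blocks, so a modest value suffices |
| `ridge_lambda` | 1e-8 | ridge penalty; effectively a numerically-regularized minimum-norm least-squares fit, so realizable phenotypes are reproduced on training data |
| `max_missing_fraction` | 0.5 | drop markers missing on more than half the subjects |

All randomness flows from one run seed through named substreams
(imputation, permutations, splits, spectral k-means), so scans are
bit-reproducible and changing the draw count of one stage does not
perturb another.

## The simulator

`simulate_genotypes()` emulates a dense biallelic panel on equally spaced
cM grids: each subject's state sequence is a first-order Markov chain on
{0, 1, 2} with Hardy–Weinberg-like stationary frequencies (default
0.25/0.5/0.25), where between adjacent markers the state is redrawn from
the stationary distribution with probability `theta = r / (1 - sum(p^2))`
and copied otherwise, `r` being Haldane's map function of the cM gap.
This calibration makes the unconditional switch frequency between
adjacent markers equal `r` exactly, which the suite verifies against a
binomial oracle. Physical positions default to `mb = cm / 2`. Entries
are replaced by the missing code independently at a configurable rate
(default 2%, a typical post-QC missingness).

`simulate_phenotypes()` draws one causative marker per chromosome,
assigns exponential effect sizes (default rate 0.5, so that ~19 draws
span several orders of magnitude, as in published effect-size sweeps),
builds the summed centered-dosage effect, scales it to sample variance
exactly 1 — the scaling is applied to the *combined* multi-locus
component, not per locus, since per-locus scaling would erase the
effect-size differences the evaluation sweeps over — and adds N(0,1)
noise. Missing dosages at a causative marker are imputed with the
marker's mean observed dosage (the expectation under its empirical state
distribution), keeping the stored decomposition
`phenotype = qtl_component + noise` exact. The truth table records both
the raw draws (the scale on which effect-size sweeps are defined) and
the post-scaling coefficients.

What the simulator does **not** emulate: multi-founder haplotype mosaics
(a Markov chain calibrated to pairwise Haldane switch frequencies has
F2-cross-like long-range linkage, much stronger than in advanced
intercross or Diversity Outbred populations), sex effects and sex
chromosomes, epistasis, genotyping error, and non-uniform marker maps.
Consequences for interpreting test results are discussed under
limitations.

## Numerical choices

* `0 log 0` terms in the mutual information contribute 0; logarithm
  arguments are floored at 1e-300 to avoid `-Inf`; the joint-cell
  normalization `sum_ab P_ab = 1` is asserted for every pair.
* The ridge fit uses the SVD with singular values below `1e-12` of the
  largest treated as null directions (minimum-norm behavior); one-hot
  columns are centered, the intercept is unpenalized.
* Spectral clustering uses the symmetric normalized Laplacian; zero
  degrees are guarded; the k-means stage runs 20 restarts under a fixed
  substream seed, making decompositions deterministic.
* Markers at identical cM positions are kept, stable-sorted by input
  order; the distance view treats them as duplicates and the information
  view separates them if their genotypes differ.
* Block-partition coverage, disjointness and contiguity are asserted on
  every decomposition; `sum(L) >= 1` is asserted on every likelihood run.

## Evaluation harness

Scored SNPs become effect-size-sorted points (each carrying its
chromosome instance's causative effect size, its score, and a truth
flag); overlapping windows (partial trailing windows dropped) yield
power and FDR as functions of effect size; ROC curves sweep the score
threshold with ties grouped, and AUROC equals the Mann–Whitney
concordance. The d-Mb tolerance mode bins each chromosome into fixed
width-d bins anchored at 0 Mb and collapses calls per bin. Threshold
matching between two score sets equates mean FDR over windows with at
least one call (windows with no calls are excluded — how empty windows
enter the average is otherwise a free choice). Both R-values and
P-values are treated as "small is significant".

The bundled study sizes keep the full pipeline inexpensive: the
end-to-end simulation study uses 200 subjects, 19 chromosomes of 60
markers (100 cM / 50 Mb), `n_perm = 30`, `n_trial = 200` (200 subjects
halve into 100/100 splits), `n_p = 10`, with 6 phenotype replicates
pooled for the FDR-by-effect-size trend; null calibration uses 20 seeds
of a 3-chromosome configuration. These sizes were fixed once when the
suite was designed.

## Known limitations

* **Fine-scale localization under strong linkage.** Within the winning
  haplotype block, SNP ranking rests entirely on the phenotype-independent
  inter-block odds pattern; when linkage decays slowly (as in the
  simulator's F2-like chain, or any small cross), neighbouring markers
  carry nearly identical patterns and narrow physical-bin localization of
  the causative marker is limited for any method at a few hundred
  subjects — the information is simply not in the sample. The method's
  strength at this scale is block-level detection and the behavior of its
  error rates with effect size, not sub-block pinpointing.
* One causative block per chromosome is assumed; multiple linked QTL on
  one chromosome are not resolved.
* Effects of opposing sign on tightly linked markers can cancel in the
  block model, as in single-locus scans.
* The uniform equal-size segmentation alternative is deliberately not
  offered as a primary path; data-driven blocks are the point of the
  method.
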