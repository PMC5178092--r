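# bnm — Block Network Mapping of quantitative trait loci

`bnm` maps quantitative trait loci (QTL) by exploiting the correlation
structure of the sampled genotypes instead of scanning one marker at a
time. It is aimed at analyses of dense biallelic SNP panels with a single
quantitative phenotype per subject — the setting of experimental crosses
and multiparent populations such as Diversity Outbred mice — where
classical interval mapping treats each position in isolation and leaves
the linkage information between markers on the table.

## Method

For each chromosome the package builds two views of the S markers:

* a **genetic-distance matrix** `D[s, s'] = |cM_s − cM_s'|`, and
* a **phenotype-weighted mutual-information matrix**
  `I[s, s'] = Σ_ab P_ab log( P_ab / (P_a P_b) )`, where the joint cell
  probabilities weight each subject by its normalized phenotype
  `rho_m = w_m / Σ w`, averaged over many random permutations of `rho` so
  that `I` is independent of which subject carries which phenotype.

The two views are fused by **Similarity Network Fusion** (cross-diffusion
of κ-nearest-neighbour kernels) into one similarity matrix `M`, which is
decomposed into contiguous **haplotype blocks** by hierarchical spectral
clustering under a contiguity constraint; the (κ, η) kernel parameters
are chosen by a minimax criterion on the largest resulting block.

Each block k is then scored by its predictive power for the phenotype:
over repeated train/test splits a ridge model on one-hot marker states
predicts held-out log phenotypes, giving an observed test correlation
`r_{k,t}` and permutation-null correlations `r^p_{k,t}`, combined as
`R_{k,t} = exp(r_{k,t}) / Σ_p exp(r^p_{k,t})`. The block likelihood
`L_k` is the fraction of trials in which block k attains the maximal
ratio. Finally, every SNP s receives inter-block odds
`L0_{s,b} = Q_{s,b} / Σ_{b'≠b} Q_{s,b'}` with
`Q_{s,b} = max_{s'∈b, s'≠s} M[s, s']`, and the **pseudo-probability**
`r_s = max(0, cor(L0_{s,·}, L))`. Scans report the R-value
`R(s) = 1 − r_s`; small R-values mark strong candidates.

A full simulator (Markov-chain genotypes with Haldane-calibrated linkage
decay, one causative locus per chromosome, exponential effect sizes,
unit-variance genetic component plus N(0,1) noise) and an evaluation
harness (sliding effect-size windows, power, FDR, ROC/AUROC, d-Mb block
tolerance, FDR-matched threshold pairing) are included.

## Worked example

```r
library(bnm)

g   <- simulate_genotypes(n_subjects = 150, n_chromosomes = 2,
                          markers_per_chromosome = 40, cm_length = 60,
                          missing_rate = 0.02, seed = 11)
sim <- simulate_phenotypes(g, seed = 12, effect_sizes = c(3, 0.2))
sim$truth$causative
#>   chromosome marker_id effect_size effect_size_scaled
#> 1          1  c01_m002         3.0           1.570305
#> 2          2  c02_m026         0.2           0.104687

phen   <- normalize_phenotype(sim$phenotype)
cfg    <- bnm_config(n_perm = 20, n_trial = 100, n_p = 8,
                     kappa_grid = 10:12, eta_grid = c(0.3, 0.5, 0.7))
scores <- bnm_scan(g, phen, cfg, seed = 13, verbose = TRUE)
#> chromosome 1: 40 markers, kappa=10 eta=0.3, 6 blocks [0.2s]
#> chromosome 2: 40 markers, kappa=10 eta=0.3, 7 blocks [0.2s]

head(scores[order(scores$r_value), ], 5)
#>   chromosome marker_id       mb       r_s     r_value
#> 8          1  c01_m008 5.384615 0.9974838 0.002516231
#> 7          1  c01_m007 4.615385 0.9785922 0.021407794
#> 6          1  c01_m006 3.846154 0.9668238 0.033176209
#> 5          1  c01_m005 3.076923 0.9605649 0.039435062
#> 4          1  c01_m004 2.307692 0.9583183 0.041681738
```

The strong simulated locus (`c01_m002`, scaled effect 1.57) drives the
chromosome-1 minimum R-value of 0.0025 a few markers away inside the same
haplotype block, while the weak chromosome-2 locus (scaled effect 0.10)
produces no comparably small R-value. `r_value` near 0 means the SNP's
phenotype-independent inter-block correlation pattern closely matches the
observed block likelihoods; values near 1 mean no evidence.

File-based workflows (`read_genotypes()`, `read_phenotypes()`,
`run_pipeline()` with a YAML configuration, and the `inst/cli/bnm.R`
script with `simulate` / `scan` / `evaluate` subcommands) wrap the same
functions.

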