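# Run configuration and the simulate -> scan -> evaluate pipeline.

#' Scan configuration with validated defaults
#'
#' @param n_perm permutations averaged in the mutual-information matrix
#'   (default 100).
#' @param n_trial train/test trials per chromosome for the block
#'   likelihoods (default 1000).
#' @param n_p permutation-null trials per split (default 20; the null
#'   denominator scale cancels in the winner comparison, so a modest value
#'   suffices).
#' @param kappa_grid,eta_grid SNF parameter grids searched by the minimax
#'   block-size criterion (defaults `10:15` and `seq(0.3, 0.7, 0.1)`).
#' @param s_min minimum block size (default 2).
#' @param t_max maximum clustering iterations (default 50).
#' @param snf_iterations cross-diffusion steps (default 20).
#' @param q_statistic `"max"` or `"mean"` block similarity summary for the
#'   inter-block odds.
#' @param ridge_lambda ridge penalty of the default block model.
#' @param max_missing_fraction missingness filter threshold (default 0.5).
#' @return validated list of class `bnm_config`.
#' @export
bnm_config <- function(n_perm = 100, n_trial = 1000, n_p = 20,
                       kappa_grid = 10:15, eta_grid = seq(0.3, 0.7, by = 0.1),
                       s_min = 2, t_max = 50, snf_iterations = 20,
                       q_statistic = c("max", "mean"), ridge_lambda = 1e-8,
                       max_missing_fraction = 0.5) {
  q_statistic <- match.arg(q_statistic)
  stopifnot(n_perm >= 1, n_trial >= 1, n_p >= 1, snf_iterations >= 0,
            ridge_lambda >= 0,
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  clustering_config(s_min, t_max, kappa_grid, eta_grid)  # validates grids
  structure(list(n_perm = as.integer(n_perm), n_trial = as.integer(n_trial),
                 n_p = as.integer(n_p), kappa_grid = as.integer(kappa_grid),
                 eta_grid = as.numeric(eta_grid), s_min = as.integer(s_min),
                 t_max = as.integer(t_max),
                 snf_iterations = as.integer(snf_iterations),
                 q_statistic = q_statistic,
                 ridge_lambda = as.numeric(ridge_lambda),
                 max_missing_fraction = as.numeric(max_missing_fraction)),
            class = "bnm_config")
}

.config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  s <- 0
  for (v in utf8ToInt(js)) s <- (s * 31 + v) %% 2147483647
  sprintf("%08x", s)
}

#' Read and validate a pipeline configuration file
#'
#' YAML with a top-level `seed`, optional `params` (fields of
#' [bnm_config()]), and per-stage sections `simulate` (simulator
#' arguments plus `out` directory), `scan` (`genotypes`, `map`,
#' `phenotypes`, `out`), and `evaluate` (`scores`, `truth`, `threshold`,
#' `window`, `offset`, optional `mb_block`, `out`).
#'
#' @param path YAML file path.
#' @return validated list of class `bnm_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- list(seed = as.integer(raw$seed %||% 1),
              params = do.call(bnm_config, raw$params %||% list()),
              simulate = raw$simulate, scan = raw$scan,
              evaluate = raw$evaluate)
  if (!is.null(cfg$scan)) {
    for (f in c("out")) {
      if (is.null(cfg$scan[[f]])) stop("scan config missing field: ", f)
    }
    if (is.null(cfg$simulate)) {
      for (f in c("genotypes", "map", "phenotypes")) {
        if (is.null(cfg$scan[[f]])) stop("scan config missing field: ", f)
        if (!file.exists(cfg$scan[[f]])) {
          stop("scan input does not exist: ", cfg$scan[[f]])
        }
      }
    }
  }
  if (!is.null(cfg$evaluate)) {
    for (f in c("threshold", "window", "offset", "out")) {
      if (is.null(cfg$evaluate[[f]])) stop("evaluate config missing field: ", f)
    }
  }
  structure(cfg, class = "bnm_run_config")
}

.stamp_and_write <- function(df, path, cfg, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bnm %s | seed %d | config %s", what, cfg$seed,
                     .config_hash(cfg$params)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the configured pipeline stages
#'
#' Executes, in order and as configured: simulate (writes the genotype,
#' map, phenotype and truth files), scan (writes the per-SNP score table),
#' evaluate (writes per-window power/FDR and a summary JSON). Every output
#' is stamped with the seed and a hash of the scan parameters. Failures
#' abort with the stage name.
#'
#' @param config path to a YAML run configuration, or a `bnm_run_config`.
#' @param verbose print progress (default TRUE).
#' @return invisibly, a named list of output paths per stage.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  cfg <- if (inherits(config, "bnm_run_config")) config
         else read_run_config(config)
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  sim_paths <- NULL
  if (!is.null(cfg$simulate)) {
    sim_paths <- stage("simulate", {
      sa <- cfg$simulate
      g <- simulate_genotypes(
        n_subjects = sa$n_subjects %||% 200,
        n_chromosomes = sa$n_chromosomes %||% 19,
        markers_per_chromosome = sa$markers_per_chromosome %||% 60,
        cm_length = sa$cm_length %||% 100,
        missing_rate = sa$missing_rate %||% 0.02,
        seed = substream_seed(cfg$seed, 101))
      ph <- simulate_phenotypes(g, rate = sa$rate %||% 0.5,
                                seed = substream_seed(cfg$seed, 102),
                                effect_sizes = sa$effect_sizes)
      write_simulation(g, ph$phenotype, ph$truth, sa$out %||% ".")
    })
    out$simulate <- sim_paths
  }
  if (!is.null(cfg$scan)) {
    out$scan <- stage("scan", {
      sc <- cfg$scan
      gpath <- sc$genotypes %||% sim_paths[["genotypes"]]
      mpath <- sc$map %||% sim_paths[["map"]]
      ppath <- sc$phenotypes %||% sim_paths[["phenotypes"]]
      g <- read_genotypes(gpath, mpath)
      phen <- read_phenotypes(ppath, subject_ids = g[[1]]$subject_ids)
      scores <- bnm_scan(g, phen, config = cfg$params, seed = cfg$seed,
                         verbose = verbose)
      .stamp_and_write(scores, sc$out, cfg, "scan")
    })
  }
  if (!is.null(cfg$evaluate)) {
    out$evaluate <- stage("evaluate", {
      ev <- cfg$evaluate
      spath <- ev$scores %||% out$scan
      scores <- utils::read.table(spath, header = TRUE, sep = "\t",
                                  comment.char = "#",
                                  stringsAsFactors = FALSE)
      truth <- utils::read.table(ev$truth %||% sim_paths[["truth"]],
                                 header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
      points <- scan_points(scores, truth)
      if (!is.null(ev$mb_block)) {
        points <- collapse_mb_blocks(points, d = ev$mb_block)
      }
      pf <- power_fdr(points, ev$threshold,
                      window = min(ev$window, nrow(points)),
                      offset = ev$offset)
      base <- sub("\\.tsv$", "", ev$out)
      .stamp_and_write(pf, ev$out, cfg, "evaluate")
      summary <- list(threshold = ev$threshold,
                      mean_fdr = mean(pf$fdr, na.rm = TRUE),
                      mean_power = mean(pf$power, na.rm = TRUE),
                      auroc = tryCatch(roc_curve(points)$auroc,
                                       error = function(e) NA_real_))
      jsonlite::write_json(summary, paste0(base, "_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      ev$out
    })
  }
  invisible(out)
}

#' Assemble marker-level evaluation points from a scan and its truth
#'
#' Each scored SNP becomes one point: its R-value, a truth flag (it is the
#' causative marker of its chromosome), and the effect size of its
#' chromosome's causative locus; points are sorted by effect size.
#'
#' @param scores scan table ([bnm_scan()] output, or several concatenated
#'   with an `instance` column identifying the phenotype).
#' @param truth causative-locus table (`chromosome`, `marker_id`,
#'   `effect_size`, optionally `instance`).
#' @return point table for [power_fdr()] / [roc_curve()] /
#'   [collapse_mb_blocks()].
#' @export
scan_points <- function(scores, truth) {
  if (is.null(scores$instance)) scores$instance <- 1L
  if (is.null(truth$instance)) truth$instance <- 1L
  key_s <- paste(scores$instance, scores$chromosome)
  key_t <- paste(truth$instance, truth$chromosome)
  idx <- match(key_s, key_t)
  if (anyNA(idx)) stop("chromosome without a truth row")
  out <- data.frame(
    effect_size = truth$effect_size[idx],
    score = scores$r_value,
    is_true = scores$marker_id == truth$marker_id[idx],
    chromosome = scores$chromosome,
    marker_id = scores$marker_id,
    mb = scores$mb,
    instance = scores$instance,
    stringsAsFactors = FALSE)
  out <- out[order(out$effect_size), ]
  rownames(out) <- NULL
  out
}
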