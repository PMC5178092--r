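# Genotype, genetic-map and phenotype I/O.
#
# SNP states are encoded 0 (homozygous dominant), 1 (heterozygous),
# 2 (homozygous recessive), 3 (missing). A genotype_matrix holds one
# chromosome: an S x N integer state matrix (rows = markers in cM order,
# columns = subjects) plus its genetic map.

#' Construct a per-chromosome genotype matrix
#'
#' @param states integer matrix, markers x subjects, entries in `{0,1,2,3}`.
#' @param map data.frame with columns `marker_id`, `chromosome`, `cm`, `mb`,
#'   one row per row of `states`, sorted by increasing `cm` (ties keep input
#'   order).
#' @param subject_ids character vector naming the columns of `states`.
#' @return an object of class `genotype_matrix` with elements `states`,
#'   `map`, `subject_ids`.
#' @export
genotype_matrix <- function(states, map, subject_ids = colnames(states)) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(ncol(states)))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("marker_id", "chromosome", "cm", "mb")
  if (!all(need %in% names(map))) {
    stop("map must have columns marker_id, chromosome, cm, mb")
  }
  if (nrow(states) != nrow(map)) stop("states and map row counts differ")
  if (nrow(states) < 1) stop("need at least one marker")
  if (ncol(states) < 2) stop("need at least two subjects")
  bad <- which(!(states %in% 0:3))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(states))
    stop(sprintf("invalid SNP state %s at marker '%s', subject '%s'",
                 states[bad[1]], map$marker_id[rc[1]], subject_ids[rc[2]]))
  }
  if (anyDuplicated(map$marker_id)) stop("duplicated marker ids")
  if (length(unique(map$chromosome)) != 1) {
    stop("a genotype_matrix holds a single chromosome")
  }
  if (any(map$cm < 0) || any(map$mb < 0)) stop("negative map positions")
  o <- order(map$cm)                     # stable: ties keep file order
  states <- states[o, , drop = FALSE]
  map <- map[o, , drop = FALSE]
  rownames(map) <- NULL
  dimnames(states) <- list(map$marker_id, subject_ids)
  structure(list(states = states, map = map,
                 subject_ids = as.character(subject_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: chromosome %s, %d markers x %d subjects\n",
              x$map$chromosome[1], nrow(x$states), ncol(x$states)))
  invisible(x)
}

#' Number of markers / subjects of a genotype matrix
#' @param g a `genotype_matrix`.
#' @return integer count.
#' @export
n_markers <- function(g) nrow(g$states)

#' @rdname n_markers
#' @export
n_subjects <- function(g) ncol(g$states)

.detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read genotypes and a genetic map from delimited text
#'
#' The genotype file has one row per marker: first column the marker id,
#' remaining columns the integer states per subject, subject ids in the
#' header. The map file has columns `marker_id`, `chromosome`, `cm`, `mb`.
#' Comma- and tab-delimited files are auto-detected.
#'
#' @param genotype_path,map_path file paths.
#' @return named list of `genotype_matrix`, one per chromosome, markers
#'   sorted by cM within each chromosome.
#' @export
read_genotypes <- function(genotype_path, map_path) {
  for (p in c(genotype_path, map_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  gsep <- .detect_sep(genotype_path)
  geno <- utils::read.table(genotype_path, header = TRUE, sep = gsep,
                            check.names = FALSE, stringsAsFactors = FALSE)
  map <- utils::read.table(map_path, header = TRUE, sep = .detect_sep(map_path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  marker_ids <- as.character(geno[[1]])
  subject_ids <- colnames(geno)[-1]
  states <- as.matrix(geno[, -1, drop = FALSE])
  suppressWarnings(storage.mode(states) <- "integer")
  bad <- which(is.na(states) | !(states %in% 0:3))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(states))
    stop(sprintf(
      "unparseable or out-of-range SNP state at marker '%s', subject '%s'",
      marker_ids[rc[1]], subject_ids[rc[2]]))
  }
  missing_in_map <- setdiff(marker_ids, map$marker_id)
  if (length(missing_in_map)) {
    stop("markers absent from map: ", paste(utils::head(missing_in_map, 5),
                                            collapse = ", "))
  }
  map <- map[match(marker_ids, map$marker_id), , drop = FALSE]
  map$chromosome <- as.character(map$chromosome)
  out <- list()
  for (chr in unique(map$chromosome)) {
    sel <- map$chromosome == chr
    out[[chr]] <- genotype_matrix(states[sel, , drop = FALSE],
                                  map[sel, , drop = FALSE], subject_ids)
  }
  out
}

#' Write genotypes and map back to delimited text
#'
#' @param g a `genotype_matrix` or a list of them (one per chromosome).
#' @param genotype_path,map_path output file paths.
#' @param sep field separator (default tab).
#' @return invisibly, the paths written.
#' @export
write_genotypes <- function(g, genotype_path, map_path, sep = "\t") {
  gl <- as_genotype_list(g)
  states <- do.call(rbind, lapply(gl, function(x) x$states))
  map <- do.call(rbind, lapply(gl, function(x) x$map))
  gdf <- data.frame(marker_id = rownames(states), states,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(gdf, genotype_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  utils::write.table(map, map_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(c(genotype_path, map_path))
}

#' Coerce to a per-chromosome list of genotype matrices
#' @param g a `genotype_matrix` or list of them.
#' @return named list of `genotype_matrix`.
#' @export
as_genotype_list <- function(g) {
  if (inherits(g, "genotype_matrix")) {
    gl <- list(g)
    names(gl) <- g$map$chromosome[1]
    return(gl)
  }
  if (is.list(g) && all(vapply(g, inherits, TRUE, "genotype_matrix"))) {
    if (is.null(names(g))) {
      names(g) <- vapply(g, function(x) as.character(x$map$chromosome[1]), "")
    }
    return(g)
  }
  stop("expected a genotype_matrix or a list of genotype_matrix")
}

#' Drop markers with too many missing states
#'
#' Removes SNPs whose state is missing (state 3) on more than
#' `max_missing_fraction` of the subjects; a marker missing on exactly the
#' threshold fraction is kept.
#'
#' @param g a `genotype_matrix`.
#' @param max_missing_fraction maximum tolerated missing fraction,
#'   default 0.5 (drop markers missing on more than half the subjects).
#' @return filtered `genotype_matrix`.
#' @export
filter_missing <- function(g, max_missing_fraction = 0.5) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (max_missing_fraction < 0 || max_missing_fraction > 1) {
    stop("max_missing_fraction must be in [0, 1]")
  }
  n_missing <- rowSums(g$states == 3L)
  keep <- n_missing <= max_missing_fraction * ncol(g$states)
  if (!any(keep)) stop("no markers survive missingness filter")
  if (all(keep)) return(g)
  genotype_matrix(g$states[keep, , drop = FALSE],
                  g$map[keep, , drop = FALSE], g$subject_ids)
}

#' Normalize a phenotype into positive weights summing to one
#'
#' Phenotypes enter the mutual-information weighting as
#' `rho_m = w_m / sum(w)` with `w_m = exp(y_m)`; exponentiation makes
#' arbitrary real-valued phenotypes positive. If the input is already
#' positive (e.g. counts), set `log_scale = FALSE` and the values are used
#' as `w` directly (their logs become the raw scale used by the block
#' regressions).
#'
#' @param y numeric phenotype vector, length >= 2, finite.
#' @param log_scale if `TRUE` (default) `y` is on the raw (possibly signed)
#'   scale and is exponentiated; if `FALSE`, `y` must be positive and is
#'   taken as `w` directly.
#' @return object of class `phenotype_vector` with elements `raw` (log
#'   scale), `positive` (`w`), and `rho` (normalized weights summing to 1).
#' @export
normalize_phenotype <- function(y, log_scale = TRUE) {
  y <- as.numeric(y)
  if (length(y) < 2) stop("need at least two phenotype values")
  if (any(!is.finite(y))) stop("non-finite phenotype values")
  if (log_scale) {
    raw <- y
    positive <- exp(y)
  } else {
    if (any(y <= 0)) stop("phenotype declared positive has values <= 0")
    positive <- y
    raw <- log(y)
  }
  rho <- positive / sum(positive)
  structure(list(raw = raw, positive = positive, rho = rho),
            class = "phenotype_vector")
}

#' Read a phenotype file and align it with genotype subjects
#'
#' @param path delimited text with columns `subject_id`, `value`.
#' @param subject_ids if given, phenotypes are reordered to match; an error
#'   is thrown for subjects without a phenotype.
#' @param log_scale passed to [normalize_phenotype()].
#' @return a `phenotype_vector`.
#' @export
read_phenotypes <- function(path, subject_ids = NULL, log_scale = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  val <- as.numeric(df[[2]])
  if (!is.null(subject_ids)) {
    idx <- match(subject_ids, ids)
    if (anyNA(idx)) {
      stop("subjects without phenotype: ",
           paste(utils::head(subject_ids[is.na(idx)], 5), collapse = ", "))
    }
    val <- val[idx]
    ids <- subject_ids
  }
  ph <- normalize_phenotype(val, log_scale = log_scale)
  names(ph$raw) <- names(ph$positive) <- names(ph$rho) <- ids
  ph
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("phenotype_vector: %d subjects, sum(rho) = %.12f\n",
              length(x$rho), sum(x$rho)))
  invisible(x)
}

.as_rho <- function(rho) {
  if (inherits(rho, "phenotype_vector")) rho <- rho$rho
  rho <- as.numeric(rho)
  if (abs(sum(rho) - 1) > 1e-8 || any(rho < 0)) {
    stop("rho must be non-negative weights summing to 1")
  }
  rho
}
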