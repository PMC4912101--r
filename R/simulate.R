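# Balding-Nichols island-model simulator: genotype tables with known
# ground-truth differentiation, for end-to-end validation of the pipeline.

#' Simulation configuration
#'
#' Balding-Nichols island model: for each locus an ancestral insertion
#' frequency `p0` is drawn from `ancestral_law`, then each population's
#' frequency is an independent Beta draw with mean `p0` and shape
#' parameters `p0 (1 - fst) / fst` and `(1 - p0)(1 - fst) / fst`, so the
#' between-population variance is `fst * p0 (1 - p0)` — `fst` is exactly
#' the differentiation the Gst pipeline should recover. Genotypes within
#' each population are drawn at Hardy-Weinberg proportions; loci are
#' independent.
#'
#' @param K Number of populations (>= 2).
#' @param L Number of loci (>= 1).
#' @param n Diploid individuals per population; scalar or length-`K`.
#' @param fst Differentiation parameter, strictly in (0, 1).
#' @param p0_range Range of the uniform ancestral-frequency law, default
#'   `c(0.1, 0.9)` (keeps loci informatively polymorphic, like the
#'   moderate-frequency Alu markers the design mimics).
#' @param seed Integer RNG seed; identical configs give identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(K, L, n, fst, p0_range = c(0.1, 0.9), seed = 1L) {
  if (K < 2L) stop("need K >= 2 populations")
  if (L < 1L) stop("need L >= 1 loci")
  if (!length(n) %in% c(1L, K) || any(n < 1 | n != round(n))) {
    stop("`n` must be a positive integer, scalar or length K")
  }
  if (fst <= 0 || fst >= 1) stop("`fst` must lie strictly in (0, 1)")
  if (length(p0_range) != 2L || p0_range[1L] <= 0 || p0_range[2L] >= 1 ||
      p0_range[1L] > p0_range[2L]) {
    stop("`p0_range` must be an increasing pair inside (0, 1)")
  }
  structure(list(K = as.integer(K), L = as.integer(L),
                 n = as.integer(rep_len(n, K)), fst = fst,
                 p0_range = p0_range, seed = as.integer(seed)),
            class = "sim_config")
}

.sim_freqs <- function(cfg) {
  p0 <- stats::runif(cfg$L, cfg$p0_range[1L], cfg$p0_range[2L])
  shape_scale <- (1 - cfg$fst) / cfg$fst
  p <- vapply(seq_len(cfg$L), function(l) {
    stats::rbeta(cfg$K, p0[l] * shape_scale, (1 - p0[l]) * shape_scale)
  }, numeric(cfg$K))
  dimnames(p) <- list(sprintf("pop%02d", seq_len(cfg$K)),
                      sprintf("locus%02d", seq_len(cfg$L)))
  list(p0 = stats::setNames(p0, colnames(p)), p = p)
}

.sim_geno <- function(p, n) {
  K <- nrow(p); L <- ncol(p)
  pop_i <- rep(seq_len(K), times = n * L)
  ind_i <- unlist(lapply(seq_len(K), function(j) rep(seq_len(n[j]),
                                                     each = L)))
  loc_i <- unlist(lapply(seq_len(K), function(j) rep(seq_len(L),
                                                     times = n[j])))
  p_rec <- p[cbind(pop_i, loc_i)]
  alleles <- stats::rbinom(length(p_rec), 2L, p_rec)  # insertion dosage
  df <- data.frame(
    population = rownames(p)[pop_i],
    individual = sprintf("%s_%04d", rownames(p)[pop_i], ind_i),
    locus = colnames(p)[loc_i],
    genotype = c("DD", "ID", "II")[alleles + 1L],
    stringsAsFactors = FALSE)
  as_genotype_table(df, populations = rownames(p), loci = colnames(p))
}

#' Simulate per-population allele frequencies
#'
#' The frequency layer of the Balding-Nichols model (see [sim_config()]).
#'
#' @param cfg A [sim_config()].
#' @return List with `p0` (ancestral frequencies per locus), `p`
#'   (population x locus frequency matrix) and `fst`.
#' @export
simulate_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  f <- .sim_freqs(cfg)
  list(p0 = f$p0, p = f$p, fst = cfg$fst)
}

#' Simulate a genotype table at given frequencies
#'
#' Each individual's genotype at each locus is an independent draw at
#' Hardy-Weinberg proportions `(p^2, 2pq, q^2)` for that population x
#' locus frequency.
#'
#' @param p Population x locus frequency matrix (row/column names become
#'   population and locus labels).
#' @param n Diploids per population, scalar or per-population.
#' @param seed Optional seed set before drawing; `NULL` uses the current
#'   RNG state (as inside [simulate_dataset()]).
#' @return A `genotype_table`.
#' @export
simulate_genotypes <- function(p, n, seed = NULL) {
  p <- as.matrix(p)
  if (is.null(rownames(p))) {
    rownames(p) <- sprintf("pop%02d", seq_len(nrow(p)))
  }
  if (is.null(colnames(p))) {
    colnames(p) <- sprintf("locus%02d", seq_len(ncol(p)))
  }
  if (any(is.na(p) | p < 0 | p > 1)) stop("frequencies must lie in [0, 1]")
  n <- rep_len(as.integer(n), nrow(p))
  if (any(n < 1L)) stop("`n` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  .sim_geno(p, n)
}

#' Simulate a complete dataset with serialized ground truth
#'
#' Draws frequencies and genotypes in one seeded pass and keeps the truth
#' (ancestral and per-population frequencies, `fst`) alongside the data so
#' parameter-recovery checks can compare estimate to target.
#'
#' @param cfg A [sim_config()].
#' @return A `simulated_dataset`: list with `truth`, `genotypes`, `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  f <- .sim_freqs(cfg)
  gt <- .sim_geno(f$p, cfg$n)
  structure(list(truth = list(p0 = f$p0, p = f$p, fst = cfg$fst),
                 genotypes = gt, config = cfg),
            class = "simulated_dataset")
}

#' Write a simulated dataset to a directory
#'
#' `genotypes.tsv` (the genotype table) plus `truth.json` (ancestral and
#' per-population frequencies, `fst`, and the full configuration).
#'
#' @param x A `simulated_dataset`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(x, dir) {
  stopifnot(inherits(x, "simulated_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotype_table(x$genotypes, file.path(dir, "genotypes.tsv"))
  truth <- list(fst = x$truth$fst,
                p0 = as.list(x$truth$p0),
                p = apply(x$truth$p, 1L, as.list, simplify = FALSE),
                config = unclass(x$config))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
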