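# End-to-end orchestration: frequencies -> heterozygosity/HWE ->
# gene-diversity decomposition -> distances/NJ tree -> PCA, with a JSON
# run manifest.

#' Run the full analysis pipeline
#'
#' Executes the analysis sequence on a genotype table or directly on a
#' published frequency matrix: per-cell statistics and Hardy-Weinberg scan
#' (genotype input only), gene-diversity decomposition, genetic distances
#' with a neighbor-joining tree, and PCA. Every stage writes a TSV (or
#' Newick) artifact into `out_dir`, and `manifest.json` records inputs,
#' resolved method flags, outputs and collected warnings, so a run is
#' reproducible from its manifest. Outputs carry no timestamps: re-running
#' the same configuration yields byte-identical files.
#'
#' @param genotypes A `genotype_table`, or path to a genotype TSV; `NULL`
#'   for frequencies-only mode (e.g. re-analysis of published tables), in
#'   which case the stats/HWE stage is skipped with a warning.
#' @param frequencies A [frequency_matrix()] or path to a frequency TSV;
#'   ignored (recomputed by direct counting) when `genotypes` is given.
#' @param out_dir Output directory, created if needed.
#' @param stages Subset of `c("stats", "gst", "tree", "pca")` to run.
#' @param het Heterozygosity series for the stats table: `"observed"` or
#'   `"expected"`.
#' @param hwe_family Bonferroni family for the HWE scan, see [hwe_scan()].
#' @param convention Multi-locus Gst rule, see [multilocus_diversity()].
#' @param distance Distance method, see [nei_distance()].
#' @param scale_pca Unit-variance scaling in PCA; default `FALSE` (raw
#'   frequencies, centred only).
#' @return The manifest (list), invisibly.
#' @export
run_pipeline <- function(genotypes = NULL, frequencies = NULL, out_dir,
                         stages = c("stats", "gst", "tree", "pca"),
                         het = c("observed", "expected"),
                         hwe_family = c("run", "per-locus"),
                         convention = c("mean-of-ratios", "ratio-of-means"),
                         distance = c("nei1972", "da1983"),
                         scale_pca = FALSE) {
  het <- match.arg(het)
  hwe_family <- match.arg(hwe_family)
  convention <- match.arg(convention)
  distance <- match.arg(distance)
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(genotypes) && is.null(frequencies)) {
    stop("supply `genotypes` and/or `frequencies`")
  }
  inputs <- list()
  if (is.character(genotypes)) {
    if (!file.exists(genotypes)) stop("missing input: ", genotypes)
    inputs$genotypes <- genotypes
    genotypes <- read_genotype_table(genotypes)
  }
  if (is.character(frequencies)) {
    if (!file.exists(frequencies)) stop("missing input: ", frequencies)
    inputs$frequencies <- frequencies
    frequencies <- read_frequency_matrix(frequencies)
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  notes <- character(0)
  note <- function(...) notes <<- c(notes, paste0(...))
  outputs <- character(0)
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <<- c(outputs, file)
  }

  if ("stats" %in% stages) {
    if (is.null(genotypes)) {
      warning("stats stage skipped: no genotype-level input")
      note("stats stage skipped: frequencies-only input")
      stages <- setdiff(stages, "stats")
    } else {
      ht <- heterozygosity_table(genotypes, series = het)
      emit(ht, "stats.tsv")
      hw <- withCallingHandlers(
        hwe_scan(genotypes, family = hwe_family),
        warning = function(w) {
          note("hwe: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      emit(hw, "hwe.tsv")
    }
  }

  if (!is.null(genotypes)) {
    frequencies <- count_allele_frequencies(genotypes)
  }

  if ("gst" %in% stages) {
    div <- withCallingHandlers(
      gene_diversity(frequencies, convention = convention),
      warning = function(w) {
        note("gst: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    tab <- diversity_table(div)
    tab$convention <- convention
    emit(tab, "gst.tsv")
  }

  if ("tree" %in% stages) {
    if (nrow(frequencies) < 3L) {
      warning("tree stage skipped: fewer than 3 populations")
      note("tree stage skipped: fewer than 3 populations")
    } else {
      d <- genetic_distance(frequencies, method = distance)
      emit(data.frame(population = rownames(d), d, check.names = FALSE),
           "dist.tsv")
      tr <- withCallingHandlers(
        neighbor_joining(d),
        warning = function(w) {
          note("tree: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      write_newick(tr, file.path(out_dir, "tree.nwk"))
      outputs <- c(outputs, "tree.nwk")
    }
  }

  if ("pca" %in% stages) {
    pc <- pca_frequencies(frequencies, scale = scale_pca,
                          impute_missing = TRUE)
    emit(data.frame(population = rownames(pc$scores), pc$scores,
                    check.names = FALSE), "scores.tsv")
    emit(data.frame(component = seq_along(pc$variance_fraction),
                    variance_fraction = pc$variance_fraction),
         "variance.tsv")
  }

  manifest <- list(
    package = "alupopdiv",
    version = as.character(utils::packageVersion("alupopdiv")),
    inputs = inputs,
    flags = list(het = het, hwe_family = hwe_family,
                 convention = convention, distance = distance,
                 scale_pca = scale_pca),
    stages = stages,
    outputs = as.list(outputs),
    notes = as.list(notes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
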