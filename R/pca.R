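# Principal component analysis of population x locus allele frequencies.

#' PCA of a population allele-frequency matrix
#'
#' Column-centred (optionally unit-variance scaled) singular value
#' decomposition of the population x locus insertion-frequency matrix.
#' Populations are observations, loci are variables. By default the raw
#' frequencies are only centred, not scaled. Each component's loading
#' vector is sign-flipped so that its largest-magnitude entry is positive,
#' making score plots reproducible across platforms.
#'
#' @param m A [frequency_matrix()] (or plain numeric matrix, populations in
#'   rows) with at least 2 populations and 1 locus.
#' @param n_components Components to retain in `scores`/`loadings`;
#'   default: all non-trivial components (at most
#'   `min(populations - 1, loci)`). `variance_fraction` always covers all
#'   non-trivial components so it sums to 1.
#' @param scale Unit-variance scaling of loci before decomposition
#'   (sensitivity analysis); default `FALSE`.
#' @param impute_missing Replace `NA` cells by their locus (column) mean
#'   before decomposition; default `FALSE` (missing cells are an error).
#' @return A `pca_result`: list with `scores` (populations x components),
#'   `loadings` (loci x components), `variance_fraction`, `sdev`, `center`,
#'   `scale`.
#' @export
pca_frequencies <- function(m, n_components = NULL, scale = FALSE,
                            impute_missing = FALSE) {
  x <- unclass(m)
  attr(x, "n") <- NULL
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L) stop("need at least 2 populations")
  if (anyNA(x)) {
    if (!impute_missing) {
      stop("missing cells; set impute_missing = TRUE for column-mean ",
           "imputation")
    }
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (all(nas)) stop("locus ", colnames(x)[j], " entirely untyped")
      x[nas, j] <- mean(x[!nas, j])
    }
  }
  if (scale) {
    const <- apply(x, 2L, stats::sd) == 0
    if (any(const)) {
      stop("cannot scale constant locus/loci: ",
           paste(colnames(x)[const], collapse = ", "))
    }
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  ev <- pc$sdev^2
  if (sum(ev) <= 0) {
    stop("degenerate input: all populations have identical profiles, ",
         "no variance to decompose")
  }
  nontrivial <- ev > max(ev) * 1e-12
  ev <- ev[nontrivial]
  scores <- pc$x[, nontrivial, drop = FALSE]
  loadings <- pc$rotation[, nontrivial, drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(loadings))) {
    peak <- which.max(abs(loadings[, k]))
    if (loadings[peak, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  if (is.null(n_components)) n_components <- ncol(scores)
  n_components <- min(n_components, ncol(scores))
  structure(list(scores = scores[, seq_len(n_components), drop = FALSE],
                 loadings = loadings[, seq_len(n_components), drop = FALSE],
                 variance_fraction = ev / sum(ev),
                 sdev = sqrt(ev),
                 center = pc$center,
                 scale = if (scale) pc$scale else FALSE),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- ncol(x$scores)
  cat("PCA of allele frequencies: ", nrow(x$scores), " populations, ",
      k, " component(s) retained\n", sep = "")
  vf <- x$variance_fraction[seq_len(min(k, length(x$variance_fraction)))]
  cat("variance explained:",
      paste0(sprintf("PC%d %.2f%%", seq_along(vf), 100 * vf),
             collapse = ", "), "\n")
  invisible(x)
}
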