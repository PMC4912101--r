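# Nei's gene-diversity decomposition: per-locus Ht, Hs, Gst across
# populations and multi-locus aggregation.

#' Gst from total and within-population diversity
#'
#' Nei's coefficient of gene differentiation `(Ht - Hs) / Ht`: the fraction
#' of total gene diversity attributable to between-population differences.
#' Vectorised.
#'
#' @param ht Total gene diversity (from the mean allele frequency), > 0.
#' @param hs Mean within-population gene diversity.
#' @return `(ht - hs) / ht`.
#' @export
gst_from_ht_hs <- function(ht, hs) {
  if (any(!is.na(ht) & ht <= 0)) {
    stop("Gst undefined for Ht <= 0 (no total diversity)")
  }
  (ht - hs) / ht
}

#' Gene-diversity decomposition for one locus
#'
#' Across `K >= 2` populations with insertion frequencies `p_j`:
#' `Hs = mean_j 2 p_j (1 - p_j)` (unweighted by default), `Ht = 2 pbar
#' (1 - pbar)` with `pbar = mean_j p_j`, and `Gst = (Ht - Hs) / Ht`.
#' A locus fixed for the same allele everywhere has `Ht = 0`; its `Gst` is
#' `NA` and a warning is raised (such loci are excluded from multi-locus
#' aggregation).
#'
#' @param p Insertion-allele frequencies across populations (`NA` entries =
#'   populations untyped at this locus, dropped).
#' @param locus Optional locus label carried into the result.
#' @param weights Optional population weights (e.g. sample sizes) for an
#'   n-weighted variant; default equal weights, which is what reproduces
#'   published tables that omit the external populations' sample sizes.
#' @return A one-row data frame: `locus`, `K`, `Ht`, `Hs`, `Gst`.
#' @export
locus_diversity <- function(p, locus = NA_character_, weights = NULL) {
  keep <- !is.na(p)
  p <- p[keep]
  if (!is.null(weights)) {
    weights <- weights[keep]
    if (anyNA(weights) || any(weights <= 0)) stop("invalid weights")
    weights <- weights / sum(weights)
  } else {
    weights <- rep(1 / length(p), length(p))
  }
  if (length(p) < 2L) stop("need frequencies from at least 2 populations")
  if (any(p < 0 | p > 1)) stop("allele frequencies must lie in [0, 1]")
  hs <- sum(weights * 2 * p * (1 - p))
  pbar <- sum(weights * p)
  ht <- 2 * pbar * (1 - pbar)
  if (ht > 0) {
    gst <- gst_from_ht_hs(ht, hs)
  } else {
    warning("locus ", locus, " fixed in all populations: Gst undefined")
    gst <- NA_real_
  }
  data.frame(locus = locus, K = length(p), Ht = ht, Hs = hs, Gst = gst,
             stringsAsFactors = FALSE)
}

#' Multi-locus aggregation of per-locus diversities
#'
#' Two conventions:
#' * `"mean-of-ratios"` (default): `Ht_all`, `Hs_all` and `Gst_all` are the
#'   unweighted means of the per-locus values — the rule that reproduces
#'   every published "all loci" row in the bundled study tables.
#' * `"ratio-of-means"` (Nei's classical estimator): `Gst_all =
#'   (mean Ht - mean Hs) / mean Ht`.
#'
#' Loci with undefined `Gst` (`Ht = 0`) are dropped with a warning.
#'
#' @param per_locus Data frame with columns `Ht`, `Hs`, `Gst` (one row per
#'   locus), e.g. rows from [locus_diversity()].
#' @param convention Aggregation rule, see above.
#' @return List with `Ht_all`, `Hs_all`, `Gst_all`, `convention`,
#'   `n_loci` (loci actually aggregated).
#' @export
multilocus_diversity <- function(per_locus,
                                 convention = c("mean-of-ratios",
                                                "ratio-of-means")) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(per_locus),
            all(c("Ht", "Hs", "Gst") %in% names(per_locus)))
  if (nrow(per_locus) == 0L) stop("no loci to aggregate")
  drop <- is.na(per_locus$Gst)
  if (any(drop)) {
    warning(sum(drop), " locus/loci with undefined Gst excluded from ",
            "multi-locus aggregation")
    per_locus <- per_locus[!drop, , drop = FALSE]
  }
  if (nrow(per_locus) == 0L) stop("all loci have undefined Gst")
  ht_all <- mean(per_locus$Ht)
  hs_all <- mean(per_locus$Hs)
  gst_all <- if (convention == "mean-of-ratios") {
    mean(per_locus$Gst)
  } else {
    gst_from_ht_hs(ht_all, hs_all)
  }
  list(Ht_all = ht_all, Hs_all = hs_all, Gst_all = gst_all,
       convention = convention, n_loci = nrow(per_locus))
}

#' Gene-diversity decomposition over a frequency matrix
#'
#' Runs [locus_diversity()] on every locus (column) of a population x locus
#' frequency matrix and aggregates with [multilocus_diversity()].
#'
#' @param m A [frequency_matrix()].
#' @param convention Multi-locus rule, see [multilocus_diversity()].
#' @param weights Optional population weights passed to [locus_diversity()].
#' @return A `diversity_summary`: list with `per_locus` (data frame),
#'   `Ht_all`, `Hs_all`, `Gst_all`, `convention`.
#' @export
gene_diversity <- function(m, convention = c("mean-of-ratios",
                                             "ratio-of-means"),
                           weights = NULL) {
  stopifnot(inherits(m, "frequency_matrix"))
  convention <- match.arg(convention)
  if (nrow(m) < 2L) stop("need at least 2 populations")
  per_locus <- do.call(rbind, lapply(colnames(m), function(loc) {
    locus_diversity(m[, loc], locus = loc, weights = weights)
  }))
  all <- multilocus_diversity(per_locus, convention = convention)
  structure(list(per_locus = per_locus,
                 Ht_all = all$Ht_all, Hs_all = all$Hs_all,
                 Gst_all = all$Gst_all, convention = convention),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, digits = 4, ...) {
  cat("Gene-diversity decomposition (", nrow(x$per_locus), " loci, ",
      x$convention, ")\n", sep = "")
  df <- x$per_locus
  df[c("Ht", "Hs", "Gst")] <- lapply(df[c("Ht", "Hs", "Gst")], round,
                                     digits = digits)
  print(df, row.names = FALSE)
  cat(sprintf("All loci: Ht = %.*f  Hs = %.*f  Gst = %.*f\n",
              digits, x$Ht_all, digits, x$Hs_all, digits, x$Gst_all))
  invisible(x)
}

#' Tidy per-locus + all-loci table from a diversity summary
#'
#' @param x A `diversity_summary` from [gene_diversity()].
#' @return Data frame with one row per locus and a final `"All loci"` row.
#' @export
diversity_table <- function(x) {
  stopifnot(inherits(x, "diversity_summary"))
  rbind(x$per_locus[c("locus", "Ht", "Hs", "Gst")],
        data.frame(locus = "All loci", Ht = x$Ht_all, Hs = x$Hs_all,
                   Gst = x$Gst_all, stringsAsFactors = FALSE))
}
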