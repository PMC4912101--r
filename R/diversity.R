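# Allele frequencies by direct counting, heterozygosity and
# Hardy-Weinberg testing.

#' Insertion-allele frequency by direct counting
#'
#' `p = (2 n_II + n_ID) / (2n)` over the typed individuals of one cell;
#' the deletion frequency is `q = 1 - p`.
#'
#' @param counts A [genotype_counts()] object.
#' @return A `locus_frequency`: list with `p`, `q`, `n`.
#' @export
allele_frequency <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (counts$n == 0L) {
    stop("allele frequency undefined for an empty cell (n = 0)")
  }
  p <- (2 * counts$n_II + counts$n_ID) / (2 * counts$n)
  structure(list(p = p, q = 1 - p, n = counts$n), class = "locus_frequency")
}

#' Expected heterozygosity 2pq
#'
#' Hardy-Weinberg expected heterozygote proportion at a biallelic locus.
#' `q` may be supplied explicitly (published tables round `p` and `q`
#' independently); otherwise `q = 1 - p`. Vectorised over `p`/`q`.
#'
#' @param p Insertion-allele frequency, or a `locus_frequency` from
#'   [allele_frequency()].
#' @param q Deletion-allele frequency; default `1 - p`.
#' @param n Diploid sample size, needed only when `unbiased = TRUE`.
#' @param unbiased If `TRUE`, apply the small-sample factor `2n / (2n - 1)`.
#'   Default `FALSE`: published values match plain `2pq`.
#' @return Expected heterozygosity, in `[0, 0.5]` (slightly above when
#'   `unbiased = TRUE` at small `n`).
#' @export
expected_heterozygosity <- function(p, q = NULL, n = NULL, unbiased = FALSE) {
  if (inherits(p, "locus_frequency")) {
    if (is.null(n)) n <- p$n
    q <- p$q
    p <- p$p
  }
  if (is.null(q)) q <- 1 - p
  if (anyNA(p) || anyNA(q) || any(p < 0 | p > 1) || any(q < 0 | q > 1)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  h <- 2 * p * q
  if (unbiased) {
    if (is.null(n)) stop("`n` required for the unbiased estimator")
    h <- h * 2 * n / (2 * n - 1)
  }
  h
}

#' Observed heterozygosity
#'
#' Fraction of typed individuals that are heterozygous: `n_ID / n`.
#'
#' @param counts A [genotype_counts()] object.
#' @return Proportion in `[0, 1]`.
#' @export
observed_heterozygosity <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (counts$n == 0L) {
    stop("observed heterozygosity undefined for an empty cell (n = 0)")
  }
  counts$n_ID / counts$n
}

#' Average heterozygosity across loci
#'
#' Unweighted arithmetic mean of per-locus heterozygosities — the
#' "all loci" aggregation used in published multi-locus summaries.
#'
#' @param values Numeric vector of per-locus heterozygosities.
#' @param na.rm Drop `NA` loci before averaging.
#' @return The mean heterozygosity.
#' @export
average_heterozygosity <- function(values, na.rm = FALSE) {
  if (na.rm) values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no locus values to average")
  if (anyNA(values)) stop("NA locus values; use na.rm = TRUE to drop them")
  mean(values)
}

#' Hardy-Weinberg equilibrium test for one cell
#'
#' Default: chi-squared goodness of fit of the three genotype classes to
#' the Hardy-Weinberg proportions `(p^2, 2pq, q^2)` at the direct-count
#' allele frequency, 1 degree of freedom, no continuity correction.
#' `method = "exact"` runs the Levene-Haldane exact test (sum of
#' heterozygote-count probabilities no larger than that of the observed
#' configuration, conditioning on the allele counts).
#'
#' A monomorphic cell (estimated `p` of 0 or 1) has no test: the result is
#' flagged (`monomorphic = TRUE`) with `NA` statistics, and a warning is
#' raised.
#'
#' @param counts A [genotype_counts()] object.
#' @param m Number of tests in the Bonferroni family used for
#'   `p_adjusted = min(1, m * p_value)`; default 1 (no correction).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return An `hwe_result`: list with `chi2`, `df`, `p_value`,
#'   `p_adjusted`, `m`, `method`, `monomorphic`.
#' @export
hwe_test <- function(counts, m = 1L, method = c("chisq", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "genotype_counts"), m >= 1)
  f <- allele_frequency(counts)
  if (f$p == 0 || f$p == 1) {
    warning("monomorphic cell: Hardy-Weinberg test undefined, skipped")
    return(structure(list(chi2 = NA_real_, df = 1L, p_value = NA_real_,
                          p_adjusted = NA_real_, m = as.integer(m),
                          method = method, monomorphic = TRUE),
                     class = "hwe_result"))
  }
  if (method == "chisq") {
    obs <- c(counts$n_II, counts$n_ID, counts$n_DD)
    expc <- counts$n * c(f$p^2, 2 * f$p * f$q, f$q^2)
    chi2 <- sum((obs - expc)^2 / expc)
    pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- NA_real_
    pval <- .hwe_exact_p(counts$n_II, counts$n_ID, counts$n_DD)
  }
  structure(list(chi2 = chi2, df = 1L, p_value = pval,
                 p_adjusted = min(1, m * pval), m = as.integer(m),
                 method = method, monomorphic = FALSE),
            class = "hwe_result")
}

# Levene-Haldane exact p: enumerate all heterozygote counts compatible with
# the observed allele counts and sum the probabilities <= that observed.
.hwe_exact_p <- function(n_II, n_ID, n_DD) {
  n <- n_II + n_ID + n_DD
  nA <- 2L * n_II + n_ID
  ks <- seq.int(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
  logp <- vapply(ks, function(k) {
    x11 <- (nA - k) / 2
    x22 <- n - x11 - k
    lfactorial(n) - lfactorial(x11) - lfactorial(k) - lfactorial(x22) +
      k * log(2) + lfactorial(nA) + lfactorial(2L * n - nA) -
      lfactorial(2L * n)
  }, numeric(1))
  pk <- exp(logp - max(logp))
  pk <- pk / sum(pk)
  min(1, sum(pk[pk <= pk[ks == n_ID] * (1 + 1e-12)]))
}

#' @export
print.hwe_result <- function(x, ...) {
  if (x$monomorphic) {
    cat("Hardy-Weinberg test: monomorphic cell, no test\n")
  } else if (x$method == "chisq") {
    cat(sprintf(
      "Hardy-Weinberg chi-squared = %.4f, df = %d, p = %.4g (adjusted %.4g, m = %d)\n",
      x$chi2, x$df, x$p_value, x$p_adjusted, x$m))
  } else {
    cat(sprintf("Hardy-Weinberg exact p = %.4g (adjusted %.4g, m = %d)\n",
                x$p_value, x$p_adjusted, x$m))
  }
  invisible(x)
}

#' Bonferroni correction
#'
#' Each p-value is multiplied by the family size and clamped at 1.
#' When `m` equals the vector length (the default) this is
#' `stats::p.adjust(p, "bonferroni")`; an explicit `m` supports families
#' larger than the p-values at hand (e.g. tests skipped as monomorphic).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Family size; default `length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  if (m == length(p)) {
    stats::p.adjust(p, method = "bonferroni")
  } else {
    pmin(1, p * m)
  }
}

# counts for every population x locus cell -> list of three matrices
.count_matrices <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  keep <- !is.na(x$genotype)
  tab <- table(x$population[keep], x$locus[keep], x$genotype[keep])
  slice <- function(g) {
    m <- tab[, , g, drop = FALSE]
    dim(m) <- dim(tab)[1:2]
    dimnames(m) <- dimnames(tab)[1:2]
    m
  }
  list(n_II = slice("II"), n_ID = slice("ID"), n_DD = slice("DD"))
}

#' Allele frequencies for every population x locus cell
#'
#' Direct counting per cell; untyped cells (no non-missing calls) get `NA`.
#'
#' @param x A `genotype_table`.
#' @return A [frequency_matrix()] with per-cell typed sample sizes.
#' @export
count_allele_frequencies <- function(x) {
  cm <- .count_matrices(x)
  n <- cm$n_II + cm$n_ID + cm$n_DD
  p <- (2 * cm$n_II + cm$n_ID) / (2 * n)
  p[n == 0] <- NA_real_
  frequency_matrix(p, n = n)
}

#' Per-population heterozygosity table
#'
#' Observed (default) or expected heterozygosity for every population x
#' locus cell, plus the unweighted "all loci" average per population — the
#' layout of published multi-locus heterozygosity tables.
#'
#' @param x A `genotype_table`.
#' @param series `"observed"` (`n_ID / n`) or `"expected"` (`2pq`).
#' @param unbiased Small-sample correction for the expected series.
#' @return Data frame: `population`, one column per locus, `all_loci`.
#' @export
heterozygosity_table <- function(x, series = c("observed", "expected"),
                                 unbiased = FALSE) {
  series <- match.arg(series)
  cm <- .count_matrices(x)
  n <- cm$n_II + cm$n_ID + cm$n_DD
  if (series == "observed") {
    h <- cm$n_ID / n
  } else {
    p <- (2 * cm$n_II + cm$n_ID) / (2 * n)
    h <- 2 * p * (1 - p)
    if (unbiased) h <- h * 2 * n / (2 * n - 1)
  }
  h[n == 0] <- NA_real_
  out <- data.frame(population = rownames(h), stringsAsFactors = FALSE)
  for (loc in colnames(h)) out[[loc]] <- h[, loc]
  out$all_loci <- apply(h, 1L, function(v) mean(v, na.rm = TRUE))
  out
}

#' Hardy-Weinberg scan over all cells
#'
#' Runs [hwe_test()] for every population x locus cell with at least one
#' typed individual. Monomorphic cells are reported with `NA` statistics
#' and excluded from the Bonferroni family size.
#'
#' @param x A `genotype_table`.
#' @param family `"run"` (default): one family of all testable cells in the
#'   scan; `"per-locus"`: a separate family per locus.
#' @param method Passed to [hwe_test()].
#' @return Data frame: `population`, `locus`, `n`, `chi2`, `df`, `p_value`,
#'   `p_adjusted`, `m`, `monomorphic`.
#' @export
hwe_scan <- function(x, family = c("run", "per-locus"),
                     method = c("chisq", "exact")) {
  family <- match.arg(family)
  method <- match.arg(method)
  cm <- .count_matrices(x)
  pops <- rownames(cm$n_II)
  locs <- colnames(cm$n_II)
  grid <- expand.grid(population = pops, locus = locs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    pp <- grid$population[i]; ll <- grid$locus[i]
    cnt <- genotype_counts(cm$n_II[pp, ll], cm$n_ID[pp, ll], cm$n_DD[pp, ll])
    if (cnt$n == 0L) {
      return(data.frame(population = pp, locus = ll, n = 0L,
                        chi2 = NA_real_, df = 1L, p_value = NA_real_,
                        monomorphic = NA, stringsAsFactors = FALSE))
    }
    t <- suppressWarnings(hwe_test(cnt, method = method))
    data.frame(population = pp, locus = ll, n = cnt$n,
               chi2 = t$chi2, df = t$df, p_value = t$p_value,
               monomorphic = t$monomorphic, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  testable <- !is.na(out$p_value)
  out$m <- NA_integer_
  out$p_adjusted <- NA_real_
  if (family == "run") {
    m <- sum(testable)
    out$m[testable] <- m
    out$p_adjusted[testable] <- bonferroni_adjust(out$p_value[testable],
                                                  m = m)
  } else {
    for (ll in locs) {
      sel <- testable & out$locus == ll
      m <- sum(sel)
      if (m > 0L) {
        out$m[sel] <- m
        out$p_adjusted[sel] <- bonferroni_adjust(out$p_value[sel], m = m)
      }
    }
  }
  out[c("population", "locus", "n", "chi2", "df", "p_value",
        "p_adjusted", "m", "monomorphic")]
}
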