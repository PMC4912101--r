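# Data model and tab-separated I/O for biallelic insertion/deletion genotype
# data and for published population x locus allele-frequency tables.

GENOTYPE_CODES <- c("II", "ID", "DD")

# token -> canonical genotype; "+" is the insertion allele, "-" the deletion
.genotype_alias <- c(
  "II" = "II", "ID" = "ID", "DI" = "ID", "DD" = "DD",
  "+/+" = "II", "+/-" = "ID", "-/+" = "ID", "-/-" = "DD"
)

#' Validate a data frame of individual genotype calls
#'
#' Canonicalises genotype tokens (`"+/+"`/`"II"` style aliases), checks that
#' every call references a declared population and locus and that no
#' individual is typed twice at the same locus, and attaches the declared
#' population and locus order as attributes.
#'
#' @param x Data frame with columns `population`, `individual`, `locus`,
#'   `genotype`.
#' @param populations Optional character vector fixing population order;
#'   defaults to first appearance in `x`.
#' @param loci Optional character vector fixing locus order.
#' @param missing_code Token denoting a missing call (dropped from counts,
#'   never imputed). Default `"NA"`.
#' @return A `genotype_table`: the validated data frame with `genotype` as a
#'   factor with levels `II`, `ID`, `DD` (`NA` = missing), and attributes
#'   `populations` and `loci`.
#' @export
as_genotype_table <- function(x, populations = NULL, loci = NULL,
                              missing_code = "NA") {
  if (!is.data.frame(x)) stop("`x` must be a data frame")
  need <- c("population", "individual", "locus", "genotype")
  absent <- setdiff(need, names(x))
  if (length(absent) > 0L) {
    stop("genotype table lacks column(s): ", paste(absent, collapse = ", "))
  }
  x <- as.data.frame(x)[need]
  for (col in c("population", "individual", "locus")) {
    x[[col]] <- as.character(x[[col]])
    if (anyNA(x[[col]]) || any(!nzchar(x[[col]]))) {
      stop("column `", col, "` contains empty values")
    }
  }

  tok <- as.character(x$genotype)
  is_missing <- is.na(tok) | tok == missing_code
  canon <- unname(.genotype_alias[tok])
  bad <- !is_missing & is.na(canon)
  if (any(bad)) {
    stop("unknown genotype token(s) ",
         paste(sQuote(unique(tok[bad])), collapse = ", "),
         " at data row(s) ", paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  canon[is_missing] <- NA_character_

  if (is.null(populations)) populations <- unique(x$population)
  if (is.null(loci)) loci <- unique(x$locus)
  if (anyDuplicated(populations)) stop("duplicated population labels")
  if (anyDuplicated(loci)) stop("duplicated locus labels")
  undecl_pop <- setdiff(unique(x$population), populations)
  if (length(undecl_pop) > 0L) {
    stop("undeclared population(s): ", paste(undecl_pop, collapse = ", "))
  }
  undecl_loc <- setdiff(unique(x$locus), loci)
  if (length(undecl_loc) > 0L) {
    stop("undeclared locus/loci: ", paste(undecl_loc, collapse = ", "))
  }

  key <- paste(x$population, x$individual, x$locus, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1L]
    stop("duplicate call for individual ", sQuote(x$individual[dup]),
         " at locus ", sQuote(x$locus[dup]), " (data row ", dup, ")")
  }

  x$population <- factor(x$population, levels = populations)
  x$locus <- factor(x$locus, levels = loci)
  x$genotype <- factor(canon, levels = GENOTYPE_CODES)
  structure(x,
            populations = populations, loci = loci,
            class = c("genotype_table", "data.frame"))
}

#' Read a genotype table from TSV
#'
#' Expects a one-line header with columns `population`, `individual`,
#' `locus`, `genotype`; genotype tokens may be `"II"`/`"ID"`/`"DD"` or
#' `"+/+"`/`"+/-"`/`"-/-"` interchangeably. Population and locus order is
#' canonicalised by sorting, so downstream outputs do not depend on the
#' row order of the file; use [as_genotype_table()] with explicit
#' `populations`/`loci` to impose a display order.
#'
#' @inheritParams as_genotype_table
#' @param path Path to a tab-separated file.
#' @return A `genotype_table` (see [as_genotype_table()]).
#' @export
read_genotype_table <- function(path, missing_code = "NA") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0), quote = "",
                           comment.char = "")
  withCallingHandlers(
    as_genotype_table(raw,
                      populations = sort(unique(as.character(raw$population)),
                                         method = "radix"),
                      loci = sort(unique(as.character(raw$locus)),
                                  method = "radix"),
                      missing_code = missing_code),
    error = function(e) {
      stop("while reading ", path, " (data row r is file line r + 1): ",
           conditionMessage(e), call. = FALSE)
    }
  )
}

#' Write a genotype table to TSV
#'
#' @param x A `genotype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path) {
  stopifnot(inherits(x, "genotype_table"))
  out <- data.frame(population = as.character(x$population),
                    individual = x$individual,
                    locus = as.character(x$locus),
                    genotype = as.character(x$genotype),
                    stringsAsFactors = FALSE)
  out$genotype[is.na(out$genotype)] <- "NA"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Genotype counts for one population x locus cell
#'
#' @param n_II,n_ID,n_DD Non-negative counts of insertion homozygotes,
#'   heterozygotes and deletion homozygotes.
#' @return A `genotype_counts` object; `$n` is the typed sample size
#'   `n_II + n_ID + n_DD`.
#' @export
genotype_counts <- function(n_II, n_ID, n_DD) {
  cnt <- c(n_II, n_ID, n_DD)
  if (length(cnt) != 3L || anyNA(cnt) || any(cnt < 0) ||
      any(cnt != round(cnt))) {
    stop("counts must be three non-negative integers")
  }
  structure(list(n_II = as.integer(n_II), n_ID = as.integer(n_ID),
                 n_DD = as.integer(n_DD),
                 n = as.integer(n_II + n_ID + n_DD)),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("genotype counts: II=%d ID=%d DD=%d (n=%d)\n",
              x$n_II, x$n_ID, x$n_DD, x$n))
  invisible(x)
}

#' Tabulate genotype counts for one population x locus cell
#'
#' Missing calls are excluded, so `$n` is the typed sample size for the cell
#' and may be smaller than the number of sampled individuals.
#'
#' @param x A `genotype_table`.
#' @param population,locus Declared labels.
#' @return A [genotype_counts()] object.
#' @export
tabulate_counts <- function(x, population, locus) {
  stopifnot(inherits(x, "genotype_table"))
  if (!population %in% attr(x, "populations")) {
    stop("unknown population: ", population)
  }
  if (!locus %in% attr(x, "loci")) stop("unknown locus: ", locus)
  g <- x$genotype[x$population == population & x$locus == locus]
  tab <- table(g)
  genotype_counts(tab[["II"]], tab[["ID"]], tab[["DD"]])
}

#' Population x locus insertion-allele frequency matrix
#'
#' Stores the frequency of the insertion (+) allele only; the deletion
#' frequency is always `1 - p`, never stored, which keeps the two series
#' consistent by construction.
#'
#' @param p Numeric matrix, populations in rows, loci in columns, entries in
#'   `[0, 1]` (`NA` = untyped cell). Row and column names are required and
#'   must be unique.
#' @param n Optional matrix of diploid sample sizes, same shape as `p`
#'   (per-locus `n` because published typed sample sizes can differ by
#'   locus).
#' @return A `frequency_matrix` object.
#' @export
frequency_matrix <- function(p, n = NULL) {
  p <- as.matrix(p)
  if (!is.numeric(p)) stop("`p` must be numeric")
  if (is.null(rownames(p)) || is.null(colnames(p))) {
    stop("`p` needs population row names and locus column names")
  }
  if (anyDuplicated(rownames(p)) || anyDuplicated(colnames(p))) {
    stop("population and locus labels must be unique")
  }
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop("allele frequencies outside [0, 1]: ",
         paste(signif(p[bad], 6), collapse = ", "))
  }
  if (!is.null(n)) {
    n <- as.matrix(n)
    if (!identical(dim(n), dim(p))) stop("`n` must match the shape of `p`")
    if (any(!is.na(n) & (n < 0 | n != round(n)))) {
      stop("`n` must contain non-negative integers")
    }
    dimnames(n) <- dimnames(p)
  }
  structure(p, n = n, class = c("frequency_matrix", "matrix"))
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat("insertion-allele frequency matrix: ",
      nrow(x), " populations x ", ncol(x), " loci\n", sep = "")
  print(unclass(`attr<-`(x, "n", NULL)), ...)
  invisible(x)
}

#' Write a frequency matrix to TSV
#'
#' One row per population; first column `population`, one column per locus,
#' and (when sample sizes are stored) paired `n_<locus>` columns.
#'
#' @param m A [frequency_matrix()].
#' @param path Output path.
#' @param digits Decimal places for frequencies (default 4, the precision of
#'   most published tables); `NA` writes full double precision so that
#'   read-after-write is bit-exact.
#' @return `path`, invisibly.
#' @export
write_frequency_matrix <- function(m, path, digits = 4) {
  stopifnot(inherits(m, "frequency_matrix"))
  fmt <- function(v) {
    out <- if (is.na(digits)) sprintf("%.17g", v)
           else formatC(v, format = "f", digits = digits)
    out[is.na(v)] <- "NA"
    out
  }
  df <- data.frame(population = rownames(m), stringsAsFactors = FALSE)
  for (loc in colnames(m)) df[[loc]] <- fmt(m[, loc])
  n <- attr(m, "n")
  if (!is.null(n)) {
    for (loc in colnames(m)) {
      v <- as.character(n[, loc])
      v[is.na(v)] <- "NA"
      df[[paste0("n_", loc)]] <- v
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a frequency matrix from TSV
#'
#' @param path Path to a file written in the layout of
#'   [write_frequency_matrix()].
#' @return A [frequency_matrix()].
#' @export
read_frequency_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "",
                          comment.char = "")
  if (names(df)[1L] != "population") {
    stop("first column must be `population`: ", path)
  }
  cols <- names(df)[-1L]
  n_cols <- grep("^n_", cols, value = TRUE)
  loci <- setdiff(cols, n_cols)
  if (length(loci) == 0L) stop("no locus columns in ", path)
  p <- as.matrix(df[loci])
  storage.mode(p) <- "double"
  rownames(p) <- as.character(df$population)
  n <- NULL
  if (length(n_cols) > 0L) {
    if (!setequal(sub("^n_", "", n_cols), loci)) {
      stop("n_<locus> columns do not match locus columns in ", path)
    }
    n <- as.matrix(df[paste0("n_", loci)])
    storage.mode(n) <- "double"
    colnames(n) <- loci
    rownames(n) <- rownames(p)
  }
  frequency_matrix(p, n = n)
}
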