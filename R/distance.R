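# Genetic distances between populations and neighbor-joining trees.

.dist_methods <- c("nei1972", "da1983")

# frequencies of a pair over shared typed loci
.shared_freqs <- function(m, pop_a, pop_b) {
  for (pp in c(pop_a, pop_b)) {
    if (!pp %in% rownames(m)) stop("unknown population: ", pp)
  }
  pa <- m[pop_a, ]
  pb <- m[pop_b, ]
  keep <- !is.na(pa) & !is.na(pb)
  if (!any(keep)) stop("no shared typed loci for ", pop_a, " / ", pop_b)
  list(pa = pa[keep], pb = pb[keep])
}

#' Genetic distance between two populations
#'
#' From insertion-allele frequencies over the loci typed in both
#' populations:
#' * `"nei1972"` (default), Nei's standard genetic distance
#'   `D = -ln( Jab / sqrt(Ja Jb) )` where, per biallelic locus,
#'   `Jab = pa pb + qa qb`, `Ja = pa^2 + qa^2`, `Jb = pb^2 + qb^2`, each
#'   averaged over loci before the ratio;
#' * `"da1983"`, `Da = 1 - mean_loci( sqrt(pa pb) + sqrt(qa qb) )`.
#'
#' @param m A [frequency_matrix()].
#' @param pop_a,pop_b Population labels.
#' @param method `"nei1972"` or `"da1983"`.
#' @return Non-negative distance (0 for identical frequency profiles).
#' @export
nei_distance <- function(m, pop_a, pop_b, method = c("nei1972", "da1983")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "frequency_matrix"))
  f <- .shared_freqs(m, pop_a, pop_b)
  pa <- f$pa; qa <- 1 - pa
  pb <- f$pb; qb <- 1 - pb
  if (method == "nei1972") {
    jab <- mean(pa * pb + qa * qb)
    ja <- mean(pa^2 + qa^2)
    jb <- mean(pb^2 + qb^2)
    if (jab <= 0) {
      stop("infinite distance: zero shared gene identity for ",
           pop_a, " / ", pop_b)
    }
    # clamp tiny negative rounding when profiles are identical
    max(0, -log(jab / sqrt(ja * jb)))
  } else {
    1 - mean(sqrt(pa * pb) + sqrt(qa * qb))
  }
}

#' Pairwise genetic distance matrix
#'
#' @inheritParams nei_distance
#' @return Symmetric matrix with zero diagonal, labelled by population.
#' @export
genetic_distance <- function(m, method = c("nei1972", "da1983")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "frequency_matrix"))
  pops <- rownames(m)
  d <- matrix(0, nrow(m), nrow(m), dimnames = list(pops, pops))
  if (nrow(m) > 1L) {
    for (i in seq_len(nrow(m) - 1L)) {
      for (j in seq.int(i + 1L, nrow(m))) {
        d[i, j] <- d[j, i] <- nei_distance(m, pops[i], pops[j],
                                           method = method)
      }
    }
  }
  attr(d, "method") <- method
  d
}

.check_dist <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) rownames(d) <- colnames(d)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (anyNA(d) || any(!is.finite(d))) stop("non-finite distances")
  if (any(d < 0)) stop("negative distances")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal not zero")
  d
}

#' Neighbor-joining tree
#'
#' Standard agglomerative neighbor joining: repeatedly join the pair
#' `(i, j)` minimising `Q(i, j) = (r - 2) d(i, j) - sum_k d(i, k) -
#' sum_k d(j, k)` (`r` = current number of nodes), with rate-corrected
#' branch lengths; exact ties broken by the lexicographically smallest
#' label-index pair so runs are deterministic. On an additive matrix the
#' generating topology and branch lengths are recovered exactly.
#'
#' Negative branch lengths (possible on non-additive input) are clamped to
#' zero with the deficit moved onto the sibling branch, preserving the
#' joined pair's distance, and a warning is raised.
#'
#' @param dm Symmetric distance matrix with labels (e.g. from
#'   [genetic_distance()]), at least 3 taxa.
#' @return An unrooted `ape::phylo` tree (the basal node is trifurcating).
#' @export
neighbor_joining <- function(dm) {
  d <- .check_dist(dm)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labs <- gsub(" ", "_", rownames(d))   # Newick cannot carry spaces
  if (any(grepl("[(),:;\\[\\]']", labs))) {
    stop("taxon labels contain Newick-reserved characters")
  }
  if (anyDuplicated(labs)) stop("duplicate taxon labels")
  frag <- labs                 # Newick fragment per active node
  clamped <- FALSE
  fmt <- function(x) sprintf("%.15g", x)

  clamp <- function(li, lj, dij) {
    # keep li + lj = dij while forcing both non-negative
    if (li < 0) { lj <- lj + li; li <- 0; clamped <<- TRUE }
    if (lj < 0) { li <- li + lj; lj <- 0; clamped <<- TRUE }
    if (li < 0) { li <- 0; clamped <<- TRUE }   # dij == 0 edge case
    c(li, lj)
  }

  while (nrow(d) > 3L) {
    r <- nrow(d)
    rs <- rowSums(d)
    q <- (r - 2) * d - outer(rs, rs, "+")
    diag(q) <- Inf
    q[lower.tri(q)] <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- best[1L, 1L]; j <- best[1L, 2L]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    l2 <- clamp(li, lj, d[i, j])
    new_frag <- paste0("(", frag[i], ":", fmt(l2[1L]), ",",
                       frag[j], ":", fmt(l2[2L]), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    rownames(d2) <- colnames(d2) <- c(rownames(d)[keep],
                                      paste0("#", r))  # internal placeholder
    d <- d2
  }

  # three-point formulas for the final trifurcation
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (any(c(la, lb, lc) < 0)) {
    la <- max(0, la); lb <- max(0, lb); lc <- max(0, lc)
    clamped <- TRUE
  }
  if (clamped) {
    warning("negative branch length(s) clamped to zero ",
            "(input distances not additive)")
  }
  newick <- paste0("(", frag[1L], ":", fmt(la), ",",
                   frag[2L], ":", fmt(lb), ",",
                   frag[3L], ":", fmt(lc), ");")
  ape::read.tree(text = newick)
}

#' Write / read a tree in Newick format
#'
#' Thin wrappers over [ape::write.tree()] and [ape::read.tree()] so the
#' pipeline's tree artifacts round-trip through plain text.
#'
#' @param tree An `ape::phylo` tree.
#' @param path File path.
#' @return `write_newick()`: `path` invisibly; `read_newick()`: a `phylo`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ape::read.tree(path)
}

#' Path length between two leaves
#'
#' Sum of branch lengths along the unique leaf-to-leaf path.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param leaf_a,leaf_b Tip labels.
#' @return Path length.
#' @export
path_distance <- function(tree, leaf_a, leaf_b) {
  stopifnot(inherits(tree, "phylo"))
  for (lf in c(leaf_a, leaf_b)) {
    if (!lf %in% tree$tip.label) stop("unknown leaf: ", lf)
  }
  cp <- ape::cophenetic.phylo(tree)
  cp[leaf_a, leaf_b]
}
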