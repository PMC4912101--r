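# Shared fixtures: random genotype tables, random additive distance
# matrices, and a brute-force tally oracle used against the vectorised
# counting code.

rand_genotype_table <- function(K = 3, L = 4, n = 20, missing_rate = 0,
                                seed = 1) {
  set.seed(seed)
  pops <- sprintf("pop%02d", seq_len(K))
  locs <- sprintf("loc%02d", seq_len(L))
  df <- expand.grid(individual = sprintf("i%03d", seq_len(n)),
                    population = pops, locus = locs,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$individual <- paste(df$population, df$individual, sep = "_")
  df$genotype <- sample(c("II", "ID", "DD"), nrow(df), replace = TRUE)
  if (missing_rate > 0) {
    df$genotype[runif(nrow(df)) < missing_rate] <- "NA"
  }
  as_genotype_table(df[c("population", "individual", "locus", "genotype")],
                    populations = pops, loci = locs)
}

# literal record-list tally, independent of table()/factor machinery
brute_tally <- function(gt, population, locus) {
  g <- as.character(gt$genotype)[as.character(gt$population) == population &
                                 as.character(gt$locus) == locus]
  g <- g[!is.na(g)]
  c(n_II = sum(g == "II"), n_ID = sum(g == "ID"), n_DD = sum(g == "DD"))
}

# additive distance matrix from a random tree, plus the tree itself
rand_additive <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, br = function(k) runif(k, 0.1, 2))
  tr <- ape::unroot(tr)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

rand_frequency_matrix <- function(K = 12, L = 7, seed = 1) {
  set.seed(seed)
  p <- matrix(runif(K * L), K, L,
              dimnames = list(sprintf("pop%02d", seq_len(K)),
                              sprintf("loc%02d", seq_len(L))))
  frequency_matrix(p)
}
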