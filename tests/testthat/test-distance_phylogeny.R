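test_that("identical frequency profiles are at distance zero", {
  p <- rbind(A = c(0.3, 0.7, 0.5), B = c(0.3, 0.7, 0.5))
  colnames(p) <- c("l1", "l2", "l3")
  m <- frequency_matrix(p)
  expect_equal(nei_distance(m, "A", "B", "nei1972"), 0)
  expect_equal(nei_distance(m, "A", "B", "da1983"), 0)
})

test_that("a fixed difference saturates Da at 1", {
  m <- frequency_matrix(matrix(c(1, 0), 2, 1,
                               dimnames = list(c("A", "B"), "l1")))
  expect_equal(nei_distance(m, "A", "B", "da1983"), 1)
  expect_error(nei_distance(m, "A", "B", "nei1972"), "infinite distance")
})

test_that("distances match a step-by-step oracle on random pairs", {
  set.seed(51)
  for (i in 1:20) {
    L <- sample(2:8, 1)
    pa <- runif(L, 0.05, 0.95)
    pb <- runif(L, 0.05, 0.95)
    pm <- rbind(A = pa, B = pb)
    colnames(pm) <- paste0("l", seq_len(L))
    m <- frequency_matrix(pm)
    # spreadsheet-style oracle, term by term
    jab <- ja <- jb <- numeric(L)
    for (l in seq_len(L)) {
      jab[l] <- pa[l] * pb[l] + (1 - pa[l]) * (1 - pb[l])
      ja[l] <- pa[l]^2 + (1 - pa[l])^2
      jb[l] <- pb[l]^2 + (1 - pb[l])^2
    }
    d72 <- -log(mean(jab) / sqrt(mean(ja) * mean(jb)))
    da <- 1 - mean(sqrt(pa * pb) + sqrt((1 - pa) * (1 - pb)))
    expect_equal(nei_distance(m, "A", "B", "nei1972"), d72)
    expect_equal(nei_distance(m, "B", "A", "nei1972"), d72)  # symmetry
    expect_equal(nei_distance(m, "A", "B", "da1983"), da)
  }
})

test_that("genetic_distance builds a valid symmetric matrix", {
  m <- rand_frequency_matrix(K = 6, L = 7, seed = 2)
  d <- genetic_distance(m)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_true(all(d >= 0))
  expect_equal(d["pop01", "pop02"], nei_distance(m, "pop01", "pop02"))
})

test_that("NJ recovers the 4-taxon additive worked example exactly", {
  # tree (A:1, B:2) -- internal 1 -- (C:3, D:4)
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_setequal(tr$tip.label, LETTERS[1:4])
  # split AB|CD: path A-B avoids the internal edge
  expect_equal(path_distance(tr, "A", "B"), 3)
  expect_equal(path_distance(tr, "C", "D"), 7)
  expect_equal(path_distance(tr, "A", "C"), 5)
  expect_equal(path_distance(tr, "B", "D"), 7)
  # pendant branch lengths are exactly 1, 2, 3, 4
  pend <- tr$edge.length[tr$edge[, 2] <= 4]
  names(pend) <- tr$tip.label[tr$edge[tr$edge[, 2] <= 4, 2]]
  expect_equal(pend[LETTERS[1:4]], c(A = 1, B = 2, C = 3, D = 4))
  # internal edge 1
  expect_equal(sum(tr$edge.length), 11)
})

test_that("3-taxon branch lengths solve the pairwise-sum equations", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(d)
  expect_equal(path_distance(tr, "x", "y"), 2)
  expect_equal(path_distance(tr, "x", "z"), 3)
  expect_equal(path_distance(tr, "y", "z"), 5)
})

test_that("NJ is consistent on additive matrices from random trees", {
  for (seed in 1:10) {
    n <- sample(5:10, 1)
    ref <- rand_additive(n, seed = seed)
    tr <- neighbor_joining(ref$d)
    expect_equal(ape::dist.topo(tr, ref$tree), 0,
                 ignore_attr = TRUE)
    cp <- ape::cophenetic.phylo(tr)[rownames(ref$d), colnames(ref$d)]
    expect_lt(max(abs(cp - ref$d)), 1e-9)
  }
})

test_that("NJ agrees with an independent implementation", {
  set.seed(61)
  m <- rand_frequency_matrix(K = 8, L = 20, seed = 61)
  d <- genetic_distance(m)
  mine <- neighbor_joining(d)
  ref <- ape::nj(as.dist(d))
  expect_equal(ape::dist.topo(mine, ape::unroot(ref)), 0,
               ignore_attr = TRUE)
  cp_mine <- ape::cophenetic.phylo(mine)
  cp_ref <- ape::cophenetic.phylo(ref)[rownames(cp_mine), colnames(cp_mine)]
  expect_equal(cp_mine, cp_ref, tolerance = 1e-8)
})

test_that("permuted input yields an isomorphic tree", {
  ref <- rand_additive(7, seed = 77)
  perm <- sample(7)
  d2 <- ref$d[perm, perm]
  t1 <- neighbor_joining(ref$d)
  t2 <- neighbor_joining(d2)
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
  cp1 <- ape::cophenetic.phylo(t1)
  cp2 <- ape::cophenetic.phylo(t2)[rownames(cp1), colnames(cp1)]
  expect_equal(cp1, cp2, tolerance = 1e-9)
})

test_that("tree structure is unrooted binary over the input labels", {
  for (n in c(4, 6, 9)) {
    ref <- rand_additive(n, seed = n)
    tr <- neighbor_joining(ref$d)
    expect_setequal(tr$tip.label, rownames(ref$d))
    expect_equal(tr$Nnode, n - 2)          # unrooted binary internal count
    expect_false(ape::is.rooted(tr))
  }
})

test_that("Newick export round-trips isomorphically", {
  ref <- rand_additive(6, seed = 99)
  tr <- neighbor_joining(ref$d)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- read_newick(path)
  expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(back)[rownames(ref$d), colnames(ref$d)],
               ref$d, tolerance = 1e-8)
  expect_error(path_distance(tr, "no_such_leaf", tr$tip.label[1]),
               "unknown leaf")
})

test_that("star-like equal distances give equal total length whatever the join order", {
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  base <- neighbor_joining(d)
  total <- sum(base$edge.length)
  # all relabelings = all join orders on 4 taxa
  perms <- list(c(1, 2, 3, 4), c(2, 3, 4, 1), c(4, 3, 2, 1), c(3, 1, 4, 2))
  for (pp in perms) {
    tr <- neighbor_joining(d[pp, pp])
    expect_equal(sum(tr$edge.length), total)
  }
})

test_that("invalid distance matrices are rejected", {
  d <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  expect_error(neighbor_joining(d), "symmetric|3 taxa")
  d3 <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(d3), "negative")
})
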