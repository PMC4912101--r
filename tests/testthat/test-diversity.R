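test_that("allele frequency by direct counting matches hand values", {
  expect_equal(allele_frequency(genotype_counts(50, 0, 0))$p, 1.0)
  expect_equal(allele_frequency(genotype_counts(10, 20, 20))$p, 0.40)
  # symmetric counts pin p at 1/2 for any k, m
  for (km in list(c(1, 1), c(7, 3), c(20, 0))) {
    cnt <- genotype_counts(km[1], km[2], km[1])
    expect_equal(allele_frequency(cnt)$p, 0.5)
  }
  expect_error(allele_frequency(genotype_counts(0, 0, 0)), "n = 0")
})

test_that("allele frequency equals brute-force allele-list expansion", {
  set.seed(11)
  for (i in 1:20) {
    cnt <- genotype_counts(rpois(1, 20), rpois(1, 20), rpois(1, 20) + 1)
    alleles <- c(rep(1, 2 * cnt$n_II), rep(c(1, 0), cnt$n_ID),
                 rep(0, 2 * cnt$n_DD))
    expect_equal(allele_frequency(cnt)$p, mean(alleles))
  }
})

test_that("expected heterozygosity is 2pq, symmetric, maximal at 1/2", {
  expect_equal(expected_heterozygosity(0.5), 0.5)
  expect_equal(expected_heterozygosity(0), 0)
  expect_equal(expected_heterozygosity(1), 0)
  p <- seq(0, 1, by = 0.05)
  expect_equal(expected_heterozygosity(p), expected_heterozygosity(1 - p))
  expect_true(all(expected_heterozygosity(p) <= 0.5 + 1e-15))
  # explicit q for independently rounded published frequencies
  expect_equal(expected_heterozygosity(0.7959, 0.2040), 2 * 0.7959 * 0.2040)
  # small-sample factor
  expect_equal(expected_heterozygosity(0.5, n = 10, unbiased = TRUE),
               0.5 * 20 / 19)
})

test_that("observed heterozygosity is the heterozygote fraction", {
  expect_equal(observed_heterozygosity(genotype_counts(1, 2, 1)), 0.5)
  expect_equal(observed_heterozygosity(genotype_counts(0, 0, 10)), 0)
  set.seed(5)
  gt <- rand_genotype_table(K = 1, L = 1, n = 200, seed = 5)
  cnt <- tabulate_counts(gt, "pop01", "loc01")
  ref <- brute_tally(gt, "pop01", "loc01")
  expect_equal(observed_heterozygosity(cnt),
               ref[["n_ID"]] / sum(ref))
})

test_that("average heterozygosity is the unweighted mean over loci", {
  kani <- c(0.5918, 0.3265, 0.2244, 0.1224, 0.1428, 0.1020, 0.5306)
  expect_equal(average_heterozygosity(kani), mean(kani))
  expect_equal(average_heterozygosity(0.37), 0.37)
  expect_error(average_heterozygosity(numeric(0)), "no locus values")
})

test_that("HWE chi-squared matches hand computation and an oracle", {
  # exact HWE proportions: statistic 0, p 1
  r <- hwe_test(genotype_counts(25, 50, 25))
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)
  # heterozygote deficit (30, 40, 30): p-hat 1/2, expected (25, 50, 25)
  r <- hwe_test(genotype_counts(30, 40, 30))
  expect_equal(r$chi2, 4)
  expect_equal(r$df, 1L)
  expect_equal(r$p_value, pchisq(4, 1, lower.tail = FALSE))
  # independent oracle: chisq.test's raw statistic at the fitted proportions
  set.seed(21)
  for (i in 1:20) {
    cnt <- genotype_counts(rpois(1, 30) + 1, rpois(1, 30) + 1,
                           rpois(1, 30) + 1)
    f <- allele_frequency(cnt)
    oracle <- suppressWarnings(chisq.test(
      c(cnt$n_II, cnt$n_ID, cnt$n_DD),
      p = c(f$p^2, 2 * f$p * f$q, f$q^2)))$statistic
    expect_equal(hwe_test(cnt)$chi2, unname(oracle))
  }
})

test_that("monomorphic cells are flagged and skipped, not tested", {
  expect_warning(r <- hwe_test(genotype_counts(30, 0, 0)), "monomorphic")
  expect_true(r$monomorphic)
  expect_true(is.na(r$p_value))
})

test_that("exact HWE test agrees with full enumeration at tiny n", {
  # enumeration oracle: all genotype configurations with the same allele
  # counts, probability proportional to multinomial coefficient * 2^het
  exact_oracle <- function(n_II, n_ID, n_DD) {
    n <- n_II + n_ID + n_DD
    nA <- 2 * n_II + n_ID
    ks <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
    w <- vapply(ks, function(k) {
      x11 <- (nA - k) / 2; x22 <- n - x11 - k
      exp(lfactorial(n) - lfactorial(x11) - lfactorial(k) -
            lfactorial(x22) + k * log(2))
    }, numeric(1))
    pr <- w / sum(w)
    sum(pr[pr <= pr[ks == n_ID] + 1e-12])
  }
  for (cnt in list(c(3, 2, 3), c(5, 0, 5), c(1, 8, 1), c(4, 4, 2))) {
    got <- hwe_test(genotype_counts(cnt[1], cnt[2], cnt[3]),
                    method = "exact")$p_value
    expect_equal(got, exact_oracle(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-10)
  }
})

test_that("Bonferroni correction multiplies and clamps", {
  expect_equal(bonferroni_adjust(0.01), 0.01)
  expect_equal(bonferroni_adjust(c(0.01, 0.5)), c(0.02, 1.0))
  expect_equal(bonferroni_adjust(0.0005, m = 84), 0.042)
  # full-vector family defers to stats::p.adjust
  p <- runif(10)
  expect_equal(bonferroni_adjust(p), p.adjust(p, "bonferroni"))
})

test_that("cell-wise frequency matrix matches per-cell direct counting", {
  gt <- rand_genotype_table(K = 5, L = 4, n = 40, missing_rate = 0.05,
                            seed = 9)
  m <- count_allele_frequencies(gt)
  for (pp in sample(attr(gt, "populations"), 3)) {
    for (ll in sample(attr(gt, "loci"), 2)) {
      cnt <- tabulate_counts(gt, pp, ll)
      expect_equal(m[pp, ll], allele_frequency(cnt)$p)
      expect_equal(attr(m, "n")[pp, ll], cnt$n)
    }
  }
})

test_that("heterozygosity table reproduces per-cell statistics", {
  gt <- rand_genotype_table(K = 4, L = 3, n = 30, seed = 13)
  obs <- heterozygosity_table(gt, series = "observed")
  exp_ <- heterozygosity_table(gt, series = "expected")
  cnt <- tabulate_counts(gt, "pop02", "loc03")
  expect_equal(obs[obs$population == "pop02", "loc03"],
               observed_heterozygosity(cnt))
  expect_equal(exp_[exp_$population == "pop02", "loc03"],
               expected_heterozygosity(allele_frequency(cnt)))
  locs <- attr(gt, "loci")
  expect_equal(obs$all_loci,
               apply(as.matrix(obs[locs]), 1, mean))
})

test_that("HWE scan uses the requested Bonferroni family", {
  gt <- rand_genotype_table(K = 3, L = 4, n = 50, seed = 17)
  run <- hwe_scan(gt, family = "run")
  testable <- !is.na(run$p_value)
  expect_equal(unique(run$m[testable]), sum(testable))
  expect_equal(run$p_adjusted[testable],
               pmin(1, run$p_value[testable] * sum(testable)))
  per <- hwe_scan(gt, family = "per-locus")
  for (ll in unique(per$locus)) {
    sel <- per$locus == ll & !is.na(per$p_value)
    expect_equal(unique(per$m[sel]), sum(sel))
  }
})

test_that("mean observed heterozygosity converges to 2pq under HWE", {
  set.seed(31)
  p <- 0.3
  gt <- simulate_genotypes(matrix(p, 1, 1), n = 20000)
  cnt <- tabulate_counts(gt, "pop01", "locus01")
  expect_equal(observed_heterozygosity(cnt), 2 * p * (1 - p),
               tolerance = 0.02)
})
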