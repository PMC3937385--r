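test_that("theta hits its structural limits", {
  # two populations fixed for different alleles at every locus: theta = 1
  d <- quick_dataset(list(A = list(matrix(101L, 5, 2), matrix(103L, 5, 2)),
                          B = list(matrix(102L, 5, 2), matrix(104L, 5, 2))))
  f <- pairwise_fst(d)
  expect_equal(f$values[1, 2], 1)
  # a population compared with a copy of itself: theta <= 0 (small negative
  # values are admissible for the estimator)
  base <- random_dataset(n_pops = 1, n_ind = 10, n_loci = 4, seed = 2)
  dup <- quick_dataset(list(
    A = lapply(1:4, function(l) cbind(base$a1[, l], base$a2[, l])),
    B = lapply(1:4, function(l) cbind(base$a1[, l], base$a2[, l]))))
  expect_lte(pairwise_fst(dup)$values[1, 2], 0)
})

test_that("theta equals the brute-force variance-component oracle to 1e-12", {
  for (seed in 1:50) {
    d <- random_dataset(n_pops = 2, n_ind = 6, n_loci = 3,
                        n_alleles = sample(2:5, 1), seed = seed)
    # sprinkle missing calls to exercise unequal sample sizes
    if (seed %% 3 == 0) {
      d$a1[1, 1] <- NA_integer_; d$a2[1, 1] <- NA_integer_
    }
    expect_equal(pairwise_fst(d)$values[1, 2], oracle_theta(d),
                 tolerance = 1e-12)
  }
})

test_that("theta is invariant under allele relabeling and population order", {
  d <- random_dataset(n_pops = 3, n_ind = 8, n_loci = 3, seed = 13)
  f1 <- pairwise_fst(d)
  relab <- d; relab$a1 <- d$a1 * 2L + 1L; relab$a2 <- d$a2 * 2L + 1L
  f2 <- pairwise_fst(relab)
  expect_equal(f1$values, f2$values)
  rev_rows <- rev(seq_len(nrow(d$individuals)))
  drev <- msatdem:::subset_dataset(d, rows = rev_rows)
  f3 <- pairwise_fst(drev)
  expect_equal(f3$values[f1$populations, f1$populations], f1$values,
               ignore_attr = TRUE)
})

test_that("permutation test of theta is seeded and exact in the fixed case", {
  # pair fixed for different alleles, 999 permutations: no permutation can
  # reach the observed theta = 1 (the all-or-nothing split is essentially
  # unreachable), so p = 1/1000
  d <- quick_dataset(list(A = list(matrix(101L, 10, 2), matrix(103L, 10, 2)),
                          B = list(matrix(102L, 10, 2), matrix(104L, 10, 2))))
  f <- fst_significance(d, permutations = 999, alpha = 0.001, seed = 17)
  expect_equal(f$p_values[1, 2], 1 / 1000)
  expect_true(attr(f$p_values, "significant")[1, 2])
  # same seed, same matrices
  d2 <- random_dataset(n_pops = 2, n_ind = 8, n_loci = 3, seed = 5)
  a <- fst_significance(d2, permutations = 99, seed = 3)
  b <- fst_significance(d2, permutations = 99, seed = 3)
  expect_identical(a$p_values, b$p_values)
})

test_that("panmictic samples are not declared significant at 0.001", {
  # two samples from one panmictic population: the test should essentially
  # never fire at the 0.001 level
  fires <- 0
  for (r in 1:10) {
    d <- hwe_dataset(c(0.4, 0.3, 0.3), n = 40, n_loci = 5, seed = 100 + r)
    d$individuals$population <- rep(c("A", "B"), each = 20)
    f <- fst_significance(d, permutations = 200, alpha = 0.001, seed = r)
    fires <- fires + attr(f$p_values, "significant")[1, 2]
  }
  expect_equal(fires, 0)
})

test_that("D_est matches the hand-formula oracle and its limits", {
  # p1 = (.5,.5,0,0), p2 = (0,0,.5,.5), n = 20 per population: disjoint,
  # internally polymorphic; the Nei-Chesser estimator gives exactly 1
  hand <- oracle_dest_locus(c(20, 20, 0, 0), c(0, 0, 20, 20))
  expect_equal(hand, 1)
  g1 <- matrix(c(rep(101L, 20), rep(102L, 20)), 20, 2)  # all AB
  g2 <- matrix(c(rep(103L, 20), rep(104L, 20)), 20, 2)
  d <- quick_dataset(list(A = list(g1), B = list(g2)))
  dest <- pairwise_dest(d, bootstrap = 0)
  expect_equal(dest$values[1, 2], 1)
  # an asymmetric case against the independently transcribed estimator
  c1 <- c(12, 5, 3, 0); c2 <- c(2, 9, 1, 8)
  hand2 <- oracle_dest_locus(c1, c2)
  mk <- function(cnt) {
    copies <- rep(100L + seq_along(cnt), cnt)
    matrix(copies, length(copies) / 2, 2)
  }
  d2 <- quick_dataset(list(A = list(mk(c1)), B = list(mk(c2))))
  expect_equal(pairwise_dest(d2, bootstrap = 0)$values[1, 2], hand2,
               tolerance = 1e-12)
  # identical allele frequencies at large n: D_est ~ 0
  g <- matrix(sample(c(101L, 102L, 103L), 800, TRUE), 400, 2)
  d3 <- quick_dataset(list(A = list(g), B = list(g)))
  expect_lt(abs(pairwise_dest(d3, bootstrap = 0)$values[1, 2]), 0.02)
})

test_that("bootstrap intervals are seeded and bracket the point estimate", {
  d <- random_dataset(n_pops = 2, n_ind = 12, n_loci = 4, seed = 19)
  a <- pairwise_dest(d, bootstrap = 100, seed = 7)
  b <- pairwise_dest(d, bootstrap = 100, seed = 7)
  expect_identical(a$ci_low, b$ci_low)
  expect_lte(a$ci_low[1, 2], a$ci_high[1, 2])
})

test_that("harmonic-mean D_est never exceeds the arithmetic mean", {
  for (seed in 1:10) {
    d <- island_dataset(F = 0.3, n_pops = 2, n_ind = 15, n_loci = 6,
                        seed = seed)
    per_locus <- vapply(seq_len(6), function(l)
      msatdem:::dest_locus(msatdem:::gene_copies(d, l, msatdem:::pop_rows(d, "A")),
                           msatdem:::gene_copies(d, l, msatdem:::pop_rows(d, "B"))),
      0)
    if (all(per_locus > 0, na.rm = TRUE)) {
      hm <- pairwise_dest(d, bootstrap = 0)$values[1, 2]
      expect_lte(hm, mean(per_locus, na.rm = TRUE) + 1e-12)
    }
  }
})

test_that("theta decreases with simulated migration in the island model", {
  # F = 1/(1 + 4Nm): three migration levels, ten replicates each
  mean_theta <- vapply(c(0.4, 0.15, 0.05), function(F) {
    mean(vapply(1:10, function(r) {
      d <- island_dataset(F = F, n_pops = 2, n_ind = 20, n_loci = 8,
                          seed = 1000 * F + r)
      pairwise_fst(d)$values[1, 2]
    }, 0))
  }, 0)
  expect_true(all(diff(mean_theta) < 0))
})

test_that("matrix correlation follows the textbook formula", {
  set.seed(31)
  v <- matrix(0, 4, 4)
  v[lower.tri(v)] <- runif(6)
  v <- v + t(v); diag(v) <- NA
  m1 <- pairwise_matrix(letters[1:4], v)
  expect_equal(matrix_correlation(m1, m1), 1)
  m2 <- pairwise_matrix(letters[1:4], 2.5 * v + 0.1)
  expect_equal(matrix_correlation(m1, m2), 1)
  w <- matrix(0, 4, 4); w[lower.tri(w)] <- runif(6); w <- w + t(w); diag(w) <- NA
  m3 <- pairwise_matrix(letters[1:4], w)
  expect_equal(matrix_correlation(m1, m3),
               stats::cor(v[lower.tri(v)], w[lower.tri(w)]))
  # undefined cells error with the cells listed
  w2 <- w; w2[2, 1] <- w2[1, 2] <- NA
  m4 <- pairwise_matrix(letters[1:4], w2)
  expect_error(matrix_correlation(m1, m4), "undefined cells")
})
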