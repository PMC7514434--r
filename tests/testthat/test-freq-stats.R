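test_that("count_frequencies: one-hot, halves, hand-tallied pair table", {
  al <- make_alphabet(c("A", "B"))
  const <- msa(matrix(1L, 3, 4), al)
  f <- count_frequencies(const)
  expect_true(all(f$site[, 1] == 1) && all(f$site[, 2] == 0))
  two <- count_frequencies(matrix(c(1L, 2L), 2, 1), q = 2, pairs = FALSE)
  expect_equal(two$site[1, ], c(0.5, 0.5))
  # 4-row, 2-column hand MSA
  mat <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(1L, 1L))
  f <- count_frequencies(mat, q = 2)
  expect_equal(f$pairs[, , 1], matrix(c(2, 1, 1, 0) / 4, 2, 2))
  expect_error(count_frequencies(matrix(integer(0), 0, 2), q = 2), "empty")
})

test_that("frequency normalization and marginal consistency hold for any weights", {
  set.seed(1)
  for (rep in 1:5) {
    M <- 30; L <- 6; q <- 4
    mat <- matrix(sample.int(q, M * L, TRUE), M, L)
    w <- runif(M, 0.1, 2)
    f <- count_frequencies(mat, q = q, weights = w)
    expect_lt(max(abs(rowSums(f$site) - 1)), 1e-10)
    expect_lt(max(abs(apply(f$pairs, 3, sum) - 1)), 1e-10)
    ps <- phylopotts:::pair_sites(L)
    for (k in sample(nrow(ps), 4))
      expect_lt(max(abs(rowSums(f$pairs[, , k]) - f$site[ps[k, 1], ])), 1e-10)
  }
})

test_that("connected correlations: independence, hand value, zero sum", {
  # product table input -> all zero
  site <- rbind(c(0.3, 0.7), c(0.6, 0.4))
  pairs <- array(outer(site[1, ], site[2, ]), c(2, 2, 1))
  st <- stationary_stats(site, pairs)
  expect_lt(max(abs(connected_correlations(st))), 1e-12)
  # two perfectly co-varying binary columns with f = (0.5, 0.5):
  # f12(A,A) = 0.5, so c(A,A) = 0.5 - 0.25 = 0.25 (hand computation)
  mat <- rbind(c(1L, 1L), c(2L, 2L), c(1L, 1L), c(2L, 2L))
  cc <- connected_correlations(count_frequencies(mat, q = 2))
  expect_equal(cc[1, 1, 1], 0.25)
  expect_equal(cc[1, 2, 1], -0.25)
  # entries of every pair block sum to zero
  set.seed(2)
  f <- count_frequencies(matrix(sample.int(3, 60, TRUE), 12, 5), q = 3)
  expect_lt(max(abs(apply(connected_correlations(f), 3, sum))), 1e-12)
})

test_that("reweighting clusters near-identical sequences", {
  q <- 4; L <- 10
  set.seed(3)
  # mutually distant rows: all weights 1
  base <- matrix(sample.int(q, 5 * L, TRUE), 5, L)
  stopifnot(min(dist(base, "manhattan")) > 0) # rows pairwise distinct
  w <- reweighting_weights(base, identity_threshold = 0.99)
  expect_equal(w, rep(1, 5))
  # exact duplicate pair -> 0.5 each
  dup <- rbind(base, base[1, ])
  w <- reweighting_weights(dup, identity_threshold = 0.99)
  expect_equal(w[1], 0.5); expect_equal(w[6], 0.5)
  # k identical copies count once in total
  k <- 7
  copies <- matrix(rep(base[2, ], k), k, L, byrow = TRUE)
  w <- reweighting_weights(rbind(copies), identity_threshold = 0.8)
  expect_equal(w, rep(1 / k, k))
  expect_equal(sum(w), 1)
  # permutation invariance
  msa1 <- rbind(base, base[1, ], copies)
  perm <- sample(nrow(msa1))
  w1 <- reweighting_weights(msa1)
  w2 <- reweighting_weights(msa1[perm, ])
  expect_equal(w2, w1[perm])
})

test_that("hamming distance counts differing positions", {
  expect_identical(hamming(1:10, 1:10), 0L)
  expect_identical(hamming(rep(1L, 25), rep(2L, 25)), 25L)
  expect_identical(hamming(c(0, 1, 1, 0), c(0, 1, 0, 1)), 2L)
  expect_error(hamming(1:3, 1:4), "length")
})

test_that("compare_stats returns textbook Pearson and OLS slope", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(compare_stats(x, x), list(pearson = 1, slope = 1))
  expect_equal(compare_stats(x, 2 * x), list(pearson = 1, slope = 2))
  y <- c(2.0, 1.5, 4.0, 3.5, 6.0)
  ref_slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ref_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- compare_stats(x, y)
  expect_equal(got$pearson, ref_r)
  expect_equal(got$slope, ref_slope)
  expect_error(compare_stats(rep(1, 5), x), "variance")
})

test_that("flatten_stats orders entries reproducibly and can drop majors", {
  site <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.3, 0.6))
  expect_equal(flatten_stats(site, "site"), c(0.7, 0.2, 0.1, 0.1, 0.3, 0.6))
  expect_equal(flatten_stats(site, "site", drop_major = TRUE),
               c(0.2, 0.1, 0.1, 0.3))
})

test_that("stats TSV round-trips", {
  set.seed(4)
  f <- count_frequencies(matrix(sample.int(3, 40, TRUE), 10, 4), q = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stats_tsv(f, path)
  f2 <- read_stats_tsv(path)
  expect_equal(f2$site, f$site, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(f2$pairs, f$pairs, tolerance = 1e-9)
  expect_identical(f2$provenance, "empirical-f")
})
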