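test_that("site propagator limits and algebra", {
  omega <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(site_propagator(omega, 0.7, 0), diag(4))
  Pinf <- site_propagator(omega, 1, 1e9)
  expect_equal(Pinf, matrix(omega, 4, 4, byrow = TRUE))
  set.seed(1)
  for (rep in 1:10) {
    w <- random_simplex(4)
    mu <- runif(1, 0.1, 3); t1 <- runif(1, 0.05, 2); t2 <- runif(1, 0.05, 2)
    P1 <- site_propagator(w, mu, t1)
    expect_equal(rowSums(P1), rep(1, 4), tolerance = 1e-12)
    expect_equal(as.vector(w %*% P1), w, tolerance = 1e-12)         # stationary
    expect_equal(P1 * w, t(P1 * w), tolerance = 1e-12)              # detailed balance
    expect_equal(P1 %*% site_propagator(w, mu, t2),
                 site_propagator(w, mu, t1 + t2), tolerance = 1e-12) # semigroup
  }
  expect_error(site_propagator(c(0.5, 0.6), 1, 1), "sum to 1")
})

test_that("single-leaf likelihood is the stationary log-probability", {
  tree <- ape::read.tree(text = "(t1:0.4);")
  omega <- c(0.15, 0.35, 0.5)
  for (a in 1:3)
    expect_equal(site_likelihood(a, tree, omega, 0.7), log(omega[a]))
})

test_that("pruning equals exhaustive enumeration on small trees", {
  set.seed(2)
  for (rep in 1:12) {
    nt <- sample(2:4, 1)
    tree <- random_tree(nt)
    q <- sample(2:4, 1)
    omega <- random_simplex(q)
    mu <- runif(1, 0.1, 2.5)
    col <- sample.int(q, nt, TRUE)
    expect_equal(site_likelihood(col, tree, omega, mu),
                 brute_site_likelihood(tree, col, omega, mu),
                 tolerance = 1e-9)
  }
})

test_that("pruning handles multifurcations", {
  tree <- ape::read.tree(text = "(t1:0.3,t2:0.5,t3:0.2,t4:0.4);")
  set.seed(3)
  omega <- random_simplex(3)
  col <- c(1L, 2L, 3L, 2L)
  expect_equal(site_likelihood(col, tree, omega, 0.8),
               brute_site_likelihood(tree, col, omega, 0.8),
               tolerance = 1e-9)
})

test_that("infinite-rate likelihood factorizes over leaves", {
  tree <- grow_binary_tree(3, 0.3)
  set.seed(4)
  omega <- random_simplex(4)
  col <- sample.int(4, 8, TRUE)
  expect_equal(site_likelihood(col, tree, omega, 1e8),
               sum(log(omega[col])), tolerance = 1e-8)
})

test_that("full-sequence pruning under a factorized propagator is the sum of
          per-site likelihoods (tiny-instance oracle)", {
  set.seed(5)
  tree <- random_tree(3)
  q <- 2; L <- 2
  omega_list <- list(random_simplex(q), random_simplex(q))
  mu <- 0.6
  leaf_mat <- matrix(sample.int(q, 3 * L, TRUE), 3, L)
  full <- brute_fullseq_likelihood(tree, leaf_mat, omega_list, mu)
  sites <- sum(vapply(1:L, function(i)
    site_likelihood(leaf_mat[, i], tree, omega_list[[i]], mu), numeric(1)))
  expect_equal(full, sites, tolerance = 1e-9)
})

test_that("named columns are matched to tips by label", {
  tree <- grow_binary_tree(2, 0.3)
  omega <- c(0.4, 0.6)
  col <- c(1L, 1L, 2L, 2L)
  names(col) <- tree$tip.label
  shuffled <- col[c(3, 1, 4, 2)]
  expect_equal(site_likelihood(col, tree, omega, 0.5),
               site_likelihood(shuffled, tree, omega, 0.5))
  expect_error(site_likelihood(col[1:3], tree, omega, 0.5), "leaves")
})

test_that("site optimizer: i.i.d. MLE, constant column, monotone trace", {
  set.seed(6)
  # star tree with effectively infinite branches: MLE = column frequencies
  star <- ape::read.tree(text = "(t1:99,t2:99,t3:99,t4:99,t5:99,t6:99,t7:99,t8:99);")
  col <- c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L)
  # the default start IS the i.i.d. MLE here, so "no accepted moves" is the
  # expected (warned) outcome
  res <- suppressWarnings(
    optimize_site_frequencies(col, star, 1,
                              schedule = optimizer_schedule(n_iter = 3000)))
  mle <- tabulate(col, 3) / 8
  expect_lt(max(abs(res$omega - mle)), 0.02)
  # constant column: nearly all mass on the observed symbol
  tree <- grow_binary_tree(3, 0.3)
  resc <- optimize_site_frequencies(rep(2L, 8), tree, 0.5)
  expect_gt(resc$omega[2], 0.9)
  # accepted-move trace is nondecreasing
  expect_true(all(diff(res$trace) >= 0))
  expect_true(all(diff(resc$trace) >= 0))
})

test_that("correct_all_sites returns one profile per column and is a no-op
          on unbiased star-like data", {
  set.seed(7)
  h <- matrix(rnorm(8, 0, 0.8), 2, 4)
  m <- potts_model(h = h)
  star <- ape::read.tree(text = paste0("(",
    paste0("t", 1:64, ":99", collapse = ","), ");"))
  s <- sample_iid(m, 64, seed = 8)
  rownames(s$mat) <- star$tip.label
  omega <- correct_all_sites(s, star, 1)
  expect_identical(dim(omega$site), c(2L, 4L))
  f <- count_frequencies(s, pairs = FALSE)$site
  expect_lt(max(abs(omega$site - f)), 0.03)
  expect_identical(omega$provenance, "site-corrected-omega")
})
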