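test_that("pair propagator: identity limit, stochasticity, stationarity", {
  set.seed(1)
  oij <- random_pair_table(4)
  expect_equal(pair_propagator(oij, 0.5, 0), diag(16))
  for (rep in 1:10) {
    w <- random_pair_table(sample(2:4, 1))
    mu <- runif(1, 0.1, 3); dt <- runif(1, 0.05, 2)
    P <- pair_propagator(w, mu, dt)
    expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12)
    wf <- as.vector(t(w)) # flattened (a-1)q+b
    expect_equal(as.vector(wf %*% P), wf, tolerance = 1e-12)
  }
  bad <- matrix(c(0.5, 0.5, 0, 0), 2, 2) # zero column marginal
  expect_error(pair_propagator(bad, 1, 1), "marginal")
})

test_that("single-leaf pair likelihood is the stationary log-probability", {
  tree <- ape::read.tree(text = "(t1:0.4);")
  set.seed(2)
  oij <- random_pair_table(3)
  for (a in 1:3) for (b in 1:3)
    expect_equal(pair_likelihood(a, b, tree, oij, 0.7), log(oij[a, b]))
})

test_that("pair pruning equals exhaustive enumeration on small trees", {
  set.seed(3)
  for (rep in 1:8) {
    nt <- sample(2:3, 1)
    tree <- random_tree(nt)
    q <- sample(2:4, 1)
    oij <- random_pair_table(q)
    mu <- runif(1, 0.1, 2.5)
    ci <- sample.int(q, nt, TRUE); cj <- sample.int(q, nt, TRUE)
    expect_equal(pair_likelihood(ci, cj, tree, oij, mu),
                 brute_pair_likelihood(tree, ci, cj, oij, mu),
                 tolerance = 1e-9)
  }
  # 4-leaf instance too (the spec's bound)
  tree <- random_tree(4)
  oij <- random_pair_table(2)
  ci <- sample.int(2, 4, TRUE); cj <- sample.int(2, 4, TRUE)
  expect_equal(pair_likelihood(ci, cj, tree, oij, 0.9),
               brute_pair_likelihood(tree, ci, cj, oij, 0.9),
               tolerance = 1e-9)
})

test_that("product tables factorize at the exactly-factorizing limits", {
  set.seed(4)
  wi <- random_simplex(3); wj <- random_simplex(3)
  oij <- outer(wi, wj)
  tree <- random_tree(4)
  ci <- sample.int(3, 4, TRUE); cj <- sample.int(3, 4, TRUE)
  # dt = 0 everywhere
  t0 <- tree; t0$edge.length[] <- 0
  expect_equal(pair_likelihood(ci, cj, t0, oij, 0.7),
               site_likelihood(ci, t0, wi, 0.7) +
                 site_likelihood(cj, t0, wj, 0.7), tolerance = 1e-9)
  # mu -> infinity: i.i.d. limit factorizes too
  expect_equal(pair_likelihood(ci, cj, tree, oij, 1e8),
               site_likelihood(ci, tree, wi, 1e8) +
                 site_likelihood(cj, tree, wj, 1e8), tolerance = 1e-7)
  # for a product table the conditionals reduce to the marginals, so the
  # pair propagator IS the tensor product of the site propagators and the
  # likelihood factorizes exactly at any finite dt as well
  expect_equal(pair_likelihood(ci, cj, tree, oij, 0.7),
               site_likelihood(ci, tree, wi, 0.7) +
                 site_likelihood(cj, tree, wj, 0.7), tolerance = 1e-9)
})

test_that("compensatory fields reproduce pinned marginals", {
  # J = 0: independence product, exactly
  res <- fit_compensatory_fields(matrix(0, 3, 3), c(0.2, 0.3, 0.5),
                                 c(0.6, 0.3, 0.1))
  expect_equal(res$omega, outer(c(0.2, 0.3, 0.5), c(0.6, 0.3, 0.1)),
               tolerance = 1e-10)
  # q = 2 with uniform targets: closed-form characterization of the scaled
  # table -- the odds ratio of exp(J) is preserved and marginals are exact
  set.seed(5)
  J <- matrix(rnorm(4), 2, 2)
  res <- fit_compensatory_fields(J, c(0.5, 0.5), c(0.5, 0.5))
  odds <- function(m) m[1, 1] * m[2, 2] / (m[1, 2] * m[2, 1])
  expect_equal(odds(res$omega), odds(exp(J)), tolerance = 1e-8)
  expect_equal(rowSums(res$omega), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(colSums(res$omega), c(0.5, 0.5), tolerance = 1e-10)
  # the returned fields reconstruct the table: omega = exp(J + h_i + h_j)
  rec <- exp(J + outer(res$h_i, res$h_j, "+"))
  expect_equal(rec, res$omega, tolerance = 1e-8)
  # random case: marginals within stopping tolerance
  J <- matrix(rnorm(16, 0, 2), 4, 4)
  tr <- random_simplex(4); tc <- random_simplex(4)
  res <- fit_compensatory_fields(J, tr, tc)
  expect_lt(max(abs(rowSums(res$omega) - tr)), 1e-9)
  expect_lt(max(abs(colSums(res$omega) - tc)), 1e-9)
  expect_error(fit_compensatory_fields(J, c(0.5, 0.5, 0, 0), tc), "positive")
})

test_that("pair optimizer improves on independence and keeps constraints", {
  set.seed(6)
  q <- 3
  oij_true <- fit_compensatory_fields(diag(1.5, q), random_simplex(q),
                                      random_simplex(q))$omega
  tree <- grow_binary_tree(6, 0.3)
  mu <- 1
  # simulate the independent-pair dynamics exactly
  P <- pair_propagator(oij_true, mu, 0.3)
  cl <- reorder(tree, "cladewise")
  nt <- 64
  state <- integer(nt + tree$Nnode)
  state[nt + 1] <- sample.int(q * q, 1, prob = as.vector(t(oij_true)))
  for (e in seq_len(nrow(cl$edge)))
    state[cl$edge[e, 2]] <- sample.int(q * q, 1,
                                       prob = P[state[cl$edge[e, 1]], ])
  ci <- (state[1:nt] - 1L) %/% q + 1L
  cj <- (state[1:nt] - 1L) %% q + 1L
  names(ci) <- names(cj) <- tree$tip.label
  tr <- rowSums(oij_true); tc <- colSums(oij_true)
  res <- optimize_pair_frequencies(ci, cj, tree, mu, tr, tc)
  ll0 <- pair_likelihood(ci, cj, tree, outer(tr, tc), mu)
  expect_gte(res$loglik, ll0) # at least the independence baseline
  expect_lt(max(abs(rowSums(res$omega) - tr)), 1e-8)
  expect_lt(max(abs(colSums(res$omega) - tc)), 1e-8)
  expect_true(all(diff(res$trace) >= 0))
})

test_that("correct_all_pairs: table count, pinned marginals, Eq.13-style
          diagnostics in unconstrained mode", {
  set.seed(7)
  m <- generate_toy_model(L = 5, q = 3, c = 2, seed = 8)$model
  tree <- grow_binary_tree(5, 0.3)
  msa_t <- sample_tree_msa(m, tree, 0.8, seed = 9)
  sched <- optimizer_schedule(n_iter = 400)
  omega_site <- correct_all_sites(msa_t, tree, 0.8, sched)
  op <- correct_all_pairs(msa_t, tree, 0.8, omega_site, sched)
  expect_identical(dim(op$pairs)[3], 10L) # L(L-1)/2 for L = 5
  ps <- phylopotts:::pair_sites(5)
  for (k in seq_len(10)) {
    expect_lt(max(abs(rowSums(op$pairs[, , k]) - omega_site$site[ps[k, 1], ])),
              1e-8)
    expect_lt(max(abs(colSums(op$pairs[, , k]) - omega_site$site[ps[k, 2], ])),
              1e-8)
  }
  # diagnostic mode: marginals of the same site disagree across pairs
  diag_run <- correct_all_pairs(msa_t, tree, 0.8, omega_site, sched,
                                constrain = FALSE)
  expect_gt(attr(diag_run, "marginal_inconsistency"), 0)
})
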