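test_that("hamiltonian matches its definition on frozen examples", {
  zero <- potts_model(L = 25, q = 4)
  expect_identical(hamiltonian(zero, rep(1L, 25)), 0)
  fields <- potts_model(h = matrix(1, 25, 4))
  expect_equal(hamiltonian(fields, sample.int(4, 25, TRUE)), -25)
  # L = 2, q = 2, J_12(1,1) = 1, else 0: enumeration done by hand
  m <- potts_model(J = array(c(1, 0, 0, 0), c(2, 2, 1)), L = 2, q = 2)
  expect_equal(hamiltonian(m, c(1, 1)), -1)
  expect_equal(hamiltonian_msa(m, rbind(c(1, 2), c(2, 1), c(2, 2))),
               c(0, 0, 0))
})

test_that("hamiltonian rejects malformed sequences", {
  m <- potts_model(L = 4, q = 3)
  expect_error(hamiltonian(m, c(1, 2, 3)), "length")
  expect_error(hamiltonian(m, c(1, 2, 3, 9)), "1..q")
})

test_that("get_coupling resolves the symmetric convention", {
  set.seed(1)
  m <- random_model(4, 3)
  expect_equal(get_coupling(m, 1, 3), t(get_coupling(m, 3, 1)))
  expect_error(get_coupling(m, 2, 2), "self")
})

test_that("toy model generator honours its degenerate limits", {
  empty <- generate_toy_model(c = 0, seed = 1)
  expect_true(all(empty$model$J == 0))
  expect_identical(nrow(empty$edges), 0L)
  frozen <- generate_toy_model(sigma_J = 0, seed = 2)
  k <- pair_index(frozen$edges[1, 1], frozen$edges[1, 2], 25)
  expect_equal(frozen$model$J[, , k], diag(0.8, 4))
  offdiag <- frozen$model$J[, , k]; diag(offdiag) <- 0
  expect_true(all(offdiag == 0))
})

test_that("toy model generation is reproducible and validates params", {
  a <- generate_toy_model(seed = 99)
  b <- generate_toy_model(seed = 99)
  expect_identical(a$model$J, b$model$J)
  expect_identical(a$model$h, b$model$h)
  expect_identical(a$edges, b$edges)
  expect_error(generate_toy_model(c = 30, L = 25), "c/L")
  expect_error(generate_toy_model(sigma_J = -1), "sigma")
})

test_that("mutational effects: degenerate cases and table size", {
  zero <- potts_model(L = 25, q = 4)
  wt <- sample.int(4, 25, TRUE)
  tab <- mutational_effects(zero, wt)
  expect_identical(nrow(tab), 75L) # L (q - 1)
  expect_true(all(tab$dH == 0))
  # profile model: dH_ia = h_i(A_i) - h_i(alpha)
  set.seed(3)
  prof <- potts_model(h = matrix(rnorm(100), 25, 4))
  tab <- mutational_effects(prof, wt)
  expect_equal(tab$dH,
               prof$h[cbind(tab$i, wt[tab$i])] - prof$h[cbind(tab$i, tab$a)])
})

test_that("incremental mutant energies equal full re-evaluation", {
  set.seed(4)
  for (rep in 1:20) {
    m <- random_model(sample(3:6, 1), sample(2:4, 1))
    wt <- sample.int(m$q, m$L, TRUE)
    tab <- mutational_effects(m, wt)
    pick <- sample(nrow(tab), min(5, nrow(tab)))
    for (r in pick) {
      mut <- wt; mut[tab$i[r]] <- tab$a[r]
      expect_equal(tab$dH[r], hamiltonian(m, mut) - hamiltonian(m, wt),
                   tolerance = 1e-10)
    }
  }
})

test_that("zero-sum gauge has zero marginals and preserves the distribution", {
  set.seed(5)
  m <- random_model(3, 2)
  zs <- zero_sum_gauge(m)
  expect_lt(max(abs(apply(zs$J, 3, rowSums))), 1e-12)
  expect_lt(max(abs(apply(zs$J, 3, colSums))), 1e-12)
  # energy shift is sequence-independent over all 8 sequences
  grid <- as.matrix(expand.grid(rep(list(1:2), 3)))
  shift <- hamiltonian_msa(m, grid) - hamiltonian_msa(zs, grid)
  expect_lt(diff(range(shift)), 1e-12)
  # idempotent
  zs2 <- zero_sum_gauge(zs)
  expect_equal(zs2$J, zs$J, tolerance = 1e-12)
  expect_equal(zs2$h, zs$h, tolerance = 1e-12)
})

test_that("gauge invariance of the normalized distribution (exhaustive)", {
  set.seed(6)
  for (rep in 1:5) {
    L <- sample(3:5, 1); q <- sample(2:4, 1)
    m <- random_model(L, q)
    d1 <- enum_distribution(m)
    d2 <- enum_distribution(zero_sum_gauge(m))
    expect_equal(d1$p, d2$p, tolerance = 1e-10)
  }
})

test_that("coupling scores: zeros, symmetry, single-pair dominance", {
  zero <- potts_model(L = 6, q = 3)
  sc <- coupling_scores(zero)
  expect_true(all(sc[upper.tri(sc)] == 0))
  set.seed(7)
  m <- random_model(6, 3)
  sc <- coupling_scores(m)
  expect_equal(sc, t(sc))
  one <- potts_model(L = 6, q = 3)
  one$J[, , pair_index(2, 5, 6)] <- diag(2, 3)
  sc <- coupling_scores(one)
  expect_identical(which(sc == max(sc, na.rm = TRUE)),
                   which(row(sc) %in% c(2, 5) & col(sc) %in% c(2, 5) &
                           row(sc) != col(sc)))
})

test_that("model text serialization round-trips and tolerates gaps", {
  set.seed(8)
  m <- random_model(5, 4)
  path <- withr::local_tempfile(fileext = ".txt")
  write_potts_model(m, path, drop_zeros = FALSE)
  m2 <- read_potts_model(path)
  expect_equal(m2$J, m$J, tolerance = 1e-12)
  expect_equal(m2$h, m$h, tolerance = 1e-12)
  # sparse file: unlisted entries read back as zero
  writeLines(c("L 3", "q 2", "alphabet AB", "J 1 3 A B 0.5", "h 2 A -1.25"),
             path)
  m3 <- read_potts_model(path)
  expect_equal(m3$J[1, 2, pair_index(1, 3, 3)], 0.5)
  expect_equal(sum(m3$J != 0), 1L)
  expect_equal(m3$h[2, 1], -1.25)
})
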