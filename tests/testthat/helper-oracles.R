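# Independent brute-force oracles used against the pruning and sampling
# code paths. All enumerate explicitly and never call the kernels they check.

# random small Potts model
random_model <- function(L, q, sd_J = 0.5, sd_h = 0.5) {
  potts_model(J = array(rnorm(q * q * L * (L - 1) / 2, 0, sd_J),
                        c(q, q, L * (L - 1) / 2)),
              h = matrix(rnorm(L * q, 0, sd_h), L, q))
}

# exact Boltzmann distribution by enumeration (small L, q only)
enum_distribution <- function(model) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(model$q)), model$L)))
  p <- exp(-hamiltonian_msa(model, grid))
  list(states = grid, p = p / sum(p))
}

# site likelihood by summation over all internal-node states
brute_site_likelihood <- function(tree, col, omega, mu) {
  nt <- length(tree$tip.label); nn <- tree$Nnode
  edges <- tree$edge; elen <- tree$edge.length
  q <- length(omega)
  P <- lapply(seq_len(nrow(edges)),
              function(e) site_propagator(omega, mu, elen[e]))
  grid <- as.matrix(expand.grid(rep(list(seq_len(q)), nn)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    state <- c(col, grid[g, ])
    p <- omega[state[nt + 1]] # root prior, root node id = nt + 1
    for (e in seq_len(nrow(edges)))
      p <- p * P[[e]][state[edges[e, 1]], state[edges[e, 2]]]
    tot <- tot + p
  }
  log(tot)
}

# pair likelihood by summation over all internal-node joint states
brute_pair_likelihood <- function(tree, ci, cj, oij, mu) {
  nt <- length(tree$tip.label); nn <- tree$Nnode
  edges <- tree$edge; elen <- tree$edge.length
  q <- nrow(oij)
  P <- lapply(seq_len(nrow(edges)),
              function(e) pair_propagator(oij, mu, elen[e]))
  w <- as.vector(t(oij)) # flattened (a-1)*q + b
  leafs <- (ci - 1L) * q + cj
  grid <- as.matrix(expand.grid(rep(list(seq_len(q * q)), nn)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    state <- c(leafs, grid[g, ])
    p <- w[state[nt + 1]]
    for (e in seq_len(nrow(edges)))
      p <- p * P[[e]][state[edges[e, 1]], state[edges[e, 2]]]
    tot <- tot + p
  }
  log(tot)
}

# full-sequence likelihood under a FACTORIZED propagator (product over sites
# of the single-site propagator), by enumerating all internal-node sequences.
# Must equal the sum of per-site pruning likelihoods.
brute_fullseq_likelihood <- function(tree, leaf_mat, omega_list, mu) {
  nt <- length(tree$tip.label); nn <- tree$Nnode
  L <- ncol(leaf_mat); q <- length(omega_list[[1]])
  edges <- tree$edge; elen <- tree$edge.length
  seq_prob <- function(anc, des, e) {
    p <- 1
    for (i in seq_len(L)) {
      Pe <- site_propagator(omega_list[[i]], mu, elen[e])
      p <- p * Pe[anc[i], des[i]]
    }
    p
  }
  root_prob <- function(s) prod(vapply(seq_len(L),
                                       function(i) omega_list[[i]][s[i]],
                                       numeric(1)))
  seq_grid <- as.matrix(expand.grid(rep(list(seq_len(q)), L)))
  node_grid <- as.matrix(expand.grid(rep(list(seq_len(nrow(seq_grid))), nn)))
  tot <- 0
  for (g in seq_len(nrow(node_grid))) {
    node_seq <- rbind(leaf_mat,
                      seq_grid[node_grid[g, ], , drop = FALSE])
    p <- root_prob(node_seq[nt + 1, ])
    for (e in seq_len(nrow(edges)))
      p <- p * seq_prob(node_seq[edges[e, 1], ], node_seq[edges[e, 2], ], e)
    tot <- tot + p
  }
  log(tot)
}

# small random rooted binary tree with branch lengths (ape)
random_tree <- function(n_tip, min_len = 0.05, max_len = 1.5) {
  tree <- ape::rtree(n_tip, rooted = TRUE)
  tree$edge.length <- runif(nrow(tree$edge), min_len, max_len)
  tree
}

random_simplex <- function(q, floor = 0.02) {
  w <- runif(q) + floor
  w / sum(w)
}

random_pair_table <- function(q, floor = 0.02) {
  w <- matrix(runif(q * q) + floor, q, q)
  w / sum(w)
}
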