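#' Balanced binary molecular-clock tree
#'
#' Builds the tree used by the synthetic-data generator: `K` successive
#' duplications produce a complete binary tree with `2^K` leaves and
#' `2^K - 1` internal nodes (root included); every branch has length
#' `branch_time` in molecular-clock units, so each leaf sits `K * branch_time`
#' from the root.
#'
#' @param K number of duplications (`>= 1`)
#' @param branch_time branch length `dt > 0` for every branch
#' @param max_K memory guard on tree size
#' @return an [ape::phylo] rooted tree with tip labels `t1..t(2^K)`
#' @export
grow_binary_tree <- function(K, branch_time, max_K = 16) {
  K <- as.integer(K)
  if (K < 1L) stop_input("K must be >= 1")
  if (K > max_K) stop_input("K = ", K, " exceeds the cap of ", max_K)
  if (branch_time <= 0) stop_input("branch_time must be > 0")
  tree <- ape::stree(2L^K, type = "balanced")
  tree$edge.length <- rep(branch_time, nrow(tree$edge))
  tree$tip.label <- paste0("t", seq_len(2L^K))
  tree
}

#' Evolve a sequence along one branch
#'
#' Finite-time MCMC: the number of mutation events is Poisson with mean
#' `mu * L * dt`; each event picks a uniformly random site and redraws its
#' state from the model's full conditional (heat-bath Gibbs move, which may
#' conserve the current state). `dt = 0` returns the parent unchanged.
#'
#' @param model a [potts_model()]
#' @param parent_seq integer sequence of length `L`
#' @param mu mutation rate per site and time unit
#' @param dt branch length
#' @return the child sequence
#' @export
evolve_branch <- function(model, parent_seq, mu, dt) {
  parent_seq <- check_sequence(model, parent_seq)
  if (mu * dt < 0) stop_input("mu * dt must be >= 0")
  cpp_evolve_branch(model$J, model$h, parent_seq, mu * model$L * dt)
}

#' Equilibrium ("fair" / i.i.d.) sample of a Potts model
#'
#' Gibbs sampling from a single chain: `burn_in` full sweeps (a sweep updates
#' all `L` sites once), then one sequence every `thin` sweeps. For the small
#' models used here this yields an effectively i.i.d. equilibrium sample.
#'
#' @param model a [potts_model()]
#' @param M number of sequences
#' @param burn_in burn-in sweeps (default 1000)
#' @param thin sweeps between consecutive samples (default `L`)
#' @param seed optional seed
#' @return an [msa()] with rows `iid_1..iid_M`
#' @export
sample_iid <- function(model, M, burn_in = 1000, thin = model$L, seed = NULL) {
  if (M < 1) stop_input("M must be >= 1")
  mat <- with_seed(seed,
    cpp_sample_iid(model$J, model$h, as.integer(M), as.integer(burn_in),
                   as.integer(thin)))
  msa(mat, model$alphabet, labels = paste0("iid_", seq_len(M)))
}

#' Sample an alignment down a phylogeny
#'
#' Draws a root sequence from the model equilibrium (via [sample_iid()]),
#' then recursively applies [evolve_branch()] along every branch of the tree;
#' the leaf sequences form the phylogenetically correlated ("biased") MSA.
#'
#' @param model a [potts_model()]
#' @param tree rooted [ape::phylo] with branch lengths
#' @param mu mutation rate per site and time unit
#' @param seed optional seed
#' @param keep_internal also return internal-node sequences (for oracles)
#' @param root_seq optional fixed root sequence (skips the equilibrium draw)
#' @return an [msa()] whose rows are the tree tips in tip order; with
#'   `keep_internal = TRUE`, attribute `internal` holds the internal-node
#'   sequence matrix (rows indexed by node id).
#' @export
sample_tree_msa <- function(model, tree, mu, seed = NULL,
                            keep_internal = FALSE, root_seq = NULL) {
  if (is.null(tree$edge.length)) stop_input("tree must have branch lengths")
  with_seed(seed, {
    n_tip <- length(tree$tip.label)
    n_node <- n_tip + tree$Nnode
    root <- n_tip + 1L
    seqs <- matrix(NA_integer_, n_node, model$L)
    seqs[root, ] <- if (is.null(root_seq)) sample_iid(model, 1)$mat[1, ]
                    else check_sequence(model, root_seq)
    ord <- reorder(tree, "cladewise") # parents before children
    for (e in seq_len(nrow(ord$edge))) {
      pa <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
      seqs[ch, ] <- cpp_evolve_branch(model$J, model$h, seqs[pa, ],
                                      mu * model$L * ord$edge.length[e])
    }
    out <- msa(seqs[seq_len(n_tip), , drop = FALSE], model$alphabet,
               labels = tree$tip.label)
    if (keep_internal) attr(out, "internal") <- seqs[(n_tip + 1L):n_node, , drop = FALSE]
    out
  })
}

#' Read/write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] adding the
#' validation this package needs: branch lengths are mandatory when the tree
#' feeds the pruning likelihoods, leaf labels must match MSA row labels, and
#' unrooted input is rooted at its basal trifurcation with a warning.
#'
#' @param path Newick file
#' @param require_lengths error when branch lengths are missing?
#' @param msa_labels optional character vector the tip labels must cover
#' @return an [ape::phylo]
#' @export
read_tree <- function(path, require_lengths = TRUE, msa_labels = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop_input("could not parse Newick file: ", path)
  if (require_lengths && is.null(tree$edge.length))
    stop_input("tree has no branch lengths: ", path)
  if (!ape::is.rooted(tree)) {
    warning("unrooted tree; treating the basal multifurcation as the root")
  }
  if (!is.null(msa_labels)) {
    missing <- setdiff(tree$tip.label, msa_labels)
    if (length(missing))
      stop_input("tree leaves absent from MSA: ",
                 paste(utils::head(missing, 5), collapse = ", "))
  }
  tree
}

#' @rdname read_tree
#' @param tree an [ape::phylo]
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Postorder edge arrays consumed by the pruning kernels.
tree_arrays <- function(tree) {
  po <- reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  list(edges = po$edge, elen = po$edge.length,
       n_node = n_tip + tree$Nnode, root = n_tip + 1L, n_tip = n_tip)
}

# MSA rows reordered to tip-id order; errors on label mismatch.
match_tips <- function(x, tree) {
  mat <- msa_matrix(x)
  labs <- rownames(mat)
  idx <- match(tree$tip.label, labs)
  if (anyNA(idx))
    stop_input("MSA is missing tree leaves: ",
               paste(utils::head(tree$tip.label[is.na(idx)], 5), collapse = ", "))
  mat[idx, , drop = FALSE]
}
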