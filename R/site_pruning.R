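#' Single-site substitution propagator
#'
#' The Felsenstein-model propagator toward a stationary profile `omega`:
#' `P(B | A, dt) = exp(-mu dt) delta_AB + (1 - exp(-mu dt)) omega(B)`.
#' Rows index the ancestral state `A`, columns the descendant state `B`.
#' The matrix is stochastic, stationary with respect to `omega`, satisfies
#' detailed balance, and forms a semigroup in `dt`.
#'
#' @param omega stationary distribution (length `q`, sums to 1)
#' @param mu mutation rate
#' @param dt elapsed time
#' @return `q x q` transition matrix
#' @export
site_propagator <- function(omega, mu, dt) {
  if (abs(sum(omega) - 1) > 1e-8) stop_input("omega must sum to 1")
  if (mu * dt < 0) stop_input("mu * dt must be >= 0")
  e <- exp(-mu * dt)
  q <- length(omega)
  e * diag(q) + (1 - e) * matrix(omega, q, q, byrow = TRUE)
}

#' Pruning log-likelihood of one alignment column
#'
#' Felsenstein pruning over the tree for a single site under
#' [site_propagator()] dynamics, with the stationary profile as the root
#' prior. Partial likelihoods are accumulated with per-node rescaling, and
#' multifurcating trees are handled (product over all children).
#'
#' @param column integer states (1..q), one per tree leaf
#' @param tree rooted [ape::phylo] with branch lengths; `column` is taken in
#'   tip order, or by names if `column` is named
#' @param omega stationary profile
#' @param mu mutation rate
#' @return log-likelihood
#' @export
site_likelihood <- function(column, tree, omega, mu) {
  ta <- tree_arrays(tree)
  col <- align_column(column, tree, ta$n_tip)
  if (abs(sum(omega) - 1) > 1e-8) stop_input("omega must sum to 1")
  cpp_site_loglik(ta$edges, ta$elen, ta$n_node, ta$root, col, omega, mu)
}

align_column <- function(column, tree, n_tip) {
  if (length(column) != n_tip)
    stop_input("column length ", length(column), " != number of leaves ", n_tip)
  if (!is.null(names(column))) {
    idx <- match(tree$tip.label, names(column))
    if (anyNA(idx)) stop_input("column names do not cover the tree leaves")
    column <- column[idx]
  }
  as.integer(column)
}

#' Default schedule for the stochastic frequency optimizers
#'
#' Hill climbing over the simplex (or the pair coupling table) uses additive
#' Gaussian moves whose magnitude shrinks geometrically from `mag0` to
#' `mag1`; a fraction `p_global` of moves perturb all parameters at once.
#'
#' @param n_iter move budget
#' @param mag0,mag1 initial/final move magnitude (`mag1 <= mag0`)
#' @param p_global fraction of global moves
#' @param seed optional seed recorded with the schedule
#' @return list of schedule parameters
#' @export
optimizer_schedule <- function(n_iter = 2000, mag0 = 0.3, mag1 = 0.003,
                               p_global = 0.3, seed = NULL) {
  if (mag1 > mag0) stop_input("move magnitude must not increase")
  list(n_iter = as.integer(n_iter), mag0 = mag0, mag1 = mag1,
       p_global = p_global, seed = seed)
}

#' Maximum-likelihood stationary profile of one column
#'
#' Stochastic maximization of [site_likelihood()] over the `q`-simplex:
#' global or local additive moves, clipped at a small floor so every state
#' keeps positive mass, renormalized, and accepted only on a strict
#' likelihood increase. The best profile seen is returned together with the
#' per-iteration likelihood trace.
#'
#' @inheritParams site_likelihood
#' @param schedule an [optimizer_schedule()]
#' @param omega0 starting profile (default: empirical column frequencies,
#'   floored)
#' @return list with `omega`, `loglik`, `trace`, `n_accepted`
#' @export
optimize_site_frequencies <- function(column, tree, mu,
                                      schedule = optimizer_schedule(),
                                      omega0 = NULL) {
  ta <- tree_arrays(tree)
  col <- align_column(column, tree, ta$n_tip)
  q <- max(col)
  if (!is.null(omega0)) q <- max(q, length(omega0))
  if (is.null(omega0)) {
    omega0 <- tabulate(col, q) / length(col)
    omega0 <- pmax(omega0, 1e-6)
    omega0 <- omega0 / sum(omega0)
  }
  res <- with_seed(schedule$seed,
    cpp_site_optimize(ta$edges, ta$elen, ta$n_node, ta$root, col, omega0, mu,
                      schedule$n_iter, schedule$mag0, schedule$mag1,
                      schedule$p_global, 1e-6))
  if (res$n_accepted == 0)
    warning("no accepted moves; starting profile returned")
  res
}

#' Phylogenetically corrected site profiles for a whole alignment
#'
#' Runs [optimize_site_frequencies()] independently on every column (columns
#' share no state, so this is an embarrassingly parallel contract). Column
#' failures are caught, reported, and replaced by the empirical profile.
#'
#' @param x an [msa()] (rows must match the tree leaves)
#' @param tree rooted [ape::phylo] with branch lengths
#' @param mu mutation rate (e.g. from [estimate_mu()])
#' @param schedule an [optimizer_schedule()]
#' @param q alphabet size
#' @return a [stationary_stats()] with provenance `"site-corrected-omega"`;
#'   attribute `loglik` holds the per-column likelihoods, `failures` any
#'   column errors
#' @export
correct_all_sites <- function(x, tree, mu, schedule = optimizer_schedule(),
                              q = NULL) {
  mat <- match_tips(x, tree)
  if (inherits(x, "msa")) q <- q %||% x$alphabet$q
  if (is.null(q)) q <- max(mat)
  ta <- tree_arrays(tree)
  L <- ncol(mat)
  site <- matrix(0, L, q)
  ll <- numeric(L)
  failures <- character(0)
  for (i in seq_len(L)) {
    col <- mat[, i]
    omega0 <- pmax(tabulate(col, q) / length(col), 1e-6)
    omega0 <- omega0 / sum(omega0)
    res <- tryCatch(
      cpp_site_optimize(ta$edges, ta$elen, ta$n_node, ta$root, col, omega0,
                        mu, schedule$n_iter, schedule$mag0, schedule$mag1,
                        schedule$p_global, 1e-6),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("column ", i, ": ", conditionMessage(res)))
      site[i, ] <- omega0
    } else {
      site[i, ] <- res$omega
      ll[i] <- res$loglik
    }
  }
  if (length(failures))
    warning("site correction failed for ", length(failures), " column(s)")
  out <- stationary_stats(site, provenance = "site-corrected-omega")
  attr(out, "loglik") <- ll
  attr(out, "failures") <- failures
  out
}
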