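#' Independent-pair substitution propagator
#'
#' Transition matrix on joint states of a site pair `(i, j)` under the
#' independent-pair evolution model with stationary table `omega_ij`
#' (`e = exp(-mu dt)`):
#' `P(C,D | A,B) = e^2 d_AC d_BD + e(1-e) [ w(D|A) d_AC + w(C|B) d_BD ]
#'  + (1-e)^2 w_ij(C,D)`,
#' with `w(D|A) = w_ij(A,D) / sum_D' w_ij(A,D')` the conditional of `j`
#' given `i` (and symmetrically for `w(C|B)`). Conditionals let the pair
#' dynamics carry epistasis that the single-site model cannot. Joint states
#' `(A, B)` are flattened row-major as `(A-1)*q + B` — `A` is the state at
#' the smaller site index.
#'
#' @param omega_ij `q x q` joint table (rows: site `i`; columns: site `j`),
#'   normalized, with strictly positive marginals
#' @param mu mutation rate
#' @param dt elapsed time
#' @return `q^2 x q^2` stochastic matrix over flattened pair states
#' @export
pair_propagator <- function(omega_ij, mu, dt) {
  if (abs(sum(omega_ij) - 1) > 1e-8) stop_input("omega_ij must sum to 1")
  if (mu * dt < 0) stop_input("mu * dt must be >= 0")
  q <- nrow(omega_ij)
  ri <- rowSums(omega_ij); cj <- colSums(omega_ij)
  if (any(ri <= 0) || any(cj <= 0))
    stop_input("omega_ij has a zero marginal; conditionals undefined")
  w_ji <- omega_ij / ri            # w(D|A): row A, col D
  w_ij_c <- t(t(omega_ij) / cj)    # w(C|B): row C, col B
  e <- exp(-mu * dt)
  S <- q * q
  P <- matrix(0, S, S)
  for (A in seq_len(q)) for (B in seq_len(q)) {
    from <- (A - 1L) * q + B
    for (C in seq_len(q)) for (D in seq_len(q)) {
      to <- (C - 1L) * q + D
      P[from, to] <- e^2 * (A == C) * (B == D) +
        e * (1 - e) * (w_ji[A, D] * (A == C) + w_ij_c[C, B] * (B == D)) +
        (1 - e)^2 * omega_ij[C, D]
    }
  }
  P
}

# Encode two leaf columns as flattened pair states (state at i is the row).
encode_pair_states <- function(col_i, col_j, q) {
  (as.integer(col_i) - 1L) * q + as.integer(col_j)
}

#' Pruning log-likelihood of a column pair
#'
#' Felsenstein pruning over `q^2` joint states under [pair_propagator()]
#' dynamics, with `omega_ij` as the root prior. The per-edge message is
#' contracted in `O(q^2)` using the propagator's low-rank structure.
#'
#' @param col_i,col_j integer leaf states for sites `i` and `j` (tip order,
#'   or named by tip labels)
#' @param tree rooted [ape::phylo] with branch lengths
#' @param omega_ij `q x q` stationary joint table
#' @param mu mutation rate
#' @return log-likelihood
#' @export
pair_likelihood <- function(col_i, col_j, tree, omega_ij, mu) {
  ta <- tree_arrays(tree)
  ci <- align_column(col_i, tree, ta$n_tip)
  cj <- align_column(col_j, tree, ta$n_tip)
  if (abs(sum(omega_ij) - 1) > 1e-8) stop_input("omega_ij must sum to 1")
  cpp_pair_loglik(ta$edges, ta$elen, ta$n_node, ta$root,
                  encode_pair_states(ci, cj, nrow(omega_ij)), omega_ij, mu)
}

#' Compensatory fields by iterative proportional fitting
#'
#' Given a coupling table `J`, finds fields `h_i`, `h_j` such that
#' `omega_ij(A,B) = exp(J(A,B) + h_i(A) + h_j(B)) / z` has the prescribed
#' row and column marginals, by alternately rescaling rows and columns of
#' `exp(J)` (Sinkhorn scaling) until the largest marginal error falls below
#' `tol`.
#'
#' @param J `q x q` coupling table
#' @param target_row,target_col strictly positive simplex vectors
#' @param tol marginal tolerance (default 1e-10)
#' @param maxit iteration cap
#' @return list with `omega` (`q x q`, marginals = targets), `h_i`, `h_j`
#'   (log scaling factors), `iterations`, `residual`, `converged`
#' @export
fit_compensatory_fields <- function(J, target_row, target_col, tol = 1e-10,
                                    maxit = 10000) {
  if (any(target_row <= 0) || any(target_col <= 0))
    stop_input("marginal targets must be strictly positive")
  if (abs(sum(target_row) - 1) > 1e-8 || abs(sum(target_col) - 1) > 1e-8)
    stop_input("marginal targets must sum to 1")
  res <- cpp_ipf(as.matrix(J), target_row, target_col, tol, maxit)
  if (!res$converged)
    warning("marginal fitting did not reach tol; residual = ",
            format(res$residual))
  res
}

#' Constrained maximum-likelihood pair table for one site pair
#'
#' Stochastic maximization of [pair_likelihood()] over joint tables whose
#' marginals are pinned to the site-corrected profiles: the table is
#' reparameterized through a `q x q` coupling `J` and compensatory fields
#' ([fit_compensatory_fields()]), moves perturb `J` (global/local, shrinking
#' magnitude, entries bounded to `[-j_bound, j_bound]`, zero-centered after
#' acceptance — a pure gauge choice), and each proposal is completed by IPF
#' so the constraints hold at every accepted step. Acceptance requires a
#' strict likelihood increase; `J = 0` (the independence table) is the
#' default start.
#'
#' @inheritParams pair_likelihood
#' @param target_row,target_col site-corrected marginal profiles for `i`, `j`
#' @param schedule an [optimizer_schedule()]
#' @param J0 starting coupling table (default zero)
#' @param j_bound bound on coupling entries (default 8)
#' @return list with `omega` (best table), `J`, `loglik`, `trace`,
#'   `n_accepted`
#' @export
optimize_pair_frequencies <- function(col_i, col_j, tree, mu, target_row,
                                      target_col,
                                      schedule = optimizer_schedule(),
                                      J0 = NULL, j_bound = 8) {
  ta <- tree_arrays(tree)
  ci <- align_column(col_i, tree, ta$n_tip)
  cj <- align_column(col_j, tree, ta$n_tip)
  q <- length(target_row)
  J0 <- J0 %||% matrix(0, q, q)
  with_seed(schedule$seed,
    cpp_pair_optimize(ta$edges, ta$elen, ta$n_node, ta$root,
                      encode_pair_states(ci, cj, q),
                      target_row, target_col, J0, mu,
                      schedule$n_iter, schedule$mag0, schedule$mag1,
                      schedule$p_global, j_bound, 1e-10, 10000))
}

#' Phylogenetically corrected pair tables for a whole alignment
#'
#' Optimizes all `L(L-1)/2` pairs independently (read-only shared inputs).
#' With `constrain = TRUE` (the default and the method proper) every table's
#' marginals equal the supplied site profiles; `constrain = FALSE` is a
#' diagnostic mode that optimizes each pair's marginals freely, exposing the
#' marginal inconsistencies across pairs sharing a site that motivate the
#' constraint.
#'
#' @param x an [msa()]
#' @param tree rooted [ape::phylo] with branch lengths
#' @param mu mutation rate
#' @param omega_site a site-corrected [stationary_stats()] (or `L x q`
#'   matrix) supplying the pinned marginals
#' @param schedule an [optimizer_schedule()]
#' @param constrain pin marginals to `omega_site`? (default `TRUE`)
#' @return a [stationary_stats()] with provenance `"pair-corrected-omega"`;
#'   attributes `loglik` (per pair) and, in diagnostic mode,
#'   `marginal_inconsistency` (mean over sites of the largest total-variation
#'   gap between marginals of the same site extracted from different pairs)
#' @export
correct_all_pairs <- function(x, tree, mu, omega_site,
                              schedule = optimizer_schedule(),
                              constrain = TRUE) {
  mat <- match_tips(x, tree)
  site <- if (inherits(omega_site, "stationary_stats")) omega_site$site
          else as.matrix(omega_site)
  L <- ncol(mat); q <- ncol(site)
  if (nrow(site) != L) stop_input("omega_site has wrong number of sites")
  ta <- tree_arrays(tree)
  ps <- pair_sites(L)
  pairs_arr <- array(0, dim = c(q, q, nrow(ps)))
  ll <- numeric(nrow(ps))
  failures <- character(0)
  for (k in seq_len(nrow(ps))) {
    i <- ps[k, 1]; j <- ps[k, 2]
    tr <- site[i, ]; tc <- site[j, ]
    if (!constrain) {
      # free marginals: empirical pair frequencies, floored
      emp <- table(factor(mat[, i], 1:q), factor(mat[, j], 1:q)) / nrow(mat)
      emp <- pmax(as.matrix(emp), 1e-6); emp <- emp / sum(emp)
      tr <- rowSums(emp); tc <- colSums(emp)
    }
    res <- tryCatch(
      cpp_pair_optimize(ta$edges, ta$elen, ta$n_node, ta$root,
                        encode_pair_states(mat[, i], mat[, j], q),
                        tr, tc, matrix(0, q, q), mu,
                        schedule$n_iter, schedule$mag0, schedule$mag1,
                        schedule$p_global, 8, 1e-10, 10000),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("pair (", i, ",", j, "): ",
                                     conditionMessage(res)))
      pairs_arr[, , k] <- outer(tr, tc)
    } else {
      pairs_arr[, , k] <- res$omega
      ll[k] <- res$loglik
    }
  }
  if (length(failures))
    warning("pair correction failed for ", length(failures), " pair(s)")
  out <- stationary_stats(site, pairs_arr, provenance = "pair-corrected-omega")
  attr(out, "loglik") <- ll
  attr(out, "failures") <- failures
  if (!constrain)
    attr(out, "marginal_inconsistency") <- marginal_inconsistency(pairs_arr, L, q)
  out
}

# Largest total-variation disagreement between the marginals of the same site
# extracted from different pair tables (diagnostic for the unconstrained mode).
marginal_inconsistency <- function(pairs_arr, L, q) {
  ps <- pair_sites(L)
  worst <- numeric(L)
  for (i in seq_len(L)) {
    margs <- list()
    for (k in seq_len(nrow(ps))) {
      if (ps[k, 1] == i) margs[[length(margs) + 1]] <- rowSums(pairs_arr[, , k])
      if (ps[k, 2] == i) margs[[length(margs) + 1]] <- colSums(pairs_arr[, , k])
    }
    m <- do.call(rbind, margs)
    tv <- 0
    for (u in seq_len(nrow(m) - 1)) for (v in (u + 1):nrow(m))
      tv <- max(tv, sum(abs(m[u, ] - m[v, ])) / 2)
    worst[i] <- tv
  }
  mean(worst)
}
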