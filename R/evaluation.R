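#' Symmetrized Kullback-Leibler divergence between two Potts models
#'
#' Monte-Carlo estimate of
#' `D_KL(p || q) + D_KL(q || p) = <H_q - H_p>_p + <H_p - H_q>_q`,
#' where each average runs over an equilibrium Gibbs sample of the
#' corresponding model — the partition functions cancel in the symmetrized
#' form, which is zero iff the distributions coincide and positive
#' otherwise. The standard error is estimated by batch means.
#'
#' @param p,q_model two [potts_model()] objects with equal `L`, `q`
#' @param n_samples Monte-Carlo sample size per model (default 1e4)
#' @param burn_in,thin Gibbs sweeps for burn-in / between samples
#' @param seed optional seed
#' @param n_batches batches for the standard error
#' @return list with `kl` (point estimate) and `se`
#' @export
symmetrized_kl <- function(p, q_model, n_samples = 1e4, burn_in = 1000,
                           thin = p$L, seed = NULL, n_batches = 20) {
  if (p$L != q_model$L || p$q != q_model$q)
    stop_input("models must share L and q")
  with_seed(seed, {
    sp <- cpp_sample_iid(p$J, p$h, as.integer(n_samples),
                         as.integer(burn_in), as.integer(thin))
    sq <- cpp_sample_iid(q_model$J, q_model$h, as.integer(n_samples),
                         as.integer(burn_in), as.integer(thin))
    # <H_q - H_p>_p + <H_p - H_q>_q
    d1 <- cpp_hamiltonian(q_model$J, q_model$h, sp) -
          cpp_hamiltonian(p$J, p$h, sp)
    d2 <- cpp_hamiltonian(p$J, p$h, sq) -
          cpp_hamiltonian(q_model$J, q_model$h, sq)
    est <- mean(d1) + mean(d2)
    bsize <- floor(n_samples / n_batches)
    bm <- function(v) {
      b <- vapply(seq_len(n_batches), function(k)
        mean(v[((k - 1) * bsize + 1):(k * bsize)]), numeric(1))
      stats::var(b) / n_batches
    }
    list(kl = est, se = sqrt(bm(d1) + bm(d2)))
  })
}

#' Exact symmetrized KL for factorized (J = 0) models
#'
#' Closed form used as the estimator's oracle:
#' `sum_i sum_A (p_i(A) - q_i(A)) log(p_i(A) / q_i(A))` with
#' `p_i = softmax(h_i)`.
#'
#' @param p,q_model profile models (couplings ignored — must be zero)
#' @return exact symmetrized KL
#' @export
symmetrized_kl_profile <- function(p, q_model) {
  if (any(p$J != 0) || any(q_model$J != 0))
    stop_input("closed form requires J = 0 in both models")
  soft <- function(h) exp(h) / rowSums(exp(h))
  pp <- soft(p$h); qq <- soft(q_model$h)
  sum((pp - qq) * log(pp / qq))
}

#' Positive predictive value curve for contact prediction
#'
#' Pairs are ranked by descending score (ties broken lexicographically by
#' `(i, j)`); `PPV(N)` is the fraction of the first `N` predictions that are
#' true edges.
#'
#' @param scores symmetric `L x L` score matrix (`NA` diagonal allowed)
#' @param true_edges 2-column matrix of true edges (`i < j`)
#' @param n_max curve length (default all pairs)
#' @return data frame with `N`, `ppv`, plus the ranked `i`, `j`, `hit`
#' @export
ppv_curve <- function(scores, true_edges, n_max = NULL) {
  L <- nrow(scores)
  ps <- pair_sites(L)
  sc <- scores[ps]
  ord <- order(-sc, ps[, 1], ps[, 2])
  ps <- ps[ord, , drop = FALSE]
  n_max <- min(n_max %||% nrow(ps), nrow(ps))
  truth <- rep(FALSE, L * (L - 1) / 2)
  if (length(true_edges)) {
    te <- as.matrix(true_edges)
    ii <- pmin(te[, 1], te[, 2]); jj <- pmax(te[, 1], te[, 2])
    truth[pair_index(ii, jj, L)] <- TRUE
  }
  hit <- truth[pair_index(ps[, 1], ps[, 2], L)][seq_len(n_max)]
  data.frame(N = seq_len(n_max), ppv = cumsum(hit) / seq_len(n_max),
             i = ps[seq_len(n_max), 1], j = ps[seq_len(n_max), 2], hit = hit)
}

#' Mutational-effect prediction quality
#'
#' For every wild type in `wt_set`, the Pearson correlation between the
#' `L(q-1)` true single-mutant energy shifts (under `true_model`) and the
#' predicted ones (under `inferred_model`), averaged over wild types.
#' Optionally groups the per-wild-type correlations by Hamming distance to
#' the nearest training sequence.
#'
#' @param true_model,inferred_model [potts_model()] objects sharing `L`, `q`
#' @param wt_set an [msa()] (or matrix) of wild-type sequences
#' @param training optional [msa()] to compute nearest-sequence distances
#' @return list with `mean_pearson`, per-wild-type `pearson`, and (when
#'   `training` is given) `by_distance` (data frame distance / mean r / n)
#' @export
mutant_prediction_score <- function(true_model, inferred_model, wt_set,
                                    training = NULL) {
  if (true_model$L != inferred_model$L || true_model$q != inferred_model$q)
    stop_input("models must share L and q")
  wts <- msa_matrix(wt_set)
  r <- rep(NA_real_, nrow(wts))
  for (m in seq_len(nrow(wts))) {
    t0 <- cpp_mutational_effects(true_model$J, true_model$h, wts[m, ])
    t1 <- cpp_mutational_effects(inferred_model$J, inferred_model$h, wts[m, ])
    keep <- t(matrix(seq_len(true_model$q), true_model$q, true_model$L)) !=
      wts[m, ] # L x q mask of non-wt states
    v0 <- t0[keep]; v1 <- t1[keep]
    if (stats::sd(v0) == 0 || stats::sd(v1) == 0) {
      warning("degenerate mutant vector for wild type ", m, "; skipped")
      next
    }
    r[m] <- stats::cor(v0, v1)
  }
  out <- list(mean_pearson = mean(r, na.rm = TRUE), pearson = r)
  if (!is.null(training)) {
    tr <- msa_matrix(training)
    dmin <- vapply(seq_len(nrow(wts)), function(m)
      min(rowSums(tr != matrix(wts[m, ], nrow(tr), ncol(tr), byrow = TRUE))),
      numeric(1))
    agg <- stats::aggregate(r, list(distance = dmin),
                            function(v) mean(v, na.rm = TRUE))
    cnt <- stats::aggregate(r, list(distance = dmin), length)
    out$by_distance <- data.frame(distance = agg$distance, mean_pearson = agg$x,
                                  n = cnt$x)
  }
  out
}
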