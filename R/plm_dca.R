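#' Potts model inference by pseudo-likelihood maximization
#'
#' Asymmetric plmDCA: for every site `r` the conditional multinomial logit
#' `P(A_r | A_{\\r})` is maximized over `h_r` and the couplings `J_rj`
#' (weighted, normalized log-likelihood with L2 penalties
#' `lambda_J ||J||^2 + lambda_h ||h||^2`) with a deterministic quasi-Newton
#' optimizer (L-BFGS-B over an analytic gradient). The two per-site estimates
#' of every `J_ij` are symmetrized by averaging and the result is returned in
#' zero-sum gauge.
#'
#' @param x an [msa()] or integer matrix
#' @param weights per-sequence weights (default 1; see
#'   [reweighting_weights()] for the 80%-identity baseline)
#' @param lambda_J,lambda_h L2 penalties (default 0.01 each)
#' @param q alphabet size
#' @param maxit L-BFGS-B iteration cap per site
#' @param factr L-BFGS-B convergence tolerance
#' @return a [potts_model()] in zero-sum gauge; attribute `convergence`
#'   holds the per-site optimizer codes, `grad_norm` the per-site final
#'   gradient norms
#' @export
plm_infer <- function(x, weights = NULL, lambda_J = 0.01, lambda_h = 0.01,
                      q = NULL, maxit = 400, factr = 1e7) {
  mat <- msa_matrix(x)
  if (inherits(x, "msa")) q <- q %||% x$alphabet$q
  if (is.null(q)) q <- max(mat)
  M <- nrow(mat); L <- ncol(mat)
  weights <- weights %||% rep(1, M)
  J_acc <- array(0, dim = c(q, q, (L * (L - 1L)) %/% 2L))
  h <- matrix(0, L, q)
  conv <- integer(L); gnorm <- numeric(L)
  others <- function(r) setdiff(seq_len(L), r)
  for (r in seq_len(L)) {
    npar <- q + (L - 1L) * q * q
    par0 <- numeric(npar)
    fn <- function(p) cpp_plm_obj(p, mat, weights, r, q, lambda_J, lambda_h,
                                  FALSE)$value
    gr <- function(p) cpp_plm_obj(p, mat, weights, r, q, lambda_J, lambda_h,
                                  TRUE)$gradient
    op <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                       control = list(maxit = maxit, factr = factr))
    conv[r] <- op$convergence
    gnorm[r] <- sqrt(mean(gr(op$par)^2))
    h[r, ] <- op$par[seq_len(q)]
    Jblocks <- op$par[-seq_len(q)]
    ot <- others(r)
    for (jj in seq_along(ot)) {
      j <- ot[jj]
      blk <- matrix(Jblocks[((jj - 1L) * q * q + 1L):(jj * q * q)], q, q)
      # blk rows: state at r; columns: state at j
      if (r < j) {
        k <- pair_index(r, j, L)
        J_acc[, , k] <- J_acc[, , k] + blk / 2
      } else {
        k <- pair_index(j, r, L)
        J_acc[, , k] <- J_acc[, , k] + t(blk) / 2
      }
    }
  }
  if (any(conv != 0))
    warning("plm optimizer did not fully converge for ",
            sum(conv != 0), " site(s); max scaled gradient norm ",
            format(max(gnorm)))
  model <- potts_model(J = J_acc, h = h, L = L, q = q,
                       alphabet = if (inherits(x, "msa")) x$alphabet else NULL)
  model <- zero_sum_gauge(model)
  attr(model, "convergence") <- conv
  attr(model, "grad_norm") <- gnorm
  model
}

#' Profile (independent-site) model
#'
#' Couplings-free baseline reproducing given site frequencies through fields
#' only: `h_i(A) = log f_i(A)`, fixed to zero mean per site; `f` is floored
#' at `eps` and renormalized first.
#'
#' @param stats a [stationary_stats()] or an `L x q` frequency matrix
#' @param eps floor applied to frequencies before taking logs
#' @return a [potts_model()] with `J = 0`
#' @export
fit_profile <- function(stats, eps = 1e-6) {
  f <- if (inherits(stats, "stationary_stats")) stats$site else as.matrix(stats)
  f <- pmax(f, eps)
  f <- f / rowSums(f)
  h <- log(f)
  h <- h - rowMeans(h)
  potts_model(h = h, L = nrow(f), q = ncol(f))
}
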