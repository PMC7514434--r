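#' Time separation of leaf pairs
#'
#' Patristic distance: for each requested pair of leaves, the sum of branch
#' lengths along the connecting path. With `M` leaves there are `M(M-1)/2`
#' pairs; at most `max_pairs` are used, subsampled with the current RNG.
#'
#' @param tree rooted [ape::phylo] with branch lengths
#' @param pairs optional 2-column matrix of tip indices; default all pairs
#'   (subsampled to `max_pairs`)
#' @param max_pairs cap on the number of pairs (default 2e6)
#' @return data frame with columns `m`, `n`, `time`
#' @export
leaf_pair_times <- function(tree, pairs = NULL, max_pairs = 2e6) {
  if (is.null(tree$edge.length)) stop_input("tree has no branch lengths")
  n_tip <- length(tree$tip.label)
  if (is.null(pairs)) {
    np <- n_tip * (n_tip - 1) / 2
    if (np <= max_pairs) {
      pairs <- pair_sites(n_tip)
    } else {
      k <- sort(sample.int(np, max_pairs))
      ps <- pair_sites(n_tip)
      pairs <- ps[k, , drop = FALSE]
    }
  }
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  cl <- reorder(tree, "cladewise")
  t_sep <- cpp_patristic_pairs(cl$edge, cl$edge.length,
                               n_tip + tree$Nnode, pairs)
  data.frame(m = pairs[, 1], n = pairs[, 2], time = t_sep)
}

#' Binned Hamming-distance/time curve
#'
#' Average Hamming distance between leaf sequences as a function of their
#' time separation on the tree, using equal-count (quantile) bins; bins
#' collapse to the unique values when times are discrete (as they are on the
#' simulator's clock trees).
#'
#' @param x an [msa()] whose rows match the tree tips
#' @param pair_times data frame from [leaf_pair_times()]
#' @param tree the tree the times came from (for row/tip matching)
#' @param n_bins target number of bins (default 20)
#' @return object of class `"distance_curve"`: data frame with `time`
#'   (bin mean), `d_mean`, `n_pairs`
#' @export
binned_curve <- function(x, pair_times, tree = NULL, n_bins = 20) {
  mat <- if (!is.null(tree)) match_tips(x, tree) else msa_matrix(x)
  if (nrow(pair_times) < n_bins)
    stop_input("fewer pairs than bins")
  d <- rowSums(mat[pair_times$m, , drop = FALSE] !=
               mat[pair_times$n, , drop = FALSE])
  tt <- pair_times$time
  uq <- sort(unique(tt))
  if (length(uq) <= n_bins) {
    bin <- match(tt, uq)
  } else {
    br <- unique(stats::quantile(tt, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- cut(tt, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  agg_t <- tapply(tt, bin, mean)
  agg_d <- tapply(d, bin, mean)
  agg_n <- tapply(d, bin, length)
  out <- data.frame(time = as.numeric(agg_t), d_mean = as.numeric(agg_d),
                    n_pairs = as.integer(agg_n))
  out <- out[order(out$time), ]
  rownames(out) <- NULL
  class(out) <- c("distance_curve", "data.frame")
  out
}

#' Estimate the mutation rate from the distance curve
#'
#' Weighted nonlinear least squares of the saturation law
#' `d(t) = plateau * (1 - exp(-mu * t))` with bin pair counts as weights;
#' the curve starts at zero and approaches the plateau (the mean Hamming
#' distance of two independent equilibrium sequences) exponentially. Both
#' `mu > 0` and the plateau are free.
#'
#' @param curve a [binned_curve()] result
#' @param L sequence length (upper bound for the plateau); optional
#' @return list with `mu`, `plateau`, `residual` (weighted RMS), `fitted`
#' @export
fit_mu <- function(curve, L = NULL) {
  if (nrow(curve) < 3) stop_input("need at least 3 bins to fit")
  if (all(curve$d_mean == 0)) stop_input("degenerate curve: all distances zero")
  plateau0 <- max(curve$d_mean)
  t_half <- curve$time[which.min(abs(curve$d_mean - plateau0 / 2))]
  mu0 <- if (t_half > 0) log(2) / t_half else 1
  df <- data.frame(t = curve$time, d = curve$d_mean, w = curve$n_pairs)
  fit <- tryCatch(
    stats::nls(d ~ plateau * (1 - exp(-mu * t)), data = df, weights = df$w,
               start = list(plateau = plateau0, mu = mu0),
               algorithm = "port",
               lower = c(plateau = 1e-8, mu = 1e-8),
               upper = c(plateau = if (is.null(L)) Inf else L, mu = Inf),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to a direct weighted least-squares search
    obj <- function(p) {
      pred <- exp(p[1]) * (1 - exp(-exp(p[2]) * df$t))
      sum(df$w * (df$d - pred)^2)
    }
    op <- stats::optim(c(log(plateau0), log(mu0)), obj)
    pars <- c(plateau = exp(op$par[1]), mu = exp(op$par[2]))
    conv <- op$convergence == 0
  } else {
    pars <- stats::coef(fit)
    conv <- TRUE
  }
  if (!conv || !is.finite(pars["mu"]) || pars["mu"] <= 0)
    stop_input("mu fit did not converge; curve may be degenerate")
  fitted <- pars["plateau"] * (1 - exp(-pars["mu"] * df$t))
  resid <- sqrt(sum(df$w * (df$d - fitted)^2) / sum(df$w))
  list(mu = unname(pars["mu"]), plateau = unname(pars["plateau"]),
       residual = resid, fitted = fitted)
}

#' One-call rate estimation from MSA + tree
#'
#' Convenience wrapper chaining [leaf_pair_times()], [binned_curve()] and
#' [fit_mu()].
#'
#' @inheritParams binned_curve
#' @param tree rooted tree with branch lengths
#' @param max_pairs subsampling cap for leaf pairs
#' @param n_bins bins for the curve
#' @return as [fit_mu()], plus the `curve`
#' @export
estimate_mu <- function(x, tree, max_pairs = 2e5, n_bins = 20) {
  pt <- leaf_pair_times(tree, max_pairs = max_pairs)
  curve <- binned_curve(x, pt, tree = tree, n_bins = n_bins)
  fit <- fit_mu(curve, L = ncol(msa_matrix(x)))
  fit$curve <- curve
  fit
}
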