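#' Combine empirical correlations with corrected site profiles
#'
#' Builds the artificial pairwise frequency matrix used when only the
#' single-site correction is available:
#' `omega_ij(A,B) = f_ij(A,B) - f_i(A) f_j(B) + omega_i(A) omega_j(B)`,
#' i.e. corrected marginals with uncorrected connected correlations. The
#' combination is inconsistent in general: entries can fall outside
#' `[0, 1]`. They are counted and flagged, never clipped — only the derived
#' covariance feeds the annealer.
#'
#' @param f empirical [stationary_stats()] (with pair tables)
#' @param omega_site site-corrected [stationary_stats()] (or `L x q` matrix)
#' @return a [stationary_stats()] with provenance `"combined"` and the
#'   out-of-range count set
#' @export
combine_site_correction <- function(f, omega_site) {
  if (is.null(f$pairs)) stop_input("empirical stats must carry pair tables")
  site <- if (inherits(omega_site, "stationary_stats")) omega_site$site
          else as.matrix(omega_site)
  if (!all(dim(site) == dim(f$site))) stop_input("shape mismatch: L or q differ")
  L <- f$L; q <- f$q
  ps <- pair_sites(L)
  pairs <- f$pairs
  for (k in seq_len(nrow(ps))) {
    i <- ps[k, 1]; j <- ps[k, 2]
    pairs[, , k] <- f$pairs[, , k] - outer(f$site[i, ], f$site[j, ]) +
      outer(site[i, ], site[j, ])
  }
  oor <- sum(pairs < 0 | pairs > 1)
  stationary_stats(site, pairs, provenance = "combined",
                   n_out_of_range = oor)
}

#' Profile-sampled alignment
#'
#' Generates an `M x L` alignment whose columns are independent i.i.d.
#' draws from the target site profiles — the annealer's starting point,
#' which already has the right single-site statistics.
#'
#' @param omega_target `L x q` site profiles (or a [stationary_stats()])
#' @param M number of rows
#' @param alphabet optional [make_alphabet()]
#' @param seed optional seed
#' @return an [msa()]
#' @export
init_profile_msa <- function(omega_target, M, alphabet = NULL, seed = NULL) {
  site <- if (inherits(omega_target, "stationary_stats")) omega_target$site
          else as.matrix(omega_target)
  if (M < 1) stop_input("M must be >= 1")
  L <- nrow(site); q <- ncol(site)
  alphabet <- alphabet %||% (if (q == 4) toy_alphabet() else
    make_alphabet(c(LETTERS, letters)[seq_len(q)]))
  mat <- with_seed(seed, {
    m <- matrix(0L, M, L)
    for (i in seq_len(L))
      m[, i] <- sample.int(q, M, replace = TRUE, prob = site[i, ])
    m
  })
  msa(mat, alphabet, labels = paste0("art_", seq_len(M)))
}

#' Annealing schedule
#'
#' The inverse temperature rises geometrically over `n_stages` stages; the
#' total move budget defaults to `moves_per_cell * M * L`.
#'
#' @param n_moves total swap attempts
#' @param beta0 initial inverse temperature
#' @param beta1 final inverse temperature
#' @param n_stages number of temperature stages
#' @param seed optional seed
#' @return list with `betas` (per stage) and `moves_per_stage`
#' @export
anneal_schedule <- function(n_moves, beta0 = 10, beta1 = 1e4, n_stages = 20,
                            seed = NULL) {
  if (beta1 <= beta0) stop_input("beta must increase")
  betas <- beta0 * (beta1 / beta0)^(seq(0, 1, length.out = n_stages))
  list(betas = betas, moves_per_stage = as.integer(ceiling(n_moves / n_stages)),
       seed = seed)
}

#' Anneal an alignment toward target correlations
#'
#' Metropolis sampling over within-column permutations: each move picks a
#' random column `i` and two rows, and proposes swapping their symbols; the
#' move is accepted with probability
#' `min(1, exp(-beta * (||C' - C_target|| - ||C - C_target||)))` where
#' `||.||` is the Frobenius norm over the flattened connected-correlation
#' entries of all site pairs (diagonal one-site blocks excluded). Swaps leave
#' every column's symbol counts — hence all single-site frequencies — exactly
#' invariant. The best (closest) configuration seen is returned.
#'
#' @param x starting [msa()] (e.g. from [init_profile_msa()])
#' @param c_target target connected correlations, a `q x q x L(L-1)/2` array
#'   (e.g. from [connected_correlations()] or [target_covariance()])
#' @param schedule an [anneal_schedule()]; default budget `200 * M * L` moves
#' @return the annealed [msa()]; attributes `d_init`, `d_best`, `d_final`
#'   and the per-stage `trace` (beta, distance)
#' @export
anneal_msa <- function(x, c_target, schedule = NULL) {
  mat <- msa_matrix(x)
  q <- if (inherits(x, "msa")) x$alphabet$q else max(mat)
  M <- nrow(mat); L <- ncol(mat)
  if (!all(dim(c_target) == c(q, q, (L * (L - 1L)) %/% 2L)))
    stop_input("c_target must be q x q x L(L-1)/2")
  schedule <- schedule %||% anneal_schedule(200 * M * L)
  res <- with_seed(schedule$seed,
    cpp_anneal(mat, q, as.numeric(c_target), schedule$betas,
               schedule$moves_per_stage))
  out <- if (inherits(x, "msa"))
    msa(res$msa, x$alphabet, labels = rownames(mat)) else res$msa
  attr(out, "d_init") <- res$d_init
  attr(out, "d_best") <- res$d_best
  attr(out, "d_final") <- res$d_final
  attr(out, "trace") <- data.frame(beta = res$trace_beta, d = res$trace_d)
  out
}

#' Target covariance from corrected statistics
#'
#' Connected correlations `omega_ij - omega_i omega_j` of a corrected (or
#' combined) stats object, in the array layout [anneal_msa()] expects.
#'
#' @param stats a [stationary_stats()] with pair tables
#' @return `q x q x L(L-1)/2` array
#' @export
target_covariance <- function(stats) {
  if (is.null(stats$pairs)) stop_input("stats has no pair tables")
  connected_from(stats$site, stats$pairs)
}

#' Covariance update after one swap move (reference implementation)
#'
#' Recomputes only the `O(L q^2)` affected entries of the connected
#' correlation array after exchanging the symbols of rows `m` and `n` in
#' column `i`; equals recomputation from scratch. This is the R reference
#' for the annealer's internal incremental update.
#'
#' @param cc current connected-correlation array for `msa_before`
#' @param msa_before integer matrix before the swap
#' @param move list with `i`, `m`, `n`
#' @param q alphabet size
#' @return updated array
#' @export
incremental_covariance_update <- function(cc, msa_before, move, q) {
  i <- move$i; m <- move$m; n <- move$n
  am <- msa_before[m, i]; an <- msa_before[n, i]
  if (m == n || am == an) return(cc)
  M <- nrow(msa_before); L <- ncol(msa_before)
  dM <- 1 / M
  for (j in seq_len(L)) {
    if (j == i) next
    bm <- msa_before[m, j]; bn <- msa_before[n, j]
    if (i < j) {
      k <- pair_index(i, j, L)
      cc[am, bm, k] <- cc[am, bm, k] - dM
      cc[an, bm, k] <- cc[an, bm, k] + dM
      cc[an, bn, k] <- cc[an, bn, k] - dM
      cc[am, bn, k] <- cc[am, bn, k] + dM
    } else {
      k <- pair_index(j, i, L)
      cc[bm, am, k] <- cc[bm, am, k] - dM
      cc[bm, an, k] <- cc[bm, an, k] + dM
      cc[bn, an, k] <- cc[bn, an, k] - dM
      cc[bn, am, k] <- cc[bn, am, k] + dM
    }
  }
  cc
}
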