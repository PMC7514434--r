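#' Site and pair frequency statistics
#'
#' Container for single-site profiles and pairwise tables, either empirical
#' (`f_i`, `f_ij`) or phylogenetically corrected (`omega`). Site rows lie on
#' the simplex; pair tables sum to one except for the `combined` provenance
#' (the artificial pairwise matrix built by [combine_site_correction()]),
#' whose entries can leave `[0, 1]` and which carries an out-of-range count.
#'
#' @param site `L x q` matrix, rows on the simplex
#' @param pairs optional `q x q x L(L-1)/2` array (slab order [pair_index()])
#' @param provenance one of `"empirical-f"`, `"site-corrected-omega"`,
#'   `"pair-corrected-omega"`, `"combined"`
#' @param n_out_of_range entries outside `[0,1]` (combined provenance only)
#' @return object of class `"stationary_stats"`
#' @export
stationary_stats <- function(site, pairs = NULL,
                             provenance = c("empirical-f",
                                            "site-corrected-omega",
                                            "pair-corrected-omega",
                                            "combined"),
                             n_out_of_range = 0L) {
  provenance <- match.arg(provenance)
  site <- as.matrix(site)
  if (max(abs(rowSums(site) - 1)) > 1e-8)
    stop_input("site rows must sum to 1")
  if (!is.null(pairs)) {
    L <- nrow(site); q <- ncol(site)
    if (!all(dim(pairs) == c(q, q, (L * (L - 1L)) %/% 2L)))
      stop_input("pairs must be q x q x L(L-1)/2")
  }
  structure(list(site = site, pairs = pairs, provenance = provenance,
                 n_out_of_range = as.integer(n_out_of_range),
                 L = nrow(site), q = ncol(site)),
            class = "stationary_stats")
}

#' @export
print.stationary_stats <- function(x, ...) {
  cat("stationary_stats [", x$provenance, "]: L =", x$L, ", q =", x$q,
      if (!is.null(x$pairs)) "with pair tables" else "site-only", "\n")
  if (x$n_out_of_range > 0)
    cat("  ", x$n_out_of_range, "pair entries outside [0, 1]\n")
  invisible(x)
}

#' Empirical frequencies of an alignment
#'
#' Weighted single-site frequencies `f_i(A)` and, optionally, pairwise
#' frequencies `f_ij(A,B)` with a small pseudocount mixed toward uniform.
#' Marginal consistency `sum_B f_ij(A,B) = f_i(A)` holds exactly at
#' `pseudocount = 0`.
#'
#' @param x an [msa()] or integer matrix
#' @param q alphabet size (taken from the msa if available)
#' @param weights per-sequence weights (default 1)
#' @param pseudocount fraction of uniform admixture in `[0, 1)` (default 0)
#' @param pairs compute pair tables too?
#' @return a [stationary_stats()] with provenance `"empirical-f"`
#' @export
count_frequencies <- function(x, q = NULL, weights = NULL, pseudocount = 0,
                              pairs = TRUE) {
  mat <- msa_matrix(x)
  if (inherits(x, "msa")) q <- q %||% x$alphabet$q
  if (is.null(q)) q <- max(mat)
  M <- nrow(mat); L <- ncol(mat)
  if (M < 1L) stop_input("empty MSA")
  weights <- weights %||% rep(1, M)
  W <- sum(weights)
  f1 <- matrix(0, L, q)
  for (i in seq_len(L))
    f1[i, ] <- tabulate_weighted(mat[, i], q, weights) / W
  fp <- NULL
  if (pairs) fp <- array(cpp_pair_counts(mat, q, as.numeric(weights)),
                         dim = c(q, q, (L * (L - 1L)) %/% 2L))
  if (pseudocount > 0) {
    f1 <- (1 - pseudocount) * f1 + pseudocount / q
    if (pairs) fp <- (1 - pseudocount) * fp + pseudocount / q^2
  }
  stationary_stats(f1, fp, provenance = "empirical-f")
}

tabulate_weighted <- function(states, q, w) {
  out <- numeric(q)
  agg <- rowsum(w, states)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Connected correlations
#'
#' `c_ij(A,B) = f_ij(A,B) - f_i(A) f_j(B)` for every pair, in the same
#' `q x q x npairs` layout as the pair tables.
#'
#' @param stats a [stationary_stats()] with pair tables
#' @return array of connected correlations
#' @export
connected_correlations <- function(stats) {
  if (is.null(stats$pairs)) stop_input("stats has no pair tables")
  cc <- stats$pairs
  ps <- pair_sites(stats$L)
  for (k in seq_len(nrow(ps)))
    cc[, , k] <- cc[, , k] - outer(stats$site[ps[k, 1], ], stats$site[ps[k, 2], ])
  cc
}

# Connected correlations directly from site profile + pair array (used when
# the pair array is a corrected omega rather than part of a stats object).
connected_from <- function(site, pairs) {
  L <- nrow(site)
  cc <- pairs
  ps <- pair_sites(L)
  for (k in seq_len(nrow(ps)))
    cc[, , k] <- cc[, , k] - outer(site[ps[k, 1], ], site[ps[k, 2], ])
  cc
}

#' Similarity-based sequence reweighting
#'
#' The standard DCA baseline: each sequence gets weight `1 / n_m` where `n_m`
#' counts the alignment rows (itself included) with fractional identity at
#' least `identity_threshold`, so a cluster of near-duplicates counts as one
#' effective observation. Identity is `1 - hamming / L`; gaps count as a
#' symbol.
#'
#' @param x an [msa()] or integer matrix
#' @param identity_threshold clustering threshold (default 0.8)
#' @return numeric weight vector; `sum(w)` is the effective sample size
#' @export
reweighting_weights <- function(x, identity_threshold = 0.8) {
  cpp_reweighting(msa_matrix(x), identity_threshold)
}

#' Hamming distance
#'
#' @param a,b equal-length integer (or character) vectors
#' @return number of differing positions
#' @export
hamming <- function(a, b) {
  if (length(a) != length(b)) stop_input("sequences differ in length")
  sum(a != b)
}

#' Pearson correlation and regression slope between two statistics vectors
#'
#' Used to compare flattened frequency/correlation tables between samples:
#' Pearson `r` plus the ordinary-least-squares slope of `y` on `x`.
#'
#' @param x,y equal-length numeric vectors
#' @return list with `pearson` and `slope`
#' @export
compare_stats <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_input("vectors differ in length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_input("zero variance: comparison undefined")
  list(pearson = stats::cor(x, y),
       slope = stats::cov(x, y) / stats::var(x))
}

#' Flatten statistics for cross-sample comparison
#'
#' Concatenates all `(i, A)` site entries, or all `(i<j, A, B)` pair entries,
#' in a fixed documented order so Pearson/slope comparisons are reproducible.
#' All states are included by default; `drop_major = TRUE` removes each
#' site's (or pair's) most frequent state entries as an alternative mode.
#'
#' @param x a [stationary_stats()], a site matrix, or a pair array
#' @param what `"site"` or `"pairs"`
#' @param drop_major drop per-site dominant-state entries?
#' @return numeric vector
#' @export
flatten_stats <- function(x, what = c("site", "pairs"), drop_major = FALSE) {
  what <- match.arg(what)
  if (inherits(x, "stationary_stats"))
    x <- if (what == "site") x$site else x$pairs
  if (is.null(x)) stop_input("requested tables are absent")
  v <- as.vector(if (what == "site") t(x) else x)
  if (drop_major) {
    if (what == "site") {
      major <- apply(x, 1, which.max)
      drop <- (seq_len(nrow(x)) - 1L) * ncol(x) + major
      v <- v[-drop]
    } else {
      q2 <- dim(x)[1] * dim(x)[2]
      major <- apply(x, 3, which.max)
      drop <- (seq_len(dim(x)[3]) - 1L) * q2 + major
      v <- v[-drop]
    }
  }
  v
}

#' Write stats tables as TSV
#'
#' Site profiles as one row per site; pair tables as blocks keyed by (i, j).
#'
#' @param stats a [stationary_stats()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_stats_tsv <- function(stats, path) {
  con <- file(path, "w"); on.exit(close(con))
  q <- stats$q
  writeLines(paste0("# provenance\t", stats$provenance), con)
  writeLines(paste(c("site", paste0("state", seq_len(q))), collapse = "\t"), con)
  for (i in seq_len(stats$L))
    writeLines(paste(c(i, sprintf("%.10g", stats$site[i, ])), collapse = "\t"), con)
  if (!is.null(stats$pairs)) {
    ps <- pair_sites(stats$L)
    writeLines(paste(c("i", "j", "a", "b", "value"), collapse = "\t"), con)
    for (k in seq_len(nrow(ps)))
      for (b in seq_len(q)) for (a in seq_len(q))
        writeLines(paste(c(ps[k, 1], ps[k, 2], a, b,
                           sprintf("%.10g", stats$pairs[a, b, k])),
                         collapse = "\t"), con)
  }
  invisible(path)
}

#' Read stats tables written by [write_stats_tsv()]
#'
#' @param path TSV file
#' @return a [stationary_stats()]
#' @export
read_stats_tsv <- function(path) {
  lines <- readLines(path)
  prov <- sub("^# provenance\t", "", lines[1])
  body <- lines[-1]
  hdr2 <- grep("^i\tj\ta\tb\tvalue$", body)
  site_rows <- if (length(hdr2)) body[2:(hdr2 - 1)] else body[-1]
  site <- do.call(rbind, lapply(strsplit(site_rows, "\t"), function(t)
    as.numeric(t[-1])))
  L <- nrow(site); q <- ncol(site)
  pairs <- NULL
  if (length(hdr2)) {
    rec <- do.call(rbind, lapply(strsplit(body[(hdr2 + 1):length(body)], "\t"),
                                 as.numeric))
    pairs <- array(0, dim = c(q, q, (L * (L - 1L)) %/% 2L))
    pairs[cbind(rec[, 3], rec[, 4], pair_index(rec[, 1], rec[, 2], L))] <- rec[, 5]
  }
  oor <- if (!is.null(pairs)) sum(pairs < 0 | pairs > 1) else 0L
  stationary_stats(site, pairs, provenance = prov, n_out_of_range = oor)
}
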