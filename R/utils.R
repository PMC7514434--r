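#' @useDynLib phylopotts, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Linear index of the unordered pair (i, j), i < j, among the L*(L-1)/2 pairs,
# ordered (1,2), (1,3), ..., (1,L), (2,3), ...
#' Linear index of an unordered site pair
#'
#' Pair tables for all `L*(L-1)/2` site pairs are stored as slabs of a 3-d
#' array; this maps `(i, j)` with `i < j` to the slab index.
#'
#' @param i,j site indices (1-based, `i < j`)
#' @param L number of sites
#' @return integer index in `1..L*(L-1)/2`
#' @export
pair_index <- function(i, j, L) {
  stopifnot(all(i >= 1L), all(j <= L), all(i < j))
  (i - 1L) * L - (i * (i - 1L)) %/% 2L + (j - i)
}

# Inverse of pair_index: matrix with columns i, j for k = 1..L(L-1)/2
pair_sites <- function(L) {
  i <- rep.int(seq_len(L - 1L), times = (L - 1L):1L)
  j <- sequence((L - 1L):1L, from = 2L:L)
  cbind(i = i, j = j)
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
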