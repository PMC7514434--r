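#' Potts model over aligned sequences
#'
#' A Potts model assigns each length-`L` sequence `A = (A_1..A_L)` over a
#' `q`-letter alphabet the probability `P(A) = exp(-H(A)) / Z` with
#' Hamiltonian `H(A) = -sum_{i<j} J_ij(A_i, A_j) - sum_i h_i(A_i)`.
#' Couplings are stored once per unordered pair `i < j` (slab
#' [pair_index()] of a `q x q x L(L-1)/2` array); the accessor
#' [get_coupling()] resolves the `J_ij(A,B) = J_ji(B,A)` symmetry, which
#' prevents silent double counting in the energy.
#'
#' @param J numeric array `q x q x L(L-1)/2` of couplings (slab `k` is
#'   `J_ij` for the pair with [pair_index()] `k`), or `NULL` for zero
#' @param h numeric matrix `L x q` of fields, or `NULL` for zero
#' @param L,q dimensions (inferred from `J`/`h` when given)
#' @param alphabet an [make_alphabet()] object; default built from `q`
#' @return object of class `"potts_model"`
#' @export
potts_model <- function(J = NULL, h = NULL, L = NULL, q = NULL, alphabet = NULL) {
  if (!is.null(h)) {
    L <- L %||% nrow(h); q <- q %||% ncol(h)
  }
  if (!is.null(J)) {
    q <- q %||% dim(J)[1]
    if (is.null(L)) {
      np <- dim(J)[3]
      L <- as.integer(round((1 + sqrt(1 + 8 * np)) / 2))
    }
  }
  if (is.null(L) || is.null(q)) stop_input("cannot infer L and q")
  L <- as.integer(L); q <- as.integer(q)
  np <- (L * (L - 1L)) %/% 2L
  if (is.null(J)) J <- array(0, dim = c(q, q, np))
  if (is.null(h)) h <- matrix(0, L, q)
  if (!all(dim(J) == c(q, q, np))) stop_input("J must be q x q x L(L-1)/2")
  if (!all(dim(h) == c(L, q))) stop_input("h must be L x q")
  if (!all(is.finite(J)) || !all(is.finite(h)))
    stop_input("model parameters must be finite")
  if (is.null(alphabet)) {
    alphabet <- if (q == 4L) toy_alphabet()
    else if (q == 21L) protein_alphabet()
    else make_alphabet(c(LETTERS, letters)[seq_len(q)])
  }
  if (alphabet$q != q) stop_input("alphabet size does not match q")
  structure(list(L = L, q = q, J = J, h = h, alphabet = alphabet),
            class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  nz <- sum(apply(x$J, 3, function(m) any(m != 0)))
  cat("Potts model: L =", x$L, ", q =", x$q, ",", nz, "non-zero coupling pairs\n")
  invisible(x)
}

#' @describeIn potts_model coupling table `J_ij` for any ordered `(i, j)`,
#'   `i != j`; transposed automatically when `i > j`.
#' @param model a `potts_model`
#' @param i,j site indices
#' @export
get_coupling <- function(model, i, j) {
  if (i == j) stop_input("no self-couplings: i must differ from j")
  if (i < j) model$J[, , pair_index(i, j, model$L)]
  else t(model$J[, , pair_index(j, i, model$L)])
}

check_sequence <- function(model, seq) {
  seq <- as.integer(seq)
  if (length(seq) != model$L)
    stop_input("sequence length ", length(seq), " != L = ", model$L)
  if (any(seq < 1L) || any(seq > model$q))
    stop_input("sequence states must lie in 1..q")
  seq
}

#' Potts energy of a sequence
#'
#' Computes `H(A) = -sum_{i<j} J_ij(A_i, A_j) - sum_i h_i(A_i)`.
#'
#' @param model a [potts_model()]
#' @param seq integer vector of length `L` with states in `1..q`
#' @return scalar energy
#' @export
hamiltonian <- function(model, seq) {
  seq <- check_sequence(model, seq)
  cpp_hamiltonian(model$J, model$h, matrix(seq, nrow = 1))[1]
}

#' Potts energies of many sequences
#'
#' @param model a [potts_model()]
#' @param msa integer matrix, one sequence per row
#' @return numeric vector of energies
#' @export
hamiltonian_msa <- function(model, msa) {
  msa <- msa_matrix(msa)
  if (ncol(msa) != model$L) stop_input("MSA width != model L")
  cpp_hamiltonian(model$J, model$h, msa)
}

#' Sparse ferromagnetic toy model
#'
#' Draws the controlled ground-truth model used throughout the synthetic
#' experiments: each unordered pair carries a coupling with probability
#' `c / L` (`s_ij ~ Bernoulli(c/L)`, giving mean node degree ~ `c`), active
#' couplings are diagonal `J_ij(a,b) = x_ij delta_ab` with
#' `x_ij ~ N(mu_J, sigma_J)`, and fields are `h_i(a) ~ N(mu_h, sigma_h)`
#' (i.i.d. per `(i, a)` by default; `field_mode = "per_site"` draws one value
#' per site shared by all states).
#'
#' @param L,q model dimensions
#' @param c mean degree of the coupling graph (`c / L` must be in `[0, 1]`)
#' @param mu_J,sigma_J mean and standard deviation of active coupling values
#' @param mu_h,sigma_h mean and standard deviation of field values
#' @param field_mode `"per_entry"` (default) or `"per_site"`
#' @param seed optional integer seed (RNG state is restored afterwards)
#' @return list with `model` (a [potts_model()]) and `edges` (two-column
#'   matrix of coupled site pairs, the true contact graph)
#' @export
generate_toy_model <- function(L = 25, q = 4, c = 3, mu_J = 0.8, sigma_J = 0.2,
                               mu_h = 0, sigma_h = 0.6,
                               field_mode = c("per_entry", "per_site"),
                               seed = NULL) {
  field_mode <- match.arg(field_mode)
  if (c / L < 0 || c / L > 1) stop_input("c/L must be in [0, 1]")
  if (sigma_J < 0 || sigma_h < 0) stop_input("sigma_J, sigma_h must be >= 0")
  with_seed(seed, {
    np <- (L * (L - 1L)) %/% 2L
    s <- stats::rbinom(np, 1L, c / L)
    x <- stats::rnorm(np, mu_J, sigma_J)
    J <- array(0, dim = c(q, q, np))
    for (k in which(s == 1L)) J[, , k] <- diag(x[k], q)
    h <- if (field_mode == "per_entry") {
      matrix(stats::rnorm(L * q, mu_h, sigma_h), L, q)
    } else {
      matrix(rep(stats::rnorm(L, mu_h, sigma_h), q), L, q)
    }
    ps <- pair_sites(L)
    list(model = potts_model(J = J, h = h, L = L, q = q),
         edges = ps[s == 1L, , drop = FALSE])
  })
}

#' Paper-default toy parameters
#'
#' The frozen preset for the synthetic experiments: `L = 25`, `q = 4`,
#' `c = 3`, `mu_J = 0.8`, `sigma_J = 0.2`, `mu_h = 0`, `sigma_h = 0.6`.
#' @return named list of parameters for [generate_toy_model()]
#' @export
toy_model_params <- function() {
  list(L = 25, q = 4, c = 3, mu_J = 0.8, sigma_J = 0.2, mu_h = 0, sigma_h = 0.6)
}

#' Single-mutant energy shifts
#'
#' For a wild-type sequence `A` and every single substitution `(i, a)`,
#' `a != A_i`, computes `dH_ia = H(A^(i,a)) - H(A)` incrementally: only the
#' field at `i` and the couplings touching `i` enter the difference, which
#' equals the full re-evaluation exactly.
#'
#' @param model a [potts_model()]
#' @param wt wild-type integer sequence of length `L`
#' @return data frame with columns `i`, `a` (mutant state), `dH`;
#'   `L * (q - 1)` rows
#' @export
mutational_effects <- function(model, wt) {
  wt <- check_sequence(model, wt)
  L <- model$L; q <- model$q
  dH <- cpp_mutational_effects(model$J, model$h, wt)  # L x q, 0 at wt states
  i <- rep(seq_len(L), each = q)
  a <- rep(seq_len(q), times = L)
  keep <- a != wt[i]
  data.frame(i = i[keep], a = a[keep], dH = as.vector(t(dH))[keep])
}

#' Zero-sum gauge
#'
#' Returns the gauge-equivalent model whose coupling tables have zero row and
#' column sums, with the shifts absorbed into the fields (made zero-mean per
#' site; the residual constant is dropped). Sequence probabilities are
#' unchanged: energies shift by a sequence-independent constant.
#'
#' @param model a [potts_model()]
#' @return a [potts_model()] in zero-sum gauge
#' @export
zero_sum_gauge <- function(model) {
  L <- model$L; q <- model$q
  J <- model$J; h <- model$h
  ps <- pair_sites(L)
  for (k in seq_len(nrow(ps))) {
    Jk <- J[, , k]
    rm_ <- rowMeans(Jk); cm <- colMeans(Jk); mm <- mean(Jk)
    J[, , k] <- Jk - outer(rm_, rep(1, q)) - outer(rep(1, q), cm) + mm
    # absorbed into fields: h_i(A) += mean_B J_ij(A,B), h_j(B) += mean_A J_ij(A,B)
    h[ps[k, 1], ] <- h[ps[k, 1], ] + rm_ - mm
    h[ps[k, 2], ] <- h[ps[k, 2], ] + cm - mm
  }
  h <- h - rowMeans(h)
  potts_model(J = J, h = h, L = L, q = q, alphabet = model$alphabet)
}

#' Coupling strength scores
#'
#' Frobenius norms of the coupling tables in zero-sum gauge, the standard
#' ranking statistic for contact prediction. The diagonal is `NA`. The
#' average-product correction is available but off by default.
#'
#' @param model a [potts_model()]
#' @param apc apply the average-product correction?
#' @return symmetric `L x L` matrix of scores with `NA` diagonal
#' @export
coupling_scores <- function(model, apc = FALSE) {
  zs <- zero_sum_gauge(model)
  L <- model$L
  F_ <- matrix(0, L, L)
  ps <- pair_sites(L)
  fr <- sqrt(apply(zs$J^2, 3, sum))
  F_[ps] <- fr
  F_ <- F_ + t(F_)
  if (apc) {
    diag(F_) <- NA
    rm_ <- rowMeans(F_, na.rm = TRUE)
    F_ <- F_ - outer(rm_, rm_) / mean(F_[ps])
    F_ <- (F_ + t(F_)) / 2
  }
  diag(F_) <- NA
  F_
}

#' Read/write the plain-text Potts model format
#'
#' Key/value format: a header `L <L>`, `q <q>`, `alphabet <symbols>` followed
#' by lines `J i j a b value` and `h i a value` with 1-based site indices and
#' symbols as letters. Missing entries are zero.
#'
#' @param model a [potts_model()]
#' @param path file path
#' @param drop_zeros omit zero entries when writing
#' @return `read_potts_model` returns a [potts_model()];
#'   `write_potts_model` returns `path` invisibly.
#' @export
write_potts_model <- function(model, path, drop_zeros = TRUE) {
  sym <- model$alphabet$symbols
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("L", model$L), paste("q", model$q),
               paste("alphabet", paste(sym, collapse = ""))), con)
  ps <- pair_sites(model$L)
  for (k in seq_len(nrow(ps))) {
    Jk <- model$J[, , k]
    for (a in seq_len(model$q)) for (b in seq_len(model$q)) {
      if (!drop_zeros || Jk[a, b] != 0)
        writeLines(sprintf("J %d %d %s %s %.17g", ps[k, 1], ps[k, 2],
                           sym[a], sym[b], Jk[a, b]), con)
    }
  }
  for (i in seq_len(model$L)) for (a in seq_len(model$q)) {
    if (!drop_zeros || model$h[i, a] != 0)
      writeLines(sprintf("h %d %s %.17g", i, sym[a], model$h[i, a]), con)
  }
  invisible(path)
}

#' @rdname write_potts_model
#' @export
read_potts_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  hdr <- function(key) {
    hit <- which(vapply(toks, function(t) t[1] == key, logical(1)))
    if (!length(hit)) stop_input("model file missing header '", key, "'")
    toks[[hit[1]]][2]
  }
  L <- as.integer(hdr("L")); q <- as.integer(hdr("q"))
  alphabet <- make_alphabet(strsplit(hdr("alphabet"), "")[[1]])
  if (alphabet$q != q) stop_input("alphabet length != q in model file")
  J <- array(0, dim = c(q, q, (L * (L - 1L)) %/% 2L))
  h <- matrix(0, L, q)
  for (t in toks) {
    if (t[1] == "J") {
      i <- as.integer(t[2]); j <- as.integer(t[3])
      a <- encode_symbols(t[4], alphabet); b <- encode_symbols(t[5], alphabet)
      v <- as.numeric(t[6])
      if (i < j) J[a, b, pair_index(i, j, L)] <- v
      else if (i > j) J[b, a, pair_index(j, i, L)] <- v
      else stop_input("self-coupling J ", i, " ", j, " in model file")
    } else if (t[1] == "h") {
      h[as.integer(t[2]), encode_symbols(t[3], alphabet)] <- as.numeric(t[4])
    }
  }
  potts_model(J = J, h = h, L = L, q = q, alphabet = alphabet)
}
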