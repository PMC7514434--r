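#' Symbol alphabets
#'
#' An alphabet is a bijection between `q` unique single-character symbols and
#' the integer states `1..q`. The toy model uses four abstract states written
#' `A`, `B`, `C`, `D`; protein mode uses the 20 amino acids plus the gap
#' character `-` (q = 21).
#'
#' @param symbols character vector of unique single characters
#' @return an object of class `"alphabet"` with elements `q` and `symbols`
#' @examples
#' make_alphabet(c("A", "B", "C", "D"))
#' @export
make_alphabet <- function(symbols) {
  symbols <- as.character(symbols)
  if (length(symbols) < 2L) stop_input("alphabet needs at least 2 symbols")
  if (anyDuplicated(symbols)) stop_input("alphabet symbols must be unique")
  if (any(nchar(symbols) != 1L)) stop_input("alphabet symbols must be single characters")
  structure(list(q = length(symbols), symbols = symbols), class = "alphabet")
}

#' @rdname make_alphabet
#' @export
toy_alphabet <- function() make_alphabet(c("A", "B", "C", "D"))

#' @rdname make_alphabet
#' @export
protein_alphabet <- function() {
  make_alphabet(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                  "P", "Q", "R", "S", "T", "V", "W", "Y", "-"))
}

#' @export
print.alphabet <- function(x, ...) {
  cat("alphabet of size", x$q, ":", paste(x$symbols, collapse = " "), "\n")
  invisible(x)
}

# symbols -> integer states 1..q; strict = error on unknown symbols,
# otherwise unknowns map to the gap/last symbol with a message.
encode_symbols <- function(chars, alphabet, strict = TRUE) {
  idx <- match(chars, alphabet$symbols)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    if (strict)
      stop_input("unknown symbols for alphabet: ", paste(bad, collapse = ", "))
    message("mapping unknown symbols to '", alphabet$symbols[alphabet$q], "': ",
            paste(bad, collapse = ", "))
    idx[is.na(idx)] <- alphabet$q
  }
  idx
}

decode_states <- function(states, alphabet) alphabet$symbols[states]
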