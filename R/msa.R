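#' Multiple-sequence alignments
#'
#' An `msa` is an `M x L` integer matrix with states in `1..q`, unique row
#' labels, an [make_alphabet()] and optional per-row weights.
#'
#' @param mat integer matrix `M x L`, states in `1..q`
#' @param alphabet an [make_alphabet()]
#' @param labels row labels (default `seq_1..seq_M`)
#' @param weights optional per-row weights
#' @return object of class `"msa"`
#' @export
msa <- function(mat, alphabet, labels = NULL, weights = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (nrow(mat) < 1L) stop_input("MSA must have at least one row")
  if (any(mat < 1L) || any(mat > alphabet$q))
    stop_input("MSA entries must lie in 1..q")
  labels <- labels %||% rownames(mat) %||% paste0("seq_", seq_len(nrow(mat)))
  if (anyDuplicated(labels)) stop_input("MSA row labels must be unique")
  if (!is.null(weights) && length(weights) != nrow(mat))
    stop_input("weights length must equal number of rows")
  rownames(mat) <- labels
  structure(list(mat = mat, alphabet = alphabet, weights = weights),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("MSA:", nrow(x$mat), "sequences x", ncol(x$mat),
      "sites, q =", x$alphabet$q, "\n")
  invisible(x)
}

#' @export
dim.msa <- function(x) dim(x$mat)

# Accept either an msa object or a bare integer matrix.
msa_matrix <- function(x) {
  if (inherits(x, "msa")) x$mat
  else { m <- as.matrix(x); storage.mode(m) <- "integer"; m }
}

#' Read an alignment from FASTA
#'
#' Strict reader for aligned FASTA: all records must have equal length and
#' unique headers. Unknown symbols are an error unless `lenient = TRUE`, in
#' which case lowercase is uppercased and remaining unknowns map to the
#' alphabet's last symbol (the gap in protein mode), with a message.
#'
#' @param path FASTA file
#' @param alphabet an [make_alphabet()]
#' @param lenient tolerate case/unknown symbols?
#' @return an [msa()]
#' @export
read_msa <- function(path, alphabet, lenient = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_input("empty FASTA file: ", path)
  hdr_at <- grep("^>", lines)
  if (!length(hdr_at) || hdr_at[1] != 1L)
    stop_input("not a FASTA file (no leading '>'): ", path)
  labels <- sub("^>\\s*", "", lines[hdr_at])
  labels <- sub("\\s.*$", "", labels)
  if (anyDuplicated(labels))
    stop_input("duplicate FASTA headers: ",
               paste(unique(labels[duplicated(labels)]), collapse = ", "))
  ends <- c(hdr_at[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr_at), function(k) {
    paste(lines[(hdr_at[k] + 1L):ends[k]], collapse = "")
  }, character(1))
  if (any(ends < hdr_at + 1L) || any(!nzchar(seqs)))
    stop_input("FASTA record with empty sequence")
  len <- nchar(seqs)
  if (length(unique(len)) != 1L) {
    bad <- which(len != len[1])[1]
    stop_input("ragged alignment: record '", labels[bad], "' has length ",
               len[bad], ", expected ", len[1])
  }
  if (lenient) seqs <- toupper(seqs)
  mat <- do.call(rbind, lapply(strsplit(seqs, ""), encode_symbols,
                               alphabet = alphabet, strict = !lenient))
  msa(mat, alphabet, labels = labels)
}

#' Write an alignment to FASTA
#'
#' @param x an [msa()] (or integer matrix plus `alphabet`)
#' @param path output file
#' @param alphabet required when `x` is a bare matrix
#' @return `path`, invisibly
#' @export
write_msa <- function(x, path, alphabet = NULL) {
  if (inherits(x, "msa")) { alphabet <- x$alphabet; mat <- x$mat }
  else { mat <- msa_matrix(x); if (is.null(alphabet)) stop_input("alphabet required") }
  labels <- rownames(mat) %||% paste0("seq_", seq_len(nrow(mat)))
  out <- character(2L * nrow(mat))
  out[c(TRUE, FALSE)] <- paste0(">", labels)
  out[c(FALSE, TRUE)] <- apply(mat, 1, function(r)
    paste(decode_states(r, alphabet), collapse = ""))
  writeLines(out, path)
  invisible(path)
}
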