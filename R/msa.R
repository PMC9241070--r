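# Multiple sequence alignments and the position-specific frequency matrix.

#' Read an alignment (aligned FASTA or A3M)
#'
#' A3M insertion states (lowercase letters) are removed per the A3M
#' convention, after which all rows must have equal length.
#'
#' @param path Path to the alignment file.
#' @param format One of `"auto"`, `"fasta"`, `"a3m"`.  `"auto"` decides by
#'   extension (`.a3m` -> A3M).
#' @return Character vector of aligned sequences (names preserved).
#' @export
read_msa <- function(path, format = c("auto", "fasta", "a3m")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "a3m") "a3m" else "fasta"
  seqs <- as.character(Biostrings::readBStringSet(path))
  if (format == "a3m")
    seqs <- vapply(seqs, function(s) gsub("[a-z.]", "", s), character(1))
  if (length(unique(nchar(seqs))) > 1)
    stop("ragged alignment in ", path, ": row lengths ",
         paste(unique(nchar(seqs)), collapse = ", "))
  toupper(seqs)
}

#' Position-specific frequency matrix from an alignment
#'
#' Alignment columns are projected onto the query (columns where the query
#' has a gap are dropped).  For each retained column the frequencies of the
#' 20 standard amino acids are counted over the sequences holding a standard
#' residue there; nonstandard residues are ignored.  Columns where strictly
#' more than half of the sequences have a gap are masked and carry the query
#' one-hot instead, so every query residue keeps a conservation row.
#'
#' @param msa Character vector of aligned sequences (equal lengths).
#' @param query_row Index of the query sequence (default 1).
#' @return Object of class `psfm`: list with `length`, `freqs` (L x 20
#'   matrix, canonical amino-acid order), `masked` (logical per position),
#'   and `query` (the ungapped query sequence).
#' @export
psfm_from_msa <- function(msa, query_row = 1) {
  if (length(msa) == 0) stop("empty alignment")
  if (length(unique(nchar(msa))) > 1) stop("ragged alignment")
  if (query_row < 1 || query_row > length(msa))
    stop("query index out of range: ", query_row)
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  gap <- mat == "-" | mat == "."
  keep <- !gap[query_row, ]
  mat <- mat[, keep, drop = FALSE]
  gap <- gap[, keep, drop = FALSE]
  L <- ncol(mat)
  n <- nrow(mat)
  freqs <- matrix(0, L, 20, dimnames = list(NULL, .AA))
  masked <- logical(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    n_gap <- sum(gap[, j])
    std <- col[col %in% .AA]
    if (n_gap * 2 > n || length(std) == 0) {
      masked[j] <- TRUE
      q <- mat[query_row, j]
      if (!q %in% .AA)
        stop("query has nonstandard residue '", q, "' at masked position ", j)
      freqs[j, q] <- 1
    } else {
      tab <- table(factor(std, levels = .AA))
      freqs[j, ] <- as.numeric(tab) / length(std)
    }
  }
  structure(list(length = L, freqs = freqs, masked = masked,
                 query = paste(mat[query_row, ], collapse = "")),
            class = "psfm")
}

#' @export
print.psfm <- function(x, ...) {
  cat("PSFM over", x$length, "positions (", sum(x$masked),
      "masked majority-gap columns )\n")
  invisible(x)
}
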