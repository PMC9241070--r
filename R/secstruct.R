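# Secondary structure: DSSP parsing with a coordinate-based fallback.
# Four classes: helix (DSSP H/G/I), sheet (E/B), turn (T), other.

.SS_CLASSES <- c("helix", "sheet", "turn", "other")

.dssp_map <- function(code) {
  out <- rep("other", length(code))
  out[code %in% c("H", "G", "I")] <- "helix"
  out[code %in% c("E", "B")] <- "sheet"
  out[code == "T"] <- "turn"
  out
}

#' Parse a DSSP output file
#'
#' @param path Path to a `.dssp` file.
#' @param chain Optional chain filter.
#' @return Data frame with `position`, `chain`, `resno`, `klass`.
#' @export
parse_dssp <- function(path, chain = NULL) {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) != 1)
    stop("unparseable DSSP file (no residue table header): ", path)
  body <- lines[(hdr + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  resno <- suppressWarnings(as.integer(substr(body, 6, 10)))
  ch <- trimws(substr(body, 12, 12))
  ss <- substr(body, 17, 17)
  keep <- !is.na(resno)            # chain-break rows have '!' markers
  out <- data.frame(chain = ch[keep], resno = resno[keep],
                    klass = .dssp_map(trimws(ss[keep])),
                    stringsAsFactors = FALSE)
  if (!is.null(chain)) out <- out[out$chain == chain, , drop = FALSE]
  out$position <- seq_len(nrow(out))
  out[, c("position", "chain", "resno", "klass")]
}

#' Per-residue secondary structure
#'
#' Uses a DSSP file when provided; otherwise assigns a coarse secondary
#' structure from C-alpha geometry: runs with d(CA_i, CA_i+4) < 6.8 A are
#' helix, stretches with d(CA_i, CA_i+3) > 9.2 A are sheet (extended), and
#' chain reversals (angle between the i->i+1 and i+2->i+3 directions above
#' 90 degrees with d(CA_i, CA_i+3) < 7.5 A) are turns.
#'
#' @param model An `mbs_structure` (used for the fallback; may be `NULL`
#'   when `dssp_path` is given).
#' @param chain Chain identifier.
#' @param dssp_path Optional DSSP file.
#' @return Data frame with `position` and `klass`.
#' @export
secondary_structure <- function(model = NULL, chain = NULL, dssp_path = NULL) {
  if (!is.null(dssp_path)) {
    d <- parse_dssp(dssp_path, chain = chain)
    return(d[, c("position", "klass")])
  }
  if (is.null(model)) stop("need either a structure model or a DSSP file")
  a <- model$atoms
  res <- .chain_residues(model, chain)
  ca <- a[!a$is_hetero & a$chain == chain & a$name == "CA", , drop = FALSE]
  ca <- ca[!duplicated(.species_key(ca)), , drop = FALSE]
  pos <- match(.species_key(ca), res$key)
  xyz <- matrix(NA_real_, nrow(res), 3)
  xyz[pos, ] <- as.matrix(ca[, c("x", "y", "z")])
  L <- nrow(res)
  klass <- rep("other", L)
  d <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  if (L >= 5) for (i in 1:(L - 4)) {
    if (!anyNA(xyz[i:(i + 4), ]) && d(i, i + 4) < 6.8)
      klass[i:(i + 4)] <- "helix"
  }
  if (L >= 4) for (i in 1:(L - 3)) {
    if (any(klass[i:(i + 3)] == "helix") || anyNA(xyz[i:(i + 3), ])) next
    if (d(i, i + 3) > 9.2) {
      klass[i:(i + 3)] <- "sheet"
    } else if (d(i, i + 3) < 7.5) {
      v1 <- xyz[i + 1, ] - xyz[i, ]
      v2 <- xyz[i + 3, ] - xyz[i + 2, ]
      if (sum(v1 * v2) < 0) klass[i:(i + 3)] <- "turn"
    }
  }
  data.frame(position = seq_len(L), klass = klass, stringsAsFactors = FALSE)
}
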