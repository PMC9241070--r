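# Solvent accessibility: internal Shrake-Rupley computation, NACCESS-style
# .rsa parsing, and conversion of absolute to relative values.

# Bondi-style van der Waals radii (Angstrom) by element; 1.70 for others.
.VDW <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
          P = 1.80, Se = 1.90, F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)

.vdw_radius <- function(element) {
  r <- .VDW[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Theoretical maximum residue accessibilities
#'
#' Per-residue-type reference maxima (Angstrom^2) used to convert absolute to
#' relative accessibility, from the theoretical Gly-X-Gly maxima of Tien et
#' al. (2013).
#'
#' @return Named numeric vector over the 20 standard residues (3-letter
#'   codes).
#' @export
max_sasa_reference <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
}

#' Per-residue solvent accessibility by the Shrake-Rupley method
#'
#' Computes absolute SASA on the isolated protein chain: metals, waters, het
#' species and all other chains are removed first, and hydrogens are not part
#' of the surface (heavy atoms only), matching the convention of computing
#' accessibility without the metal ion.
#'
#' @param model An `mbs_structure`.
#' @param chain Chain identifier.
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param points_per_atom Mesh points per atom (default 960).
#' @return Data frame with `position`, `resid`, and `absolute` (Angstrom^2).
#' @export
sasa_shrake_rupley <- function(model, chain, probe = 1.4,
                               points_per_atom = 960) {
  a <- model$atoms
  sel <- !a$is_hetero & a$chain == chain & !.is_hydrogen(a$element)
  if (!any(sel)) stop("chain '", chain, "' has no protein atoms")
  sub <- a[sel, , drop = FALSE]
  res <- .chain_residues(model, chain)
  area <- .sasa_atoms(as.matrix(sub[, c("x", "y", "z")]),
                      .vdw_radius(sub$element), probe,
                      as.integer(points_per_atom))
  key <- .species_key(sub)
  per_res <- vapply(res$key, function(k) sum(area[key == k]), numeric(1))
  data.frame(position = res$position, resid = res$resid,
             absolute = unname(per_res), stringsAsFactors = FALSE)
}

#' Convert absolute to relative accessibility
#'
#' `relative = 100 * absolute / reference[type]`.  Nonstandard residue types
#' get relative 0 and are flagged.  Values above 100 are allowed (extended
#' conformations).
#'
#' @param absolute Numeric vector of absolute SASA per position.
#' @param residue_types 3-letter codes per position.
#' @param reference Named per-type maxima (default [max_sasa_reference()]).
#' @return Data frame with `position`, `absolute`, `relative`,
#'   `nonstandard`.
#' @export
relative_from_absolute <- function(absolute, residue_types,
                                   reference = max_sasa_reference()) {
  stopifnot(length(absolute) == length(residue_types))
  ref <- reference[toupper(residue_types)]
  nonstd <- is.na(ref)
  rel <- ifelse(nonstd, 0, 100 * absolute / ref)
  data.frame(position = seq_along(absolute), absolute = absolute,
             relative = unname(rel), nonstandard = unname(nonstd))
}

#' Parse a NACCESS-style .rsa file
#'
#' Reads the all-atom absolute and relative values from `RES` lines.  Both
#' the standard dialect (with a chain-id column) and the chain-less dialect
#' are auto-detected.
#'
#' @param path Path to an `.rsa` file.
#' @param chain Optional chain filter.
#' @return Data frame with `position`, `chain`, `resno`, `resid`,
#'   `absolute`, `relative` (empty, with a warning, for a file without RES
#'   lines).
#' @export
parse_rsa <- function(path, chain = NULL) {
  lines <- readLines(path)
  res <- grep("^RES ", lines, value = FALSE)
  if (length(res) == 0) {
    warning("no RES records in ", path)
    return(data.frame(position = integer(0), chain = character(0),
                      resno = integer(0), resid = character(0),
                      absolute = numeric(0), relative = numeric(0)))
  }
  rows <- lapply(res, function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    # RES <resid> [<chain>] <resno> <abs_all> <rel_all> ...
    has_chain <- is.na(suppressWarnings(as.numeric(tok[3])))
    k <- if (has_chain) 4L else 3L
    vals <- suppressWarnings(as.numeric(tok[(k + 1):(k + 2)]))
    if (length(tok) < k + 2 || anyNA(vals) ||
        is.na(suppressWarnings(as.integer(tok[k]))))
      stop("malformed RES record at line ", i, " of ", path)
    data.frame(chain = if (has_chain) tok[3] else "",
               resno = as.integer(tok[k]), resid = tok[2],
               absolute = vals[1], relative = vals[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(chain)) out <- out[out$chain == chain, , drop = FALSE]
  out$position <- seq_len(nrow(out))
  out[, c("position", "chain", "resno", "resid", "absolute", "relative")]
}
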