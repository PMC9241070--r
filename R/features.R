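# Assembly and on-disk representation of the L x 29 per-residue feature
# matrix describing a metal-binding site on its protein chain.

#' Construct a site feature matrix object
#'
#' Low-level constructor; see [assemble_features()] for building the matrix
#' from its per-residue ingredients.
#'
#' @param values L x 29 numeric matrix, canonical column order
#'   ([feature_names()]).
#' @param label `"physiological"`, `"adventitious"`, or `"unknown"`.
#' @param site_id Site identifier.
#' @param chain Chain of record.
#' @param positions Optional integer vector mapping rows to author residue
#'   numbers.
#' @param sequence Optional one-letter sequence (length L).
#' @return Object of class `site_features`.
#' @export
site_features <- function(values, label = "unknown", site_id = "site",
                          chain = NA_character_, positions = NULL,
                          sequence = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != 29)
    stop("feature matrix must have 29 columns, got ", ncol(values))
  colnames(values) <- feature_names()
  label <- match.arg(label, c("physiological", "adventitious", "unknown"))
  x <- structure(list(site_id = site_id, values = values, label = label,
                      chain = chain, positions = positions,
                      sequence = sequence), class = "site_features")
  validate_site_features(x)
  x
}

#' Validate the invariants of a site feature matrix
#'
#' Checks the 29-column shape, finiteness, and that the role and
#' secondary-structure one-hot blocks each sum to one per row.
#'
#' @param x A `site_features` object.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_site_features <- function(x) {
  v <- x$values
  if (ncol(v) != 29) stop("expected 29 feature columns")
  if (nrow(v) < 1) stop("empty feature matrix")
  if (!all(is.finite(v))) stop("non-finite feature values")
  if (max(abs(rowSums(v[, .COL_ROLE, drop = FALSE]) - 1)) > 1e-9)
    stop("role one-hot columns must sum to 1 per row")
  if (max(abs(rowSums(v[, .COL_SS, drop = FALSE]) - 1)) > 1e-9)
    stop("secondary-structure one-hot columns must sum to 1 per row")
  invisible(x)
}

#' @export
print.site_features <- function(x, ...) {
  cat("Site features", x$site_id, "-", nrow(x$values), "residues x 29,",
      "label:", x$label, "\n")
  invisible(x)
}

#' Assemble the 29-feature matrix for a chain
#'
#' Combines the chain sequence, binding roles, PSFM, accessibility and
#' secondary structure into the canonical L x 29 matrix.  Accessibility and
#' secondary-structure records are keyed by `position`, so their row order
#' does not matter.
#'
#' @param sequence One-letter chain sequence (string or character vector).
#' @param roles Integer vector (2 ligand, 1 environment, 0 other) of length
#'   L, e.g. from [binding_roles()].
#' @param psfm A `psfm` object with `length` L.
#' @param accessibility Data frame with `position`, `absolute`, `relative`.
#' @param secondary Data frame with `position`, `klass`.
#' @param label Site label.
#' @param site_id Site identifier.
#' @param chain Chain of record.
#' @param positions Optional author residue numbers per row.
#' @return A `site_features` object.
#' @export
assemble_features <- function(sequence, roles, psfm, accessibility,
                              secondary, label = "unknown", site_id = "site",
                              chain = NA_character_, positions = NULL) {
  if (length(sequence) == 1) sequence <- strsplit(sequence, "")[[1]]
  L <- length(sequence)
  if (length(roles) != L)
    stop("roles cover ", length(roles), " positions but the sequence has ", L)
  if (psfm$length != L)
    stop("psfm covers ", psfm$length, " positions but the sequence has ", L)
  for (nm in c("accessibility", "secondary")) {
    rec <- get(nm)
    if (!all(seq_len(L) %in% rec$position))
      stop(nm, " records do not cover positions 1..", L)
  }
  acc <- accessibility[match(seq_len(L), accessibility$position), ]
  ss <- secondary[match(seq_len(L), secondary$position), ]
  v <- matrix(0, L, 29, dimnames = list(NULL, feature_names()))
  v[, .COL_FREQ] <- psfm$freqs
  v[, .COL_ABS] <- acc$absolute
  v[, .COL_REL] <- acc$relative
  v[cbind(seq_len(L), .COL_ROLE[match(roles, c(2, 1, 0))])] <- 1
  v[cbind(seq_len(L), .COL_SS[match(ss$klass, .SS_CLASSES)])] <- 1
  site_features(v, label = label, site_id = site_id, chain = chain,
                positions = positions, sequence = sequence)
}

#' Write a site feature matrix (TSV + JSON sidecar)
#'
#' The TSV holds the L x 29 matrix at full double precision (round-trips
#' bitwise); the sidecar records the site id, label, chain, and the
#' position-to-author-numbering map.
#'
#' @param x A `site_features` object.
#' @param path Output TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_site_features <- function(x, path) {
  v <- x$values
  txt <- apply(v, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = 1)
  con <- file(path, "w")
  writeLines(paste(colnames(v), collapse = "\t"), con)
  writeLines(apply(txt, 1, paste, collapse = "\t"), con)
  close(con)
  meta <- list(site_id = x$site_id, label = x$label, chain = x$chain,
               positions = x$positions,
               sequence = if (is.null(x$sequence)) NULL
                          else paste(x$sequence, collapse = ""))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a site feature matrix written by [write_site_features()]
#'
#' @param path TSV path (expects `<path>.json` sidecar alongside).
#' @return A `site_features` object.
#' @export
read_site_features <- function(path) {
  v <- as.matrix(read.delim(path, check.names = FALSE,
                            colClasses = "numeric"))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(site_id = basename(path), label = "unknown", chain = NA)
  site_features(v, label = meta$label, site_id = meta$site_id,
                chain = if (is.null(meta$chain)) NA_character_ else meta$chain,
                positions = meta$positions,
                sequence = if (is.null(meta$sequence)) NULL
                           else strsplit(meta$sequence, "")[[1]])
}

#' Bundle labelled sites into a dataset
#'
#' @param sites List of `site_features` objects.
#' @param manifest Optional list recording how the dataset was generated.
#' @return Object of class `site_dataset`.
#' @export
site_dataset <- function(sites, manifest = NULL) {
  stopifnot(length(sites) > 0,
            all(vapply(sites, inherits, TRUE, "site_features")))
  structure(list(sites = sites,
                 labels = vapply(sites, `[[`, "", "label"),
                 site_ids = vapply(sites, `[[`, "", "site_id"),
                 manifest = manifest),
            class = "site_dataset")
}

#' @export
print.site_dataset <- function(x, ...) {
  cat("Site dataset:", length(x$sites), "sites (",
      paste(sprintf("%s %d", names(table(x$labels)), table(x$labels)),
            collapse = ", "), ")\n")
  invisible(x)
}

#' @export
`[.site_dataset` <- function(x, i) {
  site_dataset(x$sites[i], manifest = x$manifest)
}

#' @export
length.site_dataset <- function(x) length(x$sites)

#' Write a dataset directory (one TSV + sidecar per site, plus manifest)
#'
#' @param x A `site_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_site_dataset <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in x$sites)
    write_site_features(s, file.path(dir, paste0(s$site_id, ".tsv")))
  jsonlite::write_json(c(list(site_ids = x$site_ids), x$manifest),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a dataset directory written by [write_site_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `site_dataset`.
#' @export
read_site_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(man_path))
    jsonlite::read_json(man_path, simplifyVector = TRUE) else NULL
  files <- if (!is.null(manifest$site_ids))
    file.path(dir, paste0(manifest$site_ids, ".tsv"))
  else sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  site_dataset(lapply(files, read_site_features), manifest = manifest)
}

# internal: dataset/list-of-matrices coercion used by the model functions
.as_matrix_list <- function(x) {
  if (inherits(x, "site_dataset")) lapply(x$sites, `[[`, "values")
  else if (inherits(x, "site_features")) list(x$values)
  else if (is.matrix(x)) list(x)
  else if (is.list(x)) lapply(x, function(s)
    if (inherits(s, "site_features")) s$values else as.matrix(s))
  else stop("cannot interpret input as feature matrices")
}

.site_ids_of <- function(x, n) {
  if (inherits(x, "site_dataset")) x$site_ids
  else if (is.list(x) && all(vapply(x, inherits, TRUE, "site_features")))
    vapply(x, `[[`, "", "site_id")
  else if (!is.null(names(x))) names(x)
  else sprintf("site_%d", seq_len(n))
}

.labels_of <- function(x, y = NULL) {
  if (!is.null(y)) return(as.character(y))
  if (inherits(x, "site_dataset")) return(x$labels)
  stop("labels (y) are required when x is not a labelled site_dataset")
}
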