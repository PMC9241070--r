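#' Read a protein structure (PDB or mmCIF)
#'
#' Parses coordinate records into a uniform atom table.  Only the first model
#' is retained.  For atoms with alternate locations, the highest-occupancy
#' altloc is kept (ties broken by the lowest altloc character).  Hydrogens are
#' retained but identifiable by element.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param format One of `"auto"`, `"pdb"`, `"mmcif"`.  `"auto"` decides by
#'   file extension (`.cif`/`.mmcif` -> mmCIF, otherwise PDB).
#' @return An object of class `mbs_structure`: a list with `atoms` (data frame
#'   with columns `name`, `element`, `resid`, `chain`, `resno`, `insert`,
#'   `x`, `y`, `z`, `occupancy`, `altloc`, `is_hetero`), `chains`,
#'   `source_id`, and `model_number` (always 1).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb")
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    else suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE)),
    error = function(e) stop("cannot parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: ", path)
  # bio3d stores all models' rows for NMR-style PDB files only when
  # multi = TRUE; with multi = FALSE the first model is returned.  mmCIF
  # tables may still carry a model number column via the row count; bio3d
  # read.cif keeps the first model's coordinates in $atom.
  atoms <- data.frame(
    name      = as.character(at$elety),
    element   = .normalise_element(at$elesy, at$elety),
    resid     = as.character(at$resid),
    chain     = ifelse(is.na(at$chain), "", as.character(at$chain)),
    resno     = as.integer(at$resno),
    insert    = ifelse(is.na(at$insert), "", as.character(at$insert)),
    x         = as.numeric(at$x),
    y         = as.numeric(at$y),
    z         = as.numeric(at$z),
    occupancy = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    altloc    = ifelse(is.na(at$alt), "", as.character(at$alt)),
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite coordinates in ", path)
  atoms <- .resolve_altloc(atoms)
  structure(list(
    atoms = atoms,
    chains = sort(unique(atoms$chain)),
    source_id = sub("\\.[^.]*$", "", basename(path)),
    model_number = 1L), class = "mbs_structure")
}

#' @export
print.mbs_structure <- function(x, ...) {
  cat("Structure", x$source_id, "-", nrow(x$atoms), "atoms,",
      length(x$chains), "chain(s):", paste(x$chains, collapse = " "), "\n")
  invisible(x)
}

.normalise_element <- function(elesy, name) {
  e <- toupper(trimws(as.character(elesy)))
  miss <- is.na(e) | e == ""
  if (any(miss)) {
    # fall back on the first alphabetic characters of the atom name
    guess <- toupper(sub("^[0-9 ]*([A-Za-z]+).*$", "\\1", as.character(name)[miss]))
    two <- c("ZN", "FE", "CU", "MN", "MG", "CA", "NA", "CL", "CO", "NI", "SE", "BR")
    e[miss] <- ifelse(substr(guess, 1, 2) %in% two,
                      substr(guess, 1, 2), substr(guess, 1, 1))
  }
  # capitalise: ZN -> Zn
  paste0(substr(e, 1, 1), tolower(substr(e, 2, nchar(e))))
}

# keep highest-occupancy altloc per (chain, resno, insert, name);
# ties -> lowest altloc character
.resolve_altloc <- function(atoms) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  keep <- !duplicated(key[ord])
  atoms[sort(ord[keep]), , drop = FALSE]
}

.is_hydrogen <- function(element) element %in% c("H", "D")

.WATER_CODES <- c("HOH", "WAT", "DOD", "H2O")

# species key: one per residue or het molecule
.species_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid, sep = ":")
}

#' Find metal atoms in a structure
#'
#' Returns hetero atoms whose element belongs to `elements`, in file order.
#'
#' @param model An `mbs_structure`.
#' @param elements Character vector of element symbols (default Zn and Fe).
#' @return Data frame of atom rows (possibly empty), with a `row` column
#'   giving the index into `model$atoms`.
#' @export
find_metal_atoms <- function(model, elements = c("Zn", "Fe")) {
  stopifnot(inherits(model, "mbs_structure"), length(elements) > 0)
  idx <- which(model$atoms$is_hetero & model$atoms$element %in% elements)
  out <- model$atoms[idx, , drop = FALSE]
  out$row <- idx
  out
}

#' Donor atoms of a metal
#'
#' All non-hydrogen atoms strictly closer than `cutoff` to the metal,
#' excluding the metal itself and any atom whose element is in
#' `metal_elements` (atoms of other metals are never donors).
#'
#' @param model An `mbs_structure`.
#' @param metal A single row as returned by [find_metal_atoms()] (must carry
#'   its `row` index), or an atom row index.
#' @param cutoff Distance cutoff in Angstrom (default 3.0, strict `<`).
#' @param metal_elements Elements excluded from donor candidacy.
#' @return Data frame of donor atom rows with `row` and `dist` columns.
#' @export
donor_atoms <- function(model, metal, cutoff = 3.0,
                        metal_elements = c("Zn", "Fe")) {
  stopifnot(cutoff > 0)
  if (is.numeric(metal)) metal <- cbind(model$atoms[metal, , drop = FALSE],
                                        row = as.integer(metal))
  a <- model$atoms
  d <- sqrt((a$x - metal$x)^2 + (a$y - metal$y)^2 + (a$z - metal$z)^2)
  keep <- d < cutoff & !.is_hydrogen(a$element) &
    !(a$element %in% metal_elements) & seq_len(nrow(a)) != metal$row
  out <- a[keep, , drop = FALSE]
  out$row <- which(keep)
  out$dist <- d[keep]
  out
}

#' Build metal-binding sites from a structure
#'
#' One site per metal atom; metals whose protein ligand-residue sets
#' intersect are merged into a single polynuclear site.  Ligand residues
#' (first coordination sphere) are the residues or chemical species
#' containing at least one donor atom; the environment (second sphere) is
#' every other species with at least one atom strictly within `env_cutoff`
#' of any atom of any ligand residue.
#'
#' @param model An `mbs_structure`.
#' @param metals Data frame from [find_metal_atoms()]; computed with default
#'   elements when `NULL`.
#' @param donor_cutoff Metal-donor cutoff in Angstrom (default 3.0, strict).
#' @param env_cutoff Ligand-environment cutoff in Angstrom (default 5.0,
#'   strict).
#' @param metal_elements Element set used both to find metals and to exclude
#'   other metals from donor lists.
#' @return List of `metal_site` objects.
#' @export
build_sites <- function(model, metals = NULL, donor_cutoff = 3.0,
                        env_cutoff = 5.0, metal_elements = c("Zn", "Fe")) {
  stopifnot(env_cutoff > 0)
  if (is.null(metals)) metals <- find_metal_atoms(model, metal_elements)
  if (nrow(metals) == 0) return(list())
  a <- model$atoms
  keys <- .species_key(a)

  donors <- lapply(seq_len(nrow(metals)), function(i)
    donor_atoms(model, metals[i, , drop = FALSE], donor_cutoff, metal_elements))
  lig_keys <- lapply(donors, function(d) unique(keys[d$row]))
  prot_lig <- lapply(seq_along(donors), function(i)
    unique(keys[donors[[i]]$row[!a$is_hetero[donors[[i]]$row]]]))

  # union-find merge on shared protein ligand residues
  parent <- seq_len(nrow(metals))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(metals))) for (j in seq_len(i - 1L)) {
    if (length(intersect(prot_lig[[i]], prot_lig[[j]])) > 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(nrow(metals)), find, 1L)
  groups <- split(seq_len(nrow(metals)), factor(roots, levels = unique(roots)))

  sites <- lapply(seq_along(groups), function(g) {
    members <- groups[[g]]
    m_rows <- metals$row[members]
    d_rows <- sort(unique(unlist(lapply(donors[members], `[[`, "row"))))
    lk <- sort(unique(unlist(lig_keys[members])))
    # environment: species with >= 1 atom < env_cutoff from a ligand atom;
    # metal atoms (of any site) are sites themselves, never environment
    lig_atom <- which(keys %in% lk)
    cand <- setdiff(seq_len(nrow(a)), c(lig_atom, metals$row))
    env_keys <- character(0)
    if (length(cand) > 0 && length(lig_atom) > 0) {
      la <- as.matrix(a[lig_atom, c("x", "y", "z")])
      ca <- as.matrix(a[cand, c("x", "y", "z")])
      d2 <- outer(rowSums(ca^2), rowSums(la^2), "+") - 2 * ca %*% t(la)
      near <- apply(d2 < env_cutoff^2, 1, any)
      env_keys <- sort(unique(keys[cand[near]]))
    }
    env_keys <- setdiff(env_keys, lk)
    .make_site(model, a, keys, m_rows, d_rows, lk, env_keys,
               sprintf("%s_site_%d", model$source_id, g))
  })
  sites
}

.residue_table <- function(a, keys, keyset) {
  idx <- match(keyset, keys)
  data.frame(key = keyset,
             chain = a$chain[idx], resno = a$resno[idx],
             insert = a$insert[idx], resid = a$resid[idx],
             is_protein = !a$is_hetero[idx],
             is_water = a$resid[idx] %in% .WATER_CODES,
             stringsAsFactors = FALSE)
}

.make_site <- function(model, a, keys, m_rows, d_rows, lig_keys, env_keys, id) {
  lig <- .residue_table(a, keys, lig_keys)
  env <- .residue_table(a, keys, env_keys)
  don <- a[d_rows, , drop = FALSE]
  don$row <- d_rows
  # distance to the nearest metal atom of the (possibly merged) site
  mx <- a[m_rows, c("x", "y", "z"), drop = FALSE]
  don$dist <- vapply(d_rows, function(r) {
    min(sqrt((mx$x - a$x[r])^2 + (mx$y - a$y[r])^2 + (mx$z - a$z[r])^2))
  }, numeric(1))
  prot_don <- don[!don$is_hetero, , drop = FALSE]
  chain_rec <- NA_character_
  if (nrow(prot_don) > 0) {
    tab <- table(prot_don$chain)
    chain_rec <- sort(names(tab)[tab == max(tab)])[1]
  }
  met <- a[m_rows, , drop = FALSE]
  met$row <- m_rows
  structure(list(
    site_id = id,
    metal_atoms = met,
    donor_atoms = don,
    ligand_residues = lig,
    environment_residues = env,
    chain_of_record = chain_rec,
    protein_donor_count = nrow(prot_don),
    protein_ligand_count = sum(lig$is_protein),
    site_residue_count = sum(lig$is_protein) + sum(env$is_protein)),
    class = "metal_site")
}

#' @export
print.metal_site <- function(x, ...) {
  cat("Metal site", x$site_id, "\n",
      " metals:", paste(x$metal_atoms$element, collapse = ","),
      "| donors:", nrow(x$donor_atoms),
      sprintf("(%d from protein)", x$protein_donor_count), "\n",
      " ligand residues:", nrow(x$ligand_residues),
      "| environment residues:", nrow(x$environment_residues),
      "| site residues (protein):", x$site_residue_count, "\n",
      " chain of record:", x$chain_of_record, "\n")
  invisible(x)
}

#' Filter extracted sites
#'
#' Drops sites without any protein donor atom and, optionally, sites whose
#' first coordination sphere contains a heme cofactor.
#'
#' @param sites List of `metal_site` objects.
#' @param exclude_heme Drop heme-ligated sites (default TRUE).
#' @param heme_codes Het codes treated as heme.
#' @return Filtered list.
#' @export
filter_sites <- function(sites, exclude_heme = TRUE,
                         heme_codes = c("HEM", "HEA", "HEB", "HEC")) {
  keep <- vapply(sites, function(s) {
    if (s$protein_donor_count == 0) return(FALSE)
    if (exclude_heme && any(s$ligand_residues$resid %in% heme_codes))
      return(FALSE)
    TRUE
  }, logical(1))
  sites[keep]
}

# ordered protein residues of a chain (file order); positions are 1..L
.chain_residues <- function(model, chain) {
  a <- model$atoms
  sel <- !a$is_hetero & a$chain == chain
  if (!any(sel)) stop("chain '", chain, "' has no protein atoms")
  keys <- .species_key(a[sel, , drop = FALSE])
  first <- !duplicated(keys)
  data.frame(position = seq_len(sum(first)),
             key = keys[first],
             resno = a$resno[sel][first],
             insert = a$insert[sel][first],
             resid = a$resid[sel][first],
             stringsAsFactors = FALSE)
}

#' One-letter sequence of a chain's observed residues
#'
#' @param model An `mbs_structure`.
#' @param chain Chain identifier.
#' @return Character vector of one-letter codes (`X` for nonstandard).
#' @export
chain_sequence <- function(model, chain) {
  res <- .chain_residues(model, chain)
  unname(vapply(res$resid, function(r) {
    one <- suppressWarnings(bio3d::aa321(r))
    if (is.na(one) || !one %in% .AA) "X" else one
  }, character(1)))
}

#' Per-residue binding roles for a chain
#'
#' Role 2 for ligand residues (first coordination sphere), 1 for environment
#' residues of the site, 0 otherwise.  Positions follow the order of residues
#' observed in the coordinate section of the chain.
#'
#' @param site A `metal_site`.
#' @param model The `mbs_structure` the site was extracted from.
#' @param chain Chain identifier (default: the site's chain of record).
#' @return Integer vector of length L with an attribute `residues` giving the
#'   position-to-author-numbering map.
#' @export
binding_roles <- function(site, model, chain = site$chain_of_record) {
  res <- .chain_residues(model, chain)
  roles <- integer(nrow(res))
  for (deg in list(list(tab = site$environment_residues, role = 1L),
                   list(tab = site$ligand_residues, role = 2L))) {
    t <- deg$tab
    t <- t[t$is_protein & t$chain == chain, , drop = FALSE]
    if (nrow(t) == 0) next
    pos <- match(t$key, res$key)
    if (anyNA(pos))
      stop("site residue(s) not found in chain ", chain, ": ",
           paste(t$key[is.na(pos)], collapse = ", "))
    roles[pos] <- deg$role
  }
  attr(roles, "residues") <- res
  roles
}

#' Serialise sites to JSON
#'
#' @param sites List of `metal_site` objects.
#' @param path Output file; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
sites_to_json <- function(sites, path = NULL) {
  payload <- lapply(sites, function(s) list(
    site_id = s$site_id,
    metal_elements = s$metal_atoms$element,
    donor_atoms = s$donor_atoms[, c("name", "element", "chain", "resno",
                                    "resid", "dist")],
    ligand_residues = s$ligand_residues$key,
    environment_residues = s$environment_residues$key,
    chain_of_record = s$chain_of_record,
    protein_donor_count = s$protein_donor_count,
    protein_ligand_count = s$protein_ligand_count,
    site_residue_count = s$site_residue_count))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
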