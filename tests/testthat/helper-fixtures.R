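# Fixture builders used across the suite: toy structure files (PDB and
# mmCIF), alignments, NACCESS/DSSP text, and random structures for the
# distance-rule oracle tests.  Everything is generated in code at test time.

# classic two-ligand zinc site: Cys10 SG at 2.3 A and His14 NE2 at 2.1 A
# from the metal, Asp30 OD1 placed 4.8 A beyond the Cys sulfur (7.1 A from
# the metal), all on the x axis
toy_site_geometry <- function() {
  data.frame(element = c("S", "N", "O"),
             name = c("SG", "NE2", "OD1"),
             resid = c("CYS", "HIS", "ASP"),
             resno = c(10L, 14L, 30L),
             distance = c(2.3, 2.1, 7.1),
             dx = c(1, -1, 1), dy = 0, dz = 0)
}

write_toy_pdb <- function(geometry = toy_site_geometry(),
                          metal_element = "ZN") {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  generate_toy_structure(geometry, metal_element = metal_element,
                         path = path)
  path
}

# the same atom table expressed as a minimal mmCIF atom_site loop
write_mmcif_from_atoms <- function(atoms) {
  path <- withr::local_tempfile(fileext = ".cif",
                                .local_envir = parent.frame())
  hdr <- c("data_fixture", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                    "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
  occ <- if (is.null(atoms$occupancy)) rep(1, nrow(atoms)) else atoms$occupancy
  rows <- sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 %d %s %s %s 1",
                  ifelse(atoms$is_hetero, "HETATM", "ATOM"),
                  seq_len(nrow(atoms)), toupper(atoms$element), atoms$name,
                  atoms$resid, atoms$chain, atoms$resno,
                  atoms$x, atoms$y, atoms$z, occ, atoms$resno, atoms$resid,
                  atoms$chain, atoms$name)
  writeLines(c(hdr, rows), path)
  path
}

# random protein-like structure for the brute-force distance oracle: atoms
# scattered in a box around a handful of metals so donor/environment
# boundaries are exercised
random_structure_atoms <- function(n_res = 40, n_metal = 2, box = 18) {
  n <- n_res * 3
  elements <- sample(c("C", "N", "O", "S"), n, replace = TRUE,
                     prob = c(0.5, 0.2, 0.2, 0.1))
  atoms <- data.frame(
    name = paste0(elements, seq_len(n)),
    element = elements,
    resid = sample(c("CYS", "HIS", "ASP", "GLU", "ALA", "GLY"), n_res,
                   replace = TRUE)[rep(seq_len(n_res), each = 3)],
    chain = "A",
    resno = rep(seq_len(n_res), each = 3),
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    is_hetero = FALSE, stringsAsFactors = FALSE)
  metals <- data.frame(
    name = "ZN", element = "Zn", resid = "ZN", chain = "A",
    resno = 900L + seq_len(n_metal),
    x = runif(n_metal, 4, box - 4), y = runif(n_metal, 4, box - 4),
    z = runif(n_metal, 4, box - 4),
    is_hetero = TRUE, stringsAsFactors = FALSE)
  rbind(atoms, metals)
}

# independent O(n^2) recomputation of donor/ligand/environment membership
# from an atom table (strict < at both cutoffs, paper merge rule)
brute_force_sites <- function(atoms, donor_cutoff = 3.0, env_cutoff = 5.0) {
  d <- function(i, j) sqrt((atoms$x[i] - atoms$x[j])^2 +
                           (atoms$y[i] - atoms$y[j])^2 +
                           (atoms$z[i] - atoms$z[j])^2)
  key <- paste(atoms$chain, atoms$resno, atoms$insert %||% "",
               atoms$resid, sep = ":")
  metal_rows <- which(atoms$is_hetero & atoms$element %in% c("Zn", "Fe"))
  per_metal <- lapply(metal_rows, function(m) {
    don <- integer(0)
    for (i in seq_len(nrow(atoms))) {
      if (i == m) next
      if (atoms$element[i] %in% c("H", "D", "Zn", "Fe")) next
      if (d(i, m) < donor_cutoff) don <- c(don, i)
    }
    list(donors = don, lig = unique(key[don]),
         prot_lig = unique(key[don[!atoms$is_hetero[don]]]))
  })
  # merge on shared protein ligand residues
  k <- length(metal_rows)
  grp <- seq_len(k)
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (grp[i] != grp[j] &&
          length(intersect(per_metal[[i]]$prot_lig,
                           per_metal[[j]]$prot_lig)) > 0) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(unique(grp), function(g) {
    members <- which(grp == g)
    lig <- sort(unique(unlist(lapply(per_metal[members], `[[`, "lig"))))
    lig_atoms <- which(key %in% lig)
    env <- character(0)
    for (i in seq_len(nrow(atoms))) {
      if (key[i] %in% lig || i %in% metal_rows) next
      for (j in lig_atoms) {
        if (d(i, j) < env_cutoff) { env <- c(env, key[i]); break }
      }
    }
    list(metal_rows = metal_rows[members], ligands = lig,
         environment = sort(setdiff(unique(env), lig)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# NACCESS-style .rsa text
rsa_fixture_lines <- function(with_chain = TRUE) {
  if (with_chain)
    c("REM  File of summed (Sum) and % (per.) accessibilities for fixture",
      "RES CYS A  10    51.20  38.9    40.10  42.0    11.10  30.1",
      "RES HIS A  14    20.50  11.2    18.00  13.9     2.50   6.3",
      "RES ASP A  30   101.00  70.3    80.00  75.0    21.00  60.1",
      "END  Absolute sums over all chains")
  else
    c("RES CYS    10    51.20  38.9    40.10  42.0    11.10  30.1",
      "RES HIS    14    20.50  11.2    18.00  13.9     2.50   6.3")
}

# minimal classic-format DSSP text (header + residue table)
dssp_fixture_lines <- function() {
  c("==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1   10 A C  H           0   0   11",
    "    2   11 A H  G           0   0   22",
    "    3   12 A A  E           0   0    5",
    "    4   13 A G  B           0   0    9",
    "    5   14 A S  T           0   0   33",
    "    6   15 A V  S           0   0   17",
    "    7   16 A L              0   0   40")
}

# small labelled synthetic dataset shared by model-level tests
quick_dataset <- function(n = 60, seed = 400) {
  generate_dataset(n, n, seed = seed)
}

quick_config <- function() mbs_net_config(conv_channels = 16, hidden = 24)

quick_control <- function(...) {
  args <- utils::modifyList(list(max_epochs = 25, patience = 6,
                                 learning_rate = 2e-3), list(...))
  do.call(mbs_train_control, args)
}
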