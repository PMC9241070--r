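# Structure parsing and geometric site extraction.

test_that("minimal PDB parses into the expected atom table", {
  geo <- data.frame(element = "S", name = "SG", resid = "CYS", resno = 10L,
                    distance = 2.3, dx = 1, dy = 0, dz = 0)
  path <- write_toy_pdb(geo)
  m <- read_structure(path)
  expect_s3_class(m, "mbs_structure")
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$chains, "A")
  expect_setequal(m$atoms$element, c("S", "Zn"))
  expect_equal(sum(m$atoms$is_hetero), 1)
})

test_that("the same content parses identically from PDB and mmCIF", {
  path <- write_toy_pdb()
  m_pdb <- read_structure(path)
  cif <- write_mmcif_from_atoms(m_pdb$atoms)
  m_cif <- read_structure(cif)
  expect_equal(nrow(m_cif$atoms), nrow(m_pdb$atoms))
  ord_p <- order(m_pdb$atoms$resno, m_pdb$atoms$name)
  ord_c <- order(m_cif$atoms$resno, m_cif$atoms$name)
  for (col in c("x", "y", "z", "resno", "element"))
    expect_equal(m_cif$atoms[[col]][ord_c], m_pdb$atoms[[col]][ord_p])
})

test_that("only the first model of a multi-model file is retained", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  SG  CYS A  10       2.300   0.000   0.000  1.00 10.00           S",
    "ENDMDL",
    "MODEL        2",
    "ATOM      2  SG  CYS A  10       9.900   0.000   0.000  1.00 10.00           S",
    "ENDMDL", "END"), path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$x, 2.3)
})

test_that("altloc resolution keeps the highest occupancy, ties lowest char", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  SG ACYS A  10       1.000   0.000   0.000  0.40 10.00           S",
    "ATOM      2  SG BCYS A  10       2.000   0.000   0.000  0.60 10.00           S",
    "ATOM      3  CB ACYS A  10       3.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CB BCYS A  10       4.000   0.000   0.000  0.50 10.00           C",
    "END"), path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[m$atoms$name == "SG"], 2.0)  # occupancy 0.60 wins
  expect_equal(m$atoms$x[m$atoms$name == "CB"], 3.0)  # tie -> altloc A
})

test_that("unreadable and empty inputs error informatively", {
  bad <- withr::local_tempfile(fileext = ".cif")
  writeLines("this is not a structure", bad)
  expect_error(read_structure(bad), "parse|empty")
  expect_error(read_structure("/nonexistent/file.pdb"), "not found")
})

test_that("find_metal_atoms respects the element set and file order", {
  geo <- toy_site_geometry()
  path <- write_toy_pdb(geo)
  m <- read_structure(path)
  expect_equal(nrow(find_metal_atoms(m, "Zn")), 1)
  expect_equal(nrow(find_metal_atoms(m, "Fe")), 0)
  # Cys S is not hetero, so never a metal even if listed
  expect_equal(nrow(find_metal_atoms(m, c("S", "Zn"))), 1)
})

test_that("donor cutoff is strict and hydrogens are excluded", {
  geo <- data.frame(element = c("S", "O", "H"),
                    name = c("SG", "OD1", "HB1"),
                    resid = c("CYS", "ASP", "CYS"),
                    resno = c(10L, 30L, 10L),
                    distance = c(2.3, 3.0, 1.0),
                    dx = c(1, -1, 0), dy = c(0, 0, 1), dz = 0)
  path <- write_toy_pdb(geo)
  m <- read_structure(path)
  metal <- find_metal_atoms(m, "Zn")
  don <- donor_atoms(m, metal, cutoff = 3.0)
  expect_equal(don$name, "SG")      # 2.3 < 3.0 in; exactly 3.0 out; H out
})

test_that("build_sites recovers ligands and environment of the classic site", {
  path <- write_toy_pdb()
  m <- read_structure(path)
  sites <- build_sites(m, metal_elements = "Zn")
  expect_length(sites, 1)
  s <- sites[[1]]
  expect_setequal(s$ligand_residues$resid, c("CYS", "HIS"))
  # Asp30 OD1 sits 4.8 A from the Cys SG -> second sphere
  expect_equal(s$environment_residues$resid, "ASP")
  expect_equal(s$protein_donor_count, 2)
  expect_equal(s$protein_ligand_count, 2)
  expect_equal(s$site_residue_count, 3)
  expect_equal(s$chain_of_record, "A")
})

test_that("metals sharing a protein ligand merge into one polynuclear site", {
  atoms <- data.frame(
    name = c("OD1", "OD2", "ZN", "ZN"),
    element = c("O", "O", "Zn", "Zn"),
    resid = c("ASP", "ASP", "ZN", "ZN"),
    chain = "A", resno = c(5L, 5L, 901L, 902L),
    x = c(0, 1.5, -1.5, 3.0), y = 0, z = 0,
    is_hetero = c(FALSE, FALSE, TRUE, TRUE))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(atoms, path)
  m <- read_structure(path)
  sites <- build_sites(m, metal_elements = "Zn")
  expect_length(sites, 1)
  expect_equal(nrow(sites[[1]]$metal_atoms), 2)
})

test_that("filter_sites drops protein-donor-free and heme sites", {
  water_site <- list(protein_donor_count = 0,
                     ligand_residues = data.frame(resid = "HOH"))
  heme_site <- list(protein_donor_count = 1,
                    ligand_residues = data.frame(resid = c("HEM", "HIS")))
  good_site <- list(protein_donor_count = 2,
                    ligand_residues = data.frame(resid = c("CYS", "HIS")))
  class(water_site) <- class(heme_site) <- class(good_site) <- "metal_site"
  out <- filter_sites(list(water_site, heme_site, good_site))
  expect_length(out, 1)
  expect_equal(out[[1]]$protein_donor_count, 2)
  expect_length(filter_sites(list(heme_site), exclude_heme = FALSE), 1)
})

test_that("binding roles map ligand/environment/other to 2/1/0 positions", {
  path <- write_toy_pdb()
  m <- read_structure(path)
  s <- build_sites(m, metal_elements = "Zn")[[1]]
  roles <- binding_roles(s, m)
  # observed chain residues in file order: Cys10, His14, Asp30 -> pos 1..3
  expect_equal(as.integer(roles), c(2L, 2L, 1L))
  res <- attr(roles, "residues")
  expect_equal(res$resno, c(10L, 14L, 30L))
})

test_that("site extraction equals the brute-force distance oracle", {
  set.seed(7101)
  for (rep in 1:25) {
    atoms <- random_structure_atoms(n_res = sample(20:50, 1),
                                    n_metal = sample(1:3, 1))
    path <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(atoms, path)
    m <- read_structure(path)
    sites <- build_sites(m, metal_elements = c("Zn", "Fe"))
    oracle <- brute_force_sites(m$atoms)
    oracle <- Filter(function(o) length(o$ligands) > 0 ||
                                  length(o$environment) > 0, oracle)
    sites <- Filter(function(s) nrow(s$ligand_residues) > 0 ||
                                 nrow(s$environment_residues) > 0, sites)
    expect_equal(length(sites), length(oracle))
    key_of <- function(s) paste(sort(s$ligand_residues$key), collapse = "|")
    okey_of <- function(o) paste(sort(o$ligands), collapse = "|")
    ord_s <- order(vapply(sites, key_of, ""))
    ord_o <- order(vapply(oracle, okey_of, ""))
    for (i in seq_along(sites)) {
      s <- sites[[ord_s[i]]]; o <- oracle[[ord_o[i]]]
      expect_setequal(s$ligand_residues$key, o$ligands)
      expect_setequal(s$environment_residues$key, o$environment)
    }
  }
})

test_that("memberships are monotone in the cutoffs and merge is idempotent", {
  set.seed(7205)
  atoms <- random_structure_atoms(n_res = 40, n_metal = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(atoms, path)
  m <- read_structure(path)
  narrow <- build_sites(m, donor_cutoff = 2.6, env_cutoff = 4.0)
  wide <- build_sites(m, donor_cutoff = 3.4, env_cutoff = 6.0)
  nl <- unlist(lapply(narrow, function(s) s$ligand_residues$key))
  wl <- unlist(lapply(wide, function(s) s$ligand_residues$key))
  expect_true(all(nl %in% wl))
  ne <- unlist(lapply(narrow, function(s)
    c(s$environment_residues$key, s$ligand_residues$key)))
  we <- unlist(lapply(wide, function(s)
    c(s$environment_residues$key, s$ligand_residues$key)))
  expect_true(all(ne %in% we))
  # merged sites partition the metals; a second pass changes nothing
  sites <- build_sites(m)
  all_metals <- sort(unlist(lapply(sites, function(s) s$metal_atoms$row)))
  expect_equal(all_metals, find_metal_atoms(m)$row)
  again <- build_sites(m)
  expect_equal(lapply(again, `[[`, "ligand_residues"),
               lapply(sites, `[[`, "ligand_residues"))
})

test_that("site membership is invariant under rigid motion", {
  set.seed(7309)
  atoms <- random_structure_atoms(n_res = 30, n_metal = 2)
  th <- 0.8
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% R
  moved <- atoms
  moved$x <- xyz[, 1] + 11.3; moved$y <- xyz[, 2] - 4.2; moved$z <- xyz[, 3]
  site_keys <- function(a) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    write_pdb(a, path)
    s <- build_sites(read_structure(path))
    lapply(s, function(x) list(lig = sort(x$ligand_residues$key),
                               env = sort(x$environment_residues$key)))
  }
  expect_equal(site_keys(moved), site_keys(atoms))
})

test_that("sites serialise to JSON with counts and residue keys", {
  path <- write_toy_pdb()
  m <- read_structure(path)
  sites <- build_sites(m, metal_elements = "Zn")
  js <- jsonlite::fromJSON(sites_to_json(sites), simplifyVector = FALSE)
  expect_length(js, 1)
  expect_equal(js[[1]]$protein_ligand_count, 2)
  expect_equal(js[[1]]$site_residue_count, 3)
})
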