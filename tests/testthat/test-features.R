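# PSFM construction, solvent accessibility, secondary structure, and
# assembly of the 29-column feature matrix.

test_that("psfm counts frequencies, projects on the query, masks gap columns", {
  p <- psfm_from_msa(c("ACD", "ACD", "ACD"))
  expect_equal(unname(p$freqs[1, "A"]), 1)
  expect_equal(unname(p$freqs[2, "C"]), 1)
  expect_false(any(p$masked))

  p2 <- psfm_from_msa(c("AAD", "AAD", "ACD"))
  expect_equal(unname(p2$freqs[2, "A"]), 2 / 3)
  expect_equal(unname(p2$freqs[2, "C"]), 1 / 3)

  # column gapped in 2 of 3 sequences, query residue H -> masked one-hot
  p3 <- psfm_from_msa(c("AHD", "A-D", "A-D"))
  expect_true(p3$masked[2])
  expect_equal(unname(p3$freqs[2, "H"]), 1)

  # query gaps drop columns entirely
  p4 <- psfm_from_msa(c("A-D", "ACD", "ACD"))
  expect_equal(p4$length, 2)

  # nonstandard residues are ignored in the counts
  p5 <- psfm_from_msa(c("AXD", "ACD", "ACD"))
  expect_equal(unname(p5$freqs[2, "C"]), 1)
})

test_that("psfm rows are stochastic or valid one-hots (property)", {
  set.seed(911)
  alphabet <- c(mbsnet:::.AA, "-", "X")
  for (rep in 1:20) {
    n <- sample(3:12, 1); L <- sample(4:15, 1)
    msa <- replicate(n, paste(sample(alphabet, L, replace = TRUE,
                                     prob = c(rep(1, 20), 8, 1)),
                              collapse = ""))
    msa[1] <- gsub("[X-]", "A", msa[1])      # clean query
    p <- psfm_from_msa(msa)
    expect_equal(unname(rowSums(p$freqs)), rep(1, p$length),
                 tolerance = 1e-9)
    expect_true(all(p$freqs >= 0))
    if (any(p$masked))
      expect_true(all(apply(p$freqs[p$masked, , drop = FALSE], 1, max) == 1))
  }
})

test_that("psfm rejects ragged alignments and bad query indices", {
  expect_error(psfm_from_msa(c("ACD", "AC")), "ragged")
  expect_error(psfm_from_msa(c("ACD", "ACC"), query_row = 5), "out of range")
})

test_that("a3m lowercase insertions are removed on reading", {
  path <- withr::local_tempfile(fileext = ".a3m")
  writeLines(c(">q", "ACDEF", ">hit", "ACddDEF"[1]), path)
  writeLines(c(">q", "ACDEF", ">hit", "ACdeDEF"), path)
  msa <- read_msa(path)
  expect_equal(unname(nchar(msa)), c(5L, 5L))
  expect_equal(unname(msa[2]), "ACDEF")
})

test_that("isolated-residue SASA matches a 10x denser mesh within 5%", {
  geo <- data.frame(element = c("N", "C", "C", "O"),
                    name = c("N", "CA", "C", "O"),
                    resid = "ALA", resno = 1L,
                    distance = c(1.5, 2.0, 3.0, 3.8))
  path <- write_toy_pdb(geo)
  m <- read_structure(path)
  coarse <- sasa_shrake_rupley(m, "A", points_per_atom = 960)
  dense <- sasa_shrake_rupley(m, "A", points_per_atom = 9600)
  expect_lt(abs(coarse$absolute - dense$absolute) / dense$absolute, 0.05)
})

test_that("a residue enclosed in a shell of atoms has near-zero SASA", {
  # central CA surrounded by a dense dodecahedral-ish shell of carbons
  sph <- function(n, r) {
    i <- seq_len(n)
    y <- 1 - 2 * (i - 0.5) / n
    rad <- sqrt(pmax(0, 1 - y^2))
    th <- pi * (3 - sqrt(5)) * i
    data.frame(x = r * cos(th) * rad, y = r * y, z = r * sin(th) * rad)
  }
  shell <- sph(80, 3.4)
  atoms <- data.frame(
    name = c("CA", paste0("C", seq_len(nrow(shell)))),
    element = "C",
    resid = c("GLY", rep("ALA", nrow(shell))),
    chain = "A",
    resno = c(1L, rep(2L, nrow(shell))),
    x = c(0, shell$x), y = c(0, shell$y), z = c(0, shell$z),
    is_hetero = FALSE)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(atoms, path)
  m <- read_structure(path)
  out <- sasa_shrake_rupley(m, "A")
  expect_equal(out$absolute[out$resid == "GLY"], 0, tolerance = 1e-6)
})

test_that("SASA is local: removing a distant atom changes nothing", {
  geo <- toy_site_geometry()
  far <- data.frame(element = "C", name = "CB", resid = "ALA", resno = 90L,
                    distance = 40, dx = 0, dy = 0, dz = 1)
  with_far <- write_toy_pdb(rbind(geo, far))
  without <- write_toy_pdb(geo)
  s1 <- sasa_shrake_rupley(read_structure(with_far), "A")
  s2 <- sasa_shrake_rupley(read_structure(without), "A")
  expect_equal(s1$absolute[match(c("CYS","HIS","ASP"), s1$resid)],
               s2$absolute[match(c("CYS","HIS","ASP"), s2$resid)])
})

test_that("per-residue SASA sums to the all-atom chain total", {
  set.seed(515)
  atoms <- random_structure_atoms(n_res = 15, n_metal = 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(atoms, path)
  m <- read_structure(path)
  out <- sasa_shrake_rupley(m, "A")
  a <- m$atoms
  sel <- !a$is_hetero & a$chain == "A"
  total <- sum(mbsnet:::.sasa_atoms(as.matrix(a[sel, c("x", "y", "z")]),
                                    mbsnet:::.vdw_radius(a$element[sel]),
                                    1.4, 960L))
  expect_equal(sum(out$absolute), total, tolerance = 1e-9)
})

test_that("relative accessibility converts by the reference maxima", {
  rec <- relative_from_absolute(c(0, 167, 114.4), c("CYS", "CYS", "GLY"))
  expect_equal(rec$relative, c(0, 100, 110))
  expect_false(any(rec$nonstandard))
  odd <- relative_from_absolute(10, "XYZ")
  expect_true(odd$nonstandard)
  expect_equal(odd$relative, 0)
})

test_that("NACCESS .rsa parsing handles both dialects and empty files", {
  path <- withr::local_tempfile(fileext = ".rsa")
  writeLines(rsa_fixture_lines(with_chain = TRUE), path)
  rec <- parse_rsa(path)
  expect_equal(rec$absolute, c(51.2, 20.5, 101.0))
  expect_equal(rec$relative, c(38.9, 11.2, 70.3))
  expect_equal(rec$chain, rep("A", 3))

  path2 <- withr::local_tempfile(fileext = ".rsa")
  writeLines(rsa_fixture_lines(with_chain = FALSE), path2)
  rec2 <- parse_rsa(path2)
  expect_equal(rec2$absolute, c(51.2, 20.5))
  expect_equal(rec2$chain, c("", ""))

  empty <- withr::local_tempfile(fileext = ".rsa")
  writeLines("REM nothing here", empty)
  expect_warning(out <- parse_rsa(empty), "no RES")
  expect_equal(nrow(out), 0)

  bad <- withr::local_tempfile(fileext = ".rsa")
  writeLines("RES CYS A ten 51.2", bad)
  expect_error(parse_rsa(bad), "line 1")
})

test_that("DSSP states map to the four classes", {
  path <- withr::local_tempfile(fileext = ".dssp")
  writeLines(dssp_fixture_lines(), path)
  rec <- parse_dssp(path, chain = "A")
  expect_equal(rec$klass,
               c("helix", "helix", "sheet", "sheet", "turn", "other",
                 "other"))
  expect_equal(rec$position, 1:7)
})

test_that("coordinate fallback returns other for chains too short to classify", {
  atoms <- data.frame(name = c("CA", "CA"), element = "C",
                      resid = c("ALA", "GLY"), chain = "A", resno = 1:2,
                      x = c(0, 3.8), y = 0, z = 0, is_hetero = FALSE)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(atoms, path)
  rec <- secondary_structure(read_structure(path), "A")
  expect_equal(rec$klass, c("other", "other"))
})

test_that("assemble_features builds the canonical 29-column matrix", {
  L <- 5
  psfm <- structure(list(length = L,
                         freqs = matrix(rep(c(1, rep(0, 19)), L), L, 20,
                                        byrow = TRUE,
                                        dimnames = list(NULL, mbsnet:::.AA)),
                         masked = rep(FALSE, L)), class = "psfm")
  acc <- data.frame(position = 1:L, absolute = 1:5 * 10,
                    relative = 1:5 * 8)
  ss <- data.frame(position = 1:L,
                   klass = c("helix", "helix", "turn", "sheet", "other"))
  roles <- c(0L, 2L, 1L, 0L, 0L)
  sf <- assemble_features(rep("A", L), roles, psfm, acc, ss,
                          label = "physiological", site_id = "t1")
  expect_equal(dim(sf$values), c(5, 29))
  expect_equal(colnames(sf$values), feature_names())
  expect_equal(unname(sf$values[2, c("role_ligand", "role_env", "role_other")]),
               c(1, 0, 0))
  expect_equal(unname(sf$values[3, c("role_ligand", "role_env", "role_other")]),
               c(0, 1, 0))
  expect_equal(rowSums(sf$values[, 26:29]), rep(1, 5))
  expect_equal(unname(sf$values[, "abs_sasa"]), 1:5 * 10)

  # record order does not matter: inputs are keyed by position
  sf2 <- assemble_features(rep("A", L), roles, psfm, acc[L:1, ], ss[L:1, ],
                           label = "physiological", site_id = "t1")
  expect_identical(sf2$values, sf$values)

  expect_error(assemble_features(rep("A", 4), roles, psfm, acc, ss),
               "roles cover")
  expect_error(assemble_features(rep("A", L), roles, psfm, acc[-2, ], ss),
               "accessibility")
})

test_that("feature matrices round-trip bitwise through TSV + sidecar", {
  set.seed(616)
  sf <- generate_site("physiological", site_id = "rt1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_features(sf, path)
  back <- read_site_features(path)
  expect_identical(unname(back$values), unname(sf$values))
  expect_equal(back$label, "physiological")
  expect_equal(back$site_id, "rt1")
  expect_equal(back$sequence, sf$sequence)
})

test_that("site datasets round-trip through a directory", {
  ds <- generate_dataset(3, 2, seed = 77)
  dir <- withr::local_tempdir()
  write_site_dataset(ds, dir)
  back <- read_site_dataset(dir)
  expect_equal(length(back), 5L)
  expect_identical(lapply(back$sites, `[[`, "values"),
                   lapply(ds$sites, `[[`, "values"))
  expect_equal(back$labels, ds$labels)
})
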