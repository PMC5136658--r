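test_that("PDB read/write round-trip preserves residues, numbering and coordinates", {
  b <- build_bundle(bundle_spec(seed = 2, residues_per_helix = 12))
  path <- tempfile(fileext = ".pdb")
  write_structure(b$model, path)
  m2 <- read_structure(path)
  expect_equal(nrow(m2$atoms), nrow(b$model$atoms))
  expect_equal(m2$atoms$resno, b$model$atoms$resno)
  expect_equal(m2$atoms$resname, b$model$atoms$resname)
  expect_lt(max(abs(as.matrix(m2$atoms[, c("x", "y", "z")]) -
                    as.matrix(b$model$atoms[, c("x", "y", "z")]))), 1.5e-3)
})

test_that("two-atom fixture parses with coordinates equal to the file values", {
  path <- write_pdb_lines(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 11.104, 6.134, -6.504),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 11.639, 6.071, -5.147)))
  m <- read_structure(path)
  expect_equal(length(unique(m$atoms$chain)), 1)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x, c(11.104, 11.639))
  expect_equal(m$atoms$z, c(-6.504, -5.147))
})

test_that("altloc resolution keeps highest occupancy with alphabetical tie-break", {
  mk <- function(occ_a, occ_b) write_pdb_lines(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = occ_a, altloc = "A"),
    pdb_atom_line(3, "CA", "ALA", "A", 1, 2.0, 0, 0, occ = occ_b, altloc = "B")))
  keep_a <- read_structure(mk(0.6, 0.4))
  expect_equal(keep_a$atoms$x[keep_a$atoms$elety == "CA"], 1.0)
  keep_b <- read_structure(mk(0.4, 0.6))
  expect_equal(keep_b$atoms$x[keep_b$atoms$elety == "CA"], 2.0)
  tie <- read_structure(mk(0.5, 0.5))
  expect_equal(tie$atoms$x[tie$atoms$elety == "CA"], 1.0)
  expect_equal(sum(tie$atoms$elety == "CA"), 1L)
})

test_that("degenerate files raise informative errors", {
  empty <- tempfile(fileext = ".pdb")
  file.create(empty)
  expect_error(read_structure(empty), "empty")
  garbage <- write_pdb_lines(c("REMARK nothing here"))
  expect_error(read_structure(garbage), "empty|parse")
})

test_that("mmCIF atom_site records are read with author numbering", {
  path <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_test", "loop_", "_atom_site.group_PDB", "_atom_site.id",
    "_atom_site.type_symbol", "_atom_site.label_atom_id",
    "_atom_site.label_alt_id", "_atom_site.label_comp_id",
    "_atom_site.label_asym_id", "_atom_site.label_entity_id",
    "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . GLU A 1 518 ? 1.0 2.0 3.0 1.00 10.0 ? 518 GLU A N 1",
    "ATOM 2 C CA . GLU A 1 518 ? 2.0 2.5 3.5 1.00 10.0 ? 518 GLU A CA 1"),
    path)
  m <- read_structure(path)
  expect_equal(m$source_format, "mmcif")
  expect_equal(unique(m$atoms$resno), 518L)
})

test_that("chain_sequence maps residue names and numbering index-by-index", {
  path <- write_pdb_lines(c(
    pdb_atom_line(1, "CA", "GLU", "A", 518, 0, 0, 0),
    pdb_atom_line(2, "CA", "ARG", "A", 519, 3.8, 0, 0),
    pdb_atom_line(3, "CA", "TRP", "A", 520, 7.6, 0, 0)))
  s <- chain_sequence(read_structure(path), "A")
  expect_equal(s$sequence, "ERW")
  expect_equal(s$numbering, c(518L, 519L, 520L))
  expect_error(chain_sequence(read_structure(path), "B"), "unknown chain")
})

test_that("nonstandard residues become X and length matches residue count", {
  path <- write_pdb_lines(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "MSE", "A", 2, 3.8, 0, 0),
    pdb_atom_line(3, "CA", "GLY", "A", 3, 7.6, 0, 0)))
  s <- chain_sequence(read_structure(path, keep_het = TRUE), "A")
  expect_equal(s$sequence, "AXG")
  b <- build_bundle(bundle_spec(seed = 1, residues_per_helix = 10))
  s2 <- chain_sequence(b$model, "A")
  expect_equal(nchar(s2$sequence), length(s2$numbering))
})

test_that("missing_report lists absent and CA-less annotated residues", {
  b <- build_bundle(bundle_spec(seed = 3, residues_per_helix = 12))
  expect_equal(nrow(missing_report(b$model, b$tm)), 0)
  a <- b$model$atoms
  a <- a[a$resno != 105, , drop = FALSE]                  # delete one residue
  a <- a[!(a$resno == 203 & a$elety == "CA"), , drop = FALSE]  # strip one CA
  m2 <- as_tmd_structure(a, "edited", "synthetic")
  rep <- missing_report(m2, b$tm)
  expect_setequal(rep$resno, c(105L, 203L))
  expect_equal(rep$status[rep$resno == 105], "absent")
  expect_equal(rep$status[rep$resno == 203], "incomplete")
})

test_that("TM annotation validates ranges and reads from YAML", {
  expect_error(tm_annotation(list(TM1 = c(1, 5))), "missing|shorter")
  good <- stats::setNames(lapply(0:6, function(k) c(k * 20 + 1, k * 20 + 15)),
                          paste0("TM", 1:7))
  tm <- tm_annotation(good, chain = "B", ec_end_tm1 = "last")
  expect_equal(tm$chain, "B")
  bad <- good; bad$TM2 <- c(10, 30)
  expect_error(tm_annotation(bad), "overlap")
  path <- tempfile(fileext = ".yaml")
  writeLines(c("chain: A", "extracellular_end_of_TM1: first", "helices:",
               paste0("  TM", 1:7, ": [", seq(1, 121, 20), ", ",
                      seq(15, 135, 20), "]")), path)
  tm2 <- read_tm_annotation(path)
  expect_equal(tm2$ranges$TM3, c(41, 55))
})
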