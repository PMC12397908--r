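test_that("a single ATOM record parses to its coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$x, m$y, m$z), c(1, 2, 3))
  expect_equal(m$chain, "A")
})

test_that("write/read round-trip preserves coordinates to PDB precision", {
  hp <- make_hinge_protein(50, 50, 35)
  m <- trace_to_model(hp$confA)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2), nrow(m))
  expect_lt(max(abs(as.matrix(m[, c("x", "y", "z")]) -
                    as.matrix(m2[, c("x", "y", "z")]))), 1e-3)
})

test_that("an empty model writes a file containing only END", {
  m <- structure_model(data.frame(chain = character(0), resno = integer(0),
                                  resid = character(0), elety = character(0),
                                  x = numeric(0), y = numeric(0),
                                  z = numeric(0)))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  expect_identical(readLines(f), "END")
})

test_that("coordinates beyond the fixed-width field range are refused", {
  m <- structure_model(data.frame(chain = "A", resno = 1, resid = "ALA",
                                  elety = "CA", x = 1e6, y = 0, z = 0))
  expect_error(write_structure(m, withr::local_tempfile(fileext = ".pdb")),
               "field range")
})

test_that("duplicated atom records are rejected", {
  atoms <- data.frame(chain = "A", resno = c(1, 1), resid = "ALA",
                      elety = "CA", x = c(0, 1), y = 0, z = 0)
  expect_error(structure_model(atoms), "duplicated")
})

test_that("altloc policy keeps the highest-occupancy conformer, ties alphabetical", {
  atoms <- data.frame(chain = "A", resno = 1, resid = "SER", elety = "OG",
                      x = c(0, 5), y = 0, z = 0, o = c(0.4, 0.6),
                      alt = c("A", "B"))
  m <- structure_model(atoms)
  expect_equal(nrow(m), 1)
  expect_equal(m$x, 5)  # the 0.6-occupancy B conformer
  atoms$o <- c(0.5, 0.5)
  expect_equal(structure_model(atoms)$x, 0)  # tie: alphabetically first
})

test_that("waters are dropped by default and heteroatoms kept", {
  atoms <- data.frame(chain = "A", resno = c(1, 2, 901),
                      resid = c("ALA", "HOH", "FAD"),
                      elety = c("CA", "O", "N5"),
                      x = 0:2, y = 0, z = 0, het = c(FALSE, TRUE, TRUE))
  m <- structure_model(atoms)
  expect_equal(m$resid, c("ALA", "FAD"))
})

test_that("CA extraction skips residues lacking CA, with a warning", {
  atoms <- data.frame(chain = "A", resno = c(1, 2, 3, 3),
                      resid = "ALA", elety = c("CA", "N", "CA", "N"),
                      x = c(0, 3, 7.6, 8), y = 0, z = 0)
  m <- structure_model(atoms)
  expect_warning(tr <- extract_ca_trace(m, "A"), "lack a CA")
  expect_equal(tr$resno, c(1L, 3L))
})

test_that("CA extraction is order-stable under record shuffling", {
  hp <- make_hinge_protein(20, 20, 40)
  m <- trace_to_model(hp$confA)
  set.seed(42)
  shuffled <- structure_model(as.data.frame(m)[sample(nrow(m)), ])
  t1 <- extract_ca_trace(m, "A")
  t2 <- extract_ca_trace(shuffled, "A")
  expect_equal(t2$resno, t1$resno)
  expect_equal(t2$xyz, t1$xyz)
})

test_that("hinge-generator bookkeeping flows through extraction", {
  hp <- make_hinge_protein(60, 48, 60, tail_len = 12, seed = 1)
  m <- trace_to_model(hp$confA)
  expect_equal(length(extract_ca_trace(m, "A")), 60 + 48 + 12)
  expect_error(extract_ca_trace(m, "Z"), "chain")
})

test_that("mmCIF atom_site records parse", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(minimal_cif_lines(), f)
  m <- read_structure(f)
  expect_equal(nrow(m), 2)
  expect_equal(m$x, c(1, 4.5))
  expect_equal(m$resno, c(1L, 2L))
})

test_that("unreadable input raises a parse/format error", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines("not a structure", f)
  expect_error(read_structure(f), "format")
  expect_error(read_structure("no/such/file.pdb"), "not found")
})

test_that("atom selectors resolve uniquely or report candidates", {
  atoms <- data.frame(chain = rep(c("B", "D"), each = 2),
                      resno = c(454, 901, 454, 901),
                      resid = c("LYS", "FAD", "LYS", "FAD"),
                      elety = c("NZ", "N5", "NZ", "N5"),
                      x = c(0, 3, 50, 53), y = 0, z = 0,
                      het = c(FALSE, TRUE, FALSE, TRUE))
  m <- structure_model(atoms)
  expect_equal(resolve_atom(m, atom_selector("B", "NZ", resno = 454)),
               c(0, 0, 0))
  # one FAD per chain: chain + residue-name filter is unique
  expect_equal(resolve_atom(m, atom_selector("D", "N5", resid = "FAD")),
               c(53, 0, 0))
  expect_error(resolve_atom(m, atom_selector("B", "SG", resno = 1)),
               "matches no atom")
  # two LYS 454 NZ atoms in one chain would be ambiguous; emulate by
  # dropping the chain filter via a resid-only selector over... chain B has
  # a single NZ, so force ambiguity with two FAD copies in one chain
  m2 <- structure_model(data.frame(chain = "B", resno = c(901, 902),
                                   resid = "FAD", elety = "N5",
                                   x = c(0, 9), y = 0, z = 0, het = TRUE))
  expect_error(resolve_atom(m2, atom_selector("B", "N5", resid = "FAD")),
               "ambiguous")
})
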