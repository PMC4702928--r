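# Secondary-structure assignment and element mapping.

pep_structure <- function(atoms, id = "pep") {
  st <- list(id = id, assembly_id = "1", atoms = atoms, bonds = NULL)
  class(st) <- "pdna_structure"
  st
}

test_that("an ideal alpha helix assigns H to all interior residues", {
  h <- dpimodes:::.build_peptide(18, -57, -47, rep("ALA", 18))
  ss <- assign_secondary_structure(pep_structure(h))
  expect_equal(nrow(ss), 18)
  expect_true(all(ss$raw[3:16] == "H"))
  expect_true(all(ss$element[3:16] == "Helix"))
})

test_that("an ideal antiparallel strand pair assigns E to interior residues", {
  frag <- dpimodes:::.probe_fragment("strand", "hbond", 101L, "Backbone")
  ss <- assign_secondary_structure(pep_structure(frag$atoms))
  el <- stats::setNames(ss$element, ss$resno)
  expect_equal(unname(el[as.character(frag$contact_resno)]), "Strand")
  expect_true(sum(ss$raw == "E") >= 4)
})

test_that("a fully extended isolated chain is all coil", {
  l <- dpimodes:::.build_peptide(6, -140, 140, rep("GLY", 6))
  ss <- assign_secondary_structure(pep_structure(l))
  expect_true(all(ss$raw == "C"))
  expect_true(all(ss$element == "Loop"))
})

test_that("raw code mapping matches the element definitions", {
  expect_equal(map_ss_to_element(c("H", "G", "I")), rep("Helix", 3))
  expect_equal(map_ss_to_element("E"), "Strand")
  expect_equal(map_ss_to_element(c("T", "C", "B", "S")), rep("Loop", 4))
  expect_error(map_ss_to_element("Q"), "unknown")
})

test_that("element assignment is rigid-body invariant", {
  h <- dpimodes:::.build_peptide(14, -57, -47, rep("ALA", 14))
  st <- pep_structure(h)
  base <- assign_secondary_structure(st)$element
  for (s in 1:3) {
    got <- assign_secondary_structure(apply_rigid(st, random_rigid(s)))$element
    expect_equal(got, base)
  }
})

test_that("Stride reports import and map to elements", {
  p <- withr::local_tempfile(fileext = ".stride")
  writeLines(c(
    "REM  -------------------- Secondary structure summary ----------------",
    "ASG  ALA A    1    1    C          Coil    360.00    -35.26     120.6",
    "ASG  ALA A    2    2    H    AlphaHelix    -57.00    -47.00      90.2",
    "ASG  ALA A    3    3    G      310Helix    -60.00    -30.00      80.1",
    "ASG  ALA A    4    4    E        Strand   -139.00    135.00      50.0",
    "ASG  ALA A    5    5    T          Turn    -70.00    -20.00      70.0"), p)
  ss <- import_external_ss(p, "stride")
  expect_equal(attr(ss, "source"), "stride")
  expect_equal(ss$element, c("Loop", "Helix", "Helix", "Strand", "Loop"))
})

test_that("DSSP import agrees with the internal assignment on an ideal helix", {
  h <- dpimodes:::.build_peptide(12, -57, -47, rep("ALA", 12))
  st <- pep_structure(h)
  internal <- assign_secondary_structure(st)
  # synthesize a DSSP report carrying the internal raw codes
  p <- withr::local_tempfile(fileext = ".dssp")
  hdr <- "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC"
  body <- sprintf("%5d%5d %s %s  %s", seq_len(12), seq_len(12), "P",
                  "A", internal$raw)
  writeLines(c("==== Secondary Structure Definition ====", hdr, body), p)
  ss <- import_external_ss(p, "dssp", structure = st)
  expect_equal(ss$element, internal$element)
})

test_that("a truncated external report names the first missing residue", {
  h <- dpimodes:::.build_peptide(5, -57, -47, rep("ALA", 5))
  st <- pep_structure(h)
  p <- withr::local_tempfile(fileext = ".stride")
  writeLines(c(
    "ASG  ALA P    1    1    H    AlphaHelix    -57.00    -47.00      90.2",
    "ASG  ALA P    2    2    H    AlphaHelix    -57.00    -47.00      90.2"), p)
  expect_error(import_external_ss(p, "stride", structure = st), "missing")
})
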