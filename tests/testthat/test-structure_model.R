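# Parsing, covalent topology and domain definitions.

test_that("a minimal PDB parses with one atom per line", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(p)
  st <- load_structure(p)
  expect_equal(nrow(st$atoms), 5)
  expect_equal(st$atoms$resid, rep("ALA", 5))
  expect_equal(st$atoms$chain, rep("A", 5))
})

test_that("altloc keeps the highest-occupancy conformer only", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       1.400   0.100   0.000  0.40  0.00           C",
    "END"), p)
  st <- load_structure(p)
  ca <- st$atoms[st$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.458, tolerance = 1e-6)
})

test_that("waters are dropped at load", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "HETATM    2  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "END"), p)
  st <- load_structure(p)
  expect_equal(nrow(st$atoms), 1)
})

test_that("fixture duplex round-trips through PDB text to 1e-3 A", {
  st <- fiber12()
  # atom count equals the generator's own record count
  seqv <- strsplit("GCGCAATTGCGC", "")[[1]]
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  nexp <- sum(vapply(seqv, function(b)
    nrow(dpimodes:::.fiber_template[[paste0("D", b)]]) +
      nrow(dpimodes:::.fiber_template[[paste0("D", comp[[b]])]]), 0L))
  expect_equal(nrow(st$atoms), nexp)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, p)
  st2 <- load_structure(p)
  expect_equal(nrow(st2$atoms), nrow(st$atoms))
  # align rows by identity
  key1 <- paste(st$atoms$chain, st$atoms$resno, st$atoms$elety)
  key2 <- paste(st2$atoms$chain, st2$atoms$resno, st2$atoms$elety)
  m <- match(key1, key2)
  expect_false(any(is.na(m)))
  expect_lt(max(abs(st$atoms$x - st2$atoms$x[m])), 1e-3 + 1e-9)
  expect_lt(max(abs(st$atoms$y - st2$atoms$y[m])), 1e-3 + 1e-9)
  expect_lt(max(abs(st$atoms$z - st2$atoms$z[m])), 1e-3 + 1e-9)
})

test_that("bond relation is symmetric, irreflexive, and chemically right", {
  st <- fiber12()
  b <- st$bonds
  expect_true(all(b[, 1] != b[, 2]))
  expect_true(all(b[, 1] < b[, 2]))       # stored once in canonical order
  nb <- neighbor_list(st)
  # phosphodiester continuity: every O3' links to the following P
  a <- st$atoms
  o3 <- which(a$elety == "O3'" & a$chain == "A" & a$resno < 12)
  for (i in o3) {
    partners <- nb[[i]]
    expect_true("P" %in% a$elety[partners])
  }
})

test_that("serine CB neighbors follow the amino-acid template", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  SER A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   SER A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   SER A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  SER A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "ATOM      6  OG  SER A   1       1.500  -2.080  -1.100  1.00  0.00           O",
    "END"), p)
  st <- covalent_neighbors(load_structure(p))
  nb <- neighbor_list(st)
  cb <- which(st$atoms$elety == "CB")
  expect_setequal(st$atoms$elety[nb[[cb]]], c("CA", "OG"))
})

test_that("unknown residues fall back to the 2.0 A distance rule", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  C1  XYZ A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  C2  XYZ A   1       2.500   0.000   0.000  1.00  0.00           C",
    "HETATM    3  C3  XYZ A   1       1.400   0.000   0.000  1.00  0.00           C",
    "END"), p)
  st <- suppressMessages(covalent_neighbors(load_structure(p)))
  nb <- neighbor_list(st)
  expect_false(2 %in% nb[[1]])   # 2.5 A apart: not bonded
  expect_true(3 %in% nb[[1]])    # 1.4 A apart: bonded
})

test_that("domain definition tables parse and validate", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines("1BDT\t1\tA\t1\t53\td1bdta_\ta.43.1.1", p)
  dd <- load_domain_definitions(p)
  expect_equal(nrow(dd), 1)
  expect_equal(dd$start_no, 1L)
  expect_equal(dd$end_no, 53L)
  expect_equal(dd$family_id, "a.43.1.1")

  # empty file -> empty table
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), p2)
  expect_equal(nrow(load_domain_definitions(p2)), 0)

  # inconsistent family for one domain id -> error
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1AAA\t1\tA\t1\t50\tdom1\ta.1.1.1",
               "1BBB\t1\tA\t1\t50\tdom1\tb.2.2.2"), p3)
  expect_error(load_domain_definitions(p3), "inconsistent family")

  # duplicate (structure, chain, range) -> error
  p4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1AAA\t1\tA\t1\t50\tdom1\ta.1.1.1",
               "1AAA\t1\tA\t1\t50\tdom2\ta.1.1.1"), p4)
  expect_error(load_domain_definitions(p4), "duplicate")
})
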