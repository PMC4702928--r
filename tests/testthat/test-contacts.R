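# Hydrogen-bond and hydrophobic contact detection, with brute-force
# oracles.

test_that("non-polar atom rules follow the carbon/sulphur definition", {
  fx <- fixture_one_probe("helix", "Backbone", "hydrophobic")
  st <- fx$structure
  np <- nonpolar_atoms(st)
  a <- st$atoms
  nb <- neighbor_list(st)
  # protein backbone C (bonded to O) excluded
  protC <- which(a$chain == "P" & a$elety == "C")
  expect_false(any(protC %in% np))
  # protein N/O never in the set
  expect_false(any(a$elesy[np] %in% c("N", "O")))
  # all DNA carbons included unconditionally (even C1', bonded to O4')
  dnaC <- which(a$chain %in% c("A", "B") & a$elesy == "C")
  expect_true(all(dnaC %in% np))
  # LEU side-chain carbons without N/O neighbors included
  cb <- which(a$chain == "P" & a$resid == "LEU" & a$elety == "CB")
  expect_true(cb %in% np)
})

test_that("hydrogen-bond power combines the distance ramp and geometry", {
  # two isolated O atoms with no covalent neighbors: pure distance ramp
  mk <- function(d) {
    atoms <- data.frame(
      chain = c("P", "A"), resno = c(1L, 1L), insert = "",
      resid = c("SER", "DA"), elety = c("OG", "N7"), elesy = c("O", "N"),
      x = c(0, d), y = 0, z = 0, het = FALSE, stringsAsFactors = FALSE)
    st <- list(id = "x", assembly_id = "1", atoms = atoms,
               bonds = matrix(integer(0), 0, 2))
    class(st) <- "pdna_structure"
    st
  }
  expect_equal(hydrogen_bond_power(mk(2.9), 1, 2), 1.0)
  expect_equal(hydrogen_bond_power(mk(3.35), 1, 2), 0.5, tolerance = 1e-9)
  expect_equal(hydrogen_bond_power(mk(3.8), 1, 2), 0)
  expect_error(hydrogen_bond_power({
    s <- mk(3); s$atoms$elesy[1] <- "C"; s
  }, 1, 2), "N/O")
})

test_that("bonds beyond 3.7 A are rejected before scoring", {
  st <- build_ideal_bdna("GCGCAATTGCGC")
  st <- covalent_neighbors(st)
  a <- st$atoms
  hb <- detect_hydrogen_bonds(st, which(a$chain == "A"), which(a$chain == "B"))
  expect_true(all(hb$distance < 3.7))
  expect_true(all(hb$power > 0.1))
})

test_that("line of sight: open space, midpoint blocker, off-axis clearance", {
  mk <- function(extra = NULL) {
    atoms <- data.frame(
      chain = "X", resno = seq_len(2 + NROW(extra)), insert = "",
      resid = "XYZ", elety = "C1", elesy = "C",
      x = c(0, 8, if (!is.null(extra)) extra[, 1]),
      y = c(0, 0, if (!is.null(extra)) extra[, 2]),
      z = c(0, 0, if (!is.null(extra)) extra[, 3]),
      het = TRUE, stringsAsFactors = FALSE)
    st <- list(id = "x", assembly_id = "1", atoms = atoms,
               bonds = matrix(integer(0), 0, 2))
    class(st) <- "pdna_structure"
    st
  }
  expect_true(line_of_sight(mk(), 1, 2))
  expect_false(line_of_sight(mk(matrix(c(4, 0, 0), 1)), 1, 2))
  # blocker 2.0 A off-axis: clearance exceeds the 1.70 A carbon radius
  expect_true(line_of_sight(mk(matrix(c(4, 2.0, 0), 1)), 1, 2))
})

test_that("hydrophobic clusters are single-linkage components with min size", {
  fx <- fixture_one_probe("helix", "MajorGroove", "hydrophobic")
  st <- fx$structure
  np <- nonpolar_atoms(st)
  cl <- hydrophobic_clusters(st, np)
  expect_length(cl, length(np))
  sizes <- table(cl[!is.na(cl)])
  expect_true(all(sizes >= 5))
  # the designed LEU side chain shares a cluster with DNA carbons
  a <- st$atoms
  cd1 <- which(a$resid == "LEU" & a$elety == "CD1")
  expect_true(cd1 %in% as.integer(names(cl)[!is.na(cl)]))
})

test_that("an isolated non-polar atom forms no cluster", {
  atoms <- data.frame(
    chain = "X", resno = 1:2, insert = "", resid = "XYZ",
    elety = c("C1", "C2"), elesy = "C",
    x = c(0, 30), y = 0, z = 0, het = TRUE, stringsAsFactors = FALSE)
  st <- list(id = "x", assembly_id = "1", atoms = atoms,
             bonds = matrix(integer(0), 0, 2))
  class(st) <- "pdna_structure"
  cl <- hydrophobic_clusters(st, 1:2)
  expect_true(all(is.na(cl)))
})

test_that("contact detection matches a brute-force oracle", {
  # O(n^2)/O(n^3) oracle written independently of the implementation
  oracle_hbonds <- function(st, prot, dna) {
    a <- st$atoms
    nb <- neighbor_list(st)
    out <- NULL
    for (i in prot) for (j in dna) {
      if (!(a$elesy[i] %in% c("N", "O")) || !(a$elesy[j] %in% c("N", "O")))
        next
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                       c(a$x[j], a$y[j], a$z[j]))^2))
      if (d >= 3.7) next
      if (hydrogen_bond_power(st, i, j, nb) > 0.1)
        out <- rbind(out, c(i, j))
    }
    out
  }
  oracle_los <- function(st, i, j) {
    a <- st$atoms
    rad <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
    ri <- rad[a$elesy[i]]; rj <- rad[a$elesy[j]]
    ri <- ifelse(is.na(ri), 1.70, ri); rj <- ifelse(is.na(rj), 1.70, rj)
    p <- c(a$x[i], a$y[i], a$z[i]); q <- c(a$x[j], a$y[j], a$z[j])
    L <- sqrt(sum((q - p)^2))
    if (ri + rj >= L) return(TRUE)
    vh <- (q - p) / L
    p2 <- p + ri * vh; q2 <- q - rj * vh
    for (k in seq_len(nrow(a))) {
      if (k == i || k == j || a$elesy[k] == "H") next
      rk <- rad[a$elesy[k]]; if (is.na(rk)) rk <- 1.70
      w <- c(a$x[k], a$y[k], a$z[k])
      tt <- sum((w - p2) * (q2 - p2)) / sum((q2 - p2)^2)
      tt <- min(1, max(0, tt))
      if (sqrt(sum((p2 + tt * (q2 - p2) - w)^2)) < rk) return(FALSE)
    }
    TRUE
  }
  fx <- fixture_one_probe("loop", "MajorGroove", "hydrophobic")
  st <- fx$structure
  a <- st$atoms
  prot <- which(a$chain == "P")
  dna <- which(a$chain %in% c("A", "B"))

  hb <- detect_hydrogen_bonds(st, prot, dna)
  ohb <- oracle_hbonds(st, prot, dna)
  got <- if (nrow(hb)) paste(hb$protein_atom, hb$dna_atom) else character(0)
  want <- if (!is.null(ohb)) paste(ohb[, 1], ohb[, 2]) else character(0)
  expect_setequal(got, want)

  # hydrophobic: brute-force over all nonpolar pairs
  np <- nonpolar_atoms(st)
  cl <- hydrophobic_clusters(st, np)
  hp <- detect_hydrophobic_contacts(st, prot, dna, cl)
  want <- NULL
  for (i in intersect(np, prot)) for (j in intersect(np, dna)) {
    d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - c(a$x[j], a$y[j], a$z[j]))^2))
    if (d >= 5.4) next
    if (is.na(cl[as.character(i)]) || is.na(cl[as.character(j)])) next
    if (cl[as.character(i)] != cl[as.character(j)]) next
    if (!oracle_los(st, i, j)) next
    want <- rbind(want, c(i, j))
  }
  got <- if (nrow(hp)) paste(hp$protein_atom, hp$dna_atom) else character(0)
  wantv <- if (!is.null(want)) paste(want[, 1], want[, 2]) else character(0)
  expect_setequal(got, wantv)
  expect_gt(length(got), 0)
})

test_that("adding a blocker on a contact segment removes that contact only", {
  fx <- fixture_one_probe("helix", "MajorGroove", "hydrophobic")
  st <- fx$structure
  a <- st$atoms
  prot <- which(a$chain == "P"); dna <- which(a$chain %in% c("A", "B"))
  np <- nonpolar_atoms(st)
  cl <- hydrophobic_clusters(st, np)
  hp <- detect_hydrophobic_contacts(st, prot, dna, cl)
  expect_gt(nrow(hp), 0)
  hb0 <- detect_hydrogen_bonds(st, prot, dna)
  # block the first contact's mid-segment with a metal-like hetero atom
  i <- hp$protein_atom[1]; j <- hp$dna_atom[1]
  mid <- (c(a$x[i], a$y[i], a$z[i]) + c(a$x[j], a$y[j], a$z[j])) / 2
  st2 <- st
  st2$atoms <- rbind(a, data.frame(
    chain = "Z", resno = 999L, insert = "", resid = "ZN", elety = "ZN",
    elesy = "ZN", x = mid[1], y = mid[2], z = mid[3], het = TRUE,
    stringsAsFactors = FALSE))
  st2$bonds <- st$bonds
  np2 <- nonpolar_atoms(st2)
  cl2 <- hydrophobic_clusters(st2, np2)
  hp2 <- detect_hydrophobic_contacts(st2, prot, dna, cl2)
  expect_false(paste(i, j) %in% paste(hp2$protein_atom, hp2$dna_atom))
  hb2 <- detect_hydrogen_bonds(st2, prot, dna)
  expect_equal(nrow(hb2), nrow(hb0))   # hydrogen bonds unaffected
})

test_that("contacts never involve water and are rigid-body invariant", {
  fx <- fixture_one_probe("helix", "MajorGroove", "hbond")
  st <- fx$structure
  a <- st$atoms
  expect_false(any(a$resid %in% c("HOH", "WAT")))
  prot <- which(a$chain == "P"); dna <- which(a$chain %in% c("A", "B"))
  hb0 <- detect_hydrogen_bonds(st, prot, dna)
  for (s in 1:3) {
    st2 <- apply_rigid(st, random_rigid(200 + s))
    hb <- detect_hydrogen_bonds(st2, prot, dna)
    expect_equal(paste(hb$protein_atom, hb$dna_atom),
                 paste(hb0$protein_atom, hb0$dna_atom))
    expect_equal(hb$power, hb0$power, tolerance = 1e-6)
  }
})
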