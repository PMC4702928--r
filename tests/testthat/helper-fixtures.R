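# Shared fixture constructions (built once per test run; deterministic).

fiber12 <- function() {
  key <- "test_fiber12"
  cache <- dpimodes:::.dpi_cache
  if (is.null(cache[[key]])) {
    st <- build_ideal_bdna("GCGCAATTGCGC")
    cache[[key]] <- covalent_neighbors(st)
  }
  cache[[key]]
}

fixture_one_probe <- function(kind, target, interaction = "hbond",
                              seed = 20151209) {
  key <- paste("test_fx", kind, target, interaction, seed)
  cache <- dpimodes:::.dpi_cache
  if (is.null(cache[[key]]))
    cache[[key]] <- build_fixture(
      "GCGCAATTGCGC",
      probes = list(list(kind = kind, target = target,
                         interaction = interaction)),
      seed = seed)
  cache[[key]]
}

# a small rigid-body transform generator (rotation + translation)
random_rigid <- function(rng_seed) {
  set.seed(rng_seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, 360)
  tr <- stats::rnorm(3, 0, 20)
  list(R = dpimodes:::.rotaxis(ax, ang), t = tr)
}

apply_rigid <- function(structure, rigid) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- t(rigid$R %*% t(xyz)) + matrix(rigid$t, nrow(xyz), 3, byrow = TRUE)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

# minimal single-residue PDB text
write_mini_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}
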