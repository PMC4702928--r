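# Hydrogen-bond and hydrophobic contact detection between protein domains
# and duplex DNA.

#' Non-polar atom set
#'
#' All carbon and sulphur atoms of protein that are not covalently bonded
#' to oxygen or nitrogen, and all carbon atoms of DNA (unconditionally).
#'
#' @param structure a `pdna_structure` with bonds
#'   (see [covalent_neighbors()]).
#' @return integer vector of atom row indices.
#' @export
nonpolar_atoms <- function(structure) {
  a <- structure$atoms
  nb <- neighbor_list(structure)
  isprot <- .is_aa_resid(a$resid)
  isdna <- .is_dna_resid(a$resid)
  out <- logical(nrow(a))
  cs <- which(isprot & a$elesy %in% c("C", "S"))
  for (i in cs) {
    nbs <- nb[[i]]
    if (!length(nbs) || !any(a$elesy[nbs] %in% c("O", "N"))) out[i] <- TRUE
  }
  out[isdna & a$elesy == "C"] <- TRUE
  which(out)
}

#' Hydrogen-bonding power of an N/O atom pair
#'
#' A unitless plausibility score in `[0, 1]`:
#' `f_d(d) * g_a * g_b`, where the distance factor `f_d` is 1 up to 3.0 A
#' and falls linearly to 0 at 3.7 A, and each angular factor `g` is the
#' cosine of the deviation between the contact vector and the atom's
#' idealized donor/acceptor direction (away from the mean of its covalent
#' neighbor directions), clipped to zero beyond 90 degrees.  Atoms without
#' covalent neighbors score `g = 1`.
#'
#' @param structure a `pdna_structure` with bonds.
#' @param i,j atom row indices (must be nitrogen or oxygen).
#' @param neighbors optional precomputed [neighbor_list()].
#' @return numeric score.
#' @export
hydrogen_bond_power <- function(structure, i, j, neighbors = NULL) {
  a <- structure$atoms
  if (!all(a$elesy[c(i, j)] %in% c("N", "O")))
    stop("hydrogen_bond_power is defined for N/O atoms only")
  if (is.null(neighbors)) neighbors <- neighbor_list(structure)
  pi_ <- c(a$x[i], a$y[i], a$z[i]); pj <- c(a$x[j], a$y[j], a$z[j])
  d <- sqrt(sum((pi_ - pj)^2))
  fd <- if (d <= 3.0) 1 else if (d >= 3.7) 0 else (3.7 - d) / 0.7
  gfun <- function(k, other) {
    nbs <- neighbors[[k]]
    nbs <- nbs[a$elesy[nbs] != "H"]
    if (!length(nbs)) return(1)
    pk <- c(a$x[k], a$y[k], a$z[k])
    u <- colSums(do.call(rbind, lapply(nbs, function(m) {
      v <- c(a$x[m], a$y[m], a$z[m]) - pk; v / sqrt(sum(v^2))
    })))
    if (sqrt(sum(u^2)) < 1e-8) return(1)
    ideal <- -u / sqrt(sum(u^2))
    v <- other - pk; v <- v / sqrt(sum(v^2))
    max(0, sum(ideal * v))
  }
  fd * gfun(i, pj) * gfun(j, pi_)
}

#' Detect protein-DNA hydrogen bonds
#'
#' All nitrogen/oxygen pairs with one atom in the protein domain and one in
#' the DNA duplex, center distance strictly below `max_dist` and
#' hydrogen-bonding power above `min_power`.  Ion (electrostatic) pairs
#' such as lysine NZ against phosphate oxygens are included.  Symmetric in
#' atom order.
#'
#' @param structure a `pdna_structure` with bonds.
#' @param domain_rows atom row indices of the protein domain.
#' @param dna_rows atom row indices of the duplex nucleotides.
#' @param max_dist distance cutoff (A), exclusive.
#' @param min_power power threshold, exclusive.
#' @param power_fun scoring function; defaults to [hydrogen_bond_power()].
#' @return data frame with columns `protein_atom`, `dna_atom` (row
#'   indices), `distance`, `power`.
#' @export
detect_hydrogen_bonds <- function(structure, domain_rows, dna_rows,
                                  max_dist = 3.7, min_power = 0.1,
                                  power_fun = hydrogen_bond_power) {
  a <- structure$atoms
  pd <- domain_rows[a$elesy[domain_rows] %in% c("N", "O")]
  dd <- dna_rows[a$elesy[dna_rows] %in% c("N", "O")]
  empty <- data.frame(protein_atom = integer(0), dna_atom = integer(0),
                      distance = numeric(0), power = numeric(0))
  if (!length(pd) || !length(dd)) return(empty)
  dm <- sqrt(outer(a$x[pd], a$x[dd], "-")^2 +
               outer(a$y[pd], a$y[dd], "-")^2 +
               outer(a$z[pd], a$z[dd], "-")^2)
  hit <- which(dm < max_dist, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  nb <- neighbor_list(structure)
  rows <- lapply(seq_len(nrow(hit)), function(r) {
    i <- pd[hit[r, 1]]; j <- dd[hit[r, 2]]
    pw <- power_fun(structure, i, j, neighbors = nb)
    if (pw > min_power)
      data.frame(protein_atom = i, dna_atom = j,
                 distance = dm[hit[r, 1], hit[r, 2]], power = pw)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

#' Line-of-sight test between two atoms
#'
#' True when no other atom's van der Waals sphere separates the two atoms:
#' the test segment runs between the two atomic surfaces (the segment of
#' centers shortened by each endpoint's own van der Waals radius), and the
#' pair is blocked when any other atom's sphere intersects it.  Testing
#' against the full center-to-center segment would reject every pair, since
#' a covalent neighbor's sphere (radius about 1.7 A at bond length about
#' 1.5 A) always engulfs the endpoint itself.  Hydrogens are ignored; the
#' two endpoint atoms themselves never block.
#'
#' @param structure a `pdna_structure`.
#' @param i,j atom row indices.
#' @return logical.
#' @export
line_of_sight <- function(structure, i, j) {
  .los_pairs(structure, cbind(i, j))[1]
}

# vectorized LOS over a 2-column index matrix
.los_pairs <- function(structure, ij) {
  a <- structure$atoms
  xyz <- cbind(a$x, a$y, a$z)
  rad <- .vdw_radii[a$elesy]
  rad[is.na(rad)] <- .vdw_default
  blockrad <- rad
  blockrad[a$elesy == "H"] <- -1  # hydrogens never block
  out <- logical(nrow(ij))
  for (r in seq_len(nrow(ij))) {
    i <- ij[r, 1]; j <- ij[r, 2]
    p <- xyz[i, ]; q <- xyz[j, ]
    v <- q - p; L <- sqrt(sum(v^2))
    if (rad[i] + rad[j] >= L) { out[r] <- TRUE; next }  # surfaces touch
    vh <- v / L
    p2 <- p + rad[i] * vh; q2 <- q - rad[j] * vh
    v2 <- q2 - p2; L22 <- sum(v2^2)
    mid <- (p2 + q2) / 2
    d2mid <- (xyz[, 1] - mid[1])^2 + (xyz[, 2] - mid[2])^2 + (xyz[, 3] - mid[3])^2
    cand <- which(d2mid <= (sqrt(L22) / 2 + 2.0)^2)
    cand <- cand[cand != i & cand != j]
    if (!length(cand)) { out[r] <- TRUE; next }
    w <- xyz[cand, , drop = FALSE]
    t <- ((w[, 1] - p2[1]) * v2[1] + (w[, 2] - p2[2]) * v2[2] +
            (w[, 3] - p2[3]) * v2[3]) / L22
    t <- pmin(1, pmax(0, t))
    dx <- p2[1] + t * v2[1] - w[, 1]
    dy <- p2[2] + t * v2[2] - w[, 2]
    dz <- p2[3] + t * v2[3] - w[, 3]
    out[r] <- !any(dx^2 + dy^2 + dz^2 < blockrad[cand]^2)
  }
  out
}

#' Hydrophobic clusters
#'
#' Single-linkage connected components over the non-polar atom set, with
#' an edge between two atoms when their distance is below `max_dist` and
#' the line of sight between them is clear.  Components smaller than
#' `min_cluster_size` atoms are discarded.
#'
#' @param structure a `pdna_structure` with bonds.
#' @param nonpolar integer row indices from [nonpolar_atoms()].
#' @param max_dist edge distance bound (A), exclusive.
#' @param min_cluster_size minimum component size (default 5).
#' @return integer vector parallel to `nonpolar`: cluster id or `NA` for
#'   atoms in discarded components, with `nonpolar` as names.
#' @export
hydrophobic_clusters <- function(structure, nonpolar = nonpolar_atoms(structure),
                                 max_dist = 5.4, min_cluster_size = 5) {
  a <- structure$atoms
  m <- length(nonpolar)
  if (!m) return(stats::setNames(integer(0), character(0)))
  xyz <- .xyz(structure, nonpolar)
  dm <- as.matrix(stats::dist(xyz))
  cand <- which(dm < max_dist & upper.tri(dm), arr.ind = TRUE)
  if (nrow(cand)) {
    ij <- cbind(nonpolar[cand[, 1]], nonpolar[cand[, 2]])
    ok <- .los_pairs(structure, ij)
    cand <- cand[ok, , drop = FALSE]
  }
  # union-find
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (r in seq_len(nrow(cand))) {
    ra <- find(cand[r, 1]); rb <- find(cand[r, 2])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(seq_len(m), find, integer(1))
  sz <- table(comp)
  ids <- as.integer(names(sz)[sz >= min_cluster_size])
  out <- ifelse(comp %in% ids, match(comp, ids), NA_integer_)
  stats::setNames(out, nonpolar)
}

#' Detect protein-DNA hydrophobic contacts
#'
#' A contact between a protein non-polar atom and a DNA non-polar atom
#' requires center distance strictly below `max_dist`, a clear line of
#' sight, and joint membership in one hydrophobic cluster.
#'
#' @param structure a `pdna_structure` with bonds.
#' @param domain_rows protein-domain atom rows.
#' @param dna_rows duplex DNA atom rows.
#' @param clusters result of [hydrophobic_clusters()].
#' @param max_dist distance cutoff (A), exclusive.
#' @return data frame with `protein_atom`, `dna_atom`, `distance`,
#'   `cluster`.
#' @export
detect_hydrophobic_contacts <- function(structure, domain_rows, dna_rows,
                                        clusters, max_dist = 5.4) {
  a <- structure$atoms
  np <- as.integer(names(clusters))[!is.na(clusters)]
  cl <- clusters[!is.na(clusters)]
  pd <- np[np %in% domain_rows]
  dd <- np[np %in% dna_rows]
  empty <- data.frame(protein_atom = integer(0), dna_atom = integer(0),
                      distance = numeric(0), cluster = integer(0))
  if (!length(pd) || !length(dd)) return(empty)
  dm <- sqrt(outer(a$x[pd], a$x[dd], "-")^2 +
               outer(a$y[pd], a$y[dd], "-")^2 +
               outer(a$z[pd], a$z[dd], "-")^2)
  hit <- which(dm < max_dist, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  same <- cl[match(pd[hit[, 1]], np)] == cl[match(dd[hit[, 2]], np)]
  hit <- hit[same, , drop = FALSE]
  if (!nrow(hit)) return(empty)
  ij <- cbind(pd[hit[, 1]], dd[hit[, 2]])
  ok <- .los_pairs(structure, ij)
  hit <- hit[ok, , drop = FALSE]
  if (!nrow(hit)) return(empty)
  data.frame(protein_atom = pd[hit[, 1]], dna_atom = dd[hit[, 2]],
             distance = dm[hit], cluster = unname(cl[match(pd[hit[, 1]], np)]))
}

#' All typed contacts of one domain instance with duplex DNA
#'
#' Runs hydrogen-bond and hydrophobic detection for the atoms of one
#' domain against all nucleotides of duplexes of at least the minimum
#' length, then annotates each contact with the protein element of its
#' residue and the DNA element of its atom.  Contacts through DNA atoms
#' outside the published element lists are dropped from typing.
#'
#' @param structure a `pdna_structure` with bonds.
#' @param domain_rows protein atom rows of the domain instance.
#' @param duplexes list from [detect_duplexes()].
#' @param ss an `ss_assignment` covering the domain.
#' @param clusters optional precomputed [hydrophobic_clusters()].
#' @return data frame (class `dpi_contacts`) with one row per contact:
#'   `kind`, atom and residue identifiers, `distance`, `score`,
#'   `protein_element`, `dna_element`.
#' @export
domain_contacts <- function(structure, domain_rows, duplexes, ss,
                            clusters = NULL) {
  a <- structure$atoms
  nt_keys <- unique(unlist(lapply(duplexes, `[[`, "nt_keys")))
  dna_rows <- which(.reskey(a) %in% nt_keys)
  empty <- data.frame(kind = character(0), protein_atom = integer(0),
                      dna_atom = integer(0), distance = numeric(0),
                      score = numeric(0), protein_res = character(0),
                      dna_res = character(0), protein_element = character(0),
                      dna_element = character(0))
  class(empty) <- c("dpi_contacts", class(empty))
  if (!length(dna_rows) || !length(domain_rows)) return(empty)
  hb <- detect_hydrogen_bonds(structure, domain_rows, dna_rows)
  if (is.null(clusters)) clusters <- hydrophobic_clusters(structure)
  hp <- detect_hydrophobic_contacts(structure, domain_rows, dna_rows, clusters)
  mk <- function(df, kind, score) {
    if (!nrow(df)) return(NULL)
    data.frame(kind = kind, protein_atom = df$protein_atom,
               dna_atom = df$dna_atom, distance = df$distance,
               score = score(df),
               protein_res = .reskey(a)[df$protein_atom],
               dna_res = .reskey(a)[df$dna_atom])
  }
  out <- rbind(mk(hb, "hbond", function(d) d$power),
               mk(hp, "hydrophobic", function(d) as.numeric(d$cluster)))
  if (is.null(out)) return(empty)
  ssmap <- .ss_lookup(ss)
  out$protein_element <- unname(ssmap[out$protein_res])
  out$protein_element[is.na(out$protein_element)] <- "Loop"
  out$dna_element <- classify_dna_atom(a$resid[out$dna_atom],
                                       a$elety[out$dna_atom])
  class(out) <- c("dpi_contacts", class(out))
  out
}

#' Write a contact table as TSV
#'
#' @param contacts a `dpi_contacts` data frame.
#' @param structure the source structure (for atom names).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, structure, path) {
  a <- structure$atoms
  df <- data.frame(kind = contacts$kind,
                   protein_chain = a$chain[contacts$protein_atom],
                   protein_resno = a$resno[contacts$protein_atom],
                   protein_resid = a$resid[contacts$protein_atom],
                   protein_atom = a$elety[contacts$protein_atom],
                   dna_chain = a$chain[contacts$dna_atom],
                   dna_resno = a$resno[contacts$dna_atom],
                   dna_resid = a$resid[contacts$dna_atom],
                   dna_atom = a$elety[contacts$dna_atom],
                   distance = round(contacts$distance, 3),
                   score = round(contacts$score, 3),
                   protein_element = contacts$protein_element,
                   dna_element = contacts$dna_element)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
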