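# Atomic data model: parsed structures, covalent connectivity and
# domain-definition tables.

#' Load a protein-DNA complex structure
#'
#' Reads a PDB or mmCIF file into a uniform atom table.  Only the first
#' model of multi-model (NMR) entries is used.  Alternate locations are
#' reduced to the highest-occupancy conformer, water molecules are removed,
#' and hydrogens are retained if present but never required.
#'
#' @param path path to a PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param assembly_id assembly label recorded on the returned object.  The
#'   atoms of the file are taken as the biological assembly; symmetry
#'   expansion beyond what the file states is not performed.
#' @param id entry identifier; defaults to the file base name.
#' @return an object of class `pdna_structure`: a list with `id`,
#'   `assembly_id`, `atoms` (data frame with columns `chain`, `resno`,
#'   `insert`, `resid`, `elety`, `elesy`, `x`, `y`, `z`, `het`) and, once
#'   [covalent_neighbors()] has run, `bonds` (two-column index matrix).
#' @export
load_structure <- function(path, assembly_id = "1", id = NULL) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, verbose = FALSE)
  }
  at <- pdb$atom
  atoms <- data.frame(
    chain  = as.character(at$chain),
    resno  = as.integer(at$resno),
    insert = ifelse(is.na(at$insert) | at$insert == "", "", as.character(at$insert)),
    resid  = as.character(at$resid),
    elety  = as.character(at$elety),
    elesy  = toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                            substr(gsub("[^A-Za-z].*", "", at$elety), 1, 1),
                            as.character(at$elesy))),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt) | at$alt == "", "", as.character(at$alt)),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "

  # drop waters ("water-mediated contacts are not considered")
  atoms <- atoms[!(atoms$resid %in% .water_names), , drop = FALSE]

  # altloc: keep the highest-occupancy conformer per atom site
  if (any(atoms$alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
    ord <- order(key, -atoms$o, atoms$alt)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno,
                                     atoms$insert, atoms$elety)), , drop = FALSE]
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  rownames(atoms) <- NULL
  atoms$o <- NULL; atoms$alt <- NULL

  structure(list(id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id,
                 assembly_id = as.character(assembly_id),
                 atoms = atoms, bonds = NULL),
            class = "pdna_structure")
}

#' @export
print.pdna_structure <- function(x, ...) {
  a <- x$atoms
  cat("pdna_structure", x$id, " (assembly ", x$assembly_id, ")\n", sep = "")
  cat("  ", nrow(a), " atoms, ", length(unique(a$chain)), " chains: ",
      paste(sort(unique(a$chain)), collapse = " "), "\n", sep = "")
  nres <- length(unique(paste(a$chain, a$resno, a$insert)))
  aa <- unique(a[.is_aa_resid(a$resid), c("chain","resno","insert")])
  nt <- unique(a[.is_dna_resid(a$resid), c("chain","resno","insert")])
  cat("  ", nres, " residues (", nrow(aa), " amino acid, ",
      nrow(nt), " nucleotide)\n", sep = "")
  if (!is.null(x$bonds)) cat("  ", nrow(x$bonds), " covalent bonds\n", sep = "")
  invisible(x)
}

#' Write a structure back to PDB text
#'
#' @param structure a `pdna_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  con <- file(path, "w")
  on.exit(close(con))
  ser <- 0L
  lastchain <- NULL
  for (i in seq_len(nrow(a))) {
    if (!is.null(lastchain) && a$chain[i] != lastchain)
      writeLines("TER", con)
    lastchain <- a$chain[i]
    ser <- ser + 1L
    nm <- a$elety[i]
    nm <- if (nchar(nm) >= 4) substr(nm, 1, 4) else paste0(" ", formatC(nm, width = -3))
    writeLines(sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       if (a$het[i]) "HETATM" else "ATOM", ser, nm, "",
                       a$resid[i], a$chain[i], a$resno[i],
                       ifelse(a$insert[i] == "", " ", a$insert[i]),
                       a$x[i], a$y[i], a$z[i], 1, 0, a$elesy[i]), con)
  }
  writeLines(c("TER", "END"), con)
  invisible(path)
}

#' Covalent bond relation of a structure
#'
#' Bonds within standard residues come from embedded chemical-component
#' templates; consecutive residues are linked by the peptide (C-N) or
#' phosphodiester (O3'-P) bond when the atoms are within 2.0 A.  Atoms of
#' unknown residues fall back to a 2.0 A distance rule between non-hydrogen
#' atoms.  The relation is symmetric and irreflexive; the matrix stores
#' each bond once with both orders retrievable via [neighbor_list()].
#'
#' @param structure a `pdna_structure`.
#' @return the structure with `$bonds` set (two-column matrix of atom row
#'   indices).
#' @export
covalent_neighbors <- function(structure) {
  a <- structure$atoms
  n <- nrow(a)
  rkey <- paste(a$chain, a$resno, a$insert)
  bonds_i <- integer(0); bonds_j <- integer(0)
  add <- function(i, j) {
    bonds_i <<- c(bonds_i, i); bonds_j <<- c(bonds_j, j)
  }
  # intra-residue template bonds
  for (rk in unique(rkey)) {
    sel <- which(rkey == rk)
    rn <- a$resid[sel[1]]
    tmpl_name <- if (rn %in% names(.residue_bonds)) rn else {
      nd <- .norm_dna_resid(rn); if (!is.na(nd)) nd else NA
    }
    if (!is.na(tmpl_name) && (rn %in% .aa3 || !is.na(.norm_dna_resid(rn)))) {
      tm <- .residue_bonds[[tmpl_name]]
      idx <- stats::setNames(sel, a$elety[sel])
      # tolerate */' naming variants on sugars
      names(idx) <- gsub("\\*", "'", names(idx))
      for (b in seq_len(nrow(tm))) {
        i <- idx[tm[b, 1]]; j <- idx[tm[b, 2]]
        if (!is.na(i) && !is.na(j)) add(unname(i), unname(j))
      }
      # extra atoms not in the template (e.g. OXT, OP3): distance rule
      extra <- sel[!(gsub("\\*", "'", a$elety[sel]) %in% unique(c(tm))) &
                     a$elesy[sel] != "H"]
      if (length(extra)) {
        for (i in extra) {
          d2 <- (a$x[sel] - a$x[i])^2 + (a$y[sel] - a$y[i])^2 + (a$z[sel] - a$z[i])^2
          near <- sel[d2 < 4 & d2 > 1e-9 & a$elesy[sel] != "H"]
          for (j in near) add(i, j)
        }
      }
    } else {
      # unknown residue: 2.0 A rule among non-H atoms
      message("unknown residue ", rn, " at ", rk, ": distance-rule bonds")
      hs <- sel[a$elesy[sel] != "H"]
      if (length(hs) > 1) {
        xyz <- as.matrix(a[hs, c("x","y","z")])
        dm <- as.matrix(stats::dist(xyz))
        w <- which(dm < 2.0 & upper.tri(dm), arr.ind = TRUE)
        if (nrow(w)) for (r in seq_len(nrow(w))) add(hs[w[r,1]], hs[w[r,2]])
      }
    }
  }
  # inter-residue links along each chain (author numbering order)
  for (ch in unique(a$chain)) {
    sel <- which(a$chain == ch)
    rks <- unique(rkey[sel])
    for (k in seq_along(rks)[-1]) {
      prev <- which(rkey == rks[k - 1]); cur <- which(rkey == rks[k])
      # peptide C-N
      i <- prev[a$elety[prev] == "C"]; j <- cur[a$elety[cur] == "N"]
      if (length(i) == 1 && length(j) == 1 &&
          sum((a[i, c("x","y","z")] - a[j, c("x","y","z")])^2) < 4) add(i, j)
      # phosphodiester O3'(k-1)-P(k)
      i <- prev[gsub("\\*", "'", a$elety[prev]) == "O3'"]
      j <- cur[a$elety[cur] == "P"]
      if (length(i) == 1 && length(j) == 1 &&
          sum((a[i, c("x","y","z")] - a[j, c("x","y","z")])^2) < 4) add(i, j)
    }
  }
  bonds <- cbind(bonds_i, bonds_j)
  bonds <- bonds[bonds[, 1] != bonds[, 2], , drop = FALSE]
  # canonical order, unique
  bonds <- unique(cbind(pmin(bonds[, 1], bonds[, 2]),
                        pmax(bonds[, 1], bonds[, 2])))
  dimnames(bonds) <- list(NULL, c("i", "j"))
  structure$bonds <- bonds
  structure
}

#' Neighbor list from the bond relation
#'
#' @param structure a `pdna_structure` processed by [covalent_neighbors()].
#' @return list mapping each atom row index to the integer vector of its
#'   covalent neighbors.
#' @export
neighbor_list <- function(structure) {
  if (is.null(structure$bonds)) stop("run covalent_neighbors() first")
  n <- nrow(structure$atoms)
  nb <- vector("list", n)
  b <- structure$bonds
  for (r in seq_len(nrow(b))) {
    nb[[b[r, 1]]] <- c(nb[[b[r, 1]]], b[r, 2])
    nb[[b[r, 2]]] <- c(nb[[b[r, 2]]], b[r, 1])
  }
  nb
}

#' Load a domain-definition table
#'
#' Tab-separated text, one row per domain instance, with columns
#' `structure_id`, `assembly_id`, `chain_id`, `start`, `end`, `domain_id`,
#' `family_id`.  Residue ranges are inclusive author numbering; insertion
#' codes may be appended to `start`/`end` (e.g. `52A`).
#'
#' @param path path to the TSV file.
#' @return data frame of validated domain definitions.
#' @export
load_domain_definitions <- function(path) {
  cols <- c("structure_id","assembly_id","chain_id","start","end",
            "domain_id","family_id")
  if (!file.exists(path)) stop("cannot read domain definitions: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = cols, colClasses = "character",
                           comment.char = "#", blank.lines.skip = TRUE,
                           fill = FALSE)
  if (nrow(raw) == 0) return(raw)
  split_num <- function(v, what) {
    m <- regmatches(v, regexec("^(-?[0-9]+)([A-Za-z]?)$", v))
    bad <- vapply(m, length, 1L) == 0
    if (any(bad)) stop("malformed ", what, " in row(s) ",
                       paste(which(bad), collapse = ", "))
    list(no = as.integer(vapply(m, `[`, "", 2)),
         ins = vapply(m, `[`, "", 3))
  }
  s <- split_num(raw$start, "start"); e <- split_num(raw$end, "end")
  raw$start_no <- s$no; raw$start_ins <- s$ins
  raw$end_no <- e$no; raw$end_ins <- e$ins
  if (any(raw$end_no < raw$start_no))
    stop("empty residue range in row(s) ",
         paste(which(raw$end_no < raw$start_no), collapse = ", "))
  dup <- duplicated(raw[, c("structure_id","assembly_id","chain_id","start","end")])
  if (any(dup))
    stop("duplicate (structure, chain, range) in row(s) ",
         paste(which(dup), collapse = ", "))
  fam <- tapply(raw$family_id, raw$domain_id, function(v) length(unique(v)))
  if (any(fam > 1))
    stop("inconsistent family_id for domain_id(s): ",
         paste(names(fam)[fam > 1], collapse = ", "))
  raw
}

# Select the atom rows of one domain instance within a structure.
.domain_atoms <- function(structure, dom) {
  a <- structure$atoms
  sel <- a$chain == dom$chain_id &
    a$resno >= dom$start_no & a$resno <= dom$end_no
  # insertion codes participate via numeric bounds only at the edges
  which(sel)
}

.xyz <- function(structure, idx = NULL) {
  a <- structure$atoms
  m <- cbind(a$x, a$y, a$z)
  if (is.null(idx)) m else m[idx, , drop = FALSE]
}

# residue keys
.reskey <- function(atoms) paste(atoms$chain, atoms$resno, atoms$insert)
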