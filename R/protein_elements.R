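# Assignment of protein residues to interacting elements:
# helix (alpha or 3-10), strand, or loop (turn / unstructured).

#' Assign secondary structure from backbone hydrogen-bond patterns
#'
#' A Kabsch-Sander style assignment: amide hydrogens are reconstructed from
#' the preceding carbonyl, backbone N-H...O=C hydrogen bonds are scored with
#' the electrostatic energy model (bond if E < -0.5 kcal/mol), and raw
#' states are derived from n-turn and bridge patterns: `H` (alpha helix),
#' `G` (3-10 helix), `I` (pi helix), `E` (extended strand in a ladder),
#' `B` (isolated bridge), `T` (turn), `C` (coil).  Deterministic for fixed
#' input.  Residues missing backbone atoms are assigned `C` with a warning.
#'
#' @param structure a `pdna_structure`.
#' @param chain chain identifier(s); default all protein chains.
#' @return object of class `ss_assignment`: data frame with `chain`,
#'   `resno`, `insert`, `resid`, `raw` (DSSP-style code) and `element`
#'   (`Helix`/`Strand`/`Loop`), plus attribute `source = "internal"`.
#' @export
assign_secondary_structure <- function(structure, chain = NULL) {
  a <- structure$atoms
  keep <- .is_aa_resid(a$resid)
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0)
    return(.mk_ss(data.frame(chain = character(0), resno = integer(0),
                             insert = character(0), resid = character(0),
                             raw = character(0)), "internal"))
  rk <- .reskey(a)
  res <- a[!duplicated(rk), c("chain", "resno", "insert", "resid")]
  res <- res[order(res$chain, res$resno, res$insert), , drop = FALSE]
  rownames(res) <- NULL
  n <- nrow(res)
  get_at <- function(i, name) {
    sel <- which(a$chain == res$chain[i] & a$resno == res$resno[i] &
                   a$insert == res$insert[i] & a$elety == name)
    if (length(sel) != 1) return(c(NA_real_, NA_real_, NA_real_))
    c(a$x[sel], a$y[sel], a$z[sel])
  }
  N <- t(vapply(seq_len(n), get_at, numeric(3), name = "N"))
  CA <- t(vapply(seq_len(n), get_at, numeric(3), name = "CA"))
  C <- t(vapply(seq_len(n), get_at, numeric(3), name = "C"))
  O <- t(vapply(seq_len(n), get_at, numeric(3), name = "O"))
  okbb <- rowSums(is.na(cbind(N, CA, C, O))) == 0
  if (any(!okbb))
    warning("residues with missing backbone assigned loop: ",
            paste(res$resno[!okbb], collapse = ", "))
  # chain-continuity: previous residue in same chain and numbering contiguous
  contig <- res$chain[-1] == res$chain[-n] &
    (res$resno[-1] - res$resno[-n] <= 1L)
  prev_ok <- c(FALSE, contig) & okbb & c(FALSE, okbb[-n])
  # reconstructed amide H: 1.0 A from N opposite the previous carbonyl
  H <- matrix(NA_real_, n, 3)
  for (i in which(prev_ok)) {
    co <- C[i - 1, ] - O[i - 1, ]
    H[i, ] <- N[i, ] + co / sqrt(sum(co^2))
  }
  # hydrogen-bond energies: donor i (N-H), acceptor j (C=O)
  hb <- matrix(FALSE, n, n)
  q1q2f <- 0.084 * 332
  for (i in which(!is.na(H[, 1]))) {
    dON <- sqrt(rowSums(sweep(O, 2, N[i, ])^2))
    cand <- which(dON < 5.2 & okbb)
    cand <- cand[abs(cand - i) >= 2 | res$chain[cand] != res$chain[i]]
    for (j in cand) {
      rON <- sqrt(sum((O[j, ] - N[i, ])^2))
      rCH <- sqrt(sum((C[j, ] - H[i, ])^2))
      rOH <- sqrt(sum((O[j, ] - H[i, ])^2))
      rCN <- sqrt(sum((C[j, ] - N[i, ])^2))
      E <- q1q2f * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      if (E < -0.5) hb[i, j] <- TRUE
    }
  }
  same_chain_span <- function(i, k) {
    i + k <= n && res$chain[i + k] == res$chain[i] &&
      res$resno[i + k] - res$resno[i] == k
  }
  turn <- function(nlen) {
    v <- logical(n)
    for (i in seq_len(n))
      if (same_chain_span(i, nlen) && hb[i + nlen, i]) v[i] <- TRUE
    v
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
  raw <- rep("C", n)
  # helices: two consecutive n-turns; alpha has priority over 3-10 and pi
  mark_helix <- function(tv, nlen, code) {
    for (i in which(tv)) {
      if (i > 1 && tv[i - 1] && same_chain_span(i, nlen)) {
        span <- i:(i + nlen - 1)
        free <- raw[span] %in% c("C", "T") |
          (code == "H" & raw[span] %in% c("G", "I"))
        raw[span[free]] <<- code
      }
    }
  }
  mark_helix(t4, 4, "H")
  mark_helix(t3, 3, "G")
  mark_helix(t5, 5, "I")
  # bridges
  bridge <- matrix(FALSE, n, n)
  if (n >= 3) for (i in 2:(n - 1)) {
    if (!okbb[i]) next
    for (j in 2:(n - 1)) {
      if (abs(i - j) < 3 && res$chain[i] == res$chain[j]) next
      par <- (hb[i, j - 1] && hb[j + 1, i]) || (hb[j, i - 1] && hb[i + 1, j])
      anti <- (hb[i, j] && hb[j, i]) || (hb[j + 1, i - 1] && hb[i + 1, j - 1])
      if (par || anti) bridge[i, j] <- TRUE
    }
  }
  has_bridge <- rowSums(bridge) > 0 | colSums(bridge) > 0
  for (i in which(has_bridge)) {
    if (raw[i] %in% c("H")) next
    # ladder: a neighboring residue also bridges to a neighboring partner
    js <- which(bridge[i, ] | bridge[, i])
    ladder <- FALSE
    for (j in js) {
      for (di in c(-1, 1)) for (dj in c(-1, 1)) {
        i2 <- i + di; j2 <- j + dj
        if (i2 >= 1 && i2 <= n && j2 >= 1 && j2 <= n &&
            (bridge[i2, j2] || bridge[j2, i2])) ladder <- TRUE
      }
    }
    raw[i] <- if (ladder) "E" else "B"
  }
  # turns: interior of any n-turn not otherwise assigned
  for (i in which(t3)) for (k in 1:2)
    if (same_chain_span(i, k) && raw[i + k] == "C") raw[i + k] <- "T"
  for (i in which(t4)) for (k in 1:3)
    if (same_chain_span(i, k) && raw[i + k] == "C") raw[i + k] <- "T"
  for (i in which(t5)) for (k in 1:4)
    if (same_chain_span(i, k) && raw[i + k] == "C") raw[i + k] <- "T"
  raw[!okbb] <- "C"
  res$raw <- raw
  .mk_ss(res, "internal")
}

.mk_ss <- function(res, source) {
  res$element <- map_ss_to_element(res$raw)
  attr(res, "source") <- source
  class(res) <- c("ss_assignment", class(res))
  res
}

#' Map a raw secondary-structure code to an interacting element
#'
#' Alpha (`H`), 3-10 (`G`) and pi (`I`) helices map to `Helix`; extended
#' strands (`E`) map to `Strand`; turns (`T`), coil (`C`), bends (`S`) and
#' isolated beta-bridges (`B`, not part of a strand segment) map to `Loop`.
#'
#' @param raw_code character vector of DSSP/Stride codes.
#' @return character vector of `"Helix"`, `"Strand"`, `"Loop"`.
#' @export
map_ss_to_element <- function(raw_code) {
  up <- toupper(raw_code)
  out <- rep(NA_character_, length(up))
  out[up %in% c("H", "G", "I")] <- "Helix"
  out[up %in% c("E")] <- "Strand"
  out[up %in% c("B", "T", "C", "S", " ", "")] <- "Loop"
  if (any(is.na(out)))
    stop("unknown secondary-structure code(s): ",
         paste(unique(up[is.na(out)]), collapse = ", "))
  out
}

#' Import an external secondary-structure assignment
#'
#' Parses Stride (`ASG` records) or DSSP output and maps the per-residue
#' codes onto the structure's residues.
#'
#' @param path path to the report file.
#' @param format `"stride"` or `"dssp"`.
#' @param structure optional `pdna_structure`; when given, every standard
#'   protein residue of the structure must be present in the file.
#' @return an `ss_assignment` with `source` set to the file format.
#' @export
import_external_ss <- function(path, format = c("stride", "dssp"),
                               structure = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "stride") {
    asg <- grep("^ASG ", lines, value = TRUE)
    if (!length(asg)) stop("no ASG records in ", path)
    res <- data.frame(
      resid = substr(asg, 6, 8),
      chain = sub(" ", "", substr(asg, 10, 10)),
      resno = as.integer(substr(asg, 12, 15)),
      insert = "",
      raw = toupper(sub("\\s+", "", substr(asg, 25, 25))),
      stringsAsFactors = FALSE)
  } else {
    hdr <- grep("^  #  RESIDUE", lines)
    if (!length(hdr)) stop("not a DSSP file: ", path)
    body <- lines[(hdr[1] + 1):length(lines)]
    body <- body[nchar(body) >= 17 & substr(body, 14, 14) != "!"]
    raw <- substr(body, 17, 17)
    raw[raw == " "] <- "C"
    res <- data.frame(
      resid = "",
      chain = sub(" ", "", substr(body, 12, 12)),
      resno = as.integer(substr(body, 6, 10)),
      insert = sub(" ", "", substr(body, 11, 11)),
      raw = toupper(raw),
      stringsAsFactors = FALSE)
  }
  res$raw[res$raw %in% c("-", ".")] <- "C"
  if (!is.null(structure)) {
    a <- structure$atoms
    want <- unique(a[.is_aa_resid(a$resid), c("chain", "resno", "insert")])
    have <- paste(res$chain, res$resno, res$insert)
    miss <- !(paste(want$chain, want$resno, want$insert) %in% have)
    if (any(miss)) {
      w <- want[which(miss)[1], ]
      stop("residue ", w$chain, ":", w$resno, w$insert,
           " of the structure is missing from ", path)
    }
    res$resid <- NULL
    key <- paste(a$chain, a$resno, a$insert)
    rid <- a$resid[match(paste(res$chain, res$resno, res$insert), key)]
    res$resid <- rid
  }
  .mk_ss(res[, c("chain", "resno", "insert", "resid", "raw")], format)
}

# element of each residue key, for contact typing
.ss_lookup <- function(ss) {
  stats::setNames(ss$element, paste(ss$chain, ss$resno, ss$insert))
}
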