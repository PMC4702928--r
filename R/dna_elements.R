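# Detection of double-helical DNA and classification of DNA atoms into
# backbone, major-groove and minor-groove elements.

# Base (nucleobase) atom names per normalized residue; used for plane fits
# and pairing criteria.
.base_atoms <- list(
  DA = c("N9","C8","N7","C5","C6","N6","N1","C2","N3","C4"),
  DG = c("N9","C8","N7","C5","C6","O6","N1","C2","N2","N3","C4"),
  DT = c("N1","C2","O2","N3","C4","O4","C5","C7","C5M","C6"),
  DC = c("N1","C2","O2","N3","C4","N4","C5","C6"))

# Per-structure nucleotide inventory: one row per nucleotide with C1'
# position, base centroid, plane normal and atom row indices.
.nucleotides <- function(structure) {
  a <- structure$atoms
  keep <- .is_dna_resid(a$resid)
  if (!any(keep)) return(NULL)
  a2 <- a[keep, , drop = FALSE]
  idx <- which(keep)
  rk <- .reskey(a2)
  out <- list()
  for (u in unique(rk)) {
    sel <- idx[rk == u]
    rn <- .norm_dna_resid(structure$atoms$resid[sel[1]])
    ety <- gsub("\\*", "'", structure$atoms$elety[sel])
    c1 <- sel[ety == "C1'"]
    bs <- sel[structure$atoms$elety[sel] %in% .base_atoms[[rn]]]
    if (length(c1) != 1 || length(bs) < 6) next
    xyz <- .xyz(structure, bs)
    ctr <- colMeans(xyz)
    sv <- svd(sweep(xyz, 2, ctr))
    out[[u]] <- list(key = u, resid = rn,
                     chain = structure$atoms$chain[sel[1]],
                     resno = structure$atoms$resno[sel[1]],
                     insert = structure$atoms$insert[sel[1]],
                     rows = sel, base_rows = bs, c1 = .xyz(structure, c1)[1, ],
                     centroid = ctr, normal = sv$v[, 3])
  }
  if (!length(out)) return(NULL)
  out
}

#' Detect Watson-Crick-like base pairs
#'
#' A candidate pair must satisfy: C1'-C1' distance within
#' `c1_range`, inter-base-plane angle at most `max_plane_angle` degrees, and
#' at least `min_hbonds` base N/O - N/O distances at or below `hbond_max` A.
#' Candidates are accepted greedily by score (number of hydrogen-bond-range
#' atom pairs, then mean of those distances) so that each nucleotide occurs
#' in at most one pair.  Pairing is not restricted to canonical
#' Watson-Crick partners.
#'
#' @param structure a `pdna_structure`.
#' @param c1_range numeric length-2, allowed C1'-C1' distance (A).
#' @param max_plane_angle maximum angle between base planes (degrees).
#' @param hbond_max inter-base N/O contact distance bound (A).
#' @param min_hbonds minimum number of such contacts.
#' @return data frame with one row per pair (residue keys, geometry and
#'   score columns); empty if the structure contains no DNA.
#' @export
detect_base_pairs <- function(structure, c1_range = c(8.5, 12.0),
                              max_plane_angle = 35, hbond_max = 3.5,
                              min_hbonds = 2) {
  nts <- .nucleotides(structure)
  empty <- data.frame(nt1 = character(0), nt2 = character(0),
                      c1_dist = numeric(0), plane_angle = numeric(0),
                      n_hbonds = integer(0))
  if (is.null(nts) || length(nts) < 2) return(empty)
  a <- structure$atoms
  keys <- names(nts)
  c1 <- t(vapply(nts, `[[`, numeric(3), "c1"))
  cand <- which(as.matrix(stats::dist(c1)) >= c1_range[1] &
                  as.matrix(stats::dist(c1)) <= c1_range[2] &
                  upper.tri(matrix(0, length(keys), length(keys))),
                arr.ind = TRUE)
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    n1 <- nts[[i]]; n2 <- nts[[j]]
    # same-strand neighbors cannot pair
    if (n1$chain == n2$chain && abs(n1$resno - n2$resno) < 3) next
    ang <- acos(pmin(1, abs(sum(n1$normal * n2$normal)))) * 180 / pi
    if (ang > max_plane_angle) next
    b1 <- n1$base_rows[a$elesy[n1$base_rows] %in% c("N", "O")]
    b2 <- n2$base_rows[a$elesy[n2$base_rows] %in% c("N", "O")]
    if (!length(b1) || !length(b2)) next
    dm <- sqrt(outer(a$x[b1], a$x[b2], "-")^2 +
                 outer(a$y[b1], a$y[b2], "-")^2 +
                 outer(a$z[b1], a$z[b2], "-")^2)
    nh <- sum(dm <= hbond_max)
    if (nh < min_hbonds) next
    rows[[length(rows) + 1]] <- data.frame(
      nt1 = n1$key, nt2 = n2$key,
      c1_dist = sqrt(sum((n1$c1 - n2$c1)^2)),
      plane_angle = ang, n_hbonds = nh,
      mean_hb = mean(dm[dm <= hbond_max]))
  }
  if (!length(rows)) return(empty)
  cand_df <- do.call(rbind, rows)
  cand_df <- cand_df[order(-cand_df$n_hbonds, cand_df$mean_hb), , drop = FALSE]
  used <- character(0)
  keep <- logical(nrow(cand_df))
  for (r in seq_len(nrow(cand_df))) {
    if (cand_df$nt1[r] %in% used || cand_df$nt2[r] %in% used) next
    keep[r] <- TRUE
    used <- c(used, cand_df$nt1[r], cand_df$nt2[r])
  }
  out <- cand_df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$mean_hb <- NULL
  out
}

#' Chain base pairs into duplexes
#'
#' Pairs are chained by stacking: two pairs are adjacent when the distance
#' between their C1'-C1' midpoints is at most `stack_max` A.  A single
#' missing pair (one-nucleotide loop or base excision) may be bridged
#' (midpoint distance at most `2 * stack_max`), and is recorded as a gap.
#' Runs shorter than `min_bp` base pairs are discarded.
#'
#' @param base_pairs data frame from [detect_base_pairs()].
#' @param structure the same `pdna_structure`.
#' @param min_bp minimum duplex length in base pairs (default 10).
#' @param stack_max stacking distance bound between adjacent pair midpoints.
#' @return list of duplexes; each has `pairs` (data frame ordered along the
#'   helix), `length`, `gaps` (indices after which a bridged interruption
#'   occurs) and `nt_keys` (residue keys of all member nucleotides).
#' @export
detect_duplexes <- function(base_pairs, structure, min_bp = 10,
                            stack_max = 5.5) {
  if (nrow(base_pairs) == 0) return(list())
  nts <- .nucleotides(structure)
  mid <- t(vapply(seq_len(nrow(base_pairs)), function(r) {
    (nts[[base_pairs$nt1[r]]]$c1 + nts[[base_pairs$nt2[r]]]$c1) / 2
  }, numeric(3)))
  n <- nrow(base_pairs)
  dm <- as.matrix(stats::dist(mid))
  direct <- dm <= stack_max & dm > 0
  bridged <- dm <= 2 * stack_max & dm > 0
  # connected components under the bridged relation
  comp <- rep(NA_integer_, n); cc <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cc <- cc + 1; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cc
      queue <- c(queue, which(bridged[v, ] & is.na(comp)))
    }
  }
  out <- list()
  for (g in unique(comp)) {
    sel <- which(comp == g)
    if (length(sel) < min_bp) next
    # order along the principal axis of the midpoints
    ctr <- colMeans(mid[sel, , drop = FALSE])
    ax <- svd(sweep(mid[sel, , drop = FALSE], 2, ctr))$v[, 1]
    ord <- sel[order(as.vector(sweep(mid[sel, , drop = FALSE], 2, ctr) %*% ax))]
    # gaps: adjacent in order but only bridged, not directly stacked
    gaps <- integer(0)
    okrun <- TRUE
    for (k in seq_along(ord)[-1]) {
      if (!direct[ord[k - 1], ord[k]]) {
        if (bridged[ord[k - 1], ord[k]]) gaps <- c(gaps, k - 1L) else okrun <- FALSE
      }
    }
    if (!okrun) {
      # split at hard breaks into directly/bridged-connected runs
      runs <- split(seq_along(ord), cumsum(c(TRUE, vapply(seq_along(ord)[-1],
        function(k) !bridged[ord[k - 1], ord[k]], logical(1)))))
      for (rn in runs) {
        if (length(rn) < min_bp) next
        o2 <- ord[rn]
        g2 <- integer(0)
        for (k in seq_along(o2)[-1])
          if (!direct[o2[k - 1], o2[k]]) g2 <- c(g2, k - 1L)
        out[[length(out) + 1]] <- .mk_duplex(base_pairs, o2, g2)
      }
      next
    }
    out[[length(out) + 1]] <- .mk_duplex(base_pairs, ord, gaps)
  }
  out
}

.mk_duplex <- function(base_pairs, ord, gaps) {
  p <- base_pairs[ord, , drop = FALSE]
  rownames(p) <- NULL
  list(pairs = p, length = nrow(p), gaps = gaps,
       nt_keys = unique(c(p$nt1, p$nt2)))
}

#' Classify a DNA atom into backbone / major groove / minor groove
#'
#' Backbone atoms are the deoxyribose and phosphate-group atoms; groove
#' atoms follow the per-base published lists; any other base atom (such as
#' the glycosidic nitrogens N9/N1) is `Unclassified`.
#'
#' @param residue_name residue name (standard, alias or mapped modified).
#' @param atom_name PDB atom name.
#' @return one of `"Backbone"`, `"MajorGroove"`, `"MinorGroove"`,
#'   `"Unclassified"`.
#' @export
classify_dna_atom <- function(residue_name, atom_name) {
  rn <- .norm_dna_resid(residue_name)
  if (any(is.na(rn))) stop("unknown DNA residue name: ",
                           paste(unique(residue_name[is.na(rn)]), collapse = ", "))
  an <- gsub("\\*", "'", atom_name)
  out <- rep("Unclassified", length(an))
  out[an %in% .dna_backbone_atoms] <- "Backbone"
  for (b in unique(rn)) {
    i <- rn == b & out == "Unclassified"
    out[i & an %in% .dna_major_atoms[[b]]] <- "MajorGroove"
    i <- rn == b & out == "Unclassified"
    out[i & an %in% .dna_minor_atoms[[b]]] <- "MinorGroove"
  }
  out
}
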