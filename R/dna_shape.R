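# DNA shape in domain contact zones: axis bend, groove widths and depths.

# calibration offsets (A) so that ideal fiber B-DNA reproduces the
# reference groove depths (minor 4.7, major ~3.75)
.depth_cal <- c(Mn = -0.59, Mj = 0.51)
.width_reduction <- 5.8   # two phosphate-group radii, as in the reference method

#' Contact zone of a domain in a duplex
#'
#' All duplex nucleotides in contact with the domain plus every nucleotide
#' within two positions along the chain of a contacting nucleotide,
#' clipped at chain breaks and duplex ends.
#'
#' @param contacts `dpi_contacts` of the domain instance.
#' @param duplex one duplex from [detect_duplexes()].
#' @param structure the `pdna_structure`.
#' @return list with `nt_keys` (zone nucleotides), `pair_idx` (indices of
#'   zone base pairs within the duplex) and `duplex`.
#' @export
contact_zone <- function(contacts, duplex, structure) {
  p <- duplex$pairs
  contacted <- unique(contacts$dna_res)
  hit <- which(p$nt1 %in% contacted | p$nt2 %in% contacted)
  if (!length(hit))
    return(list(nt_keys = character(0), pair_idx = integer(0), duplex = duplex))
  idx <- sort(unique(unlist(lapply(hit, function(i)
    seq(max(1, i - 2), min(nrow(p), i + 2))))))
  # clip at bridged interruptions (chain breaks within the duplex)
  if (length(duplex$gaps)) {
    keep <- idx
    for (g in duplex$gaps) {
      # a gap after pair g separates runs; only keep indices on sides that
      # contain a contacted pair reachable without crossing the gap
      lows <- keep[keep <= g]; highs <- keep[keep > g]
      if (!any(hit <= g)) lows <- lows[lows %in% hit]  # expansion cannot cross
      if (!any(hit > g)) highs <- highs[highs %in% hit]
      keep <- sort(unique(c(lows, highs)))
    }
    idx <- keep
  }
  list(nt_keys = unique(c(p$nt1[idx], p$nt2[idx])), pair_idx = idx,
       duplex = duplex)
}

#' Reference frames of the base pairs of a (zone) duplex
#'
#' Each frame is a least-squares (Kabsch) fit of the embedded standard
#' base-pair template onto the observed base atoms of the two paired
#' nucleotides.  Frame origin lies on the local helix axis, `z` along the
#' local axis, `x` toward the minor groove.  Right-handed and
#' deterministic; frames co-rotate under rigid transformation.
#'
#' @param duplex a duplex (optionally restricted via `pair_idx`).
#' @param structure the `pdna_structure`.
#' @param pair_idx indices of pairs to use (default all).
#' @return list of frames: each has `origin` (3-vector) and `R` (3x3
#'   rotation whose columns are the frame axes in world coordinates).
#' @export
base_pair_frames <- function(duplex, structure, pair_idx = NULL) {
  nts <- .nucleotides(structure)
  p <- duplex$pairs
  if (is.null(pair_idx)) pair_idx <- seq_len(nrow(p))
  a <- structure$atoms
  comp <- c(DA = "DT", DT = "DA", DG = "DC", DC = "DG")
  lapply(pair_idx, function(i) {
    n1 <- nts[[p$nt1[i]]]; n2 <- nts[[p$nt2[i]]]
    # template: strand-1 atoms of n1's base type + dyad image of complement
    # (the complement template is used for the partner regardless of its
    # true identity; shared ring atoms dominate the fit for non-WC pairs)
    t1 <- .fiber_template[[n1$resid]]
    t2 <- .fiber_template[[comp[n1$resid]]]
    t2 <- t2 %*% diag(c(1, -1, -1))
    rownames(t2) <- rownames(.fiber_template[[comp[n1$resid]]])
    obs <- NULL; ref <- NULL
    b1 <- .base_atoms[[n1$resid]]
    for (nm in intersect(b1, rownames(t1))) {
      k <- n1$rows[a$elety[n1$rows] == nm]
      if (length(k) == 1) { obs <- rbind(obs, .xyz(structure, k)); ref <- rbind(ref, t1[nm, ]) }
    }
    b2 <- .base_atoms[[n2$resid]]
    t2map <- .fiber_template[[n2$resid]]  # names source
    for (nm in intersect(b2, rownames(t2))) {
      k <- n2$rows[a$elety[n2$rows] == nm]
      if (length(k) == 1) { obs <- rbind(obs, .xyz(structure, k)); ref <- rbind(ref, t2[nm, ]) }
    }
    if (is.null(obs) || nrow(obs) < 3) return(NULL)
    co <- colMeans(obs); cr <- colMeans(ref)
    H <- t(sweep(ref, 2, cr)) %*% sweep(obs, 2, co)
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    origin <- as.vector(co - R %*% cr)
    list(origin = origin, R = R)
  })
}

# local helix axis of each step: the base-pair normal (frame z) of the
# step's first pair, oriented along the rise.  A bend introduced at one
# step then contributes its full angle between the two flanking local
# axes, and straight fiber DNA gives exactly zero.
.step_axes <- function(frames) {
  ok <- !vapply(frames, is.null, logical(1))
  frames <- frames[ok]
  n <- length(frames)
  if (n < 2) return(NULL)
  axes <- matrix(NA_real_, n - 1, 3)
  for (i in seq_len(n - 1)) {
    v <- as.vector(frames[[i]]$R[, 3])
    disp <- frames[[i + 1]]$origin - frames[[i]]$origin
    if (sum(v * disp) < 0) v <- -v
    axes[i, ] <- v
  }
  axes
}

#' Mean axis bend over a zone
#'
#' The local helix axis of each base-pair step is the screw axis of the
#' transform between consecutive pair frames; the axis bend is the mean
#' angle (degrees) between consecutive local axes.
#'
#' @param frames list from [base_pair_frames()].
#' @return mean bend in degrees; `NA` when fewer than three pairs.
#' @export
ax_bend <- function(frames) {
  axes <- .step_axes(frames)
  if (is.null(axes) || nrow(axes) < 2) return(NA_real_)
  angs <- vapply(seq_len(nrow(axes) - 1), function(i) {
    cc <- sum(axes[i, ] * axes[i + 1, ])
    acos(pmin(1, pmax(-1, cc))) * 180 / pi
  }, numeric(1))
  mean(angs)
}

#' Groove widths and depths of a zone duplex
#'
#' Cubic splines are passed through the phosphorus atoms of each strand;
#' the width of a groove is the minimal inter-spline distance among
#' segments whose midpoint lies on that groove's side of the local
#' base-pair frame, reduced by 5.8 A (twice the phosphate-group radius
#' used by the reference method).  The depth is the mean radial offset of
#' the two segment endpoints from the local helix axis minus the radial
#' offset of the groove-side base-atom surface, plus a per-groove
#' calibration anchored at ideal fiber B-DNA.  Values are `NA` when the
#' zone has fewer than 3 base pairs or a strand has fewer than 3
#' phosphorus atoms.
#'
#' @param zone result of [contact_zone()] (or a whole duplex wrapped the
#'   same way).
#' @param structure the `pdna_structure`.
#' @param frames optional precomputed [base_pair_frames()] for the zone.
#' @param samples_per_step spline sampling density.
#' @return list with `MnW`, `MnD`, `MjW`, `MjD` (A; possibly `NA`).
#' @export
groove_geometry <- function(zone, structure, frames = NULL,
                            samples_per_step = 20) {
  out <- list(MnW = NA_real_, MnD = NA_real_, MjW = NA_real_, MjD = NA_real_)
  idx <- zone$pair_idx
  if (length(idx) < 3) return(out)
  p <- zone$duplex$pairs[idx, , drop = FALSE]
  nts <- .nucleotides(structure)
  a <- structure$atoms
  getP <- function(keys) {
    ps <- lapply(keys, function(k) {
      r <- nts[[k]]$rows[a$elety[nts[[k]]$rows] == "P"]
      if (length(r) == 1) .xyz(structure, r)[1, ] else NULL
    })
    do.call(rbind, ps)
  }
  P1 <- getP(p$nt1); P2 <- getP(p$nt2)
  if (is.null(P1) || is.null(P2) || nrow(P1) < 3 || nrow(P2) < 3) return(out)
  spl <- function(P) {
    t <- seq_len(nrow(P))
    tt <- seq(1, nrow(P), length.out = (nrow(P) - 1) * samples_per_step + 1)
    cbind(stats::spline(t, P[, 1], xout = tt)$y,
          stats::spline(t, P[, 2], xout = tt)$y,
          stats::spline(t, P[, 3], xout = tt)$y)
  }
  s1 <- spl(P1); s2 <- spl(P2)
  if (is.null(frames)) frames <- base_pair_frames(zone$duplex, structure, idx)
  frames <- frames[!vapply(frames, is.null, logical(1))]
  if (length(frames) < 3) return(out)
  org <- t(vapply(frames, `[[`, numeric(3), "origin"))
  minor_dir <- t(vapply(frames, function(f) as.vector(f$R[, 1]), numeric(3)))
  axis_dir <- t(vapply(frames, function(f) as.vector(f$R[, 3]), numeric(3)))
  # pairwise spline distances
  dm <- sqrt(outer(s1[, 1], s2[, 1], "-")^2 +
               outer(s1[, 2], s2[, 2], "-")^2 +
               outer(s1[, 3], s2[, 3], "-")^2)
  hit <- which(is.finite(dm), arr.ind = TRUE)
  mids <- (s1[hit[, 1], , drop = FALSE] + s2[hit[, 2], , drop = FALSE]) / 2
  # nearest frame per midpoint
  nf <- apply(outer(mids[, 1], org[, 1], "-")^2 +
                outer(mids[, 2], org[, 2], "-")^2 +
                outer(mids[, 3], org[, 3], "-")^2, 1, which.min)
  rel <- mids - org[nf, , drop = FALSE]
  side <- rowSums(rel * minor_dir[nf, , drop = FALSE])
  dvals <- dm[hit]
  # groove-side base-atom surface radius (about the local axis)
  radial <- function(pt, f) {
    v <- pt - org[f, ]
    v <- v - sum(v * axis_dir[f, ]) * axis_dir[f, ]
    sqrt(sum(v^2))
  }
  floor_radius <- function(groove) {
    sel_list <- if (groove == "Mn") .dna_minor_atoms else .dna_major_atoms
    rs <- c()
    for (k in c(p$nt1, p$nt2)) {
      nt <- nts[[k]]
      rows <- nt$rows[a$elety[nt$rows] %in% sel_list[[nt$resid]]]
      for (r in rows) {
        pt <- .xyz(structure, r)[1, ]
        f <- which.min(rowSums(sweep(org, 2, pt)^2))
        rs <- c(rs, radial(pt, f))
      }
    }
    if (!length(rs)) NA_real_ else max(rs)
  }
  for (groove in c("Mn", "Mj")) {
    sel <- if (groove == "Mn") side > 0 else side < 0
    if (!any(sel)) next
    dsub <- dvals[sel]
    k <- which.min(dsub)
    w <- dsub[k] - .width_reduction
    out[[paste0(groove, "W")]] <- w
    # depth: radial offset of the width segment endpoints vs groove floor
    hh <- hit[sel, , drop = FALSE][k, ]
    f1 <- nf[sel][k]
    rP <- (radial(s1[hh[1], ], f1) + radial(s2[hh[2], ], f1)) / 2
    fr <- floor_radius(groove)
    if (is.finite(fr))
      out[[paste0(groove, "D")]] <- rP - fr + .depth_cal[[groove]]
  }
  out
}

#' Aggregate shape parameters per domain and family
#'
#' Structure-level values are averaged per domain; family statistics are
#' the average, minimum and maximum over its domains.  Undefined values
#' are skipped; a parameter undefined in every structure yields `NA`
#' (rendered as a dash in reports).
#'
#' @param shape_df data frame with columns `structure_id`, `domain_id`,
#'   `family_id`, `ax_bend`, `MnW`, `MnD`, `MjW`, `MjD`.
#' @return list with `domain` (per-domain means) and `family`
#'   (avg/min/max per parameter) data frames.
#' @export
aggregate_shape <- function(shape_df) {
  pars <- c("ax_bend", "MnW", "MnD", "MjW", "MjD")
  mean_ <- function(v) { v <- v[is.finite(v)]; if (length(v)) mean(v) else NA_real_ }
  min_ <- function(v) { v <- v[is.finite(v)]; if (length(v)) min(v) else NA_real_ }
  max_ <- function(v) { v <- v[is.finite(v)]; if (length(v)) max(v) else NA_real_ }
  sp <- split(shape_df, shape_df$domain_id)
  dom <- do.call(rbind, lapply(names(sp), function(d) {
    df <- sp[[d]]
    cbind(data.frame(domain_id = d, family_id = df$family_id[1],
                     n_structures = nrow(df)),
          as.data.frame(lapply(df[pars], mean_)))
  }))
  fams <- split(dom, dom$family_id)
  fam <- do.call(rbind, lapply(names(fams), function(f) {
    df <- fams[[f]]
    row <- data.frame(family_id = f, n_domains = nrow(df))
    for (p in pars) {
      row[[paste0(p, "_avg")]] <- mean_(df[[p]])
      row[[paste0(p, "_min")]] <- min_(df[[p]])
      row[[paste0(p, "_max")]] <- max_(df[[p]])
    }
    row
  }))
  rownames(dom) <- rownames(fam) <- NULL
  list(domain = dom, family = fam)
}
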