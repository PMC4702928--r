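# Synthetic protein-DNA complexes with known ground truth: ideal fiber
# B-DNA plus peptide probes placed to realize designed contacts.

.comp_base <- c(DA = "DT", DT = "DA", DG = "DC", DC = "DG")

.rotz <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# rotation matrix about unit axis u by deg (Rodrigues)
.rotaxis <- function(u, deg) {
  a <- deg * pi / 180
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Build an ideal fiber B-form DNA duplex
#'
#' The duplex is assembled from an embedded repeating unit (see
#' `R/data-fiber.R`): each base pair is the unit rotated by `twist` degrees
#' and translated by `rise` A along the global z axis, so the helix axis is
#' straight along z.  Chain A holds `sequence` 5'->3'; chain B is its
#' reverse complement.  An optional bend rotates all pairs beyond a given
#' step about a local in-plane axis.
#'
#' @param sequence character string over A/C/G/T, length >= 3.
#' @param twist helical twist per step (degrees, default 36).
#' @param rise rise per step (A, default 3.38).
#' @param bend_step optional `list(position =, angle =)`: a bend of
#'   `angle` degrees introduced at step `position` (between pair
#'   `position` and `position + 1`).
#' @param id structure identifier.
#' @param chains chain identifiers for the two strands.
#' @return a `pdna_structure` (without bonds; run [covalent_neighbors()]).
#' @export
build_ideal_bdna <- function(sequence, twist = 36.0, rise = 3.38,
                             bend_step = NULL, id = "fiber",
                             chains = c("A", "B")) {
  seqv <- strsplit(toupper(sequence), "")[[1]]
  if (length(seqv) < 3) stop("sequence length must be >= 3")
  if (!all(seqv %in% c("A", "C", "G", "T")))
    stop("sequence must be over A/C/G/T")
  n <- length(seqv)
  res1 <- paste0("D", seqv)
  rows <- list()
  pair_of_chainA <- function(j) n - j  # chain A residue j sits at pair n-j
  for (j in seq_len(n)) {
    i <- pair_of_chainA(j)
    R <- .rotz(twist * i); off <- c(0, 0, rise * i)
    tm <- .fiber_template[[res1[j]]]
    xyz <- t(R %*% t(tm)) + matrix(off, nrow(tm), 3, byrow = TRUE)
    dimnames(xyz) <- NULL
    rows[[length(rows) + 1]] <- data.frame(
      chain = chains[1], resno = j, insert = "", resid = res1[j],
      elety = rownames(tm),
      elesy = substr(rownames(tm), 1, 1),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], het = FALSE,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(n)) {
    i <- k - 1                         # chain B residue k sits at pair k-1
    typ <- unname(.comp_base[res1[n + 1 - k]])
    R <- .rotz(twist * i); off <- c(0, 0, rise * i)
    tm <- .fiber_template[[typ]] %*% diag(c(1, -1, -1))  # pair dyad
    xyz <- t(R %*% t(tm)) + matrix(off, nrow(tm), 3, byrow = TRUE)
    dimnames(xyz) <- NULL
    rows[[length(rows) + 1]] <- data.frame(
      chain = chains[2], resno = k, insert = "", resid = typ,
      elety = rownames(.fiber_template[[typ]]),
      elesy = substr(rownames(.fiber_template[[typ]]), 1, 1),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], het = FALSE,
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  if (!is.null(bend_step)) {
    pos <- bend_step$position
    zc <- rise * (pos - 0.5)
    u <- .rotz(twist * (pos - 0.5)) %*% c(1, 0, 0)
    R <- .rotaxis(as.vector(u), bend_step$angle)
    # rotate all atoms of pairs with index >= pos about the point (0,0,zc)
    pr <- ifelse(atoms$chain == chains[1],
                 pair_of_chainA(atoms$resno), atoms$resno - 1)
    sel <- pr >= pos
    xyz <- as.matrix(atoms[sel, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, c(0, 0, zc))
    xyz <- t(R %*% t(xyz))
    xyz <- sweep(xyz, 2, c(0, 0, zc), "+")
    atoms[sel, c("x", "y", "z")] <- xyz
  }
  rownames(atoms) <- NULL
  structure(list(id = id, assembly_id = "1", atoms = atoms, bonds = NULL),
            class = "pdna_structure")
}

# ---- peptide geometry -----------------------------------------------------

# place atom D given A, B, C with bond |CD|, angle B-C-D (deg), torsion
# A-B-C-D (deg)
.nerf <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- ab - sum(ab * bc) * bc
  n <- -n / sqrt(sum(n^2))
  m <- pracma_cross(bc, n)
  d <- bond * (-cos(ang) * bc + sin(ang) * (cos(tor) * n + sin(tor) * m))
  C + d
}
pracma_cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                                 a[3] * b[1] - a[1] * b[3],
                                 a[1] * b[2] - a[2] * b[1])

# backbone of an ideal peptide: data frame chain "P"; GLY backbone with
# optional side chains per residue (SER adds CB+OG, LEU adds CB..CD2)
.build_peptide <- function(n, phi, psi, resnames = rep("GLY", n),
                           start_resno = 1, chi1 = 180) {
  stopifnot(length(resnames) == n)
  N <- matrix(NA, n, 3); CA <- matrix(NA, n, 3); C <- matrix(NA, n, 3)
  O <- matrix(NA, n, 3)
  N[1, ] <- c(0, 0, 0); CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- CA[1, ] + 1.525 * c(cos(pi * (180 - 111.2) / 180),
                                sin(pi * (180 - 111.2) / 180), 0)
  phi <- rep(phi, length.out = n); psi <- rep(psi, length.out = n)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- .nerf(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psi[i])
    CA[i + 1, ] <- .nerf(CA[i, ], C[i, ], N[i + 1, ], 1.458, 121.7, 180)
    C[i + 1, ] <- .nerf(C[i, ], N[i + 1, ], CA[i + 1, ], 1.525, 111.2, phi[i + 1])
  }
  for (i in seq_len(n)) {
    ref <- if (i < n) N[i + 1, ] else .nerf(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psi[i])
    v1 <- CA[i, ] - C[i, ]; v1 <- v1 / sqrt(sum(v1^2))
    v2 <- ref - C[i, ]; v2 <- v2 / sqrt(sum(v2^2))
    b <- -(v1 + v2); b <- b / sqrt(sum(b^2))
    O[i, ] <- C[i, ] + 1.231 * b
  }
  out <- list()
  for (i in seq_len(n)) {
    at <- rbind(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ])
    rn <- resnames[i]
    if (rn %in% c("SER", "LEU", "ALA", "LYS", "MET")) {
      CB <- .nerf(N[i, ], C[i, ], CA[i, ], 1.521, 110.5, 122.6)
      at <- rbind(at, CB = CB)
      if (rn == "SER") {
        OG <- .nerf(N[i, ], CA[i, ], CB, 1.417, 110.8, chi1)
        at <- rbind(at, OG = OG)
      } else if (rn == "LEU") {
        CG <- .nerf(N[i, ], CA[i, ], CB, 1.530, 116.3, chi1)
        CD1 <- .nerf(CA[i, ], CB, CG, 1.521, 110.7, 60)
        CD2 <- .nerf(CA[i, ], CB, CG, 1.521, 110.7, -60)
        at <- rbind(at, CG = CG, CD1 = CD1, CD2 = CD2)
      } else if (rn == "LYS") {
        CG <- .nerf(N[i, ], CA[i, ], CB, 1.520, 114.1, chi1)
        CD <- .nerf(CA[i, ], CB, CG, 1.520, 111.3, 180)
        CE <- .nerf(CB, CG, CD, 1.520, 111.3, 180)
        NZ <- .nerf(CG, CD, CE, 1.489, 111.9, 180)
        at <- rbind(at, CG = CG, CD = CD, CE = CE, NZ = NZ)
      } else if (rn == "MET") {
        CG <- .nerf(N[i, ], CA[i, ], CB, 1.520, 114.1, chi1)
        SD <- .nerf(CA[i, ], CB, CG, 1.803, 112.7, 180)
        CE <- .nerf(CB, CG, SD, 1.791, 100.2, 180)
        at <- rbind(at, CG = CG, SD = SD, CE = CE)
      }
    }
    out[[i]] <- data.frame(
      chain = "P", resno = start_resno + i - 1L, insert = "", resid = rn,
      elety = rownames(at), elesy = substr(rownames(at), 1, 1),
      x = at[, 1], y = at[, 2], z = at[, 3], het = FALSE,
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, out)
  rownames(atoms) <- NULL
  atoms
}

# ideal element fragments in local coordinates; `contact_resno` marks the
# residue carrying the designed side chain.  Narrow-groove targets get a
# longer side-chain arm (lysine / methionine) so the peptide body stays
# clear of the groove walls.
.probe_fragment <- function(kind = c("helix", "strand", "loop"),
                            interaction = c("hbond", "hydrophobic"),
                            start_resno = 101L, target = "Backbone",
                            chi1 = 180) {
  kind <- match.arg(kind); interaction <- match.arg(interaction)
  side <- if (interaction == "hbond") {
    if (target == "MinorGroove") "LYS" else "SER"
  } else {
    if (target == "MinorGroove") "MET" else "LEU"
  }
  key <- paste(kind, side, chi1)
  if (!is.null(.dpi_cache[[key]])) {
    frag <- .dpi_cache[[key]]
    off <- start_resno - frag$atoms$resno[1]
    frag$atoms$resno <- frag$atoms$resno + off
    frag$contact_resno <- frag$contact_resno + off
    names(frag$elements) <- as.integer(names(frag$elements)) + off
    return(frag)
  }
  if (kind == "helix") {
    rn <- rep("GLY", 12); rn[7] <- side
    atoms <- .build_peptide(12, -57, -47, rn, start_resno, chi1)
    contact_resno <- start_resno + 6L
  } else if (kind == "loop") {
    rn <- rep("GLY", 5); rn[3] <- side
    atoms <- .build_peptide(5, -75, 145, rn, start_resno, chi1)
    contact_resno <- start_resno + 2L
  } else {
    rn <- rep("GLY", 5); rn[3] <- side
    sA <- .build_peptide(5, -139, 135, rn, start_resno, chi1)
    sB <- .build_peptide(5, -139, 135, rep("GLY", 5), start_resno + 10L)
    sB <- .pair_strands(sA, sB)
    atoms <- rbind(sA, sB)
    contact_resno <- start_resno + 2L
  }
  # element of each fragment residue under the package's own assignment,
  # used to decide which stray near-contacts are type-preserving
  stf <- list(id = "frag", assembly_id = "1", atoms = atoms, bonds = NULL)
  class(stf) <- "pdna_structure"
  ssf <- assign_secondary_structure(stf)
  el <- stats::setNames(ssf$element, ssf$resno)
  ca <- c(SER = "OG", LYS = "NZ", LEU = "CD1", MET = "CE")[[side]]
  # anchor defines the arm axis (contact atom minus CB), so the approach
  # aligns the whole side chain rather than only its last bond
  aa <- "CB"
  # idealized donor/acceptor directions of the fragment's N/O atoms in the
  # local frame (away from covalent neighbors), for stray-power evaluation
  axyzf <- as.matrix(atoms[, c("x", "y", "z")])
  pno_ideal <- matrix(NA_real_, nrow(atoms), 3)
  for (i in which(atoms$elesy %in% c("N", "O"))) {
    d2 <- (axyzf[, 1] - axyzf[i, 1])^2 + (axyzf[, 2] - axyzf[i, 2])^2 +
      (axyzf[, 3] - axyzf[i, 3])^2
    nbs <- which(d2 > 1e-9 & d2 < 1.85^2)
    if (!length(nbs)) next
    s <- colSums(sweep(axyzf[nbs, , drop = FALSE], 2, axyzf[i, ]) /
                   sqrt(d2[nbs]))
    if (sqrt(sum(s^2)) > 1e-8) pno_ideal[i, ] <- -s / sqrt(sum(s^2))
  }
  # probe atoms bonded to N/O (excluded from the non-polar set); geometric,
  # independent of placement
  bonded_no <- vapply(seq_len(nrow(atoms)), function(i) {
    nbs <- which(atoms$resno == atoms$resno[i] &
                   sqrt((atoms$x - atoms$x[i])^2 + (atoms$y - atoms$y[i])^2 +
                          (atoms$z - atoms$z[i])^2) < 1.85)
    any(atoms$elesy[nbs] %in% c("N", "O") & nbs != i)
  }, logical(1))
  frag <- list(atoms = atoms, contact_resno = contact_resno,
               contact_atom = ca, anchor_atom = aa,
               elements = el, bonded_no = bonded_no, pno_ideal = pno_ideal)
  .dpi_cache[[key]] <- frag
  frag
}

# rigidly place strand B antiparallel to strand A so that the standard
# ladder hydrogen bonds form; deterministic local optimization
.pair_strands <- function(sA, sB) {
  getv <- function(df, rno, nm) {
    r <- df[df$resno == rno & df$elety == nm, ]
    c(r$x, r$y, r$z)
  }
  nA <- range(sA$resno); nB <- range(sB$resno)
  # registry: A(i) <-> B(j) with j = nB[2] - (i - nA[1])
  pairs <- list(c(nA[1] + 1, nB[2] - 1), c(nA[1] + 3, nB[2] - 3))
  xyzB <- as.matrix(sB[, c("x", "y", "z")])
  ctrB <- colMeans(xyzB)
  xyzA <- as.matrix(sA[, c("x", "y", "z")])
  idx <- function(df, r, nm) which(df$resno == r & df$elety == nm)
  caA <- xyzA[sA$elety == "CA", , drop = FALSE]
  caB_i <- which(sB$elety == "CA")
  # Kabsch-Sander energy of a backbone hydrogen bond donor->acceptor
  ks_energy <- function(N, Cp, Op, O, C) {
    H <- N + (Cp - Op) / sqrt(sum((Cp - Op)^2))
    0.084 * 332 * (1 / sqrt(sum((O - N)^2)) + 1 / sqrt(sum((C - H)^2)) -
                     1 / sqrt(sum((O - H)^2)) - 1 / sqrt(sum((C - N)^2)))
  }
  obj <- function(par) {
    R <- .rotaxis(c(1, 0, 0), par[4]) %*% .rotaxis(c(0, 1, 0), par[5]) %*%
      .rotaxis(c(0, 0, 1), par[6])
    newB <- t(R %*% t(sweep(xyzB, 2, ctrB))) +
      matrix(ctrB + par[1:3], nrow(xyzB), 3, byrow = TRUE)
    s <- 0
    for (pr in pairs) {
      # both ladder directions must be good hydrogen bonds energetically
      eAB <- ks_energy(xyzA[idx(sA, pr[1], "N"), ],
                       xyzA[idx(sA, pr[1] - 1, "C"), ],
                       xyzA[idx(sA, pr[1] - 1, "O"), ],
                       newB[idx(sB, pr[2], "O"), ], newB[idx(sB, pr[2], "C"), ])
      eBA <- ks_energy(newB[idx(sB, pr[2], "N"), ],
                       newB[idx(sB, pr[2] - 1, "C"), ],
                       newB[idx(sB, pr[2] - 1, "O"), ],
                       xyzA[idx(sA, pr[1], "O"), ], xyzA[idx(sA, pr[1], "C"), ])
      s <- s + (min(0, eAB) + 2.8)^2 + (min(0, eBA) + 2.8)^2
      s <- s + 0.3 * (sqrt(sum((xyzA[idx(sA, pr[1], "N"), ] -
                                  newB[idx(sB, pr[2], "O"), ])^2)) - 2.91)^2
      s <- s + 0.3 * (sqrt(sum((newB[idx(sB, pr[2], "N"), ] -
                                  xyzA[idx(sA, pr[1], "O"), ])^2)) - 2.91)^2
    }
    # soft clash penalty on CA distances
    caB <- newB[caB_i, , drop = FALSE]
    dm <- sqrt(outer(caA[, 1], caB[, 1], "-")^2 +
                 outer(caA[, 2], caB[, 2], "-")^2 +
                 outer(caA[, 3], caB[, 3], "-")^2)
    s + sum(pmax(0, 4.2 - dm)^2)
  }
  # init: translate to one H-bond side of A and flip about the sheet normal;
  # several starts, keep the best fit
  hdir <- getv(sA, nA[1] + 1, "N") - getv(sA, nA[1] + 1, "CA")
  hdir <- hdir / sqrt(sum(hdir^2))
  e1 <- getv(sA, nA[2], "CA") - getv(sA, nA[1], "CA")
  e1 <- e1 / sqrt(sum(e1^2))
  u0 <- pracma_cross(e1, hdir)
  ctrA <- colMeans(as.matrix(sA[sA$elety == "CA", c("x", "y", "z")]))
  xyzB_orig <- xyzB; ctrB_orig <- ctrB
  best <- NULL
  for (sgn in c(1, -1)) for (ax in list(u0, hdir)) for (dst in c(4.4, 4.8, 5.2)) {
    Rinit <- .rotaxis(ax, 180)
    xyz0 <- t(Rinit %*% t(sweep(xyzB_orig, 2, ctrB_orig))) +
      matrix(ctrA + sgn * dst * hdir, nrow(xyzB_orig), 3, byrow = TRUE)
    sB[, c("x", "y", "z")] <- xyz0
    xyzB <- xyz0; ctrB <- colMeans(xyzB)
    fit <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value)
      best <- list(value = fit$value, par = fit$par, xyzB = xyzB, ctrB = ctrB)
  }
  xyzB <- best$xyzB; ctrB <- best$ctrB
  R <- .rotaxis(c(1, 0, 0), best$par[4]) %*% .rotaxis(c(0, 1, 0), best$par[5]) %*%
    .rotaxis(c(0, 0, 1), best$par[6])
  sB[, c("x", "y", "z")] <- t(R %*% t(sweep(xyzB, 2, ctrB))) +
    matrix(ctrB + best$par[1:3], nrow(xyzB), 3, byrow = TRUE)
  sB
}

# ---- probe placement ------------------------------------------------------

# candidate DNA target atoms for (element, kind) near chain A position `at`
.pick_targets <- function(structure, target, interaction, at = NULL) {
  a <- structure$atoms
  nt <- a[a$chain == "A", ]
  n <- max(nt$resno)
  cand_res <- if (!is.null(at)) unique(pmin(n - 1, pmax(2, at + 0:1)))
  else if (target == "MinorGroove") c(2, 3, n - 1, n - 2, 4, n - 3)
  else (n %/% 2) + c(-1, 0, 1, 2, -2, 3)
  cand_res <- cand_res[cand_res >= 2 & cand_res <= n - 1]
  prefer <- if (interaction == "hbond") {
    switch(target,
           Backbone = c("OP1", "OP2", "O3'"),
           MajorGroove = c("O6", "N7", "O4", "N4", "N6"),
           MinorGroove = c("O2", "N3", "N2"))
  } else {
    switch(target,
           Backbone = c("C5'", "C2'", "C4'"),
           MajorGroove = c("C7", "C8", "C5", "C6"),
           MinorGroove = c("C2"))
  }
  out <- integer(0)
  for (r in cand_res) for (ch in c("A", "B")) for (nm in prefer) {
    rr <- if (ch == "A") r else n + 1 - r
    sel <- which(a$chain == ch & a$resno == rr & a$elety == nm)
    if (length(sel) == 1 &&
        classify_dna_atom(a$resid[sel], a$elety[sel]) == target)
      out <- c(out, sel)
  }
  if (!length(out))
    stop("no suitable ", interaction, " target atom for ", target,
         " near chain A residue ", paste(cand_res, collapse = "/"))
  out
}

# quasi-uniform unit directions (Fibonacci sphere)
.fib_dirs <- function(m = 200) {
  i <- seq_len(m) - 0.5
  phi <- acos(1 - 2 * i / m)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# maximal intrusion of any given sphere into the surface-to-surface
# segment p--q (endpoint radii rp, rq); <= 0 means the line of sight is
# clear, larger values mean deeper blocking
.seg_intrusion <- function(xyz, rad, p, q, rp = 1.7, rq = 1.7) {
  v <- q - p; L <- sqrt(sum(v^2))
  if (rp + rq >= L) return(-Inf)
  vh <- v / L
  p2 <- p + rp * vh; q2 <- q - rq * vh
  v2 <- q2 - p2; L2 <- sum(v2^2)
  t <- ((xyz[, 1] - p2[1]) * v2[1] + (xyz[, 2] - p2[2]) * v2[2] +
          (xyz[, 3] - p2[3]) * v2[3]) / L2
  t <- pmin(1, pmax(0, t))
  dx <- p2[1] + t * v2[1] - xyz[, 1]
  dy <- p2[2] + t * v2[2] - xyz[, 2]
  dz <- p2[3] + t * v2[3] - xyz[, 3]
  max(rad - sqrt(dx^2 + dy^2 + dz^2))
}

.seg_clear <- function(xyz, rad, p, q, rp = 1.7, rq = 1.7) {
  .seg_intrusion(xyz, rad, p, q, rp, rq) <= 0
}

# outward radial direction of a generator-built DNA atom: away from the
# local helix axis, approximated by base-pair C1' midpoints
.radial_dir <- function(structure, i) {
  a <- structure$atoms
  ch <- a$chain[i]; r <- a$resno[i]
  nmax <- max(a$resno[a$chain == "A"])
  c1 <- function(ch_, r_) {
    k <- which(a$chain == ch_ & a$resno == r_ & a$elety == "C1'")
    if (length(k) != 1) return(NULL)
    c(a$x[k], a$y[k], a$z[k])
  }
  mid <- function(ch_, r_) {
    p1 <- c1(ch_, r_)
    p2 <- c1(if (ch_ == "A") "B" else "A", nmax + 1 - r_)
    if (is.null(p1) || is.null(p2)) return(NULL)
    (p1 + p2) / 2
  }
  m0 <- mid(ch, r)
  mp <- mid(ch, max(1, r - 1)); mn <- mid(ch, min(nmax, r + 1))
  axd <- if (!is.null(mp) && !is.null(mn) && sum((mn - mp)^2) > 1e-6)
    (mn - mp) / sqrt(sum((mn - mp)^2)) else c(0, 0, 1)
  tp <- c(a$x[i], a$y[i], a$z[i])
  v <- tp - m0
  v <- v - sum(v * axd) * axd
  nv <- sqrt(sum(v^2))
  if (nv < 1e-6) return(.orth(axd))
  v / nv
}

# idealized outward direction of atom `i`: away from covalent neighbors
.ideal_dir <- function(structure, i, nb) {
  a <- structure$atoms
  nbs <- nb[[i]]
  p <- c(a$x[i], a$y[i], a$z[i])
  u <- colSums(do.call(rbind, lapply(nbs, function(m) {
    v <- c(a$x[m], a$y[m], a$z[m]) - p; v / sqrt(sum(v^2))
  })))
  if (sqrt(sum(u^2)) < 1e-8) {
    v <- p - c(0, 0, p[3])  # radial fallback
    return(v / sqrt(sum(v^2)))
  }
  -u / sqrt(sum(u^2))
}

#' Place a peptide probe element against a duplex
#'
#' Positions an ideal helix, two-stranded antiparallel sheet, or extended
#' loop so that exactly one designed atom pair satisfies the targeted
#' contact criterion: a serine OG donor/acceptor 2.9 A from a listed N/O
#' atom of the target DNA element (hydrogen bond), or a leucine CD1 4.5 A
#' from a target carbon with cluster support (hydrophobic).  All other
#' criteria are kept unmet by at least a 1 A margin; placement is searched
#' over the free spin angle (with seeded jitter) and fails with an error
#' if no non-clashing orientation exists.
#'
#' @param structure a `pdna_structure` containing the duplex (and any
#'   previously placed probes).
#' @param kind `"helix"`, `"strand"` or `"loop"`.
#' @param target `"Backbone"`, `"MajorGroove"` or `"MinorGroove"`.
#' @param interaction `"hbond"` or `"hydrophobic"`.
#' @param at optional chain A residue number of the target nucleotide.
#' @param start_resno first residue number of the probe (chain `P`).
#' @param rng a `sample.int`-compatible seed offset for jitter.
#' @return the structure with probe atoms appended; attribute
#'   `probe_truth` gives the designed contact type.
#' @export
place_probe_element <- function(structure, kind, target,
                                interaction = c("hbond", "hydrophobic"),
                                at = NULL, start_resno = 101L, rng = 0L) {
  interaction <- match.arg(interaction)
  structure <- covalent_neighbors(structure)
  nb <- neighbor_list(structure)
  a <- structure$atoms
  tgts <- .pick_targets(structure, target, interaction, at)
  d0 <- if (interaction == "hbond") 2.9 else 4.5
  elem <- c(helix = "Helix", strand = "Strand", loop = "Loop")[[kind]]
  set.seed(20151209 + rng)
  # candidate approach directions: quasi-uniform directions ranked by the
  # clearance of the contact-atom position from all other atoms.  Hydrogen
  # bond designs keep the approach within 60 deg of the acceptor's
  # idealized direction, so the designed power stays >= 0.5, well above
  # the 0.1 threshold; hydrophobic designs additionally require the
  # designed line of sight to be clear.
  axyz <- cbind(a$x, a$y, a$z)
  arad <- .vdw_radii[a$elesy]; arad[is.na(arad)] <- .vdw_default
  arad[a$elesy == "H"] <- -1
  dirs <- .fib_dirs(240)
  phases <- list(list(margin = 1.0, nth = 12, ndir = 32, d0x = 0),
                 list(margin = 0.3, nth = 12, ndir = 32, d0x = 0),
                 list(margin = 0.3, nth = 24, ndir = 64,
                      d0x = if (interaction == "hbond") 0.25 else 0))
  for (phase in phases) {
   margin <- phase$margin
   thetas <- seq(0, 359, length.out = phase$nth + 1)[seq_len(phase$nth)] +
     stats::runif(phase$nth, 0, 360 / phase$nth)
   for (d0cur in unique(c(d0, d0 + phase$d0x))) {
   for (chi1 in c(180, -60, 60)) {
    frag <- .probe_fragment(kind, interaction, start_resno, target, chi1)
    fa <- frag$atoms
    fxyz <- as.matrix(fa[, c("x", "y", "z")])
    ci <- which(fa$resno == frag$contact_resno & fa$elety == frag$contact_atom)
    ai <- which(fa$resno == frag$contact_resno & fa$elety == frag$anchor_atom)
    u <- fxyz[ci, ] - fxyz[ai, ]; u <- u / sqrt(sum(u^2))
    if (!identical(unname(frag$elements[as.character(frag$contact_resno)]), elem))
      next
    ctx <- .probe_ctx(structure, fa, frag, elem)
    for (tgt in tgts) {
      tp <- c(a$x[tgt], a$y[tgt], a$z[tgt])
      cand <- dirs
      if (interaction == "hbond") {
        # designed power cos(dev) stays >= 0.25, a 2.5x safety over the
        # 0.1 threshold
        w <- .ideal_dir(structure, tgt, nb)
        cand <- cand[cand %*% w >= 0.25, , drop = FALSE]
      }
      oth <- which(seq_len(nrow(a)) != tgt)
      clear <- numeric(nrow(cand)); keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        v <- cand[k, ]
        # clearance along the whole escape ray (side-chain arm and beyond)
        cl <- Inf
        for (s in c(0, 1.5, 3, 4.5, 6.5)) {
          q <- tp + (d0cur + s) * v
          d2 <- (axyz[oth, 1] - q[1])^2 + (axyz[oth, 2] - q[2])^2 +
            (axyz[oth, 3] - q[3])^2
          cl <- min(cl, min(d2))
        }
        clear[k] <- sqrt(cl)
        keep[k] <- clear[k] >= 2.7
        if (keep[k] && interaction == "hydrophobic") {
          q <- tp + d0cur * v
          d2 <- (axyz[oth, 1] - q[1])^2 + (axyz[oth, 2] - q[2])^2 +
            (axyz[oth, 3] - q[3])^2
          near <- oth[d2 < (d0 + 4)^2]
          keep[k] <- .seg_clear(axyz[near, , drop = FALSE], arad[near], q, tp)
        }
      }
      ord <- order(-clear)
      ord <- ord[keep[ord]][seq_len(min(phase$ndir, sum(keep)))]
      for (k in ord) {
        v <- cand[k, ]; q <- tp + d0cur * v
        axis <- pracma_cross(u, -v)
        if (sqrt(sum(axis^2)) < 1e-8) axis <- .orth(u)
        angle <- acos(pmin(1, pmax(-1, sum(u * -v)))) * 180 / pi
        R0 <- .rotaxis(axis, angle)
        for (th in thetas) {
          R <- .rotaxis(v, th) %*% R0
          xyz <- t(R %*% t(sweep(fxyz, 2, fxyz[ci, ]))) +
            matrix(q, nrow(fxyz), 3, byrow = TRUE)
          if (!.probe_ok(ctx, fa, xyz, ci, tgt, interaction, target,
                         margin = margin, structure = structure, R = R,
                         frag = frag)) next
          fa2 <- fa
          fa2[, c("x", "y", "z")] <- xyz
          out <- structure
          out$atoms <- rbind(structure$atoms, fa2)
          rownames(out$atoms) <- NULL
          out$bonds <- NULL
          attr(out, "probe_truth") <- contact_type(elem, target)
          return(out)
        }
      }
    }
   }
   }
  }
  stop("unsatisfiable probe placement (", kind, ", ", target, ", ",
       interaction, ")")
}

.orth <- function(v) {
  w <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- pracma_cross(v, w); u / sqrt(sum(u^2))
}

# placement context computed once per probe
.probe_ctx <- function(structure, fa, frag, elem) {
  a <- structure$atoms
  nb <- neighbor_list(structure)
  dna_idx <- which(a$chain %in% c("A", "B"))
  dna <- a[dna_idx, ]
  prev <- a[-dna_idx, , drop = FALSE]
  dno <- which(dna$elesy %in% c("N", "O"))
  dno_ideal <- matrix(NA_real_, length(dno), 3)
  for (k in seq_along(dno)) {
    i <- dna_idx[dno[k]]
    nbs <- nb[[i]]
    if (!length(nbs)) next
    p <- c(a$x[i], a$y[i], a$z[i])
    s <- colSums(do.call(rbind, lapply(nbs, function(m) {
      v <- c(a$x[m], a$y[m], a$z[m]) - p; v / sqrt(sum(v^2))
    })))
    if (sqrt(sum(s^2)) > 1e-8) dno_ideal[k, ] <- -s / sqrt(sum(s^2))
  }
  list(dna_idx = dna_idx,
       dxyz = cbind(dna$x, dna$y, dna$z),
       dna_el = classify_dna_atom(dna$resid, dna$elety),
       dno = dno, dno_ideal = dno_ideal,
       dc = which(dna$elesy == "C"),
       drad = {r <- .vdw_radii[dna$elesy]; r[is.na(r)] <- .vdw_default
               r[dna$elesy == "H"] <- -1; r},
       pxyz = if (nrow(prev)) cbind(prev$x, prev$y, prev$z) else NULL,
       pno = which(fa$elesy %in% c("N", "O")),
       pc = which(fa$elesy %in% c("C", "S") & !frag$bonded_no),
       p_ok = unname(frag$elements[as.character(fa$resno)]) == elem)
}

# margin checks for a tentative probe placement: any stray atom pair close
# enough to (or within `margin` of) a contact criterion must realize the
# designed contact type -- the type is the element pair, independent of the
# contact kind -- or involve an unclassified DNA atom (dropped from typing).
.probe_diag <- function(stage) {
  if (isTRUE(getOption("dpimodes.probe_diag"))) {
    v <- .dpi_cache$diag
    if (is.null(v)) v <- integer(0)
    v[stage] <- if (is.na(v[stage])) 1L else v[stage] + 1L
    .dpi_cache$diag <- v
  }
  invisible(NULL)
}

.probe_ok <- function(ctx, fa, xyz, ci, tgt, interaction, target,
                      margin = 1.0, structure = NULL, R = NULL,
                      frag = NULL) {
  dm <- sqrt(outer(xyz[, 1], ctx$dxyz[, 1], "-")^2 +
               outer(xyz[, 2], ctx$dxyz[, 2], "-")^2 +
               outer(xyz[, 3], ctx$dxyz[, 3], "-")^2)
  tcol <- match(tgt, ctx$dna_idx)
  # clash rule: no non-designed pair closer than 2.6
  dm2 <- dm; dm2[ci, tcol] <- Inf
  if (min(dm2) < 2.6) { .probe_diag("clash"); return(FALSE) }
  # stray polar pairs (would-be hydrogen bonds): distance margin, or for
  # closer pairs an explicit power check -- the stray must score well below
  # the 0.1 hydrogen-bond threshold (factor-2 safety)
  lim <- dm[ctx$pno, ctx$dno, drop = FALSE]
  allowed <- outer(ctx$p_ok[ctx$pno],
                   ctx$dna_el[ctx$dno] %in% c(target, "Unclassified"), "&")
  close <- which(lim < 3.7 + margin & !allowed, arr.ind = TRUE)
  if (nrow(close)) {
    if (is.null(R)) { .probe_diag("polar"); return(FALSE) }
    for (r_ in seq_len(nrow(close))) {
      ip <- ctx$pno[close[r_, 1]]; id <- ctx$dno[close[r_, 2]]
      d <- lim[close[r_, 1], close[r_, 2]]
      if (d >= 3.7) next
      fd <- min(1, max(0, (3.7 - d) / 0.7))
      v <- ctx$dxyz[ctx$dno[close[r_, 2]], ] - xyz[ip, ]
      v <- v / sqrt(sum(v^2))
      gp <- if (is.na(frag$pno_ideal[ip, 1])) 1 else
        max(0, sum((R %*% frag$pno_ideal[ip, ]) * v))
      gd <- if (is.na(ctx$dno_ideal[close[r_, 2], 1])) 1 else
        max(0, sum(ctx$dno_ideal[close[r_, 2], ] * -v))
      if (fd * gp * gd > 0.05) { .probe_diag("polarpow"); return(FALSE) }
    }
  }
  # stray non-polar pairs (would-be hydrophobic contacts): beyond the
  # distance cutoff, or robustly occluded (a blocker intruding at least
  # 0.25 A into the line of sight)
  if (length(ctx$pc) && length(ctx$dc)) {
    lim <- dm[ctx$pc, ctx$dc, drop = FALSE]
    allowed <- outer(ctx$p_ok[ctx$pc], ctx$dna_el[ctx$dc] == target, "&")
    close <- which(lim < 5.45 & !allowed, arr.ind = TRUE)
    if (nrow(close)) {
      prad <- .vdw_radii[fa$elesy]; prad[is.na(prad)] <- .vdw_default
      prad[fa$elesy == "H"] <- -1
      blockers <- rbind(ctx$dxyz, xyz)
      brad <- c(ctx$drad, prad)
      for (r_ in seq_len(nrow(close))) {
        ip <- ctx$pc[close[r_, 1]]; idc <- ctx$dc[close[r_, 2]]
        p <- xyz[ip, ]; q <- ctx$dxyz[idc, ]
        keepb <- rep(TRUE, nrow(blockers))
        keepb[idc] <- FALSE; keepb[nrow(ctx$dxyz) + ip] <- FALSE
        intr <- .seg_intrusion(blockers[keepb, , drop = FALSE],
                               brad[keepb], p, q)
        if (intr < 0.25) { .probe_diag("nonpolar"); return(FALSE) }
      }
    }
  }
  # clearance from previously placed probes
  if (!is.null(ctx$pxyz)) {
    pm <- sqrt(outer(xyz[, 1], ctx$pxyz[, 1], "-")^2 +
                 outer(xyz[, 2], ctx$pxyz[, 2], "-")^2 +
                 outer(xyz[, 3], ctx$pxyz[, 3], "-")^2)
    if (min(pm) < 4.7) { .probe_diag("prev"); return(FALSE) }
  }
  # hydrophobic design: line of sight for the designed pair
  if (interaction == "hydrophobic") {
    tmp <- structure
    fa2 <- fa; fa2[, c("x", "y", "z")] <- xyz
    tmp$atoms <- rbind(structure$atoms, fa2)
    ii <- nrow(structure$atoms) + ci
    if (!.los_pairs(tmp, cbind(ii, tgt))[1]) { .probe_diag("los"); return(FALSE) }
  }
  .probe_diag("pass")
  TRUE
}

#' Build a synthetic complex from a fixture specification
#'
#' @param dna_sequence chain A sequence, 5'->3'.
#' @param probes list of probe specs: each `list(kind =, target =,
#'   interaction =)` with optional `at` (chain A residue of the target).
#' @param twist,rise helical parameters.
#' @param bend_step optional bend, see [build_ideal_bdna()].
#' @param seed integer seed for placement jitter.
#' @param id structure identifier.
#' @return list with `structure` (bonds computed), `domain` (one-row
#'   domain-definition data frame for the probe chain) and `truth`
#'   (expected interaction-mode types and duplex length).
#' @export
build_fixture <- function(dna_sequence, probes = list(), twist = 36.0,
                          rise = 3.38, bend_step = NULL, seed = 20151209,
                          id = "fixture") {
  st <- build_ideal_bdna(dna_sequence, twist, rise, bend_step, id = id)
  truth_types <- character(0)
  # two probes designing the same contact type add nothing to the truth
  # set; keep the first of each type
  if (length(probes) > 1) {
    keykt <- vapply(probes, function(p) paste(p$kind, p$target), "")
    probes <- probes[!duplicated(keykt)]
  }
  # narrow-groove probes have the fewest viable sites; place them first
  if (length(probes) > 1) {
    tg <- vapply(probes, function(p) identical(p$target, "MinorGroove"),
                 logical(1))
    probes <- c(probes[tg], probes[!tg])
  }
  k <- 0L
  for (p in probes) {
    k <- k + 1L
    p$interaction <- if (is.null(p$interaction)) "hbond" else p$interaction
    res <- NULL
    for (att in 0:3) {
      res <- tryCatch(
        place_probe_element(st, p$kind, p$target, p$interaction,
                            at = p$at, start_resno = 100L * k + 1L,
                            rng = seed + k + att * 9973L),
        error = function(e) e)
      if (!inherits(res, "error")) break
      if (att == 1 && !is.null(p$at)) p$at <- NULL  # widen the target set
    }
    if (inherits(res, "error")) stop(res)
    st <- res
    truth_types <- c(truth_types, attr(st, "probe_truth"))
  }
  st <- covalent_neighbors(st)
  dom <- data.frame(structure_id = id, assembly_id = "1", chain_id = "P",
                    start = "1", end = "9999", domain_id = paste0(id, "_d"),
                    family_id = "fam", start_no = 1L, start_ins = "",
                    end_no = 9999L, end_ins = "",
                    stringsAsFactors = FALSE)
  list(structure = st, domain = dom,
       truth = list(types = sort_types(truth_types),
                    duplex_length = nchar(dna_sequence)))
}

#' Build a synthetic family scenario
#'
#' Generates one synthetic structure per prescribed per-structure mode and
#' the matching domain-definition table; the expected interaction class is
#' derived by set algebra from the prescription, independent of the
#' pipeline.
#'
#' @param domains named list: for each domain, a list of character vectors
#'   (one per structure) of contact-type labels such as `"H-Mj"`.
#' @param family_id family label.
#' @param dna_sequence duplex sequence used for every structure.
#' @param seed integer seed.
#' @return list with `structures` (list of fixture results), `domains`
#'   (domain-definition data frame) and `truth` (`class` character vector
#'   of types, `miscellaneous` flag, or `unclassified = TRUE` when fewer
#'   than three domains).
#' @export
make_family_scenario <- function(domains, family_id = "fam",
                                 dna_sequence = "GCGCAATTGCGC",
                                 seed = 20151209) {
  kind_of <- c(H = "helix", S = "strand", L = "loop")
  target_of <- c(Bb = "Backbone", Mj = "MajorGroove", Mn = "MinorGroove")
  structures <- list(); dom_rows <- list()
  si <- 0L
  for (dn in names(domains)) {
    for (types in domains[[dn]]) {
      si <- si + 1L
      id <- sprintf("synth%03d", si)
      probes <- lapply(seq_along(types), function(k) {
        pe <- sub("-.*", "", types[k]); de <- sub(".*-", "", types[k])
        tg <- target_of[[de]]
        list(kind = kind_of[[pe]], target = tg, interaction = "hbond",
             at = if (tg == "MinorGroove") NULL else
               2 + (2 * k) %% (nchar(dna_sequence) - 3))
      })
      fx <- build_fixture(dna_sequence, probes, seed = seed + si, id = id)
      fx$domain$domain_id <- dn
      fx$domain$family_id <- family_id
      fx$domain$structure_id <- id
      structures[[id]] <- fx
      dom_rows[[length(dom_rows) + 1]] <- fx$domain
    }
  }
  unions <- lapply(domains, function(ms) sort_types(unlist(ms)))
  truth <- if (length(domains) < 3) {
    list(unclassified = TRUE)
  } else {
    ch <- sort_types(Reduce(intersect, unions))
    list(unclassified = FALSE, class = ch, miscellaneous = length(ch) == 0)
  }
  list(structures = structures, domains = do.call(rbind, dom_rows),
       truth = truth, unions = unions)
}
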