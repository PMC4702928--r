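# Contact zones, base-pair frames, axis bend and groove geometry.

whole_zone <- function(st) {
  dup <- detect_duplexes(detect_base_pairs(st), st)[[1]]
  list(pair_idx = seq_len(dup$length), duplex = dup,
       nt_keys = dup$nt_keys)
}

test_that("contact zones expand two nucleotides and clip at ends", {
  fx <- fixture_one_probe("helix", "MajorGroove", "hbond")
  st <- fx$structure
  dup <- detect_duplexes(detect_base_pairs(st), st)[[1]]
  # synthetic contact at a mid-duplex pair
  mid <- 6
  cts <- data.frame(dna_res = c(dup$pairs$nt1[mid]))
  zn <- contact_zone(cts, dup, st)
  expect_equal(zn$pair_idx, (mid - 2):(mid + 2))
  # contact at the terminal pair clips
  cts2 <- data.frame(dna_res = c(dup$pairs$nt1[1]))
  zn2 <- contact_zone(cts2, dup, st)
  expect_equal(zn2$pair_idx, 1:3)
  # no contacts: empty zone
  zn3 <- contact_zone(data.frame(dna_res = character(0)), dup, st)
  expect_length(zn3$pair_idx, 0)
})

test_that("pair frames of an ideal duplex sit on a straight axis", {
  st <- fiber12()
  dup <- detect_duplexes(detect_base_pairs(st), st)[[1]]
  fr <- base_pair_frames(dup, st)
  org <- t(vapply(fr, `[[`, numeric(3), "origin"))
  # the generator's axis is the z axis: origins on it within fit tolerance
  expect_lt(max(abs(org[, 1])), 0.35)
  expect_lt(max(abs(org[, 2])), 0.35)
  # collinearity of origins (straight axis)
  ctr <- colMeans(org)
  sv <- svd(sweep(org, 2, ctr))
  expect_lt(sv$d[2] / sv$d[1], 0.02)
})

test_that("axis bend is zero for straight fiber DNA at any twist and rise", {
  for (pars in list(c(36, 3.38), c(34.3, 3.3), c(37, 3.5))) {
    st <- build_ideal_bdna("GCGCAATTGCGC", twist = pars[1], rise = pars[2])
    zn <- whole_zone(st)
    fr <- base_pair_frames(zn$duplex, st)
    expect_lt(abs(ax_bend(fr)), 1e-6)
  }
})

test_that("a single-step bend gives the constructed mean angle", {
  st <- build_ideal_bdna("GCGCAATTGCGCG",   # 13 bp: 12 steps, 11 angles
                         bend_step = list(position = 6, angle = 10))
  zn <- whole_zone(st)
  expect_equal(zn$duplex$length, 13)
  fr <- base_pair_frames(zn$duplex, st)
  # one bent step among 11 consecutive-axis angles
  expect_equal(ax_bend(fr), 10 / 11, tolerance = 0.06)
})

test_that("a three-pair zone reports the single bend angle", {
  st <- build_ideal_bdna("GCGCAATTGCGC",
                         bend_step = list(position = 6, angle = 8))
  dup <- detect_duplexes(detect_base_pairs(st), st)[[1]]
  # two steps whose local axes flank the bent step: one angle, the full bend
  fr <- base_pair_frames(dup, st, 6:8)
  expect_equal(ax_bend(fr), 8, tolerance = 0.5)
})

test_that("groove widths of ideal fiber DNA match the reference values", {
  st <- fiber12()
  zn <- whole_zone(st)
  fr <- base_pair_frames(zn$duplex, st)
  gg <- groove_geometry(zn, st, frames = fr)
  expect_equal(gg$MnW, 5.9, tolerance = 0.3 / 5.9)
  expect_equal(gg$MjW, 11.4, tolerance = 0.3 / 11.4)
  # depths are calibration-anchored: validated by sign only
  expect_gt(gg$MnD, 0)
  expect_gt(gg$MjD, 0)
})

test_that("groove values are undefined for zones under three pairs", {
  st <- fiber12()
  dup <- detect_duplexes(detect_base_pairs(st), st)[[1]]
  zn <- list(pair_idx = 5:6, duplex = dup)
  gg <- groove_geometry(zn, st)
  expect_true(all(is.na(unlist(gg))))
})

test_that("width responds monotonically to radial phosphate displacement", {
  st <- fiber12()
  base <- groove_geometry(whole_zone(st), st)
  # push every phosphorus 1 A radially outward (symmetric widening)
  st2 <- st
  sel <- st2$atoms$elety == "P"
  r <- sqrt(st2$atoms$x[sel]^2 + st2$atoms$y[sel]^2)
  st2$atoms$x[sel] <- st2$atoms$x[sel] * (r + 1) / r
  st2$atoms$y[sel] <- st2$atoms$y[sel] * (r + 1) / r
  wide <- groove_geometry(whole_zone(st2), st2)
  # the minimal minor chord is strongly axial, so its sensitivity to a
  # radial push is well below 1 A per A; the response must be monotone
  expect_gt(wide$MnW, base$MnW + 0.2)
  expect_gt(wide$MjW, base$MjW + 0.2)
  st3 <- st
  sel3 <- st3$atoms$elety == "P"
  r3 <- sqrt(st3$atoms$x[sel3]^2 + st3$atoms$y[sel3]^2)
  st3$atoms$x[sel3] <- st3$atoms$x[sel3] * (r3 + 2) / r3
  st3$atoms$y[sel3] <- st3$atoms$y[sel3] * (r3 + 2) / r3
  wider <- groove_geometry(whole_zone(st3), st3)
  expect_gt(wider$MnW, wide$MnW)
  expect_gt(wider$MjW, wide$MjW)
})

test_that("shape parameters are rigid-body invariant", {
  st <- fiber12()
  zn <- whole_zone(st)
  fr <- base_pair_frames(zn$duplex, st)
  base <- c(ax_bend(fr), unlist(groove_geometry(zn, st, frames = fr)))
  for (s in 1:3) {
    st2 <- apply_rigid(st, random_rigid(300 + s))
    zn2 <- whole_zone(st2)
    fr2 <- base_pair_frames(zn2$duplex, st2)
    got <- c(ax_bend(fr2), unlist(groove_geometry(zn2, st2, frames = fr2)))
    expect_equal(got, base, tolerance = 1e-6)
  }
})

test_that("aggregation gives per-domain means and family avg/min/max", {
  df <- data.frame(
    structure_id = c("s1", "s2", "s3"),
    domain_id = c("d1", "d1", "d2"),
    family_id = "f1",
    ax_bend = c(1, 3, 5), MnW = c(6, 8, NA), MnD = NA_real_,
    MjW = c(11, 11, 12), MjD = c(2, 2, 2))
  agg <- aggregate_shape(df)
  d1 <- agg$domain[agg$domain$domain_id == "d1", ]
  expect_equal(d1$ax_bend, 2)
  expect_equal(d1$MnW, 7)
  fam <- agg$family
  expect_equal(fam$ax_bend_avg, mean(c(2, 5)))
  expect_equal(fam$ax_bend_min, 2)
  expect_equal(fam$ax_bend_max, 5)
  expect_true(is.na(fam$MnD_avg))       # all-undefined parameter
  expect_true(fam$MnW_min <= fam$MnW_avg && fam$MnW_avg <= fam$MnW_max)
})
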