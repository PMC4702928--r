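# Embedded fiber B-form DNA repeating unit.
#
# One strand-1 nucleotide per base type, in the frame of its base pair:
# helix axis = z through the origin, pair pseudo-dyad along x, minor-groove
# side toward +x.  Planar base geometries follow the chemical component
# dictionary; the Watson-Crick pair placement was solved against standard
# hydrogen-bond lengths under an isomorphism constraint; the phosphate helix
# sits at the fiber B-DNA values (radius 8.91 A, phase 95.2 deg from the
# dyad, z offset 2.08 A); the deoxyribose bridge satisfies standard bond
# lengths/angles and D-sugar chirality and adopts the fiber B torsion set.
# Strand 1 runs 5'->3' along -z; strand 2 is the pair-dyad image (180 deg
# about x) of the complementary template.

.fiber_twist <- 36.0
.fiber_rise  <- 3.38
.fiber_minor_side <- c(1, 0, 0)  # minor-groove direction in the pair frame

.fiber_template <- list(
  DA = matrix(c(
    0.1549, 7.6754, 1.6591,
    1.1770, 7.1995, 2.5549,
    2.4606, 6.8866, 1.8194,
    2.5531, 5.5179, 1.3627,
    2.6780, 7.6715, 0.5283,
    4.0674, 7.6156, 0.2273,
    1.8518, 6.8405, -0.4490,
    2.1629, 5.4207, 0.0000,
    -0.8075, 8.8733, 2.0800,
    -2.0474, 8.7735, 1.2688,
    -0.0152, 10.1291, 2.0572,
    1.0102, 4.5157, -0.0000,
    -0.3015, 4.8818, -0.0000,
    -1.0583, 3.8233, -0.0000,
    -0.2821, 2.7131, -0.0000,
    -0.5331, 1.3311, -0.0000,
    -1.8296, 0.8470, -0.0000,
    0.5033, 0.4989, -0.0000,
    1.7424, 0.9516, -0.0000,
    2.0261, 2.2366, -0.0000,
    1.0553, 3.1448, -0.0000
  ), ncol = 3, byrow = TRUE, dimnames = list(c("O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "P", "OP1", "OP2", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"), c("x","y","z"))),
  DT = matrix(c(
    0.1549, 7.6754, 1.6591,
    1.1770, 7.1995, 2.5549,
    2.4606, 6.8866, 1.8194,
    2.5531, 5.5179, 1.3627,
    2.6780, 7.6715, 0.5283,
    4.0674, 7.6156, 0.2273,
    1.8518, 6.8405, -0.4490,
    2.1629, 5.4207, 0.0000,
    -0.8075, 8.8733, 2.0800,
    -2.0474, 8.7735, 1.2688,
    -0.0152, 10.1291, 2.0572,
    1.0392, 4.5297, -0.0000,
    1.2154, 3.1294, -0.0000,
    2.3169, 2.5766, -0.0000,
    0.0322, 2.3836, -0.0000,
    -1.2642, 2.8759, -0.0000,
    -2.2626, 2.1611, -0.0000,
    -1.3691, 4.3594, -0.0000,
    -2.7345, 4.9683, -0.0000,
    -0.2377, 5.0764, -0.0000
  ), ncol = 3, byrow = TRUE, dimnames = list(c("O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "P", "OP1", "OP2", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6"), c("x","y","z"))),
  DG = matrix(c(
    0.1549, 7.6754, 1.6591,
    1.1770, 7.1995, 2.5549,
    2.4606, 6.8866, 1.8194,
    2.5531, 5.5179, 1.3627,
    2.6780, 7.6715, 0.5283,
    4.0674, 7.6156, 0.2273,
    1.8518, 6.8405, -0.4490,
    2.1629, 5.4207, 0.0000,
    -0.8075, 8.8733, 2.0800,
    -2.0474, 8.7735, 1.2688,
    -0.0152, 10.1291, 2.0572,
    1.0115, 4.5167, -0.0000,
    -0.3020, 4.8842, -0.0000,
    -1.0574, 3.8242, -0.0000,
    -0.2758, 2.7169, -0.0000,
    -0.5368, 1.3267, -0.0000,
    -1.6810, 0.9065, -0.0000,
    0.5134, 0.4773, -0.0000,
    1.7878, 0.9579, -0.0000,
    2.8345, 0.0712, -0.0000,
    2.0434, 2.2469, -0.0000,
    1.0557, 3.1493, -0.0000
  ), ncol = 3, byrow = TRUE, dimnames = list(c("O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "P", "OP1", "OP2", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"), c("x","y","z"))),
  DC = matrix(c(
    0.1549, 7.6754, 1.6591,
    1.1770, 7.1995, 2.5549,
    2.4606, 6.8866, 1.8194,
    2.5531, 5.5179, 1.3627,
    2.6780, 7.6715, 0.5283,
    4.0674, 7.6156, 0.2273,
    1.8518, 6.8405, -0.4490,
    2.1629, 5.4207, 0.0000,
    -0.8075, 8.8733, 2.0800,
    -2.0474, 8.7735, 1.2688,
    -0.0152, 10.1291, 2.0572,
    1.0153, 4.5107, -0.0000,
    1.2160, 3.1814, -0.0000,
    2.3561, 2.7465, -0.0000,
    0.1906, 2.3312, -0.0000,
    -1.0584, 2.7762, -0.0000,
    -2.1099, 1.8891, -0.0000,
    -1.3023, 4.1645, -0.0000,
    -0.2501, 5.0157, -0.0000
  ), ncol = 3, byrow = TRUE, dimnames = list(c("O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "P", "OP1", "OP2", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"), c("x","y","z")))
)
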