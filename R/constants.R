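# Chemical constants shared across modules.

# session cache for deterministic, repeatedly used constructions
.dpi_cache <- new.env(parent = emptyenv())

# van der Waals radii (A) used by the line-of-sight test; hydrogens ignored.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
.vdw_default <- 1.70

# Standard residue name sets and aliases.
.aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
          "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
.dna4 <- c("DA","DT","DG","DC")
.dna_alias <- c(DA = "DA", DT = "DT", DG = "DG", DC = "DC",
                A = "DA", T = "DT", G = "DG", C = "DC",
                ADE = "DA", THY = "DT", GUA = "DG", CYT = "DC")
# Modified residues mapped to a parent deoxynucleotide (editable).
.dna_modified <- c(`5MC` = "DC", `5CM` = "DC", `6MA` = "DA", DU = "DT",
                   BRU = "DT", `5IU` = "DT", `8OG` = "DG")
.water_names <- c("HOH", "WAT", "DOD", "H2O")

# DNA element atom lists.  Backbone = deoxyribose + phosphate group atoms;
# groove atoms are the published per-base lists; any other base atom
# (e.g. purine N9, pyrimidine N1) is unclassified.
.dna_backbone_atoms <- c("P","OP1","OP2","OP3","O1P","O2P","O3P",
                         "O5'","C5'","C4'","O4'","C3'","O3'","C2'","C1'",
                         "O5*","C5*","C4*","O4*","C3*","O3*","C2*","C1*")
.dna_major_atoms <- list(
  DA = c("C5","C6","N6","N7","C8"),
  DT = c("C4","O4","C5","C6","C7","C5M"),
  DG = c("C5","C6","O6","N7","C8"),
  DC = c("C4","N4","C5","C6"))
.dna_minor_atoms <- list(
  DA = c("N1","C2","N3","C4"),
  DT = c("C2","O2","N3"),
  DG = c("N1","C2","N2","N3","C4"),
  DC = c("C2","O2","N3"))

# Protein element order used for canonical contact-type labels.
.prot_elements <- c("H", "S", "L")   # helix, strand, loop
.dna_elements  <- c("Bb", "Mj", "Mn")

.norm_dna_resid <- function(resid) {
  out <- .dna_alias[resid]
  mod <- .dna_modified[resid]
  out[is.na(out) & !is.na(mod)] <- mod[is.na(out) & !is.na(mod)]
  unname(out)
}

.is_dna_resid <- function(resid) !is.na(.norm_dna_resid(resid))
.is_aa_resid  <- function(resid) resid %in% .aa3
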