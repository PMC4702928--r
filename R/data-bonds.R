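# Heavy-atom covalent topology of standard residues (chemical component
# dictionary), used to build the bond relation; unknown residues fall back
# to a 2.0 A distance rule.

.residue_bonds <- list(
  ALA = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N"), ncol = 2, byrow = TRUE),
  ARG = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","CG", "CD","CG", "CD","NE", "CZ","NE", "CZ","NH1", "CZ","NH2"), ncol = 2, byrow = TRUE),
  ASN = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","CG", "CG","ND2", "CG","OD1"), ncol = 2, byrow = TRUE),
  ASP = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","CG", "CG","OD1", "CG","OD2"), ncol = 2, byrow = TRUE),
  CYS = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","SG"), ncol = 2, byrow = TRUE),
  GLN = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","CG", "CD","CG", "CD","NE2", "CD","OE1"), ncol = 2, byrow = TRUE),
  GLU = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","CG", "CD","CG", "CD","OE1", "CD","OE2"), ncol = 2, byrow = TRUE),
  GLY = matrix(c("C","CA", "C","O", "C","OXT", "CA","N"), ncol = 2, byrow = TRUE),
  HIS = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","CG", "CD2","CG", "CD2","NE2", "CE1","ND1", "CE1","NE2", "CG","ND1"), ncol = 2, byrow = TRUE),
  ILE = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","CG1", "CB","CG2", "CD1","CG1"), ncol = 2, byrow = TRUE),
  LEU = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","CG", "CD1","CG", "CD2","CG"), ncol = 2, byrow = TRUE),
  LYS = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","CG", "CD","CE", "CD","CG", "CE","NZ"), ncol = 2, byrow = TRUE),
  MET = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","CG", "CE","SD", "CG","SD"), ncol = 2, byrow = TRUE),
  PHE = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","CG", "CD1","CE1", "CD1","CG", "CD2","CE2", "CD2","CG", "CE1","CZ", "CE2","CZ"), ncol = 2, byrow = TRUE),
  PRO = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","CG", "CD","CG", "CD","N"), ncol = 2, byrow = TRUE),
  SER = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","OG"), ncol = 2, byrow = TRUE),
  THR = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","CG2", "CB","OG1"), ncol = 2, byrow = TRUE),
  TRP = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","CG", "CD1","CG", "CD1","NE1", "CD2","CE2", "CD2","CE3", "CD2","CG", "CE2","CZ2", "CE2","NE1", "CE3","CZ3", "CH2","CZ2", "CH2","CZ3"), ncol = 2, byrow = TRUE),
  TYR = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","CG", "CD1","CE1", "CD1","CG", "CD2","CE2", "CD2","CG", "CE1","CZ", "CE2","CZ", "CZ","OH"), ncol = 2, byrow = TRUE),
  VAL = matrix(c("C","CA", "C","O", "C","OXT", "CA","CB", "CA","N", "CB","CG1", "CB","CG2"), ncol = 2, byrow = TRUE),
  DA = matrix(c("C1'","C2'", "C1'","N9", "C1'","O4'", "C2","N1", "C2","N3", "C2'","C3'", "C3'","C4'", "C3'","O3'", "C4","C5", "C4","N3", "C4","N9", "C4'","C5'", "C4'","O4'", "C5","C6", "C5","N7", "C5'","O5'", "C6","N1", "C6","N6", "C8","N7", "C8","N9", "O5'","P", "OP1","P", "OP2","P", "OP3","P"), ncol = 2, byrow = TRUE),
  DT = matrix(c("C1'","C2'", "C1'","N1", "C1'","O4'", "C2","N1", "C2","N3", "C2","O2", "C2'","C3'", "C3'","C4'", "C3'","O3'", "C4","C5", "C4","N3", "C4","O4", "C4'","C5'", "C4'","O4'", "C5","C6", "C5","C7", "C5'","O5'", "C6","N1", "O5'","P", "OP1","P", "OP2","P", "OP3","P"), ncol = 2, byrow = TRUE),
  DG = matrix(c("C1'","C2'", "C1'","N9", "C1'","O4'", "C2","N1", "C2","N2", "C2","N3", "C2'","C3'", "C3'","C4'", "C3'","O3'", "C4","C5", "C4","N3", "C4","N9", "C4'","C5'", "C4'","O4'", "C5","C6", "C5","N7", "C5'","O5'", "C6","N1", "C6","O6", "C8","N7", "C8","N9", "O5'","P", "OP1","P", "OP2","P", "OP3","P"), ncol = 2, byrow = TRUE),
  DC = matrix(c("C1'","C2'", "C1'","N1", "C1'","O4'", "C2","N1", "C2","N3", "C2","O2", "C2'","C3'", "C3'","C4'", "C3'","O3'", "C4","C5", "C4","N3", "C4","N4", "C4'","C5'", "C4'","O4'", "C5","C6", "C5'","O5'", "C6","N1", "O5'","P", "OP1","P", "OP2","P", "OP3","P"), ncol = 2, byrow = TRUE)
)
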