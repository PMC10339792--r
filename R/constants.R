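# Physical constants and element tables used throughout.
#
# Unit conventions: lengths in Angstrom, Q in 1/Angstrom, intensities in 1/cm,
# scattering length densities (SLD) in 1/cm^2, masses in Da (g/mol),
# mass densities in g/mL.  1 g/cm^3 corresponds to 0.60221 Da/Angstrom^3.

#' @keywords internal
.const <- list(
  avogadro    = 6.02214076e23,   # 1/mol
  r_electron  = 2.8179403262e-13, # classical electron radius, cm
  da_per_A3   = 0.60221,          # 1 g/cm^3 in Da/A^3
  fm_to_cm    = 1e-13,
  A3_to_cm3   = 1e-24,
  d2o_density = 1.107,            # g/mL at 25 C
  h2o_density = 0.997             # g/mL at 25 C
)

# Element table: average atomic mass (Da), atomic number Z (electrons),
# bound coherent neutron scattering length b (fm).  D is treated as its own
# symbol so isotopic labelling is explicit in formulas.
.elements <- data.frame(
  symbol = c("H", "D", "C", "N", "O", "S", "P", "F", "Na", "Cl", "K"),
  mass   = c(1.008, 2.0141, 12.011, 14.007, 15.999, 32.06, 30.974,
             18.998, 22.990, 35.45, 39.098),
  z      = c(1, 1, 6, 7, 8, 16, 15, 9, 11, 17, 19),
  b_coh  = c(-3.7390, 6.671, 6.6460, 9.36, 5.803, 2.847, 5.13,
             5.654, 3.63, 9.577, 3.67),
  stringsAsFactors = FALSE
)
rownames(.elements) <- .elements$symbol

# Amino-acid residue table (residue = amino acid minus H2O).
# labile: side-chain N-H/O-H hydrogens exchangeable with solvent (neutral form).
# d_ion: formula change of H count upon ionisation at neutral pH
#        (+1 for protonated K/R/H, -1 for deprotonated D/E).
# aliphatic: side-chain aliphatic (sp3, non-functionalised) carbon count.
.residues <- data.frame(
  code = c("A","R","N","D","C","E","Q","G","H","I","L","K","M","F","P",
           "S","T","W","Y","V"),
  c = c(3, 6, 4, 4, 3, 5, 5, 2, 6, 6, 6, 6, 5, 9, 5, 3, 4, 11, 9, 5),
  h = c(5, 12, 6, 5, 5, 7, 8, 3, 7, 11, 11, 12, 9, 9, 7, 5, 7, 10, 9, 9),
  n = c(1, 4, 2, 1, 1, 1, 2, 1, 3, 1, 1, 2, 1, 1, 1, 1, 1, 2, 1, 1),
  o = c(1, 1, 2, 3, 1, 3, 2, 1, 1, 1, 1, 1, 1, 1, 1, 2, 2, 1, 2, 1),
  s = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0),
  labile    = c(0, 4, 2, 1, 1, 1, 2, 0, 1, 0, 0, 2, 0, 0, 0, 1, 1, 1, 1, 0),
  d_ion     = c(0, 1, 0,-1, 0,-1, 0, 0, 1, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
  aliphatic = c(1, 3, 0, 1, 1, 2, 2, 0, 1, 4, 4, 4, 3, 1, 3, 0, 1, 1, 1, 3),
  stringsAsFactors = FALSE
)
rownames(.residues) <- .residues$code
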