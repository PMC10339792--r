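# Built-in description of the K3W(QL)6K2 nanofiber system.
#
# The fiber is two stacked antiparallel beta-sheets.  The hydrophobic core
# holds the leucine and tryptophan side chains; the shell holds the backbone
# and hydrophilic residues.  Splitting the (lysine-protonated) molecule this
# way reproduces the fitted per-molecule masses: 6 x C4H9 (Leu) + C9H8N (Trp)
# = 472.9 Da core and C76H132N30O25 = 1866.1 Da shell.  The buried indole N-H
# is treated as non-exchanging; all 48 labile hydrogens (18 backbone amides
# incl. the acetamide, 15 on three-proton lysine ammoniums, 12 on glutamine
# amides, 2 on the C-terminal amide, plus the indole when dissolved) sit in
# the shell.

#' The K3W(QL)6K2 peptide sequence (compact notation)
#' @export
k3_sequence <- function() "K3W(QL)6K2"

#' Reference cross-section geometry of the K3W(QL)6K2 fiber
#'
#' Core 9.8 x 44.1 A, shells 8.4 / 8.5 A (peptide envelope 26.6 x 61.1 A),
#' length 340 A; `d = 30` A of hydrated PEG for the PEGylated fiber.
#' @param d PEG layer thickness (A), default 0.
#' @export
k3_geometry <- function(d = 0) {
  nanofiber_geometry(a_core = 9.8, a_shell = 8.4, b_core = 44.1,
                     b_shell = 8.5, c = 340, d = d, warn_decoupling = FALSE)
}

#' Region materials of the K3W(QL)6K2 fiber
#'
#' Hydrophobic core (Leu + Trp side chains, 0.95 g/mL, no exchange),
#' peptide shell (backbone + hydrophilic residues, 1.36 g/mL, 47 labile H),
#' and optionally hydrated-PEG corona materials.
#' @return list of `material` objects: `core`, `shell`, `peg_h`, `peg_d`.
#' @export
k3_fiber_materials <- function() {
  list(
    core = material("C33H62N", 0.95, n_exchangeable_h = 0,
                    label = "Leu/Trp core"),
    shell = material("C76H132N30O25", 1.36, n_exchangeable_h = 47,
                     label = "peptide shell"),
    peg_h = peg_composition(1900, deuterated = FALSE),
    peg_d = peg_composition(2100, deuterated = TRUE)
  )
}

#' Reference nanofiber scattering model from the fitted parameter set
#'
#' Builds the full model for the 10 mg/mL sample (volume fraction 0.008)
#' with region SLDs computed from the built-in materials at the requested
#' radiation and solvent.
#'
#' @param radiation `"xray"` or `"neutron"`.
#' @param f_d2o solvent D2O fraction (neutron contrast; X-ray SLDs do not
#'   depend on it beyond the solvent density mix).
#' @param d PEG layer thickness (A), default 0 (non-PEGylated).
#' @param phi volume fraction, default 0.008.
#' @param peg `"h"` or `"d"` PEG for the corona material.
#' @param background flat background (1/cm).
#' @export
#' @examples
#' k3_table_model("xray")
k3_table_model <- function(radiation = c("xray", "neutron"), f_d2o = 1,
                           d = 0, phi = 0.008, peg = c("h", "d"),
                           background = 0) {
  radiation <- match.arg(radiation)
  peg <- match.arg(peg)
  mats <- k3_fiber_materials()
  pegmat <- if (peg == "h") mats$peg_h else mats$peg_d
  if (radiation == "xray") {
    ct <- contrast_set(rho_core = xray_sld(mats$core),
                       rho_shell = xray_sld(mats$shell),
                       rho_peg = xray_sld(pegmat),
                       rho_solv = solvent_sld(f_d2o, "xray"),
                       radiation = "xray")
  } else {
    ct <- contrast_set(rho_core = neutron_sld(mats$core, f_d2o),
                       rho_shell = neutron_sld(mats$shell, f_d2o),
                       rho_peg = neutron_sld(pegmat, f_d2o),
                       rho_solv = solvent_sld(f_d2o, "neutron"),
                       radiation = "neutron")
  }
  geom <- k3_geometry(d = d)
  dq <- derive_fiber_quantities(geom, d_core = 0.95, d_shell = 1.36,
                                m_pep = 2339)
  nanofiber_model(geom, ct, phi = phi, n_agg = max(1, dq$n_agg),
                  v_peg = pegmat$volume, rg_blob = 15,
                  background = background)
}
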