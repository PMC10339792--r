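# Empirical binding-energy estimators and circular-dichroism unit
# conversion.
#
# The exchange-activation estimate sums a hydrophobic term (either Tanford
# group increments, or the 90 kJ/mol-per-24-aliphatic-carbons calibration
# from n-alkyl-PEG micelle exchange kinetics) with a one-sided backbone
# hydrogen-bond term (bond count times 8 kJ/mol).

#' Energetics configuration
#'
#' @param e_ch3 Tanford increment per CH3 group, kJ/mol (default 9).
#' @param e_ch2 Tanford increment per CH2-equivalent group, kJ/mol
#'   (default 3).  The leucine branch CH is priced at this increment, so one
#'   leucine side chain (2 CH3 + CH + CH2) contributes 24 kJ/mol.
#' @param e_hbond energy per backbone hydrogen bond, kJ/mol (default 8).
#' @param alkyl_rate calibration from alkyl-micelle exchange: kJ/mol per
#'   `alkyl_carbons` aliphatic carbons (default 90 per 24).
#' @param alkyl_carbons see `alkyl_rate`.
#' @export
energetics_config <- function(e_ch3 = 9, e_ch2 = 3, e_hbond = 8,
                              alkyl_rate = 90, alkyl_carbons = 24) {
  stopifnot(e_ch3 >= 0, e_ch2 >= 0, e_hbond >= 0, alkyl_rate >= 0,
            alkyl_carbons > 0)
  list(e_ch3 = e_ch3, e_ch2 = e_ch2, e_hbond = e_hbond,
       alkyl_rate = alkyl_rate, alkyl_carbons = alkyl_carbons)
}

#' Count aliphatic side-chain carbons
#'
#' By default only leucine contributes (4 side-chain carbons per residue);
#' `table = "all"` uses the full per-residue aliphatic-carbon table instead.
#'
#' @param sequence one-letter sequence (compact notation allowed).
#' @param table `"leucine"` (default) or `"all"`, or a named numeric vector
#'   of per-residue counts.
#' @return integer count.
#' @export
#' @examples
#' count_aliphatic_carbons("K3W(QL)6K2")  # 24
count_aliphatic_carbons <- function(sequence, table = "leucine") {
  seq <- expand_peptide(sequence)
  if (nchar(seq) == 0) return(0L)
  tab <- if (is.numeric(table)) table
         else switch(match.arg(table, c("leucine", "all")),
                     leucine = c(L = 4),
                     all = stats::setNames(.residues$aliphatic, .residues$code))
  aa <- strsplit(seq, "")[[1]]
  as.integer(sum(vapply(aa, function(r)
    if (r %in% names(tab)) tab[[r]] else 0, numeric(1))))
}

#' Tanford hydrophobic transfer energy of the leucine side chains
#'
#' Each leucine side chain is priced as two CH3 groups plus two
#' CH2-equivalents (the branch CH at the CH2 increment), i.e. 24 kJ/mol at
#' the default increments; six leucines give 144 kJ/mol.
#'
#' @inheritParams count_aliphatic_carbons
#' @param config an [energetics_config()].
#' @return energy in kJ/mol.
#' @export
#' @examples
#' tanford_hydrophobic_energy("K3W(QL)6K2")  # 144
tanford_hydrophobic_energy <- function(sequence, config = energetics_config()) {
  seq <- expand_peptide(sequence)
  n_leu <- sum(strsplit(seq, "")[[1]] == "L")
  n_leu * (2 * config$e_ch3 + 2 * config$e_ch2)
}

#' Backbone hydrogen bonds per side of the beta-sheet block
#'
#' One interstrand backbone bond per residue of the hydrogen-bonding block,
#' per side of the molecule.  The default block is the central `KW(QL)6`
#' motif (14 residues).
#'
#' @inheritParams count_aliphatic_carbons
#' @param block block motif (compact notation allowed); must occur in the
#'   sequence.
#' @return bonds per side (integer).
#' @export
#' @examples
#' hbond_block_count("K3W(QL)6K2")  # 14
hbond_block_count <- function(sequence, block = "KW(QL)6") {
  seq <- expand_peptide(sequence)
  blk <- expand_peptide(block)
  if (nchar(blk) == 0) return(0L)
  if (!grepl(blk, seq, fixed = TRUE))
    stop("block '", block, "' not found in sequence", call. = FALSE)
  nchar(blk)
}

#' Lower-bound estimate of the molecular-exchange activation energy
#'
#' Hydrophobic term (Tanford increments or the alkyl-micelle calibration
#' scaled to the sequence's aliphatic carbon count) plus the one-sided
#' backbone hydrogen-bond term.
#'
#' @inheritParams tanford_hydrophobic_energy
#' @param mode `"alkyl_calibration"` (default) or `"tanford"`.
#' @param block hydrogen-bonding block motif.
#' @return list with `hydrophobic`, `hbond`, `total` (kJ/mol) and `mode`.
#' @export
#' @examples
#' exchange_activation_estimate("K3W(QL)6K2")$total  # >= 200
exchange_activation_estimate <- function(sequence,
                                         mode = c("alkyl_calibration",
                                                  "tanford"),
                                         config = energetics_config(),
                                         block = "KW(QL)6") {
  mode <- match.arg(mode)
  hyd <- switch(mode,
    tanford = tanford_hydrophobic_energy(sequence, config),
    alkyl_calibration = config$alkyl_rate *
      count_aliphatic_carbons(sequence) / config$alkyl_carbons)
  hb <- tryCatch(hbond_block_count(sequence, block) * config$e_hbond,
                 error = function(e) 0)
  list(hydrophobic = hyd, hbond = hb, total = hyd + hb, mode = mode)
}

#' Circular dichroism spectrum container
#'
#' @param wavelength wavelength grid in nm.
#' @param mdeg raw ellipticity in millidegrees.
#' @param conc_molar peptide concentration in mol/L (> 0).
#' @param n_residues residues per molecule (>= 1).
#' @param path_mm cuvette path length in mm (> 0).
#' @export
cd_spectrum <- function(wavelength, mdeg, conc_molar, n_residues, path_mm) {
  stopifnot(length(wavelength) == length(mdeg),
            conc_molar > 0, n_residues >= 1, path_mm > 0)
  structure(list(wavelength = wavelength, mdeg = mdeg,
                 conc_molar = conc_molar, n_residues = n_residues,
                 path_mm = path_mm), class = "cd_spectrum")
}

#' Convert raw ellipticity to molar residual ellipticity
#'
#' `MRE = theta_mdeg / (10 * c * n * l)` with concentration `c` in mol/L,
#' `n` residues per molecule and path length `l` in cm, giving
#' deg cm^2 dmol^-1.  Linear in the raw signal and invertible given
#' `(c, n, l)`.
#'
#' @param spectrum a [cd_spectrum()].
#' @return numeric vector of MRE values on the wavelength grid.
#' @export
#' @examples
#' s <- cd_spectrum(220, -20, 1e-4, 18, 1)
#' mre_convert(s)
mre_convert <- function(spectrum) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  l_cm <- spectrum$path_mm / 10
  spectrum$mdeg / (10 * spectrum$conc_molar * spectrum$n_residues * l_cm)
}
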