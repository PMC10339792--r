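# Scattering length densities from chemical composition.
#
# A `material` couples an elemental formula (D distinct from H) with a bulk
# mass density and a count of labile (solvent-exchangeable) hydrogens.  The
# molecular volume is always taken from formula mass / density, so isotopic
# H/D substitution changes the scattering length but not the volume.

#' Parse a chemical formula string
#'
#' Accepts element symbols with optional (possibly fractional) counts and
#' parenthesised groups with multipliers, e.g. `"D2O"`, `"C2H4O"`,
#' `"(C2H4O)43.1"`, `"CH3(C2H4O)43OH"`.  Deuterium is written `D`.
#'
#' @param formula formula string, or an already-parsed named vector.
#' @return named numeric vector of element counts.
#' @export
#' @examples
#' parse_formula("(C2D4O)44")
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) return(formula)
  stopifnot(is.character(formula), length(formula) == 1L)
  counts <- c()
  add <- function(sym, n) {
    if (!sym %in% .elements$symbol)
      stop("unknown element symbol: '", sym, "'", call. = FALSE)
    counts[sym] <<- (if (sym %in% names(counts)) counts[[sym]] else 0) + n
  }
  s <- gsub("\\s", "", formula)
  i <- 1L
  while (i <= nchar(s)) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      depth <- 1L; j <- i
      while (depth > 0L) {
        j <- j + 1L
        if (j > nchar(s)) stop("unbalanced parenthesis in formula", call. = FALSE)
        cj <- substr(s, j, j)
        if (cj == "(") depth <- depth + 1L
        if (cj == ")") depth <- depth - 1L
      }
      inner <- parse_formula(substr(s, i + 1L, j - 1L))
      rest <- substr(s, j + 1L, nchar(s))
      m <- regmatches(rest, regexpr("^[0-9.]+", rest))
      mult <- if (length(m) && nzchar(m)) as.numeric(m) else 1
      for (sym in names(inner)) add(sym, inner[[sym]] * mult)
      i <- j + 1L + (if (length(m)) nchar(m) else 0L)
    } else {
      m <- regmatches(substr(s, i, nchar(s)),
                      regexpr("^([A-Z][a-z]?)([0-9.]*)", substr(s, i, nchar(s))))
      if (!length(m) || !nzchar(m))
        stop("cannot parse formula at position ", i, ": '", s, "'", call. = FALSE)
      sym <- sub("^([A-Z][a-z]?).*$", "\\1", m)
      if (!sym %in% .elements$symbol && nchar(sym) == 2L)
        sym <- substr(sym, 1L, 1L)  # e.g. "Ho" not in table -> try "H" + "o" fails later
      num <- sub("^[A-Z][a-z]?", "", m)
      n <- if (nzchar(num)) as.numeric(num) else 1
      add(sym, n)
      i <- i + nchar(sym) + nchar(num)
    }
  }
  counts
}

#' Define a material composition
#'
#' @param formula chemical formula string or named element-count vector.
#' @param mass_density bulk mass density in g/mL.
#' @param n_exchangeable_h number of labile hydrogens that exchange with
#'   solvent H/D.  Must not exceed the H count of the formula.
#' @param label optional text label.
#' @return object of class `material` with fields `formula`, `mass_density`,
#'   `n_exchangeable_h`, `molar_mass` (Da) and `volume` (A^3 per molecule).
#' @export
#' @examples
#' material("D2O", 1.107)
material <- function(formula, mass_density, n_exchangeable_h = 0, label = NULL) {
  f <- parse_formula(formula)
  stopifnot(all(f >= 0), mass_density > 0, n_exchangeable_h >= 0)
  n_h <- if ("H" %in% names(f)) f[["H"]] else 0
  if (n_exchangeable_h > n_h + 1e-9)
    stop("n_exchangeable_h (", n_exchangeable_h,
         ") exceeds the H count of the formula (", n_h, ")", call. = FALSE)
  m <- sum(.elements[names(f), "mass"] * f)
  structure(list(
    formula = f, mass_density = mass_density,
    n_exchangeable_h = n_exchangeable_h, molar_mass = m,
    volume = m / (mass_density * .const$da_per_A3),
    label = label %||% paste(names(f), signif(f, 6), sep = "", collapse = "")
  ), class = "material")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.material <- function(x, ...) {
  cat("<material>", x$label, "\n")
  cat(sprintf("  M = %.2f Da, density = %.3f g/mL, V = %.1f A^3, labile H = %g\n",
              x$molar_mass, x$mass_density, x$volume, x$n_exchangeable_h))
  invisible(x)
}

#' Combine two materials into a composite (e.g. a block conjugate)
#'
#' Formulas, molar masses, molecular volumes and labile-H counts add; the
#' effective density follows from total mass over total volume.
#' @param a,b `material` objects.
#' @export
combine_materials <- function(a, b) {
  stopifnot(inherits(a, "material"), inherits(b, "material"))
  syms <- union(names(a$formula), names(b$formula))
  f <- vapply(syms, function(s) {
    (if (s %in% names(a$formula)) a$formula[[s]] else 0) +
    (if (s %in% names(b$formula)) b$formula[[s]] else 0)
  }, numeric(1))
  vol <- a$volume + b$volume
  m <- a$molar_mass + b$molar_mass
  material(f, mass_density = m / (vol * .const$da_per_A3),
           n_exchangeable_h = a$n_exchangeable_h + b$n_exchangeable_h,
           label = paste(a$label, b$label, sep = "-"))
}

#' X-ray scattering length density
#'
#' Electron density times the classical electron radius:
#' `rho_X = r_e * Z_total / V_molecule`.
#'
#' @param comp a `material`.
#' @return SLD in 1/cm^2.
#' @export
#' @examples
#' xray_sld(material("D2O", 1.107))  # ~9.4e10
xray_sld <- function(comp) {
  stopifnot(inherits(comp, "material"))
  if (length(comp$formula) == 0) return(0)
  z <- sum(.elements[names(comp$formula), "z"] * comp$formula)
  .const$r_electron * z / (comp$volume * .const$A3_to_cm3)
}

#' Neutron scattering length density
#'
#' Sums bound coherent scattering lengths over the effective formula and
#' divides by the molecular volume.  Labile hydrogens are substituted H -> D
#' in proportion to the solvent D2O volume fraction times `exchange_fraction`;
#' the molecular volume is unaffected by isotope substitution.
#'
#' @param comp a `material`.
#' @param f_d2o solvent D2O volume fraction in `[0, 1]`.
#' @param exchange_fraction fraction of the labile hydrogens that actually
#'   equilibrate with the solvent (default 1, full exchange).
#' @return SLD in 1/cm^2.
#' @export
#' @examples
#' neutron_sld(material("D2O", 1.107))  # ~6.4e10
neutron_sld <- function(comp, f_d2o = 0, exchange_fraction = 1) {
  stopifnot(inherits(comp, "material"),
            f_d2o >= 0, f_d2o <= 1,
            exchange_fraction >= 0, exchange_fraction <= 1)
  if (length(comp$formula) == 0) return(0)
  b <- sum(.elements[names(comp$formula), "b_coh"] * comp$formula)
  db <- .elements["D", "b_coh"] - .elements["H", "b_coh"]
  b <- b + comp$n_exchangeable_h * exchange_fraction * f_d2o * db
  b * .const$fm_to_cm / (comp$volume * .const$A3_to_cm3)
}

#' Light and heavy water materials
#'
#' Densities default to 25 C values (0.997 and 1.107 g/mL).  Buffer salts at
#' tens of mM shift the solvent SLD by well under 1% and are neglected.
#' @param density mass density in g/mL.
#' @export
water <- function(density = .const$h2o_density) {
  material("H2O", density, n_exchangeable_h = 0, label = "H2O")
}

#' @rdname water
#' @export
heavy_water <- function(density = .const$d2o_density) {
  material("D2O", density, n_exchangeable_h = 0, label = "D2O")
}

#' Solvent SLD over a D2O fraction grid
#'
#' The neutron solvent SLD is linear in the D2O volume fraction between the
#' pure-H2O and pure-D2O endpoints; for X-rays the (small) density difference
#' between the isotopologues gives a slight slope as well.
#'
#' @param f_d2o vector of D2O volume fractions in `[0, 1]`.
#' @param radiation `"neutron"` or `"xray"`.
#' @return SLD vector in 1/cm^2.
#' @export
solvent_sld <- function(f_d2o, radiation = c("neutron", "xray")) {
  radiation <- match.arg(radiation)
  stopifnot(all(f_d2o >= 0 & f_d2o <= 1))
  sld_of <- switch(radiation, neutron = neutron_sld, xray = xray_sld)
  r0 <- sld_of(water()); r1 <- sld_of(heavy_water())
  (1 - f_d2o) * r0 + f_d2o * r1
}

#' Expand compact peptide notation
#'
#' Turns `"K3W(QL)6K2"` into `"KKKWQLQLQLQLQLQLKK"`.  Plain one-letter
#' strings pass through unchanged.
#' @param sequence compact or plain one-letter sequence.
#' @export
expand_peptide <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- gsub("\\s", "", sequence)
  out <- ""
  i <- 1L
  while (i <= nchar(s)) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      j <- regexpr(")", substr(s, i, nchar(s)), fixed = TRUE)
      if (j < 0) stop("unbalanced parenthesis in sequence", call. = FALSE)
      grp <- substr(s, i + 1L, i + j - 2L)
      rest <- substr(s, i + j, nchar(s))
      m <- regmatches(rest, regexpr("^[0-9]+", rest))
      n <- if (length(m) && nzchar(m)) as.integer(m) else 1L
      out <- paste0(out, strrep(grp, n))
      i <- i + j + (if (length(m)) nchar(m) else 0L)
    } else if (grepl("[A-Z]", ch)) {
      rest <- substr(s, i + 1L, nchar(s))
      m <- regmatches(rest, regexpr("^[0-9]+", rest))
      n <- if (length(m) && nzchar(m)) as.integer(m) else 1L
      out <- paste0(out, strrep(ch, n))
      i <- i + 1L + (if (length(m)) nchar(m) else 0L)
    } else {
      stop("cannot parse sequence at position ", i, ": '", s, "'", call. = FALSE)
    }
  }
  bad <- setdiff(strsplit(out, "")[[1]], .residues$code)
  if (length(bad))
    stop("unknown amino-acid letter(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  out
}

.terminus_delta <- function(n_term, c_term) {
  # formula deltas relative to the bare residue chain + H2O
  nt <- match.arg(n_term, c("acetyl", "free"))
  ct <- match.arg(c_term, c("amide", "acid"))
  d <- c(C = 0, H = 0, N = 0, O = 0)
  if (nt == "acetyl") d <- d + c(C = 2, H = 2, N = 0, O = 1)  # -H +COCH3
  if (ct == "amide")  d <- d + c(C = 0, H = 1, N = 1, O = -1) # -OH +NH2
  d
}

#' Peptide molar mass from sequence
#'
#' Average residue masses plus water plus terminal-modification deltas, for
#' the neutral covalent molecule.  The default termini are N-terminal acetyl
#' and C-terminal amide (solid-phase synthesis on a Rink-type resin).
#'
#' @param sequence one-letter sequence, compact notation allowed.
#' @param n_term `"acetyl"` or `"free"`.
#' @param c_term `"amide"` or `"acid"`.
#' @return molar mass in Da.
#' @export
#' @examples
#' sequence_mass("K3W(QL)6K2")  # ~2334 Da
sequence_mass <- function(sequence, n_term = "acetyl", c_term = "amide") {
  comp <- peptide_composition(sequence, n_term = n_term, c_term = c_term,
                              ionized = FALSE)
  comp$molar_mass
}

#' Peptide material composition from sequence
#'
#' Builds the elemental formula, molar mass and labile-hydrogen count of a
#' peptide.  With `ionized = TRUE` (default) basic side chains (K, R, H) are
#' protonated and acidic ones (D, E) deprotonated, the appropriate state near
#' neutral pH.  Labile hydrogens comprise every backbone amide N-H (one per
#' residue for an acetylated N-terminus), side-chain N-H/O-H, and the
#' C-terminal amide NH2.
#'
#' @inheritParams sequence_mass
#' @param ionized protonate/deprotonate ionisable side chains (pH ~7).
#' @param mass_density molecular mass density in g/mL; the default 1.370
#'   corresponds to the standard protein partial specific volume 0.73 mL/g.
#' @return a `material`.
#' @export
peptide_composition <- function(sequence, n_term = "acetyl", c_term = "amide",
                                ionized = TRUE, mass_density = 1.370) {
  seq <- expand_peptide(sequence)
  aa <- strsplit(seq, "")[[1]]
  f <- c(C = 0, H = 2, N = 0, O = 1, S = 0)  # start from H2O (termini)
  labile <- 0
  for (r in aa) {
    row <- .residues[r, ]
    f <- f + c(C = row$c, H = row$h, N = row$n, O = row$o, S = row$s)
    labile <- labile + row$labile + (r != "P")  # side chain + backbone N-H
    if (ionized && row$d_ion != 0) {
      f[["H"]] <- f[["H"]] + row$d_ion
      labile <- labile + row$d_ion
    }
  }
  if (length(aa)) {
    nt <- match.arg(n_term, c("acetyl", "free"))
    if (nt == "free") labile <- labile + 1 + (ionized)  # NH2 -> 2 (NH3+ -> 3)
    if (nt == "free" && ionized) f[["H"]] <- f[["H"]] + 1
  }
  delta <- .terminus_delta(n_term, c_term)
  f[names(delta)] <- f[names(delta)] + delta
  ct <- match.arg(c_term, c("amide", "acid"))
  labile <- labile + if (ct == "amide") 2 else 1
  f <- f[f != 0]
  material(f, mass_density, n_exchangeable_h = labile,
           label = paste0(if (match.arg(n_term, c("acetyl","free")) == "acetyl") "Ac-" else "",
                          sequence, if (ct == "amide") "-NH2" else ""))
}

#' PEG block composition
#'
#' `(C2H4O)n` (or `(C2D4O)n` when deuterated) with `n` chosen to match the
#' target molar mass.  The hydrogenous melt density is 1.13 g/mL; the
#' deuterated density is scaled by the monomer mass ratio so that the molar
#' volume is isotope-independent.  Chain-end hydroxyls are consumed in the
#' peptide coupling, so no labile hydrogens remain.
#'
#' @param molar_mass target molar mass in Da (e.g. 1900 or 2100).
#' @param deuterated logical.
#' @param mass_density override the default density (g/mL).
#' @return a `material`.
#' @export
peg_composition <- function(molar_mass, deuterated = FALSE, mass_density = NULL) {
  stopifnot(molar_mass > 0)
  m_h <- 2 * .elements["C","mass"] + 4 * .elements["H","mass"] + .elements["O","mass"]
  m_d <- 2 * .elements["C","mass"] + 4 * .elements["D","mass"] + .elements["O","mass"]
  if (deuterated) {
    n <- molar_mass / m_d
    d <- mass_density %||% (1.13 * m_d / m_h)
    material(c(C = 2 * n, D = 4 * n, O = n), d, 0,
             label = sprintf("dPEG%.0f", molar_mass))
  } else {
    n <- molar_mass / m_h
    material(c(C = 2 * n, H = 4 * n, O = n), mass_density %||% 1.13, 0,
             label = sprintf("hPEG%.0f", molar_mass))
  }
}

#' PEG-peptide conjugate composition
#'
#' The PEG carboxyl couples to the peptide N-terminus as an amide, taking the
#' structural place of the acetyl cap; compositionally the conjugate is the
#' acetylated peptide plus the PEG repeat units.
#'
#' @param sequence peptide sequence (compact notation allowed).
#' @param peg a `material` from [peg_composition()].
#' @param ... passed to [peptide_composition()].
#' @return a `material`.
#' @export
conjugate_composition <- function(sequence, peg, ...) {
  pep <- peptide_composition(sequence, n_term = "acetyl", ...)
  combine_materials(pep, peg)
}

#' Zero-average-contrast solvent composition
#'
#' Finds the D2O volume fraction at which the neutron solvent SLD equals the
#' mean of the two conjugates' SLDs.  Both conjugate SLDs depend on the
#' solvent through their labile hydrogens, so the condition is solved by 1-D
#' root finding; the bracketing function is monotone, making the root unique
#' when it exists.
#'
#' @param conj_h,conj_d `material` objects for the H- and D-labelled species.
#' @param exchange_fraction labile-H exchange fraction (default 1).
#' @return D2O volume fraction in `[0, 1]`.
#' @export
zac_match_point <- function(conj_h, conj_d, exchange_fraction = 1) {
  g <- function(f) {
    solvent_sld(f) -
      0.5 * (neutron_sld(conj_h, f, exchange_fraction) +
             neutron_sld(conj_d, f, exchange_fraction))
  }
  g0 <- g(0); g1 <- g(1)
  if (g0 * g1 > 0)
    stop("no zero-average-contrast solvent composition in [0, 1]: ",
         sprintf("mismatch %.3g at f=0 and %.3g at f=1", g0, g1), call. = FALSE)
  stats::uniroot(g, c(0, 1), tol = 1e-10)$root
}

#' Contrast match point of a single material
#'
#' D2O fraction where the solvent neutron SLD equals the material's own.
#' @inheritParams zac_match_point
#' @param comp a `material`.
#' @export
match_point <- function(comp, exchange_fraction = 1) {
  zac_match_point(comp, comp, exchange_fraction)
}

#' Derived per-fiber quantities from geometry and densities
#'
#' Region volumes follow from the cross-section dimensions and the fiber
#' length, masses from volume times density (1 g/cm^3 = 0.60221 Da/A^3), the
#' aggregation number from total mass over the per-molecule mass, and the
#' per-molecule core/shell masses by division.
#'
#' @param geom a [nanofiber_geometry()].
#' @param d_core,d_shell region mass densities in g/mL.
#' @param m_pep peptide (molecule) molar mass in Da.
#' @return list with `v_core`, `v_shell`, `v_pep` (A^3), `n_agg`,
#'   `m_core`, `m_shell`, `m_pep` (Da, per molecule) and totals.
#' @export
#' @examples
#' g <- nanofiber_geometry(9.8, 8.4, 44.1, 8.5, 340)
#' derive_fiber_quantities(g, 0.95, 1.36, 2339)$n_agg  # ~178
derive_fiber_quantities <- function(geom, d_core, d_shell, m_pep) {
  stopifnot(inherits(geom, "nanofiber_geometry"),
            d_core > 0, d_shell > 0, m_pep > 0)
  v_core <- geom$a_core * geom$b_core * geom$c
  v_pep  <- geom$a_pep * geom$b_pep * geom$c
  v_shell <- v_pep - v_core
  if (v_shell < 0) stop("negative shell volume", call. = FALSE)
  m_core_tot  <- v_core * d_core * .const$da_per_A3
  m_shell_tot <- v_shell * d_shell * .const$da_per_A3
  m_tot <- m_core_tot + m_shell_tot
  n_agg <- m_tot / m_pep
  list(v_core = v_core, v_shell = v_shell, v_pep = v_pep,
       n_agg = n_agg,
       m_core = if (n_agg > 0) m_core_tot / n_agg else 0,
       m_shell = if (n_agg > 0) m_shell_tot / n_agg else 0,
       m_pep = m_pep,
       m_core_total = m_core_tot, m_shell_total = m_shell_tot,
       m_total = m_tot,
       d_pep = if (v_pep > 0) m_tot / (v_pep * .const$da_per_A3) else 0)
}
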