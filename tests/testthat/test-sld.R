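# Composition parsing, X-ray/neutron SLDs, solvent mixing, ZAC condition,
# derived fiber quantities, and sequence masses.

test_that("formula parser handles groups, fractions and isotopes", {
  expect_equal(parse_formula("D2O"), c(D = 2, O = 1))
  expect_equal(parse_formula("(C2H4O)43"), c(C = 86, H = 172, O = 43))
  f <- parse_formula("CH3(C2D4O)2OH")
  expect_equal(f[["C"]], 5)
  expect_equal(f[["D"]], 8)
  expect_equal(f[["H"]], 4)
  expect_error(parse_formula("Xx2O"), "unknown element")
})

test_that("X-ray SLDs reproduce the solvent and region reference values", {
  # D2O: published 9.37e10 1/cm^2
  expect_equal(xray_sld(heavy_water()), 9.37e10, tolerance = 0.01)
  # H2O: frozen from the independent electron-count computation (tolerance
  # covers the 0.60221 Da/A^3 volume-conversion convention)
  expect_equal(xray_sld(water()), 9.39168648e10, tolerance = 1e-4)
  # fiber regions (published 9.07e10 core, 1.23e11 shell)
  mats <- k3_fiber_materials()
  expect_equal(xray_sld(mats$core), 9.07e10, tolerance = 0.01)
  expect_equal(xray_sld(mats$shell), 1.23e11, tolerance = 0.01)
  # empty formula -> 0
  expect_equal(xray_sld(structure(list(formula = numeric(0), volume = 1),
                                  class = "material")), 0)
  # X-ray SLD invariant under H <-> D substitution at fixed volume
  h6 <- material("C6H6", 0.88)
  d6 <- material("C6D6", 0.88 * 84.113 / 78.114)
  expect_equal(xray_sld(h6), xray_sld(d6), tolerance = 1e-3)
})

test_that("neutron SLDs reproduce solvent, PEG and region reference values", {
  expect_equal(neutron_sld(heavy_water()), 6.35e10, tolerance = 0.01)
  # hydrogenous PEG: frozen from the independent tabulated-b summation
  expect_equal(neutron_sld(material("C2H4O", 1.13)), 6.39365625e9,
               tolerance = 1e-4)
  # fiber regions in pure D2O (published -3.77e8 core, 4.06e10 shell)
  mats <- k3_fiber_materials()
  expect_equal(neutron_sld(mats$core, f_d2o = 1), -3.77e8, tolerance = 0.02)
  expect_equal(neutron_sld(mats$shell, f_d2o = 1), 4.06e10, tolerance = 0.005)
  # no exchangeables -> independent of solvent
  peg <- material("C2H4O", 1.13)
  expect_equal(neutron_sld(peg, 0), neutron_sld(peg, 1))
  # monotone increasing in f_D2O when exchangeables present
  for (comp in list(mats$shell, peptide_composition("K3W(QL)6K2"))) {
    f <- seq(0, 1, 0.1)
    sld <- vapply(f, function(x) neutron_sld(comp, x), numeric(1))
    expect_true(all(diff(sld) > 0))
  }
  expect_error(material("C2H4O", 1.13, n_exchangeable_h = 10), "exceeds")
})

test_that("solvent SLD is linear in the D2O fraction", {
  f <- c(0, 0.25, 0.5, 0.75, 1)
  s <- solvent_sld(f)
  expect_equal(s[1], neutron_sld(water()))
  expect_equal(s[5], neutron_sld(heavy_water()))
  expect_equal(s[3], (s[1] + s[5]) / 2)
  # algebraic inverse: the f solving solvent = rho* is the linear interpolant
  rho_star <- 3e10
  f_star <- (rho_star - s[1]) / (s[5] - s[1])
  expect_equal(solvent_sld(f_star), rho_star)
})

test_that("ZAC solvent composition matches the experimental design", {
  mats <- k3_fiber_materials()
  conj_h <- conjugate_composition(k3_sequence(), mats$peg_h)
  conj_d <- conjugate_composition(k3_sequence(), mats$peg_d)
  f <- zac_match_point(conj_h, conj_d)
  # published blend buffer: 56% D2O / 44% H2O, +-3 points under the
  # documented exchange assumptions
  expect_equal(f, 0.56, tolerance = 0.03 / 0.56)
  # degenerate pair: equals the single-conjugate contrast match point
  expect_equal(zac_match_point(conj_h, conj_h), match_point(conj_h))
  # closed-form check with f-independent synthetic SLD constants
  r1 <- 1e10; r2 <- 4e10
  mk <- function(target) {
    # material with no exchangeables whose SLD equals `target`
    v <- 100  # A^3
    b_fm <- target * (v * 1e-24) / 1e-13
    nc <- b_fm / 6.646
    material(c(C = nc), 12.011 * nc / (v * 0.60221))
  }
  f_lin <- zac_match_point(mk(r1), mk(r2))
  s0 <- solvent_sld(0); s1 <- solvent_sld(1)
  expect_equal(f_lin, ((r1 + r2) / 2 - s0) / (s1 - s0), tolerance = 1e-6)
  # monotone bracketing function -> error reported when no root exists
  expect_error(zac_match_point(mk(8e10), mk(9e10)), "no zero-average")
})

test_that("derived fiber quantities reproduce the fitted aggregation state", {
  g <- k3_geometry()
  dq <- derive_fiber_quantities(g, d_core = 0.95, d_shell = 1.36,
                                m_pep = 2339)
  expect_equal(dq$n_agg, 180, tolerance = 0.02)
  expect_equal(dq$m_core, 473, tolerance = 0.02)
  expect_equal(dq$m_shell, 1866, tolerance = 0.02)
  # mass balance identity: M_pep * N_agg = sum of region volume * density
  expect_equal(dq$m_pep * dq$n_agg,
               dq$v_core * 0.95 * 0.60221 + dq$v_shell * 1.36 * 0.60221)
  # m_pep consistency: V_pep * d_pep * 0.60221 ~ M_pep * N_agg
  expect_equal(dq$v_pep * dq$d_pep * 0.60221, dq$m_total)
  expect_error(derive_fiber_quantities(g, -1, 1.36, 2339))
})

test_that("sequence masses: reference peptide, difference identity, termini", {
  # published M_pep = 2339 Da (within 0.3%)
  expect_equal(sequence_mass("K3W(QL)6K2"), 2339, tolerance = 0.003)
  # adding one lysine adds exactly one lysine residue mass
  expect_equal(sequence_mass("K4W(QL)6K2") - sequence_mass("K3W(QL)6K2"),
               128.175, tolerance = 1e-6)
  # empty sequence: water + modification deltas only
  expect_equal(sequence_mass("", n_term = "free", c_term = "acid"), 18.015,
               tolerance = 1e-3)
  # acetyl + amide deltas
  expect_equal(sequence_mass("G", n_term = "acetyl", c_term = "amide") -
               sequence_mass("G", n_term = "free", c_term = "acid"),
               42.037 - 0.984, tolerance = 1e-3)
  expect_error(sequence_mass("KZZ"), "unknown amino-acid")
})

test_that("compact peptide notation expands correctly", {
  expect_equal(expand_peptide("K3W(QL)6K2"), "KKKWQLQLQLQLQLQLKK")
  expect_equal(expand_peptide("W(QL)3K5(QL)3"), "WQLQLQLKKKKKQLQLQL")
  expect_equal(expand_peptide("GAVL"), "GAVL")
})

test_that("composite conjugate bookkeeping adds masses, volumes and labiles", {
  pep <- peptide_composition("K3W(QL)6K2")
  peg <- peg_composition(1900)
  conj <- combine_materials(pep, peg)
  expect_equal(conj$molar_mass, pep$molar_mass + peg$molar_mass)
  expect_equal(conj$volume, pep$volume + peg$volume, tolerance = 1e-9)
  expect_equal(conj$n_exchangeable_h, pep$n_exchangeable_h)
  # deuterated PEG preserves the molar volume of its hydrogenous twin
  peg_d <- peg_composition(2100, deuterated = TRUE)
  expect_equal(peg_d$volume / peg_d$formula[["O"]],
               peg$volume / peg$formula[["O"]], tolerance = 1e-6)
})
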