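# Rectangle amplitude, rod factor, blob term, and the assembled intensity.

test_that("rectangle amplitude: normalization, symmetry, oracle value", {
  expect_equal(rect_amplitude(0, 0.3, 26.6, 61.1), 1.0)
  # axis swap alpha -> pi/2 - alpha with a <-> b
  for (qq in c(0.01, 0.05, 0.2)) {
    for (al in c(0, 0.3, pi / 4, 1.2)) {
      expect_equal(rect_amplitude(qq, al, 26.6, 61.1),
                   rect_amplitude(qq, pi / 2 - al, 61.1, 26.6))
    }
  }
  # frozen value from term-by-term high-precision evaluation of the
  # cardinal-sine product
  expect_equal(rect_amplitude(0.05, pi / 4, 26.6, 61.1),
               0.786831601321, tolerance = 1e-10)
  expect_error(rect_amplitude(0.1, 0.2, -1, 5), "edge")
})

test_that("rod factor: forward limit, quadrature oracle, asymptote", {
  expect_equal(rod_factor(0, 340), 1.0)
  expect_equal(rod_factor(0.01, 340), 0.743202309815, tolerance = 1e-9)
  expect_equal(rod_factor(0.01, 340), rod_factor_oracle(0.01, 340),
               tolerance = 1e-9)
  # pi/(qc) asymptote within 1% for qc > 100
  for (qq in c(0.35, 0.5, 1)) {
    expect_equal(rod_factor(qq, 340), pi / (qq * 340), tolerance = 0.01)
  }
})

test_that("cross-section amplitude limits: collapse, matching, degenerate PEG", {
  g0 <- k3_geometry()
  ct <- contrast_set(2e10, 2e10, 2e10, 0.5e10, "xray")
  m <- nanofiber_model(g0, ct, phi = 0.008)
  # contrast collapse: equals homogeneous rectangle times drho * V_tot
  q <- c(0.02, 0.1, 0.3); al <- pi / 6
  v_tot <- g0$a_tot * g0$b_tot * g0$c * 1e-24
  expect_equal(cross_section_amplitude(q, al, m),
               1.5e10 * v_tot * rect_amplitude(q, al, g0$a_tot, g0$b_tot))
  # contrast matching -> exactly zero
  ct0 <- contrast_set(1e10, 1e10, 1e10, 1e10, "xray")
  m0 <- nanofiber_model(g0, ct0, phi = 0.008)
  expect_equal(cross_section_amplitude(q, al, m0), rep(0, 3))
  # d = 0: any rho_peg gives the two-region result
  ct1 <- contrast_set(1e10, 3e10, rho_peg = 9e10, rho_solv = 2e10, "xray")
  ct2 <- contrast_set(1e10, 3e10, rho_peg = -5e10, rho_solv = 2e10,
                      radiation = "neutron")
  m1 <- nanofiber_model(g0, ct1, phi = 0.008)
  m2 <- nanofiber_model(g0, ct2, phi = 0.008)
  expect_equal(cross_section_amplitude(q, al, m1),
               cross_section_amplitude(q, al, m2))
})

test_that("blob term: forward value, zero contrast, high-q slope", {
  expect_equal(blob_scattering(0, 15, 180, 2800, 1e10),
               180 * (1e10 * 2800 * 1e-24)^2)
  expect_equal(blob_scattering(c(0.1, 0.3), 15, 180, 2800, 0), c(0, 0))
  # Gaussian-coil exponent: local log-log slope -2 (within 2%) once past
  # the unified-form crossover (q Rg > 8)
  q <- exp(seq(log(8 / 15), log(40 / 15), length.out = 40))
  b <- blob_scattering(q, 15, 180, 2800, 1e10)
  slope <- diff(log(b)) / diff(log(q))
  expect_true(all(abs(slope + 2) < 0.04))
})

test_that("assembled intensity: forward closed form, background floor, scaling", {
  m <- k3_table_model("xray")
  g <- m$geometry; ct <- m$contrasts
  v_core <- g$a_core * g$b_core * g$c * 1e-24
  v_pep <- g$a_pep * g$b_pep * g$c * 1e-24
  v_tot <- g$a_tot * g$b_tot * g$c * 1e-24
  s <- (ct$rho_core - ct$rho_solv) * v_core +
       (ct$rho_shell - ct$rho_solv) * (v_pep - v_core)
  i0_closed <- m$phi * s^2 / v_tot
  expect_equal(nanofiber_intensity(1e-8, m), i0_closed, tolerance = 1e-3)
  # I(q) >= background everywhere (sum of squares plus background)
  mb <- nanofiber_model(g, ct, phi = m$phi, background = 0.01)
  q <- q_grid(0.004, 0.7, 120)
  expect_true(all(nanofiber_intensity(q, mb) >= 0.01))
  # all contrasts zero -> flat background
  ctz <- contrast_set(5e10, 5e10, 5e10, 5e10, "xray")
  mz <- nanofiber_model(g, ctz, phi = m$phi, background = 0.02)
  expect_equal(nanofiber_intensity(q, mz), rep(0.02, length(q)))
  # doubling c doubles I(0) - background (per-volume normalization)
  g2 <- nanofiber_geometry(g$a_core, g$a_shell, g$b_core, g$b_shell,
                           2 * g$c, warn_decoupling = FALSE)
  m2 <- nanofiber_model(g2, ct, phi = m$phi)
  expect_equal(nanofiber_intensity(1e-8, m2) / nanofiber_intensity(1e-8, m),
               2, tolerance = 1e-6)
  expect_error(nanofiber_intensity(numeric(0), m), "empty")
  expect_error(nanofiber_intensity(c(0.1, -0.2), m), "negative")
})

test_that("alpha-averaged intensity is invariant under axis swap", {
  m <- k3_table_model("xray")
  g <- m$geometry
  gs <- nanofiber_geometry(g$b_core, g$b_shell, g$a_core, g$a_shell, g$c,
                           warn_decoupling = FALSE)
  ms <- nanofiber_model(gs, m$contrasts, phi = m$phi)
  q <- c(0.01, 0.05, 0.1, 0.2, 0.4)
  expect_equal(nanofiber_intensity(q, m), nanofiber_intensity(q, ms),
               tolerance = 1e-10)
})

test_that("decoupled intensity matches the full-orientation oracle", {
  # instance at the boundary of the decoupling-validity regime
  # (c = 10 * max cross-section dimension), compared where q c > 10
  ct <- k3_table_model("xray")$contrasts
  g <- nanofiber_geometry(9.8, 8.4, 44.1, 8.5, 10 * 61.1,
                          warn_decoupling = FALSE)
  m <- nanofiber_model(g, ct, phi = 0.008)
  q <- exp(seq(log(10.5 / g$c), log(0.5), length.out = 25))
  i_dec <- nanofiber_intensity(q, m)
  i_oracle <- full_orientation_intensity(q, g, ct, 0.008)
  expect_true(max(abs(i_dec - i_oracle) / i_oracle) < 0.05)
})

test_that("geometry invariants are enforced", {
  g <- nanofiber_geometry(9.8, 8.4, 44.1, 8.5, 340, d = 30,
                          warn_decoupling = FALSE)
  expect_true(g$a_core < g$a_pep && g$a_pep < g$a_tot)
  expect_true(g$b_core < g$b_pep && g$b_pep < g$b_tot)
  expect_equal(g$a_pep, 26.6)
  expect_equal(g$b_pep, 61.1)
  expect_error(nanofiber_geometry(10, 5, 40, 5, 30), "exceed")
  expect_warning(nanofiber_geometry(10, 5, 40, 5, 200), "decoupling")
  expect_error(nanofiber_geometry(-1, 5, 40, 5, 500), "finite")
})

test_that("resolution smearing preserves smooth curves and widens minima", {
  m <- k3_table_model("xray")
  q <- seq(0.15, 0.3, length.out = 60)
  sharp <- nanofiber_intensity(q, m)
  smeared <- smear_intensity(q, 0.005, function(qq) nanofiber_intensity(qq, m))
  # smearing lifts the deep minimum
  expect_gt(min(smeared), min(sharp))
  # negligible dq changes nothing
  near <- smear_intensity(q, 1e-8, function(qq) nanofiber_intensity(qq, m))
  expect_equal(near, sharp, tolerance = 1e-6)
})
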