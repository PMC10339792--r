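# Synthetic curves, contrast series, and ZAC exchange decays.

test_that("simulated curves honour the noise model and determinism contract", {
  m <- k3_table_model("xray")
  q <- q_grid(0.01, 0.3, 50)
  # zero noise -> exact model curve
  c0 <- simulate_curve(m, q, noise_rel = 0, noise_floor = 0)
  expect_equal(c0$intensity, nanofiber_intensity(q, m))
  # same seed -> identical; different seed -> different
  c1 <- simulate_curve(m, q, seed = 42)
  c2 <- simulate_curve(m, q, seed = 42)
  c3 <- simulate_curve(m, q, seed = 43)
  expect_identical(c1$intensity, c2$intensity)
  expect_false(identical(c1$intensity, c3$intensity))
  # sigma column stores the generating sigma
  expect_equal(c1$sigma, 0.02 * abs(c1$metadata$i_true) + 1e-3)
  # seeding does not disturb the session RNG stream
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(simulate_curve(m, q, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("replicate mean converges to the true curve (law of large numbers)", {
  m <- k3_table_model("xray")
  q <- c(0.02, 0.1)
  i_true <- nanofiber_intensity(q, m)
  sims <- vapply(1:200, function(s)
    simulate_curve(m, q, seed = s)$intensity, numeric(2))
  sig <- 0.02 * i_true + 1e-3
  se <- sig / sqrt(200)
  expect_true(all(abs(rowMeans(sims) - i_true) < 3 * se))
})

test_that("contrast series highlights regions and matches out the PEG corona", {
  geom <- k3_geometry(d = 30)
  mats <- k3_fiber_materials()
  # PEG match point: hydrogenous PEG has no exchangeables
  f_peg <- match_point(mats$peg_h)
  curves <- simulate_contrast_series(c(0, f_peg, 1), geom,
                                     q = q_grid(0.004, 0.3, 40),
                                     noise_rel = 0, noise_floor = 0)
  expect_length(curves, 3)
  expect_equal(curves[[2]]$metadata$f_d2o, f_peg)
  # at the PEG match contrast the curve equals the d = 0 model
  ct <- curves[[2]]$metadata$contrasts
  g0 <- k3_geometry(d = 0)
  m0 <- nanofiber_model(g0, ct, phi = 0.008,
                        n_agg = 178, v_peg = mats$peg_h$volume)
  expect_equal(curves[[2]]$intensity,
               nanofiber_intensity(curves[[2]]$q, m0), tolerance = 1e-6)
  # forward intensity varies quadratically with the mean excess SLD
  f_all <- c(0, 0.3, 0.6, 1)
  series <- simulate_contrast_series(f_all, geom, q = q_grid(1e-4, 2e-4, 2),
                                     noise_rel = 0, noise_floor = 0)
  i0 <- vapply(series, function(cur) cur$intensity[1], numeric(1))
  pred <- vapply(series, function(cur) {
    ct <- cur$metadata$contrasts
    g <- geom
    v_core <- g$a_core * g$b_core * g$c * 1e-24
    v_pep <- g$a_pep * g$b_pep * g$c * 1e-24
    v_tot <- g$a_tot * g$b_tot * g$c * 1e-24
    s <- (ct$rho_core - ct$rho_solv) * v_core +
         (ct$rho_shell - ct$rho_solv) * (v_pep - v_core) +
         (ct$rho_peg - ct$rho_solv) * (v_tot - v_pep)
    mats <- k3_fiber_materials()
    n_agg <- derive_fiber_quantities(geom, 0.95, 1.36, 2339)$n_agg
    blob0 <- n_agg * ((ct$rho_peg - ct$rho_solv) * mats$peg_h$volume * 1e-24)^2
    0.008 / v_pep * (s^2 + blob0)
  }, numeric(1))
  expect_equal(i0, pred, tolerance = 0.005)
})

test_that("exchange mechanisms: mean-field fractions and conservation", {
  times <- c(0, 0.5, 1, 2, 4, 8, 16)
  me <- exchange_mechanism("end_only", rate = 1, n_end = 10, n_agg = 178)
  mu <- exchange_mechanism("uniform_unimer", rate = 1)
  mb <- exchange_mechanism("breakup_reform", rate = 1)
  x_e <- exchange_h_fraction(me, times)
  x_u <- exchange_h_fraction(mu, times)
  expect_equal(x_e[1], 1)      # unmixed start
  expect_equal(x_u[1], 1)
  # end_only saturates at 1 - f_acc / 2; uniform relaxes to 0.5
  f_acc <- 2 * 10 / 178
  expect_equal(x_e[length(times)], 1 - f_acc / 2, tolerance = 1e-4)
  expect_equal(x_u[length(times)], 0.5, tolerance = 1e-4)
  # h fraction stays a physical fraction and decays monotonically
  expect_true(all(x_e >= 0.5 & x_e <= 1))
  expect_true(all(diff(x_e) <= 0) && all(diff(x_u) <= 0))
  expect_error(exchange_mechanism("end_only", rate = 1, n_end = 100,
                                  n_agg = 178), "n_end")
  expect_error(exchange_h_fraction(mb, c(2, 1)), "sorted")
})

test_that("ZAC decay: monotone decay, end-only plateau, mechanism continuity", {
  geom <- k3_geometry(d = 30)
  times <- c(0, 0.5, 1, 2, 4, 8)
  qg <- q_grid(0.004, 0.3, 50)
  ze <- simulate_zac_decay(geom, exchange_mechanism("end_only", rate = 1,
                                                    n_end = 10, n_agg = 178),
                           times, q = qg)
  zb <- simulate_zac_decay(geom, exchange_mechanism("breakup_reform",
                                                    rate = 1),
                           times, q = qg)
  tot_e <- vapply(ze$curves, function(cur) sum(cur$intensity), numeric(1))
  tot_b <- vapply(zb$curves, function(cur) sum(cur$intensity), numeric(1))
  # t = 0: identical unmixed blends
  expect_equal(tot_e[1], tot_b[1])
  # monotone non-increasing intensity for both mechanisms
  expect_true(all(diff(tot_e) <= 1e-9 * tot_e[1]))
  expect_true(all(diff(tot_b) <= 1e-9 * tot_b[1]))
  # end-only plateau sits strictly above the full-relaxation limit
  expect_gt(tot_e[length(times)], 2 * tot_b[length(times)])
  # breakup at t -> infinity equals the fully mixed blend
  long <- simulate_zac_decay(geom, exchange_mechanism("breakup_reform",
                                                      rate = 1),
                             c(0, 50), q = qg)
  x_mixed <- 0.5
  expect_equal(long$relaxation$x1[2], x_mixed, tolerance = 1e-6)
  # mechanism continuity: n_end -> N_agg / 2 reproduces full relaxation
  zf <- simulate_zac_decay(geom, exchange_mechanism("end_only", rate = 1,
                                                    n_end = 89, n_agg = 178),
                           times, q = qg)
  tot_f <- vapply(zf$curves, function(cur) sum(cur$intensity), numeric(1))
  expect_equal(tot_f, tot_b, tolerance = 1e-10)
  # relaxation function: R(t) tracks the population contrast amplitude
  expect_equal(ze$relaxation$R, (ze$relaxation$x1 - 0.5) / 0.5,
               tolerance = 1e-6)
  # solved ZAC solvent composition is stored
  expect_equal(ze$f_d2o, 0.56, tolerance = 0.06)
})
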