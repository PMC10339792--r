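# Shared fixtures and independent oracles.
#
# The oracles here deliberately avoid the package's own evaluation paths:
# the full-orientation average integrates the nested parallelepipeds over
# the sphere with 2-D Gauss-Legendre quadrature, the rod oracle integrates
# the rod orientational average directly, and the Percus-Yevick oracle
# Fourier-transforms the direct correlation function numerically.

table1_truth <- c(a_core = 9.8, a_shell = 8.4, b_core = 44.1,
                  b_shell = 8.5, c = 340)

.sinc_ref <- function(x) ifelse(abs(x) < 1e-9, 1, sin(x) / x)

# Brute-force orientational average of |sum_j drho_j V_j F_j|^2 for nested
# parallelepipeds (core + peptide envelope), over the sphere octant.
full_orientation_intensity <- function(q, geom, ct, phi,
                                       nth = 600, nph = 300) {
  glt <- pracma::gaussLegendre(nth, 0, pi / 2)
  glp <- pracma::gaussLegendre(nph, 0, pi / 2)
  a3 <- 1e-24
  vc <- geom$a_core * geom$b_core * geom$c * a3
  vp <- geom$a_pep * geom$b_pep * geom$c * a3
  vt <- geom$a_tot * geom$b_tot * geom$c * a3
  drc <- ct$rho_core - ct$rho_solv
  drs <- ct$rho_shell - ct$rho_solv
  st <- sin(glt$x); ctn <- cos(glt$x)
  sp <- sin(glp$x); cp <- cos(glp$x)
  wnorm <- sum(glt$w * st) * sum(glp$w)  # integral of sin over the octant
  avg <- vapply(q, function(qq) {
    qx <- qq * outer(st, cp); qy <- qq * outer(st, sp)
    zf <- .sinc_ref(qq * ctn * geom$c / 2)
    fc <- .sinc_ref(qx * geom$a_core / 2) * .sinc_ref(qy * geom$b_core / 2)
    fp <- .sinc_ref(qx * geom$a_pep / 2) * .sinc_ref(qy * geom$b_pep / 2)
    f <- (drc * vc * fc + drs * (vp * fp - vc * fc)) * zf
    as.numeric(t(glt$w) %*% (f^2 * st) %*% glp$w) / wnorm
  }, numeric(1))
  phi / vt * avg
}

# Direct quadrature of the thin-rod orientational average.
rod_factor_oracle <- function(q, c) {
  stats::integrate(function(b) {
    x <- q * c * cos(b) / 2
    .sinc_ref(x)^2 * sin(b)
  }, 0, pi / 2, rel.tol = 1e-12)$value
}

# Numeric Fourier transform of the PY direct correlation function.
py_structure_oracle <- function(q, radius, eta) {
  sig <- 2 * radius
  al <- (1 + 2 * eta)^2 / (1 - eta)^4
  be <- -6 * eta * (1 + eta / 2)^2 / (1 - eta)^4
  ga <- eta * al / 2
  n <- 6 * eta / (pi * sig^3)
  vapply(q, function(qq) {
    chat <- 4 * pi * stats::integrate(function(r)
      -(al + be * (r / sig) + ga * (r / sig)^3) * r^2 *
        .sinc_ref(qq * r), 0, sig, rel.tol = 1e-10)$value
    1 / (1 - n * chat)
  }, numeric(1))
}

# SAXS + SANS pair from the reference fitted model with 2% noise.
make_saxs_sans_pair <- function(seed, q = q_grid(0.004, 0.5, 150)) {
  mx <- k3_table_model("xray")
  mn <- k3_table_model("neutron")
  cx <- simulate_curve(mx, q, seed = 1000 + seed)
  cx$metadata$contrasts <- mx$contrasts
  cn <- simulate_curve(mn, q, seed = 2000 + seed)
  cn$metadata$contrasts <- mn$contrasts
  list(cx, cn)
}

recover_cross_section <- function(seed, n_starts = 8,
                                  q = q_grid(0.004, 0.5, 150)) {
  pair <- make_saxs_sans_pair(seed, q)
  start <- table1_truth * c(1.25, 0.8, 1.2, 0.75, 1.3)
  prob <- fit_problem(pair, "nanofiber",
                      start = c(start, phi = 0.008),
                      free = names(table1_truth), upper = c(c = 2000),
                      m_pep = 2339, d_core = 0.95, d_shell = 1.36)
  r <- fit(prob, seed = seed, n_starts = n_starts)
  abs(r$values[names(table1_truth)] - table1_truth) / table1_truth
}

recover_peg_layer <- function(seed, n_starts = 8,
                              q = q_grid(0.004, 0.5, 120)) {
  geom <- k3_geometry(d = 30)
  curves <- simulate_contrast_series(c(0, 0.25, 0.5, 0.75, 1), geom,
                                     q = q, seed = 100 * seed)
  truth <- c(table1_truth, d = 30)
  start <- truth * c(1.2, 0.85, 1.15, 0.8, 1.2, 0.7)
  mats <- k3_fiber_materials()
  prob <- fit_problem(curves, "nanofiber",
                      start = c(start, phi = 0.008, rg_blob = 15,
                                v_peg = mats$peg_h$volume),
                      free = names(truth), upper = c(c = 2000, d = 100),
                      m_pep = 2339, d_core = 0.95, d_shell = 1.36)
  r <- fit(prob, seed = seed, n_starts = n_starts)
  abs(r$values[names(truth)] - truth) / truth
}

# Locate (q, I) local extrema of a curve restricted to a q window.
curve_extrema <- function(q, i, window = c(0, Inf)) {
  s <- sign(diff(log(i)))
  idx <- which(diff(s) != 0) + 1L
  idx <- idx[q[idx] >= window[1] & q[idx] <= window[2]]
  data.frame(q = q[idx], i = i[idx],
             type = ifelse(diff(s)[idx - 1L] > 0, "min", "max"))
}
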