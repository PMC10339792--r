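# Companion scattering models: Beaucage unified fit for dissolved chains,
# inter-particle structure factors, and the legacy uniform filament.

#' Beaucage model parameters
#'
#' @param G forward (Guinier) intensity in 1/cm.
#' @param rg radius of gyration in A.
#' @param B power-law prefactor; `NULL` selects the value consistent with
#'   `G`, `rg` and `df` (for `df = 2` this reproduces the Debye high-Q tail
#'   `2 G / (Q Rg)^2`).
#' @param df power-law exponent in `[1, 4]`.
#' @param background flat background in 1/cm.
#' @export
beaucage_params <- function(G, rg, B = NULL, df = 2, background = 0) {
  stopifnot(G > 0, rg > 0, df >= 1, df <= 4, background >= 0)
  if (is.null(B)) B <- G * .beaucage_prefactor(df) / rg^df
  structure(list(G = G, rg = rg, B = B, df = df, background = background),
            class = "beaucage_params")
}

#' Beaucage unified intensity
#'
#' `I(Q) = G exp(-Q^2 Rg^2 / 3) + B [erf(Q Rg / sqrt 6)]^(3 df) / Q^df + bkg`.
#' Forward value `G + background`; high-Q slope `-df` on log-log axes.
#'
#' @param q scattering vector (1/A), vector.
#' @param params a [beaucage_params()] (or `G` given directly).
#' @inheritParams beaucage_params
#' @return intensity in 1/cm.
#' @export
#' @examples
#' beaucage_intensity(c(0, 0.1), beaucage_params(G = 1, rg = 22))
beaucage_intensity <- function(q, params = NULL, G = NULL, rg = NULL, B = NULL,
                               df = 2, background = 0) {
  if (is.null(params)) params <- beaucage_params(G, rg, B, df, background)
  stopifnot(inherits(params, "beaucage_params"), all(q >= 0))
  qr <- q * params$rg
  guinier <- params$G * exp(-qr^2 / 3)
  qstar <- ifelse(q > 0, (.erf(qr / sqrt(6)))^3 / q, 0)
  pl <- ifelse(q > 0, params$B * qstar^params$df, 0)
  guinier + pl + params$background
}

#' Convert Beaucage forward intensity to molar mass
#'
#' For dilute dissolved chains `G = phi * M_w * (drho * vbar)^2 * 1e24 / N_A`
#' with `vbar = 1 / density` the specific volume (mL/g); inverting gives the
#' apparent molar mass of the scatterers.
#'
#' @param G forward intensity (1/cm).
#' @param phi solute volume fraction.
#' @param drho excess SLD (1/cm^2).
#' @param density solute mass density (g/mL).
#' @return molar mass in Da (g/mol).
#' @export
beaucage_mw <- function(G, phi, drho, density) {
  stopifnot(G > 0, phi > 0, density > 0)
  # G = phi/V * (drho V)^2 with V the chain volume; V = M/(d NA) cm^3
  G / (phi * drho^2) * density * .const$avogadro
}

#' Percus-Yevick hard-sphere structure factor
#'
#' Analytic solution of the Percus-Yevick closure for hard spheres of radius
#' `radius` at volume fraction `volfrac`; `S(Q) -> 1` at high Q and
#' `S(0) = (1 - eta)^4 / (1 + 2 eta)^2`.
#'
#' @param q scattering vector (1/A), vector.
#' @param radius hard-sphere radius (A).
#' @param volfrac hard-sphere volume fraction in `[0, 0.74)`.
#' @return S(Q) vector (dimensionless, > 0).
#' @export
sq_hardsphere_py <- function(q, radius, volfrac) {
  stopifnot(radius > 0, volfrac >= 0, volfrac < 0.74, all(q >= 0))
  if (volfrac == 0) return(rep(1, length(q)))
  eta <- volfrac
  al <- (1 + 2 * eta)^2 / (1 - eta)^4
  be <- -6 * eta * (1 + eta / 2)^2 / (1 - eta)^4
  ga <- eta * al / 2
  u <- 2 * q * radius
  s <- numeric(length(u))
  small <- u < 1e-3
  # S(0) limit of the PY solution
  s[small] <- 1 / (1 + 24 * eta * (al / 3 + be / 4 + ga / 6))
  ub <- u[!small]
  if (length(ub)) {
    su <- sin(ub); cu <- cos(ub)
    g <- al * (su - ub * cu) / ub^2 +
      be * (2 * ub * su + (2 - ub^2) * cu - 2) / ub^3 +
      ga * (-ub^4 * cu + 4 * ((3 * ub^2 - 6) * cu + (ub^3 - 6 * ub) * su + 6)) / ub^5
    s[!small] <- 1 / (1 + 24 * eta * g / ub)
  }
  s
}

#' Screened-Coulomb (Yukawa) structure factor, RPA on a PY reference
#'
#' Adds the random-phase-approximation correction for a repulsive Yukawa
#' tail `beta u(r) = gamma_c * sigma * exp(-kappa (r - sigma)) / r` (contact
#' value `gamma_c` in kT) outside a Percus-Yevick hard core:
#' `1/S(Q) = 1/S_PY(Q) + n beta u_hat(Q)`.
#'
#' @inheritParams sq_hardsphere_py
#' @param gamma_c contact potential in kT (>= 0; repulsive).
#' @param kappa inverse screening length (1/A).
#' @export
sq_screened_coulomb <- function(q, radius, volfrac, gamma_c, kappa) {
  stopifnot(gamma_c >= 0, kappa > 0)
  s_py <- sq_hardsphere_py(q, radius, volfrac)
  if (gamma_c == 0 || volfrac == 0) return(s_py)
  sigma <- 2 * radius
  n <- volfrac / (4 / 3 * pi * radius^3)  # number density, 1/A^3
  qq <- pmax(q, 1e-8)
  uhat <- 4 * pi * gamma_c * sigma *
    (kappa * sin(qq * sigma) + qq * cos(qq * sigma)) / (qq * (kappa^2 + qq^2))
  s <- 1 / (1 / s_py + n * uhat)
  if (any(s <= 0)) stop("unphysical structure factor (S <= 0); ",
                        "reduce gamma_c or volfrac", call. = FALSE)
  s
}

#' Apply a structure factor to a form-factor intensity
#'
#' Element-wise `P(Q) * S(Q)` under the decoupling (monodisperse effective
#' sphere) approximation.
#'
#' @param intensity form-factor intensity vector (1/cm).
#' @param sq structure-factor vector, same length, all > 0.
#' @export
apply_structure_factor <- function(intensity, sq) {
  stopifnot(length(intensity) == length(sq))
  if (any(sq <= 0)) stop("S(Q) must be > 0", call. = FALSE)
  intensity * sq
}

#' Homogeneous (uniform) filament intensity
#'
#' The legacy single-contrast special case of the core-shell model: a
#' homogeneous parallelepiped `a < b < c` with uniform excess SLD `drho`.
#' Implemented as the contrast-collapsed reduction of
#' [nanofiber_intensity()].
#'
#' @param q scattering vector (1/A), vector.
#' @param a,b,c edge lengths (A), intended `a < b < c`.
#' @param drho uniform excess SLD (1/cm^2).
#' @param phi volume fraction.
#' @param background flat background (1/cm).
#' @param ... passed to [nanofiber_intensity()].
#' @export
uniform_filament_intensity <- function(q, a, b, c, drho, phi,
                                       background = 0, ...) {
  if (!(a < b && b < c))
    warning("expected a < b < c for a filament", call. = FALSE)
  geom <- nanofiber_geometry(a_core = a, a_shell = 0, b_core = b, b_shell = 0,
                             c = c, d = 0, warn_decoupling = FALSE)
  ct <- contrast_set(rho_core = drho, rho_shell = drho, rho_peg = drho,
                     rho_solv = 0, radiation = "neutron")
  m <- nanofiber_model(geom, ct, phi = phi, background = background)
  nanofiber_intensity(q, m, ...)
}
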