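# Rectangular core-shell(-shell) nanofiber form factor.
#
# The fiber is a long parallelepiped (length c) whose cross-section consists
# of a rectangular hydrophobic core (a_core x b_core), a peptide envelope of
# shell thicknesses a_shell, b_shell, and optionally a solvent-swollen PEG
# envelope of thickness d.  Because c greatly exceeds the cross-section, the
# longitudinal scattering decouples into an infinitely-thin-rod factor and
# the intensity becomes
#
#   I(Q) = phi / V_pep * [ <|A_cs(Q, alpha)|^2>_alpha * P_rod(Q, c)
#                          + N_agg (drho_PEG V_PEG)^2 B_blob(Q, Rg) ] + bkg
#
# where phi is the peptide volume fraction and V_pep the peptide-envelope
# volume per fiber, so phi / V_pep is the fiber number density regardless
# of the (solvent-swollen) PEG envelope.
#
# with A_cs the contrast-and-volume weighted superposition of nested
# rectangle amplitudes, averaged over the cross-section rotation angle alpha.

#' Nanofiber cross-section geometry
#'
#' All lengths in Angstrom.  Derived dimensions: `a_pep = a_core + 2 a_shell`,
#' `b_pep = b_core + 2 b_shell`, `a_tot = a_pep + 2 d`, `b_tot = b_pep + 2 d`.
#' The decoupling approximation assumes `c` much greater than the
#' cross-section; a warning flags `c < 10 * max(a_tot, b_tot)`.
#'
#' @param a_core,b_core core cross-section edges (A).
#' @param a_shell,b_shell peptide shell thicknesses (A).
#' @param c fiber length (A).
#' @param d PEG layer thickness (A); 0 for non-PEGylated fibers.
#' @param warn_decoupling warn when outside the safe decoupling regime.
#' @export
#' @examples
#' nanofiber_geometry(9.8, 8.4, 44.1, 8.5, 340)
nanofiber_geometry <- function(a_core, a_shell, b_core, b_shell, c, d = 0,
                               warn_decoupling = TRUE) {
  vals <- c(a_core, a_shell, b_core, b_shell, c, d)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all geometry parameters must be finite and >= 0", call. = FALSE)
  g <- list(a_core = a_core, a_shell = a_shell, b_core = b_core,
            b_shell = b_shell, c = c, d = d,
            a_pep = a_core + 2 * a_shell, b_pep = b_core + 2 * b_shell)
  g$a_tot <- g$a_pep + 2 * d
  g$b_tot <- g$b_pep + 2 * d
  if (c <= max(g$a_tot, g$b_tot))
    stop("fiber length c must exceed the cross-section dimensions",
         call. = FALSE)
  if (warn_decoupling && c < 10 * max(g$a_tot, g$b_tot))
    warning("c < 10 * max cross-section: outside the safe decoupling regime",
            call. = FALSE)
  structure(g, class = "nanofiber_geometry")
}

#' @export
print.nanofiber_geometry <- function(x, ...) {
  cat("<nanofiber_geometry> (A)\n")
  cat(sprintf("  core %.4g x %.4g, shells %.4g / %.4g -> pep %.4g x %.4g\n",
              x$a_core, x$b_core, x$a_shell, x$b_shell, x$a_pep, x$b_pep))
  cat(sprintf("  PEG layer d = %.4g -> total %.4g x %.4g, length c = %.4g\n",
              x$d, x$a_tot, x$b_tot, x$c))
  invisible(x)
}

#' Per-region scattering length densities
#'
#' @param rho_core,rho_shell,rho_peg,rho_solv SLDs in 1/cm^2.  `rho_peg` is
#'   ignored when the geometry has `d = 0`.
#' @param radiation `"xray"` or `"neutron"`.
#' @export
contrast_set <- function(rho_core, rho_shell, rho_peg = rho_solv, rho_solv,
                         radiation = c("xray", "neutron")) {
  radiation <- match.arg(radiation)
  vals <- c(rho_core, rho_shell, rho_peg, rho_solv)
  stopifnot(all(is.finite(vals)))
  if (radiation == "xray" && any(vals < 0))
    stop("X-ray SLDs must be non-negative", call. = FALSE)
  structure(list(rho_core = rho_core, rho_shell = rho_shell,
                 rho_peg = rho_peg, rho_solv = rho_solv,
                 radiation = radiation), class = "contrast_set")
}

#' Full nanofiber scattering model
#'
#' @param geometry a [nanofiber_geometry()].
#' @param contrasts a [contrast_set()].
#' @param phi peptide volume fraction (mass concentration over peptide
#'   density), in (0, 1); the PEG envelope is not counted.
#' @param n_agg molecules per fiber (used by the PEG blob term).
#' @param v_peg PEG chain molecular volume in A^3.
#' @param rg_blob blob radius of gyration in A.
#' @param background flat background in 1/cm.
#' @export
nanofiber_model <- function(geometry, contrasts, phi,
                            n_agg = 1, v_peg = 0, rg_blob = 15,
                            background = 0) {
  stopifnot(inherits(geometry, "nanofiber_geometry"),
            inherits(contrasts, "contrast_set"),
            phi > 0, phi < 1, n_agg >= 1, v_peg >= 0, rg_blob > 0,
            background >= 0)
  structure(list(geometry = geometry, contrasts = contrasts, phi = phi,
                 n_agg = n_agg, v_peg = v_peg, rg_blob = rg_blob,
                 background = background), class = "nanofiber_model")
}

.sinc <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)

#' Scattering amplitude of a rectangle
#'
#' Product of cardinal sines for the two projected edges,
#' `sinc(Q a sin(alpha) / 2) * sinc(Q b cos(alpha) / 2)`, normalised to 1 at
#' `Q = 0`.  `alpha` is the rotation angle of the cross-section about the
#' fiber axis.
#'
#' @param q scattering vector (1/A), vector allowed.
#' @param alpha rotation angle in radians, vector allowed (recycled against
#'   `q`; if both have length > 1 a `length(q) x length(alpha)` matrix is
#'   returned).
#' @param a,b rectangle edge lengths (A), both > 0.
#' @return dimensionless amplitude.
#' @export
#' @examples
#' rect_amplitude(0, 0.3, 26.6, 61.1)  # exactly 1
rect_amplitude <- function(q, alpha, a, b) {
  if (a <= 0 || b <= 0) stop("edge lengths must be > 0", call. = FALSE)
  if (any(q < 0)) stop("q must be >= 0", call. = FALSE)
  if (length(q) > 1L && length(alpha) > 1L) {
    .sinc(outer(q * a / 2, sin(alpha))) * .sinc(outer(q * b / 2, cos(alpha)))
  } else {
    .sinc(q * a / 2 * sin(alpha)) * .sinc(q * b / 2 * cos(alpha))
  }
}

#' Contrast-weighted cross-section amplitude
#'
#' Superposition of the nested rectangle amplitudes in which each physical
#' region carries its own excess SLD:
#' core (`drho_core V_core`), peptide shell (`drho_shell (V_pep - V_core)`),
#' and PEG envelope (`drho_PEG (V_tot - V_pep)`).  For `d = 0` the PEG term
#' vanishes identically.
#'
#' @inheritParams rect_amplitude
#' @param model a [nanofiber_model()].
#' @return amplitude in cm (contrast times volume), same shape rules as
#'   [rect_amplitude()].
#' @export
cross_section_amplitude <- function(q, alpha, model) {
  stopifnot(inherits(model, "nanofiber_model"))
  g <- model$geometry; ct <- model$contrasts
  a3 <- .const$A3_to_cm3
  v_core <- g$a_core * g$b_core * g$c * a3
  v_pep  <- g$a_pep * g$b_pep * g$c * a3
  v_tot  <- g$a_tot * g$b_tot * g$c * a3
  dr_core <- ct$rho_core - ct$rho_solv
  dr_shell <- ct$rho_shell - ct$rho_solv
  dr_peg <- ct$rho_peg - ct$rho_solv
  amp_core <- if (v_core > 0) rect_amplitude(q, alpha, g$a_core, g$b_core) else 0
  amp_pep <- rect_amplitude(q, alpha, g$a_pep, g$b_pep)
  out <- dr_core * v_core * amp_core +
         dr_shell * (v_pep * amp_pep - v_core * amp_core)
  if (g$d > 0) {
    amp_tot <- rect_amplitude(q, alpha, g$a_tot, g$b_tot)
    out <- out + dr_peg * (v_tot * amp_tot - v_pep * amp_pep)
  }
  out
}

#' Longitudinal factor of an infinitely thin rod
#'
#' `P_rod(Q) = 2 Si(Qc) / (Qc) - [sin(Qc/2) / (Qc/2)]^2`, the orientational
#' average over rod directions; equals 1 at `Q = 0` and falls off as
#' `pi / (Qc)`.
#'
#' @param q scattering vector (1/A), vector allowed.
#' @param c rod length (A), > 0.
#' @return dimensionless factor.
#' @export
#' @examples
#' rod_factor(0, 340)  # 1
rod_factor <- function(q, c) {
  if (c <= 0) stop("rod length must be > 0", call. = FALSE)
  if (any(q < 0)) stop("q must be >= 0", call. = FALSE)
  x <- q * c
  out <- numeric(length(x))
  small <- x < 1e-6
  out[small] <- 1
  xs <- x[!small]
  if (length(xs))
    out[!small] <- 2 * pracma::Si(xs) / xs - (.sinc(xs / 2))^2
  out
}

.beaucage_prefactor <- function(df) {
  # power-law prefactor of the unified form for unit Guinier amplitude
  (df) * (6 * df^2 / ((2 + df) * (2 + 2 * df)))^(df / 2) * gamma(df / 2)
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Unit-amplitude Beaucage term: exp(-q^2 Rg^2/3) + C(df) [erf(qRg/sqrt 6)]^(3 df) / (q Rg)^df
.beaucage_unit <- function(q, rg, df = 2) {
  qr <- q * rg
  guinier <- exp(-qr^2 / 3)
  qs <- ifelse(qr > 0, (.erf(qr / sqrt(6)))^3 / q, 0)
  pl <- ifelse(qr > 0, .beaucage_prefactor(df) * qs^df / rg^df, 0)
  guinier + pl
}

#' Blob scattering of the PEG corona
#'
#' Incoherent-like sum of `N_agg` chain blobs per fiber, each weighted by
#' `(drho_PEG V_PEG)^2`, with a unit-amplitude Beaucage form of Gaussian-coil
#' exponent 2 (high-Q slope -2).  Returns 0 for zero contrast or a
#' non-PEGylated geometry.
#'
#' @param q scattering vector (1/A).
#' @param rg blob radius of gyration (A), > 0.
#' @param n_agg molecules (chains) per fiber.
#' @param v_peg PEG molecular volume (A^3).
#' @param drho_peg PEG excess SLD (1/cm^2).
#' @param df power-law exponent (default 2, Gaussian chain).
#' @return per-fiber intensity contribution in cm^2.
#' @export
blob_scattering <- function(q, rg, n_agg, v_peg, drho_peg, df = 2) {
  stopifnot(rg > 0, n_agg >= 0, v_peg >= 0)
  if (v_peg == 0 || drho_peg == 0 || n_agg == 0) return(numeric(length(q)))
  n_agg * (drho_peg * v_peg * .const$A3_to_cm3)^2 * .beaucage_unit(q, rg, df)
}

# Gauss-Legendre nodes/weights on [0, pi/2], cached per order.
.gl_cache <- new.env(parent = emptyenv())
.gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]]))
    .gl_cache[[key]] <- pracma::gaussLegendre(n, 0, pi / 2)
  .gl_cache[[key]]
}

# alpha-average of |A_cs|^2 on a q grid with n-node Gauss-Legendre quadrature
.cs_average <- function(q, model, n_alpha) {
  gl <- .gl_nodes(n_alpha)
  amp <- cross_section_amplitude(q, gl$x, model)
  if (is.null(dim(amp))) amp <- matrix(amp, nrow = length(q))
  as.vector((amp^2) %*% gl$w) / (pi / 2)
}

#' Absolute-scale nanofiber scattering intensity
#'
#' Rotationally averages the squared cross-section amplitude over alpha by
#' Gauss-Legendre quadrature, multiplies by the thin-rod factor, adds the PEG
#' blob term, scales by the fiber number density `phi / V_pep` and adds the
#' flat background.  With
#' `adaptive = TRUE` the quadrature order is doubled until the average
#' changes by less than `alpha_tol` (relative), which matters at high
#' `Q * b_tot` where the integrand oscillates.
#'
#' @param q vector of scattering vectors (1/A), all >= 0, non-empty.
#' @param model a [nanofiber_model()].
#' @param n_alpha starting quadrature order (default 256).
#' @param adaptive double the order until converged (default TRUE).
#' @param alpha_tol relative convergence tolerance (default 1e-4).
#' @param max_n_alpha order cap (default 2048).
#' @return intensity vector in 1/cm.
#' @export
#' @examples
#' m <- k3_table_model("xray")
#' I <- nanofiber_intensity(c(0.01, 0.1, 0.3), m)
nanofiber_intensity <- function(q, model, n_alpha = 256, adaptive = TRUE,
                                alpha_tol = 1e-4, max_n_alpha = 2048) {
  stopifnot(inherits(model, "nanofiber_model"))
  if (length(q) == 0) stop("empty q grid", call. = FALSE)
  if (any(q < 0)) stop("negative q", call. = FALSE)
  g <- model$geometry
  cs <- .cs_average(q, model, n_alpha)
  if (adaptive) {
    repeat {
      n2 <- 2 * n_alpha
      cs2 <- .cs_average(q, model, n2)
      rel <- max(abs(cs2 - cs) / pmax(abs(cs2), .Machine$double.xmin))
      cs <- cs2; n_alpha <- n2
      if (rel < alpha_tol || n_alpha >= max_n_alpha) break
    }
  }
  # number density of fibers is phi / V_pep: phi is the peptide volume
  # fraction (mass concentration over peptide density), which excludes the
  # solvent-swollen PEG envelope
  v_pep <- g$a_pep * g$b_pep * g$c * .const$A3_to_cm3
  drho_peg <- model$contrasts$rho_peg - model$contrasts$rho_solv
  blob <- if (g$d > 0)
    blob_scattering(q, model$rg_blob, model$n_agg, model$v_peg, drho_peg)
  else numeric(length(q))
  model$phi / v_pep * (cs * rod_factor(q, g$c) + blob) + model$background
}

#' Gaussian resolution smearing
#'
#' Convolves a model intensity function with a Gaussian of standard deviation
#' `dq` at each grid point (5-point Gauss-Hermite rule).  Off by default in
#' all fitting/simulation entry points; used when a 4-column curve supplies
#' per-point resolution.
#'
#' @param q grid (1/A).
#' @param dq per-point Gaussian sigma (1/A), recycled.
#' @param intensity_fn function of a q vector returning intensities.
#' @return smeared intensity vector.
#' @export
smear_intensity <- function(q, dq, intensity_fn) {
  gh_x <- c(-2.0201828704561, -0.9585724646138, 0, 0.9585724646138,
            2.0201828704561)
  gh_w <- c(0.019953242059046, 0.39361932315224, 0.94530872048294,
            0.39361932315224, 0.019953242059046) / sqrt(pi)
  dq <- rep_len(dq, length(q))
  out <- numeric(length(q))
  for (k in seq_along(gh_x)) {
    qk <- pmax(q + sqrt(2) * dq * gh_x[k], 0)
    out <- out + gh_w[k] * intensity_fn(qk)
  }
  out
}
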