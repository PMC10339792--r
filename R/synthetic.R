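# Synthetic-data generation: noisy curves, H2O/D2O contrast series, and
# time-resolved zero-average-contrast (ZAC) exchange decays.
#
# Default noise mimics good beamline data: 2% relative plus a 1e-3 1/cm
# additive floor.  All randomness is driven by an explicit seed; the
# session RNG state is saved and restored.

#' Logarithmic or linear Q grid
#'
#' @param qmin,qmax grid limits (1/A).
#' @param n number of points.
#' @param log logarithmic spacing (default TRUE).
#' @export
q_grid <- function(qmin = 0.004, qmax = 0.7, n = 200, log = TRUE) {
  stopifnot(qmin > 0, qmax > qmin, n >= 2)
  if (log) exp(seq(log(qmin), log(qmax), length.out = n))
  else seq(qmin, qmax, length.out = n)
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Evaluate a model intensity on a grid
#'
#' Generic over the model containers: [nanofiber_model()],
#' [beaucage_params()], or a plain function of `q`.
#' @param model model object.
#' @param q grid (1/A).
#' @param ... passed to the underlying evaluator.
#' @export
model_intensity <- function(model, q, ...) UseMethod("model_intensity")

#' @export
model_intensity.nanofiber_model <- function(model, q, ...)
  nanofiber_intensity(q, model, ...)

#' @export
model_intensity.beaucage_params <- function(model, q, ...)
  beaucage_intensity(q, model)

#' @export
model_intensity.function <- function(model, q, ...) model(q, ...)

#' Simulate a noisy scattering curve
#'
#' Evaluates the true model on the grid and adds Gaussian noise with
#' `sigma(q) = rel * I_true(q) + floor`; the sigma column stores the
#' generating sigma.  `noise_rel = 0` with `noise_floor = 0` returns the
#' exact model curve (sigma column then holds a nominal 1).
#'
#' @param model model object (see [model_intensity()]).
#' @param q grid (1/A), default [q_grid()].
#' @param noise_rel relative noise fraction (default 0.02).
#' @param noise_floor additive noise floor in 1/cm (default 1e-3).
#' @param seed integer seed; fixes the full output stream.
#' @param metadata extra metadata stored on the curve.
#' @return a [scattering_curve()]; the true curve is attached as
#'   `metadata$i_true`.
#' @export
simulate_curve <- function(model, q = q_grid(), noise_rel = 0.02,
                           noise_floor = 1e-3, seed = NULL,
                           metadata = list()) {
  stopifnot(noise_rel >= 0, noise_floor >= 0)
  i_true <- model_intensity(model, q)
  sig <- noise_rel * abs(i_true) + noise_floor
  noisy <- if (all(sig == 0)) i_true else
    .with_seed(seed, i_true + stats::rnorm(length(q), 0, sig))
  md <- utils::modifyList(list(seed = seed, noise_rel = noise_rel,
                               noise_floor = noise_floor), metadata)
  md$i_true <- i_true
  scattering_curve(q, noisy, ifelse(sig > 0, sig, 1), metadata = md)
}

#' Simulate a H2O/D2O contrast-variation series
#'
#' One SANS curve per solvent composition, sharing the fiber geometry.
#' Region SLDs are recomputed per contrast from the material compositions
#' (solvent-exchangeable hydrogens included), so at the PEG match point the
#' corona contributes nothing.
#'
#' @param f_d2o vector of D2O volume fractions.
#' @param geometry a [nanofiber_geometry()] (PEGylated if `d > 0`).
#' @param materials list with `core`, `shell` and (if `d > 0`) `peg`
#'   [material()] objects; defaults to the built-in K3 system with hPEG.
#' @param phi volume fraction.
#' @param rg_blob blob radius of gyration (A).
#' @param background flat background (1/cm), recycled per contrast.
#' @param m_pep peptide molar mass used to derive the aggregation number.
#' @param q,noise_rel,noise_floor,seed as in [simulate_curve()].
#' @return list of [scattering_curve()], one per contrast, each with
#'   `metadata$f_d2o` and its contrast set attached.
#' @export
simulate_contrast_series <- function(f_d2o, geometry,
                                     materials = NULL,
                                     phi = 0.008, rg_blob = 15,
                                     background = 0, m_pep = 2339,
                                     q = q_grid(), noise_rel = 0.02,
                                     noise_floor = 1e-3, seed = NULL) {
  stopifnot(all(f_d2o >= 0 & f_d2o <= 1), length(f_d2o) >= 1)
  if (is.null(materials)) {
    m <- k3_fiber_materials()
    materials <- list(core = m$core, shell = m$shell, peg = m$peg_h)
  }
  dq <- derive_fiber_quantities(geometry, materials$core$mass_density,
                                materials$shell$mass_density, m_pep)
  background <- rep_len(background, length(f_d2o))
  seeds <- if (is.null(seed)) rep(list(NULL), length(f_d2o))
           else as.list(seed + seq_along(f_d2o) - 1L)
  out <- vector("list", length(f_d2o))
  for (i in seq_along(f_d2o)) {
    f <- f_d2o[i]
    ct <- contrast_set(
      rho_core = neutron_sld(materials$core, f),
      rho_shell = neutron_sld(materials$shell, f),
      rho_peg = if (geometry$d > 0) neutron_sld(materials$peg, f) else
        solvent_sld(f),
      rho_solv = solvent_sld(f), radiation = "neutron")
    mod <- nanofiber_model(geometry, ct, phi = phi,
                           n_agg = max(1, dq$n_agg),
                           v_peg = if (geometry$d > 0) materials$peg$volume else 0,
                           rg_blob = rg_blob, background = background[i])
    out[[i]] <- simulate_curve(mod, q = q, noise_rel = noise_rel,
                               noise_floor = noise_floor, seed = seeds[[i]],
                               metadata = list(f_d2o = f,
                                               label = sprintf("f_D2O=%.2f", f),
                                               radiation = "neutron"))
    out[[i]]$metadata$contrasts <- ct
  }
  out
}

#' Molecular-exchange mechanism for ZAC kinetics
#'
#' Mean-field description of how the h-fraction of each fiber population's
#' PEG corona relaxes:
#' * `end_only`: only the `n_end` molecules at each fiber end are accessible;
#'   the accessible fraction `2 n_end / N_agg` mixes with rate `rate`, the
#'   interior never does, so the contrast decay saturates at a plateau.
#' * `uniform_unimer`: every molecule exchanges; single-exponential full
#'   relaxation.
#' * `breakup_reform`: fibers break and recombine; full relaxation (each
#'   breakup-reformation event randomises compositions).
#'
#' @param kind one of `"end_only"`, `"uniform_unimer"`, `"breakup_reform"`.
#' @param rate relaxation rate (1/time unit of the time grid).
#' @param n_end molecules accessible per fiber end (required for
#'   `end_only`; must satisfy `n_end <= n_agg / 2`).
#' @param n_agg molecules per fiber (required for `end_only`).
#' @export
exchange_mechanism <- function(kind = c("end_only", "uniform_unimer",
                                        "breakup_reform"),
                               rate, n_end = NULL, n_agg = NULL) {
  kind <- match.arg(kind)
  stopifnot(rate >= 0)
  if (kind == "end_only") {
    if (is.null(n_end) || is.null(n_agg))
      stop("end_only requires n_end and n_agg", call. = FALSE)
    if (n_end > n_agg / 2)
      stop("n_end must be <= n_agg / 2", call. = FALSE)
  }
  structure(list(kind = kind, rate = rate, n_end = n_end, n_agg = n_agg),
            class = "exchange_mechanism")
}

#' Population h-fraction under an exchange mechanism
#'
#' Returns the corona h-fraction `x1(t)` of the initially fully-hydrogenous
#' population (the deuterated population is `1 - x1` by molecule
#' conservation).
#' @param mechanism an [exchange_mechanism()].
#' @param times non-negative, sorted time vector.
#' @export
exchange_h_fraction <- function(mechanism, times) {
  stopifnot(inherits(mechanism, "exchange_mechanism"), all(times >= 0))
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  relax <- 1 - exp(-mechanism$rate * times)
  switch(mechanism$kind,
    end_only = {
      f_acc <- 2 * mechanism$n_end / mechanism$n_agg
      1 - (f_acc / 2) * relax
    },
    uniform_unimer = 0.5 + 0.5 * (1 - relax),
    breakup_reform = 0.5 + 0.5 * (1 - relax))
}

#' Simulate a time-resolved ZAC blend decay
#'
#' A 50/50 blend of h-PEG and d-PEG fiber populations in a solvent at the
#' zero-average-contrast composition.  As molecules exchange, each
#' population's corona SLD relaxes toward the isotopic mean and the excess
#' intensity decays; the `end_only` mechanism saturates above the fully
#' mixed baseline.  The relaxation function
#' `R(t) = sqrt((I(t) - I_inf) / (I(0) - I_inf))` (with `I_inf` the fully
#' mixed intensity) is attached to the result.
#'
#' @param geometry PEGylated [nanofiber_geometry()] (`d > 0`).
#' @param mechanism an [exchange_mechanism()].
#' @param times sorted time vector (same unit as `1 / rate`).
#' @param materials list with `core`, `shell`, `peg_h`, `peg_d` materials;
#'   defaults to the built-in K3 system.
#' @param f_d2o solvent composition; `NULL` solves the ZAC condition from
#'   the two conjugate compositions.
#' @param sequence peptide sequence for the conjugates (ZAC solve).
#' @param phi total fiber volume fraction.
#' @param rg_blob blob radius of gyration (A).
#' @param m_pep peptide molar mass (Da).
#' @param q,noise_rel,noise_floor,seed as in [simulate_curve()].
#' @return list with `curves` (one [scattering_curve()] per time),
#'   `relaxation` (data.frame of `time`, `x1`, `R`), and `f_d2o`.
#' @export
simulate_zac_decay <- function(geometry, mechanism, times,
                               materials = NULL, f_d2o = NULL,
                               sequence = k3_sequence(),
                               phi = 0.008, rg_blob = 15, m_pep = 2339,
                               q = q_grid(), noise_rel = 0, noise_floor = 0,
                               seed = NULL) {
  stopifnot(inherits(geometry, "nanofiber_geometry"), geometry$d > 0,
            all(times >= 0))
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  if (is.null(materials)) materials <- k3_fiber_materials()
  if (is.null(f_d2o)) {
    conj_h <- conjugate_composition(sequence, materials$peg_h)
    conj_d <- conjugate_composition(sequence, materials$peg_d)
    f_d2o <- zac_match_point(conj_h, conj_d)
  }
  rho_solv <- solvent_sld(f_d2o)
  rho_h <- neutron_sld(materials$peg_h, f_d2o)
  rho_d <- neutron_sld(materials$peg_d, f_d2o)
  rho_core <- neutron_sld(materials$core, f_d2o)
  rho_shell <- neutron_sld(materials$shell, f_d2o)
  dq <- derive_fiber_quantities(geometry, materials$core$mass_density,
                                materials$shell$mass_density, m_pep)
  v_peg <- (materials$peg_h$volume + materials$peg_d$volume) / 2
  x1 <- exchange_h_fraction(mechanism, times)
  blend_intensity <- function(x) {
    rho_pop <- c(x * rho_h + (1 - x) * rho_d,       # initially-h population
                 (1 - x) * rho_h + x * rho_d)       # initially-d population
    vals <- lapply(rho_pop, function(rp) {
      ct <- contrast_set(rho_core, rho_shell, rp, rho_solv, "neutron")
      mod <- nanofiber_model(geometry, ct, phi = phi / 2,
                             n_agg = max(1, dq$n_agg), v_peg = v_peg,
                             rg_blob = rg_blob, background = 0)
      nanofiber_intensity(q, mod)
    })
    vals[[1]] + vals[[2]]
  }
  i_inf <- blend_intensity(0.5)
  seeds <- if (is.null(seed)) rep(list(NULL), length(times))
           else as.list(seed + seq_along(times) - 1L)
  curves <- vector("list", length(times))
  excess <- numeric(length(times))
  for (i in seq_along(times)) {
    i_t <- blend_intensity(x1[i])
    excess[i] <- sum(i_t - i_inf)
    sig <- noise_rel * abs(i_t) + noise_floor
    noisy <- if (all(sig == 0)) i_t else
      .with_seed(seeds[[i]], i_t + stats::rnorm(length(q), 0, sig))
    curves[[i]] <- scattering_curve(
      q, noisy, ifelse(sig > 0, sig, 1),
      metadata = list(time = times[i], f_d2o = f_d2o, radiation = "neutron",
                      label = sprintf("t=%g", times[i]), i_true = i_t))
  }
  r_t <- if (excess[1] > 0) sqrt(pmax(excess, 0) / excess[1]) else
    rep(NA_real_, length(times))
  list(curves = curves,
       relaxation = data.frame(time = times, x1 = x1, R = r_t),
       f_d2o = f_d2o)
}
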