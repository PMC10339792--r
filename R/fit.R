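# Simultaneous weighted least-squares refinement of one structural model
# against multiple datasets (SAXS + SANS, multi-contrast) with shared
# parameters.
#
# Parameters live in a flat table: shared structural parameters (geometry,
# phi, rg_blob, ...) plus optional per-dataset nuisance scale and background.
# The optimiser is a bounded Levenberg-Marquardt trust region (minpack.lm)
# with seeded multi-start, because the cross-section oscillations create
# local minima.

.nanofiber_par_names <- c("a_core", "a_shell", "b_core", "b_shell", "c", "d",
                          "phi", "rg_blob", "v_peg")
.beaucage_par_names <- c("G", "rg", "df")

#' Define a simultaneous fit problem
#'
#' @param datasets list of [scattering_curve()].  For the `"nanofiber"`
#'   model each curve must carry a `metadata$contrasts` [contrast_set()].
#' @param model `"nanofiber"` or `"beaucage"`.
#' @param start named vector of shared-parameter start values.  Nanofiber
#'   parameters: `a_core`, `a_shell`, `b_core`, `b_shell`, `c`, `d`, `phi`,
#'   `rg_blob`, `v_peg`; Beaucage: `G`, `rg`, `df`.
#' @param free character vector naming the free shared parameters.
#' @param lower,upper named bound vectors for the free parameters (defaults:
#'   positive lengths, `phi` in (0,1)).
#' @param scale per-dataset multiplicative scale start values (default 1;
#'   SANS absolute-calibration drift).
#' @param background per-dataset flat background start values (default 0).
#' @param free_scale,free_background logical vectors (recycled) marking
#'   which per-dataset nuisances float.
#' @param m_pep,d_core,d_shell when supplied, the aggregation number for the
#'   blob term and the derived structural quantities are recomputed from the
#'   current geometry at every evaluation.
#' @param n_alpha fixed quadrature order used during fitting (default 256;
#'   adaptivity is re-enabled for the final evaluation).
#' @export
fit_problem <- function(datasets, model = c("nanofiber", "beaucage"),
                        start, free = names(start),
                        lower = NULL, upper = NULL,
                        scale = 1, background = 0,
                        free_scale = FALSE, free_background = FALSE,
                        m_pep = NULL, d_core = NULL, d_shell = NULL,
                        n_alpha = 256) {
  model <- match.arg(model)
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, logical(1), "scattering_curve")))
  known <- switch(model, nanofiber = .nanofiber_par_names,
                  beaucage = .beaucage_par_names)
  bad <- setdiff(names(start), known)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!all(free %in% names(start)))
    stop("free parameters must appear in start", call. = FALSE)
  if (model == "nanofiber") {
    need <- setdiff(c("a_core", "a_shell", "b_core", "b_shell", "c", "phi"),
                    names(start))
    if (length(need)) stop("missing start value(s): ",
                           paste(need, collapse = ", "), call. = FALSE)
    for (d in datasets)
      if (!inherits(d$metadata$contrasts, "contrast_set"))
        stop("each dataset needs metadata$contrasts for the nanofiber model",
             call. = FALSE)
  }
  nd <- length(datasets)
  par <- data.frame(
    name = c(names(start),
             paste0("scale.", seq_len(nd)), paste0("background.", seq_len(nd))),
    value = c(unname(start), rep_len(scale, nd), rep_len(background, nd)),
    free = c(names(start) %in% free,
             rep_len(free_scale, nd), rep_len(free_background, nd)),
    stringsAsFactors = FALSE)
  default_bounds <- function(nm) {
    base <- sub("\\.[0-9]+$", "", nm)
    lo <- switch(base, phi = 1e-8, d = 0, background = 0, df = 1,
                 scale = 1e-3, v_peg = 0, 1e-3)
    hi <- switch(base, phi = 1 - 1e-8, df = 4, Inf)
    c(lo, hi)
  }
  par$lower <- vapply(par$name, function(n)
    if (!is.null(lower) && n %in% names(lower)) lower[[n]]
    else default_bounds(n)[1], numeric(1))
  par$upper <- vapply(par$name, function(n)
    if (!is.null(upper) && n %in% names(upper)) upper[[n]]
    else default_bounds(n)[2], numeric(1))
  structure(list(datasets = datasets, model = model, par = par,
                 m_pep = m_pep, d_core = d_core, d_shell = d_shell,
                 n_alpha = n_alpha),
            class = "fit_problem")
}

.problem_values <- function(problem, free_values = NULL) {
  v <- stats::setNames(problem$par$value, problem$par$name)
  if (!is.null(free_values))
    v[problem$par$name[problem$par$free]] <- free_values
  v
}

.eval_dataset <- function(problem, values, i, adaptive = FALSE) {
  ds <- problem$datasets[[i]]
  scale <- values[[paste0("scale.", i)]]
  bkg <- values[[paste0("background.", i)]]
  if (problem$model == "beaucage") {
    p <- beaucage_params(G = values[["G"]], rg = values[["rg"]],
                         df = if ("df" %in% names(values)) values[["df"]] else 2,
                         background = 0)
    return(scale * beaucage_intensity(ds$q, p) + bkg)
  }
  d <- if ("d" %in% names(values)) values[["d"]] else 0
  geom <- nanofiber_geometry(values[["a_core"]], values[["a_shell"]],
                             values[["b_core"]], values[["b_shell"]],
                             values[["c"]], d, warn_decoupling = FALSE)
  n_agg <- 1
  if (!is.null(problem$m_pep) && !is.null(problem$d_core))
    n_agg <- max(1, derive_fiber_quantities(geom, problem$d_core,
                                            problem$d_shell,
                                            problem$m_pep)$n_agg)
  mod <- nanofiber_model(
    geom, ds$metadata$contrasts, phi = values[["phi"]], n_agg = n_agg,
    v_peg = if ("v_peg" %in% names(values)) values[["v_peg"]] else 0,
    rg_blob = if ("rg_blob" %in% names(values)) values[["rg_blob"]] else 15,
    background = 0)
  scale * nanofiber_intensity(ds$q, mod, n_alpha = problem$n_alpha,
                              adaptive = adaptive) + bkg
}

#' Weighted residual vector of a fit problem
#'
#' Concatenates `(I_model - I_data) / sigma` across datasets, evaluating the
#' model with each dataset's own contrasts and nuisance parameters.
#'
#' @param problem a [fit_problem()].
#' @param free_values values for the free parameters, in
#'   `problem$par$name[problem$par$free]` order (default: stored values).
#' @return residual vector.
#' @export
objective <- function(problem, free_values = NULL) {
  stopifnot(inherits(problem, "fit_problem"))
  values <- .problem_values(problem, free_values)
  res <- lapply(seq_along(problem$datasets), function(i) {
    ds <- problem$datasets[[i]]
    mod <- tryCatch(.eval_dataset(problem, values, i), error = function(e)
      stop("model evaluation failed for dataset ", i, ": ",
           conditionMessage(e), call. = FALSE))
    (mod - ds$intensity) / ds$sigma
  })
  unlist(res, use.names = FALSE)
}

#' Fit a problem by bounded Levenberg-Marquardt with multi-start
#'
#' Deterministic given `seed` and the stored start values.  Additional
#' starts perturb the free parameters multiplicatively (uniform in
#' `[1 - spread, 1 + spread]`, clipped to bounds); the best local optimum
#' wins.  Uncertainties are covariance-based (J'J scaled by the reduced
#' chi-square).  With zero free parameters the input is returned as the
#' best fit together with its chi-square.
#'
#' @param problem a [fit_problem()].
#' @param seed integer seed for the multi-start draws.
#' @param n_starts number of starts (default 8).
#' @param spread relative start perturbation (default 0.3).
#' @param maxiter maximum LM iterations per start.
#' @return object of class `fit_result`: best-fit values, 1-sigma
#'   uncertainties, per-dataset and global reduced chi-square, convergence
#'   diagnostics, and (when densities and `m_pep` were supplied) derived
#'   fiber quantities recomputed from the best-fit geometry.
#' @export
fit <- function(problem, seed = NULL, n_starts = 8, spread = 0.3,
                maxiter = 200) {
  stopifnot(inherits(problem, "fit_problem"))
  free_idx <- which(problem$par$free)
  n_obs <- sum(vapply(problem$datasets, function(d) length(d$q), integer(1)))
  chisq_parts <- function(values) {
    vapply(seq_along(problem$datasets), function(i) {
      ds <- problem$datasets[[i]]
      sum(((.eval_dataset(problem, values, i) - ds$intensity) / ds$sigma)^2)
    }, numeric(1))
  }
  if (!length(free_idx)) {
    values <- .problem_values(problem)
    parts <- chisq_parts(values)
    return(structure(list(
      problem = problem, values = values, uncertainties = NULL,
      chisq = sum(parts), chisq_dataset = parts,
      chisq_reduced = sum(parts) / n_obs, n_obs = n_obs, n_free = 0,
      converged = TRUE, message = "no free parameters; evaluation only",
      derived = .fit_derived(problem, values)), class = "fit_result"))
  }
  p0 <- problem$par$value[free_idx]
  lo <- problem$par$lower[free_idx]
  hi <- problem$par$upper[free_idx]
  starts <- .with_seed(seed, {
    s <- list(p0)
    if (n_starts > 1)
      for (k in seq_len(n_starts - 1))
        s[[k + 1]] <- pmin(pmax(p0 * stats::runif(length(p0), 1 - spread,
                                                  1 + spread), lo), hi)
    s
  })
  best <- NULL
  diag_msgs <- character(0)
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lo, upper = hi,
                         fn = function(p) objective(problem, p),
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) e)
    if (inherits(res, "error")) { diag_msgs <- c(diag_msgs, conditionMessage(res)); next }
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    stop("no start converged; diagnostics: ",
         paste(unique(diag_msgs), collapse = "; "), call. = FALSE)
  values <- .problem_values(problem, best$par)
  parts <- chisq_parts(values)
  dof <- max(1, n_obs - length(free_idx))
  unc <- rep(NA_real_, length(free_idx))
  h <- tryCatch(solve(best$hessian), error = function(e) NULL)
  if (!is.null(h)) {
    # nls.lm's hessian is J'J; covariance = (J'J)^-1 * deviance / dof
    dg <- diag(h) * best$deviance / dof
    unc <- sqrt(pmax(dg, 0))
  }
  converged <- best$info %in% 1:4
  structure(list(
    problem = problem,
    values = values,
    free_names = problem$par$name[free_idx],
    uncertainties = stats::setNames(unc, problem$par$name[free_idx]),
    chisq = sum(parts), chisq_dataset = parts,
    chisq_reduced = sum(parts) / dof, n_obs = n_obs,
    n_free = length(free_idx), converged = converged,
    info = best$info, message = best$message, niter = best$niter,
    derived = .fit_derived(problem, values)), class = "fit_result")
}

.fit_derived <- function(problem, values) {
  if (problem$model != "nanofiber" || is.null(problem$m_pep) ||
      is.null(problem$d_core)) return(NULL)
  geom <- nanofiber_geometry(values[["a_core"]], values[["a_shell"]],
                             values[["b_core"]], values[["b_shell"]],
                             values[["c"]],
                             if ("d" %in% names(values)) values[["d"]] else 0,
                             warn_decoupling = FALSE)
  derive_fiber_quantities(geom, problem$d_core, problem$d_shell,
                          problem$m_pep)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$problem$model, "model,",
      length(x$problem$datasets), "dataset(s)\n")
  cat(sprintf("  chi^2 = %.4g (reduced %.4g), converged: %s\n",
              x$chisq, x$chisq_reduced, x$converged))
  if (x$n_free > 0) {
    for (nm in x$free_names) {
      u <- x$uncertainties[[nm]]
      cat(sprintf("  %-12s = %.5g%s\n", nm, x$values[[nm]],
                  if (is.finite(u)) sprintf(" +/- %.2g", u) else ""))
    }
  }
  if (!is.null(x$derived))
    cat(sprintf("  derived: N_agg = %.1f, M_core = %.0f Da, M_shell = %.0f Da\n",
                x$derived$n_agg, x$derived$m_core, x$derived$m_shell))
  invisible(x)
}
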