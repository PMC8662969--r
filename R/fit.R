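# Co-refinement of reflectivity curves against one structural model by
# differential evolution, with inequality constraints and per-curve
# multi-parameters.

.PENALTY <- 1e30

.settings_list <- function(settings, M) {
  if (inherits(settings, "refl_instrument"))
    return(rep(list(settings), M))
  if (is.list(settings) && length(settings) == M &&
      all(vapply(settings, inherits, logical(1), "refl_instrument")))
    return(settings)
  stop("'settings' must be an instrument() or a list of one per curve",
       call. = FALSE)
}

# forward model machinery shared by fitting, uncertainty and prediction.
# Returns closures operating on a full named values list (multi-parameters
# as length-M vectors).
.make_forward <- function(model, curves, settings) {
  resolver <- .compile_system(model)
  M <- length(curves)
  function(values) {
    out <- vector("list", M)
    for (i in seq_len(M)) {
      vals <- .values_for_curve(values, i)
      resolved <- resolver(vals)
      if (inherits(resolved, "refl_violation")) return(NULL)
      f <- .reflectivity_fun(resolved)
      cv <- curves[[i]]
      R <- smear(cv$Q, f, settings[[i]], cv$dQ)
      R <- tryCatch(
        finalize_reflectivity(R, settings[[i]], vals, 1L),
        error = function(e) NULL)
      if (is.null(R) || any(!is.finite(R))) return(NULL)
      out[[i]] <- R
    }
    out
  }
}

.make_objective <- function(model, layout, constraints, curves, settings,
                            fom_mode, weights) {
  forward <- .make_forward(model, curves, settings)
  check <- .compile_constraints(constraints)
  M <- length(curves)
  obj <- function(x) {
    values <- .layout_values(layout, x)
    for (i in seq_len(M))
      if (!isTRUE(tryCatch(check(.values_for_curve(values, i)),
                           error = function(e) FALSE)))
        return(.PENALTY)
    models <- forward(values)
    if (is.null(models)) return(.PENALTY)
    fom <- compute_fom(curves, models, fom_mode, weights, quiet = TRUE)
    if (!is.finite(fom)) return(.PENALTY)
    fom + .layout_penalty(layout, x)
  }
  # pure-data reduced chi-squared over the free parameters (no priors)
  chi2_red <- function(x) {
    values <- .layout_values(layout, x)
    models <- forward(values)
    if (is.null(models)) return(.PENALTY)
    st <- .chi2_stat(curves, models)
    if (is.null(st)) return(NA_real_)
    st$chi2 / max(st$n - layout$n_free, 1L)
  }
  list(obj = obj, chi2_red = chi2_red, forward = forward)
}

#' Refine a reflectivity model against one or more curves
#'
#' Fits the free parameters of an interfacial model to `M` co-refined
#' reflectivity curves by minimising one of four figures of merit with a
#' rand/1/bin differential-evolution search.  Candidates that violate an
#' inequality constraint, produce a solvent fraction outside `[0, 1]`, a
#' negative thickness/roughness, or a non-finite reflectivity receive a
#' large penalty (never `NaN`).  Normally declared parameters are searched
#' within `mean +/- 5 sd` and add a Gaussian penalty `((x - mean)/sd)^2` to
#' the objective.  Deterministic for a fixed `seed`.
#'
#' @param model a [system_model()].
#' @param parameters a [parameter_set()] declaring every symbol used in
#'   the model, constraints and instrument entries.
#' @param curves a [refl_curve()] or list of them (co-refinement).
#' @param constraints character vector of inequality constraints.
#' @param settings an [instrument()] or a list of one per curve; symbolic
#'   `scale`/`background` entries may reference (multi-)parameters.
#' @param fom figure-of-merit mode (see [compute_fom()]); `"auto"` picks
#'   `"log_err"` when every curve carries `dR` and `"log_noerr"` otherwise.
#'   An error-weighted mode requested without `dR` falls back to its
#'   no-error counterpart with a warning.
#' @param weights optional per-curve weights (default: curve `fit_weight`s).
#' @param uncertainty `"none"`, `"hessian"`, `"bootstrap"` or `"mcmc"`;
#'   post-fit parameter-uncertainty estimation (see [hessian_uncertainty()],
#'   [bootstrap_fit()], [mcmc_fit()]).
#' @param seed RNG seed recorded in the result (default 1234).
#' @param popsize,F,CR,maxiter,reltol differential-evolution settings
#'   (population `popsize` per dimension, weight `F`, crossover `CR`).
#' @param trace record every accepted candidate (see [de_minimize()]).
#' @param uncertainty_options list of extra arguments for the chosen
#'   uncertainty method (e.g. `K`, `walkers`).
#' @return an object of class `refl_fit` with methods `print`, `summary`,
#'   `coef`, `vcov`, `predict`, `fitted`, `residuals`, `plot`, `simulate`
#'   and `confint`.
#' @export
refl_fit <- function(model, parameters, curves, constraints = character(),
                     settings = instrument(), fom = "auto", weights = NULL,
                     uncertainty = c("none", "hessian", "bootstrap", "mcmc"),
                     seed = 1234, popsize = 15, F = 0.7, CR = 0.9,
                     maxiter = 2000, reltol = 1e-8, trace = FALSE,
                     uncertainty_options = list()) {
  uncertainty <- match.arg(uncertainty)
  if (inherits(curves, "refl_curve")) curves <- list(curves)
  if (!length(curves) ||
      !all(vapply(curves, inherits, logical(1), "refl_curve")))
    stop("'curves' must be refl_curve objects", call. = FALSE)
  M <- length(curves)
  settings <- .settings_list(settings, M)
  layout <- .par_layout(parameters, M)
  if (layout$n_free == 0L)
    stop("no free parameters to fit", call. = FALSE)
  has_dR <- all(vapply(curves, function(cv) !is.null(cv$dR), logical(1)))
  if (identical(fom, "auto")) {
    fom <- if (has_dR) "log_err" else "log_noerr"
  } else {
    fom <- match.arg(fom, .fom_modes)
    if (fom %in% c("linear_err", "log_err") && !has_dR) {
      fom <- sub("_err$", "_noerr", fom)
      warning("dR missing on at least one curve; falling back to FOM '",
              fom, "'", call. = FALSE)
    }
  }
  if (is.null(weights))
    weights <- vapply(curves, `[[`, numeric(1), "fit_weight")

  mk <- .make_objective(model, layout, constraints, curves, settings, fom,
                        weights)
  tab <- layout$table
  free <- which(!tab$fixed)
  lower <- tab$lower[free]
  upper <- tab$upper[free]
  de <- de_minimize(mk$obj, lower, upper, seed = seed, popsize = popsize,
                    F = F, CR = CR, maxiter = maxiter, reltol = reltol,
                    init = rbind(.layout_start(layout)), trace = trace)
  best <- stats::setNames(de$par, layout$free_names)
  values <- .layout_values(layout, de$par)
  models <- mk$forward(values)
  if (is.null(models))
    stop("best candidate fails the forward model; widen the bounds",
         call. = FALSE)
  per_curve_model <- lapply(seq_len(M), function(i)
    data.frame(Q = curves[[i]]$Q, R = models[[i]]))
  st <- .chi2_stat(curves, models)
  chi2_red <- if (is.null(st)) NULL else
    st$chi2 / max(st$n - layout$n_free, 1L)

  out <- structure(list(
    best = best, sd = NULL, lower = lower, upper = upper,
    fom = de$value - .layout_penalty(layout, de$par), fom_mode = fom,
    chi2_red = chi2_red, n_free = layout$n_free,
    model = model, parameters = parameters, layout = layout,
    constraints = as.character(constraints), curves = curves,
    settings = settings, weights = weights, values = values,
    per_curve_model = per_curve_model,
    seed = seed, iterations = de$iter, converged = de$converged,
    nfev = de$nfev, accepted = de$accepted,
    objective = mk$obj, chi2_red_fn = mk$chi2_red, forward = mk$forward,
    uncertainty = NULL, call = match.call()),
    class = "refl_fit")

  if (uncertainty != "none") {
    unc <- switch(uncertainty,
      hessian = do.call(hessian_uncertainty, c(list(out),
                                               uncertainty_options)),
      bootstrap = do.call(bootstrap_fit, c(list(out), uncertainty_options)),
      mcmc = do.call(mcmc_fit, c(list(out), uncertainty_options)))
    out$uncertainty <- unc
    out$sd <- unc$sd
  }
  out
}

#' Compare a fixed model with data
#'
#' Forward-calculates a model (no refinement) on each curve's grid and
#' reports the figure of merit and reduced chi-squared.
#'
#' @param model a [system_model()].
#' @param values named parameter values (length-M entries =
#'   multi-parameters).
#' @param curves a [refl_curve()] or list of them.
#' @param settings an [instrument()] or list of one per curve.
#' @param fom figure-of-merit mode.
#' @param weights optional per-curve weights.
#' @return list with `fom`, `chi2_red` (NULL without `dR`) and
#'   `per_curve_model` (data frames of Q, R_model).
#' @export
refl_compare <- function(model, values, curves, settings = instrument(),
                         fom = "log_err", weights = NULL) {
  if (inherits(curves, "refl_curve")) curves <- list(curves)
  M <- length(curves)
  settings <- .settings_list(settings, M)
  has_dR <- all(vapply(curves, function(cv) !is.null(cv$dR), logical(1)))
  fom <- match.arg(fom, .fom_modes)
  if (fom %in% c("linear_err", "log_err") && !has_dR) {
    fom <- sub("_err$", "_noerr", fom)
    warning("dR missing; falling back to FOM '", fom, "'", call. = FALSE)
  }
  forward <- .make_forward(model, curves, settings)
  models <- forward(values)
  if (is.null(models))
    stop("model could not be evaluated (unphysical resolved values?)",
         call. = FALSE)
  st <- .chi2_stat(curves, models)
  list(fom = compute_fom(curves, models, fom, weights),
       chi2_red = if (is.null(st)) NULL else st$chi2 / st$n,
       per_curve_model = lapply(seq_len(M), function(i)
         data.frame(Q = curves[[i]]$Q, R = models[[i]])))
}
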