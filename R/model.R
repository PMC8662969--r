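# Hierarchical interfacial model: patches -> layers -> entries.
# An entry is either a finite numeric scalar or a character string holding a
# mathematical expression in declared parameter names and the reserved
# layer-index symbol `n` (0 = fronting).

# whitelist of callables allowed inside model/constraint expressions
.expr_fns <- c("+", "-", "*", "/", "^", "(",
               "sin", "cos", "tan", "asin", "acos", "atan", "atan2",
               "exp", "log", "log10", "sqrt", "abs",
               "min", "max", "pmin", "pmax", "erf",
               "<", ">", "<=", ">=", "==", "!=", "&", "|")

#' Error function
#'
#' `erf(x) = 2*pnorm(x*sqrt(2)) - 1`; available inside model expressions.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# parse a character entry and validate that only whitelisted functions occur
.parse_entry <- function(entry) {
  ex <- tryCatch(parse(text = entry, keep.source = FALSE)[[1]],
                 error = function(e) stop("malformed model expression '", entry,
                                          "': ", conditionMessage(e), call. = FALSE))
  fns <- setdiff(all.names(ex), all.vars(ex))
  bad <- setdiff(fns, .expr_fns)
  if (length(bad))
    stop("function(s) not permitted in model expressions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  ex
}

# evaluation environment containing only whitelisted functions
.make_math_env <- function() {
  e <- new.env(parent = emptyenv())
  for (f in setdiff(.expr_fns, "erf"))
    assign(f, get(f, envir = baseenv()), envir = e)
  assign("erf", erf, envir = e)
  e
}

# pick the curve-specific value of each parameter: scalar entries apply to all
# curves, length-M entries are multi-parameters indexed by curve.
.values_for_curve <- function(values, curve_index) {
  if (is.null(values) || length(values) == 0L) return(list())
  if (!is.list(values)) values <- as.list(values)
  nm <- names(values)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("'values' must be a fully named list or vector", call. = FALSE)
  out <- lapply(values, function(v) {
    if (length(v) == 1L) return(as.numeric(v))
    if (curve_index < 1L || curve_index > length(v))
      stop("curve_index ", curve_index, " outside the ", length(v),
           " declared per-curve values of a multi-parameter", call. = FALSE)
    as.numeric(v[[curve_index]])
  })
  names(out) <- nm
  out
}

#' Evaluate a single model entry
#'
#' Model entries (sld, thickness, roughness, solvent fraction) may be numeric
#' or symbolic expressions in declared parameter names and the layer-index
#' symbol `n`.  This evaluates one entry for a given parameter map.
#'
#' @param entry numeric scalar or character expression.
#' @param params named list/vector of parameter values.
#' @param layer_index integer, bound to the symbol `n` (0 = fronting).
#' @return numeric scalar.
#' @examples
#' evaluate_entry(3.0)
#' evaluate_entry("1 - (4*A/D^2)*(D*z - z^2)",
#'                params = c(A = 0.91, D = 150, z = 74.25))
#' @export
evaluate_entry <- function(entry, params = list(), layer_index = 0L) {
  if (is.numeric(entry)) {
    if (length(entry) != 1L || !is.finite(entry))
      stop("numeric model entries must be finite scalars", call. = FALSE)
    return(as.numeric(entry))
  }
  if (!is.character(entry) || length(entry) != 1L)
    stop("a model entry must be a numeric scalar or a character expression",
         call. = FALSE)
  ex <- .parse_entry(entry)
  vars <- all.vars(ex)
  known <- c(names(params), "n")
  bad <- setdiff(vars, known)
  if (length(bad))
    stop("undeclared symbol(s) in model expression '", entry, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  env <- .make_math_env()
  if (length(params)) {
    p <- as.list(params)
    for (k in seq_along(p)) assign(names(p)[k], as.numeric(p[[k]]), envir = env)
  }
  assign("n", as.numeric(layer_index), envir = env)
  val <- eval(ex, envir = env)
  if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
    stop("model expression '", entry, "' did not evaluate to a finite scalar",
         " at layer index ", layer_index, call. = FALSE)
  as.numeric(val)
}

.check_entry <- function(x, what) {
  if (is.numeric(x)) {
    if (length(x) != 1L || !is.finite(x))
      stop("layer field '", what, "' must be a finite numeric scalar or an",
           " expression string", call. = FALSE)
  } else if (is.character(x) && length(x) == 1L) {
    .parse_entry(x)  # syntax + whitelist check at construction time
  } else {
    stop("layer field '", what, "' must be numeric or a single character",
         " expression", call. = FALSE)
  }
  x
}

#' Define a layer (slab)
#'
#' A layer is the six-element record (real sld, imaginary sld, thickness,
#' roughness, solvent volume fraction, description).  All numeric fields may
#' instead be character expressions in declared parameters and the layer index
#' `n`.  Units: sld in 1/Angstrom^2, thickness and roughness in Angstrom.
#' The roughness of layer *i* is that of the interface between layers *i* and
#' *i + 1*.  `isld >= 0` means absorption.
#'
#' @param sld real part of the scattering length density.
#' @param isld imaginary part (absorption), non-negative.
#' @param thickness layer thickness; ignored for the fronting/backing media.
#' @param roughness interfacial roughness to the next layer.
#' @param solvent solvent volume fraction in `[0, 1]` after resolution.
#' @param name free-text description.
#' @return an object of class `refl_layer`.
#' @examples
#' layer(sld = 2.07e-6, thickness = 0, roughness = 3, name = "Si")
#' @export
layer <- function(sld = 0, isld = 0, thickness = 0, roughness = 0,
                  solvent = 0, name = "") {
  structure(list(sld = .check_entry(sld, "sld"),
                 isld = .check_entry(isld, "isld"),
                 thickness = .check_entry(thickness, "thickness"),
                 roughness = .check_entry(roughness, "roughness"),
                 solvent = .check_entry(solvent, "solvent"),
                 name = as.character(name)),
            class = "refl_layer")
}

#' Define a patch (laterally coherent layer stack)
#'
#' Patches contribute incoherently to the total reflectivity, weighted by
#' surface coverage.  The first layer is the semi-infinite fronting medium and
#' the last the semi-infinite backing medium; their thickness entries are
#' stored but ignored.
#'
#' @param layers list of [layer()] objects (at least fronting + backing).
#' @param coverage surface coverage in `[0, 1]`.
#' @param solvent_from which medium provides the solvent sld used when mixing
#'   solvent into partially hydrated layers: the backing medium (default,
#'   solid/liquid geometry) or the fronting medium (air/liquid geometry).
#' @return an object of class `refl_patch`.
#' @export
patch <- function(layers, coverage = 1,
                  solvent_from = c("backing", "fronting")) {
  solvent_from <- match.arg(solvent_from)
  if (inherits(layers, "refl_layer")) layers <- list(layers)
  if (!is.list(layers) || length(layers) < 2L ||
      !all(vapply(layers, inherits, logical(1), "refl_layer")))
    stop("'layers' must be a list of at least 2 layer() objects",
         " (fronting and backing)", call. = FALSE)
  if (!is.numeric(coverage) || length(coverage) != 1L ||
      coverage < 0 || coverage > 1)
    stop("'coverage' must be a single value in [0, 1]", call. = FALSE)
  for (i in c(1L, length(layers))) {
    th <- layers[[i]]$thickness
    if (is.numeric(th) && th != 0)
      message("note: thickness of the semi-infinite ",
              if (i == 1L) "fronting" else "backing",
              " medium is ignored in calculations")
  }
  structure(list(layers = layers, coverage = coverage,
                 solvent_from = solvent_from),
            class = "refl_patch")
}

#' Define an interfacial system model
#'
#' A system model is a list of patches whose coverages sum to one; their
#' reflectivities add incoherently.
#'
#' @param ... [patch()] objects (or a single list of them).
#' @return an object of class `refl_model`.
#' @examples
#' m <- system_model(patch(list(
#'   layer(0, name = "air"),
#'   layer(5.9e-5, thickness = 40, roughness = 3, name = "Fe"),
#'   layer(2.01e-5, roughness = 3, name = "Si")), coverage = 1))
#' @export
system_model <- function(...) {
  patches <- list(...)
  if (length(patches) == 1L && is.list(patches[[1]]) &&
      !inherits(patches[[1]], "refl_patch"))
    patches <- patches[[1]]
  if (!length(patches) ||
      !all(vapply(patches, inherits, logical(1), "refl_patch")))
    stop("system_model() takes one or more patch() objects", call. = FALSE)
  cov <- vapply(patches, `[[`, numeric(1), "coverage")
  if (abs(sum(cov) - 1) > 1e-9)
    stop("patch coverages must sum to 1 (got ", format(sum(cov)), ")",
         call. = FALSE)
  structure(list(patches = patches), class = "refl_model")
}

#' @export
print.refl_model <- function(x, ...) {
  cat("Interfacial model:", length(x$patches), "patch(es)\n")
  for (p in seq_along(x$patches)) {
    pa <- x$patches[[p]]
    cat(sprintf("  patch %d  coverage %.3f  (%d layers, solvent from %s)\n",
                p, pa$coverage, length(pa$layers), pa$solvent_from))
    for (i in seq_along(pa$layers)) {
      la <- pa$layers[[i]]
      fmt <- function(v) if (is.numeric(v)) format(v, digits = 6) else
        paste0("<", v, ">")
      cat(sprintf("    [%d] sld=%s isld=%s t=%s sigma=%s phi=%s %s\n", i - 1L,
                  fmt(la$sld), fmt(la$isld), fmt(la$thickness),
                  fmt(la$roughness), fmt(la$solvent), la$name))
    }
  }
  invisible(x)
}

# ---- resolution to numeric profiles ----------------------------------------

.FIELDS <- c("sld", "isld", "thickness", "roughness", "solvent")

# sentinel for unphysical candidates met during fitting
.violation <- function(msg)
  structure(list(message = msg), class = "refl_violation")

#' @export
print.refl_violation <- function(x, ...) {
  cat("model violation:", x$message, "\n")
  invisible(x)
}

# Validate a numeric resolved patch; returns NULL if fine, else a message.
.validate_resolved <- function(df, patch_id) {
  nl <- nrow(df)
  interior <- if (nl > 2L) 2:(nl - 1L) else integer(0)
  if (length(interior) && any(df$thickness[interior] < 0))
    return(sprintf("negative thickness in patch %d, layer(s) %s", patch_id,
                   paste(interior[df$thickness[interior] < 0] - 1L,
                         collapse = ", ")))
  if (any(df$roughness[-nl] < 0))
    return(sprintf("negative roughness in patch %d", patch_id))
  tol <- 1e-9
  bad <- which(df$solvent < -tol | df$solvent > 1 + tol)
  if (length(bad))
    return(sprintf("solvent fraction outside [0, 1] in patch %d, layer(s) %s",
                   patch_id, paste(bad - 1L, collapse = ", ")))
  NULL
}

#' Resolve a model to numeric layer profiles
#'
#' Substitutes parameter values (selecting per-curve values of
#' multi-parameters) into every symbolic entry and returns numeric per-patch
#' profiles.  Solvent mixing is *not* applied here; the reflectivity engine
#' does that.
#'
#' @param model a [system_model()].
#' @param values named list/vector of parameter values; an entry of length
#'   `M > 1` is treated as a multi-parameter and indexed by `curve_index`.
#' @param curve_index index of the curve being calculated (for
#'   multi-parameters).
#' @param on_violation `"error"` to stop on unphysical resolved values
#'   (negative thickness/roughness, solvent fraction outside `[0, 1]`),
#'   `"flag"` to return a `refl_violation` object carrying the message
#'   (used to penalise candidates during fitting).
#' @return list of data frames (one per patch) with columns
#'   `sld`, `isld`, `thickness`, `roughness`, `solvent`, `name`, and an
#'   attribute `"coverages"`.
#' @export
resolve_system <- function(model, values = list(), curve_index = 1L,
                           on_violation = c("error", "flag")) {
  on_violation <- match.arg(on_violation)
  stopifnot(inherits(model, "refl_model"))
  vals <- .values_for_curve(values, curve_index)
  out <- vector("list", length(model$patches))
  for (p in seq_along(model$patches)) {
    pa <- model$patches[[p]]
    nl <- length(pa$layers)
    m <- matrix(NA_real_, nl, length(.FIELDS),
                dimnames = list(NULL, .FIELDS))
    for (i in seq_len(nl)) {
      la <- pa$layers[[i]]
      for (f in .FIELDS) {
        v <- tryCatch(evaluate_entry(la[[f]], vals, layer_index = i - 1L),
                      error = function(e) e)
        if (inherits(v, "error")) {
          if (on_violation == "flag")
            return(.violation(conditionMessage(v)))
          stop(conditionMessage(v), call. = FALSE)
        }
        m[i, f] <- v
      }
    }
    df <- as.data.frame(m)
    df$solvent <- pmin(pmax(df$solvent, 0), 1)  # clamp numeric fuzz only
    df$solvent[c(1L, nl)] <- 0                  # media are not hydrated
    df$name <- vapply(pa$layers, `[[`, character(1), "name")
    msg <- .validate_resolved(as.data.frame(m), p)
    if (!is.null(msg)) {
      if (on_violation == "flag") return(.violation(msg))
      stop(msg, call. = FALSE)
    }
    out[[p]] <- df
  }
  attr(out, "coverages") <- vapply(model$patches, `[[`, numeric(1), "coverage")
  attr(out, "solvent_from") <-
    vapply(model$patches, `[[`, character(1), "solvent_from")
  out
}

#' Check inequality constraints between parameters
#'
#' @param constraints character vector of inequality expressions, e.g.
#'   `"1 - V/(A*t) > 0"`.
#' @param values named list/vector covering every referenced name
#'   (multi-parameter entries of length `M` are indexed by `curve_index`).
#' @param curve_index curve index for multi-parameters.
#' @return `TRUE` iff every inequality holds.
#' @examples
#' check_constraints("1 - V/(A*t) > 0", c(V = 300, A = 60, t = 10))
#' @export
check_constraints <- function(constraints, values = list(), curve_index = 1L) {
  if (!length(constraints)) return(TRUE)
  constraints <- as.character(constraints)
  vals <- .values_for_curve(values, curve_index)
  env <- .make_math_env()
  for (k in seq_along(vals))
    assign(names(vals)[k], vals[[k]], envir = env)
  for (s in constraints) {
    ex <- .parse_entry(s)
    if (!is.call(ex) ||
        !as.character(ex[[1]]) %in% c("<", ">", "<=", ">=", "&", "|"))
      stop("constraint '", s, "' is not an inequality", call. = FALSE)
    bad <- setdiff(all.vars(ex), names(vals))
    if (length(bad))
      stop("constraint '", s, "' references undeclared name(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    ok <- eval(ex, envir = env)
    if (!is.logical(ok) || length(ok) != 1L || is.na(ok))
      stop("constraint '", s, "' did not evaluate to TRUE/FALSE",
           call. = FALSE)
    if (!ok) return(FALSE)
  }
  TRUE
}

# ---- compiled resolver for the fitting hot path ----------------------------
# Pre-parses every symbolic entry once and reuses one evaluation environment.
.compile_system <- function(model) {
  stopifnot(inherits(model, "refl_model"))
  env <- .make_math_env()
  patches <- lapply(model$patches, function(pa) {
    nl <- length(pa$layers)
    m <- matrix(0, nl, length(.FIELDS), dimnames = list(NULL, .FIELDS))
    dyn <- list()
    for (i in seq_len(nl)) {
      la <- pa$layers[[i]]
      for (f in .FIELDS) {
        v <- la[[f]]
        if (is.numeric(v)) m[i, f] <- v
        else dyn[[length(dyn) + 1L]] <-
            list(row = i, col = f, expr = .parse_entry(v), n = i - 1)
      }
    }
    list(base = m, dyn = dyn, nl = nl,
         names = vapply(pa$layers, `[[`, character(1), "name"))
  })
  coverages <- vapply(model$patches, `[[`, numeric(1), "coverage")
  solvent_from <- vapply(model$patches, `[[`, character(1), "solvent_from")

  function(vals) {
    # vals: named list of scalars for this curve
    for (k in seq_along(vals))
      assign(names(vals)[k], vals[[k]], envir = env)
    out <- vector("list", length(patches))
    for (p in seq_along(patches)) {
      cp <- patches[[p]]
      m <- cp$base
      for (d in cp$dyn) {
        assign("n", d$n, envir = env)
        v <- eval(d$expr, envir = env)
        if (!is.finite(v))
          return(.violation("non-finite entry"))
        m[d$row, d$col] <- v
      }
      nl <- cp$nl
      msg <- .validate_resolved(as.data.frame(m), p)
      if (!is.null(msg)) return(.violation(msg))
      m[, "solvent"] <- pmin(pmax(m[, "solvent"], 0), 1)
      m[c(1L, nl), "solvent"] <- 0
      out[[p]] <- m
    }
    attr(out, "coverages") <- coverages
    attr(out, "solvent_from") <- solvent_from
    out
  }
}

# pre-parsed constraint checker used during fitting; returns TRUE/FALSE
.compile_constraints <- function(constraints) {
  if (!length(constraints)) return(function(vals) TRUE)
  exprs <- lapply(as.character(constraints), .parse_entry)
  env <- .make_math_env()
  function(vals) {
    for (k in seq_along(vals))
      assign(names(vals)[k], vals[[k]], envir = env)
    for (ex in exprs) {
      ok <- eval(ex, envir = env)
      if (!isTRUE(ok)) return(FALSE)
    }
    TRUE
  }
}
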