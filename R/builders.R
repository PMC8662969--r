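# Layer-stack builders for analytic volume-fraction profiles:
# close-packed (poly)disperse nanoparticle layers, power-law polymer brushes,
# solvent-penetrated lipid bilayers, and generic multilayer repetition.
# Builders sample profiles at slice mid-planes and emit slabs with zero
# inter-slice roughness; outer boundaries take user-specified roughness.

#' Close-packing volume fraction of spheres
#'
#' `pi / (2*sqrt(3))`, the in-plane packing fraction of hexagonally
#' close-packed spheres; the default mid-layer volume fraction of a
#' close-packed nanoparticle layer (approximately 0.91).
#'
#' @return numeric scalar.
#' @export
close_packing_fraction <- function() pi / (2 * sqrt(3))

.fmt_num <- function(x) sprintf("%.17g", x)
.as_sym <- function(x) if (is.character(x)) x else .fmt_num(x)

.sliced <- function(layers, n_slices, slice_thickness, extent, phi_solv) {
  structure(list(layers = layers, n_slices = n_slices,
                 slice_thickness = slice_thickness, extent = extent,
                 phi_solv = phi_solv),
            class = "refl_sliced_profile")
}

#' @export
print.refl_sliced_profile <- function(x, ...) {
  cat("Sliced profile:", x$n_slices, "slices, slice thickness",
      if (is.numeric(x$slice_thickness)) format(x$slice_thickness) else
        paste0("<", x$slice_thickness, ">"), "Angstrom\n")
  invisible(x)
}

#' Layer stack for a monodisperse spherical-nanoparticle layer
#'
#' A close-packed layer of spheres of diameter `D` has particle volume
#' fraction `phi(z) = (4*A/D^2) * (D*z - z^2)` across `0 <= z <= D`, where
#' `A` is the volume fraction at the layer mid-plane.  The layer is sliced
#' into `n_slices` slabs of thickness `D/n_slices`; each slice carries the
#' solvent fraction `1 - phi(z)` evaluated at its mid-plane.  Because
#' `phi(z)` depends only on `z/D`, `A` and `D` may be parameter names
#' (symbolic entries) and the emitted solvent fractions remain valid for any
#' fitted diameter.
#'
#' @param A mid-layer particle volume fraction in `(0, 1]`, or a parameter
#'   name; defaults to the close-packing fraction.
#' @param D sphere diameter, Angstrom, or a parameter name.
#' @param n_slices number of slabs (>= 1).
#' @param sld,isld sld of the particle material (numeric or expression).
#' @param roughness roughness applied to the *last* slice (outer boundary).
#' @return a `refl_sliced_profile` with element `layers` usable inside
#'   [patch()].
#' @examples
#' np <- nanoparticle_layers(A = 0.91, D = 150, n_slices = 100, sld = 1.41e-6)
#' np$slice_thickness  # 1.5 Angstrom
#' @export
nanoparticle_layers <- function(A = close_packing_fraction(), D,
                                n_slices = 100L, sld, isld = 0,
                                roughness = 0) {
  if (is.numeric(A) && (A <= 0 || A > 1))
    stop("mid-layer volume fraction A must lie in (0, 1]", call. = FALSE)
  if (is.numeric(D) && D <= 0) stop("D must be positive", call. = FALSE)
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) stop("n_slices must be >= 1", call. = FALSE)
  xk <- (seq_len(n_slices) - 0.5) / n_slices         # z/D at slice mid-planes
  symbolic <- is.character(A) || is.character(D)
  if (symbolic) {
    phis <- sprintf("1 - 4*(%s)*%s*(1 - %s)", .as_sym(A),
                    vapply(xk, .fmt_num, character(1)),
                    vapply(xk, .fmt_num, character(1)))
    th <- sprintf("(%s)/%d", .as_sym(D), n_slices)
    thv <- rep(list(th), n_slices)
    slice_thickness <- th
    extent <- .as_sym(D)
  } else {
    phis <- 1 - 4 * A * xk * (1 - xk)
    thv <- rep(list(D / n_slices), n_slices)
    slice_thickness <- D / n_slices
    extent <- D
  }
  layers <- vector("list", n_slices)
  for (k in seq_len(n_slices))
    layers[[k]] <- layer(sld = sld, isld = isld, thickness = thv[[k]],
                         roughness = if (k == n_slices) roughness else 0,
                         solvent = if (symbolic) phis[k] else phis[k],
                         name = sprintf("np slice %d", k))
  .sliced(layers, n_slices, slice_thickness, extent, phis)
}

#' Layer stack for a polydisperse spherical-nanoparticle layer
#'
#' Nanoparticle diameters are normally distributed with mean `D` and
#' standard deviation `sigma_D`.  The particle volume fraction at height `z`
#' is the density-weighted average of the monodisperse profile over
#' diameters, integrated on `D' in [max(0, D - 4*sigma_D), D + 4*sigma_D]`
#' with a fixed 401-point trapezoid and renormalised over the truncated
#' range; the layer extends to `D + 4*sigma_D`.  Numeric arguments only.
#'
#' @param A mid-layer volume fraction of the monodisperse reference profile.
#' @param D mean diameter, Angstrom.
#' @param sigma_D diameter standard deviation, Angstrom (>= 0).
#' @param n_slices number of slabs.
#' @param sld,isld particle sld.
#' @param roughness outer-boundary roughness.
#' @return a `refl_sliced_profile`.
#' @export
nanoparticle_layers_polydisperse <- function(A = close_packing_fraction(), D,
                                             sigma_D, n_slices = 100L,
                                             sld, isld = 0, roughness = 0) {
  stopifnot(is.numeric(A), is.numeric(D), is.numeric(sigma_D))
  if (sigma_D < 0) stop("sigma_D must be >= 0", call. = FALSE)
  if (A <= 0 || A > 1)
    stop("mid-layer volume fraction A must lie in (0, 1]", call. = FALSE)
  if (sigma_D == 0) {
    out <- nanoparticle_layers(A, D, n_slices, sld, isld, roughness)
    return(out)
  }
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) stop("n_slices must be >= 1", call. = FALSE)
  extent <- D + 4 * sigma_D
  dz <- extent / n_slices
  zk <- (seq_len(n_slices) - 0.5) * dz
  Dp <- seq(max(D - 4 * sigma_D, 1e-9), D + 4 * sigma_D, length.out = 401L)
  wts <- stats::dnorm(Dp, mean = D, sd = sigma_D)
  # trapezoid weights on a uniform grid
  tw <- rep(1, length(Dp)); tw[c(1L, length(Dp))] <- 0.5
  wts <- wts * tw
  wts <- wts / sum(wts)                       # truncation renormalisation
  phi <- vapply(zk, function(z) {
    pm <- (4 * A / Dp^2) * (Dp * z - z^2)     # monodisperse profile
    pm[z > Dp] <- 0                           # above the sphere: no particle
    pm[pm < 0] <- 0
    sum(wts * pm)
  }, numeric(1))
  phis <- pmin(pmax(1 - phi, 0), 1)
  layers <- vector("list", n_slices)
  for (k in seq_len(n_slices))
    layers[[k]] <- layer(sld = sld, isld = isld, thickness = dz,
                         roughness = if (k == n_slices) roughness else 0,
                         solvent = phis[k],
                         name = sprintf("np slice %d", k))
  .sliced(layers, n_slices, dz, extent, phis)
}

#' Layer stack for a power-law polymer brush
#'
#' End-grafted polymer brushes form extended layers with volume fraction
#' `phi(z) = phi(0) * (1 - (z/L)^n)` for `0 <= z <= L` (parabolic for
#' `n = 2`).  The layer is sliced into `n_slices` slabs of thickness
#' `L/n_slices` with solvent fraction `1 - phi(z)` at slice mid-planes.
#' Because `phi` depends only on `z/L`, all three of `phi0`, `L` and `n_exp`
#' may be parameter names for fitting.
#'
#' @param phi0 volume fraction at the grafting surface, `(0, 1]`, or a
#'   parameter name.
#' @param L brush extension, Angstrom, or a parameter name.
#' @param n_exp profile exponent (> 0), or a parameter name.
#' @param n_slices number of slabs.
#' @param sld,isld polymer sld.
#' @param roughness outer-boundary roughness.
#' @return a `refl_sliced_profile`.
#' @examples
#' br <- brush_layers(phi0 = 0.10, L = 480, n_exp = 2, n_slices = 100,
#'                    sld = 1.41e-6)
#' @export
brush_layers <- function(phi0, L, n_exp, n_slices = 100L, sld, isld = 0,
                         roughness = 0) {
  if (is.numeric(phi0) && (phi0 <= 0 || phi0 > 1))
    stop("phi0 must lie in (0, 1]", call. = FALSE)
  if (is.numeric(L) && L <= 0) stop("L must be positive", call. = FALSE)
  if (is.numeric(n_exp) && n_exp <= 0)
    stop("n_exp must be positive", call. = FALSE)
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) stop("n_slices must be >= 1", call. = FALSE)
  xk <- (seq_len(n_slices) - 0.5) / n_slices           # z/L at mid-planes
  symbolic <- is.character(phi0) || is.character(L) || is.character(n_exp)
  if (symbolic) {
    phis <- sprintf("1 - (%s)*(1 - %s^(%s))", .as_sym(phi0),
                    vapply(xk, .fmt_num, character(1)), .as_sym(n_exp))
    th <- sprintf("(%s)/%d", .as_sym(L), n_slices)
    thv <- rep(list(th), n_slices)
    slice_thickness <- th
    extent <- .as_sym(L)
  } else {
    phis <- 1 - phi0 * (1 - xk^n_exp)
    thv <- rep(list(L / n_slices), n_slices)
    slice_thickness <- L / n_slices
    extent <- L
  }
  layers <- vector("list", n_slices)
  for (k in seq_len(n_slices))
    layers[[k]] <- layer(sld = sld, isld = isld, thickness = thv[[k]],
                         roughness = if (k == n_slices) roughness else 0,
                         solvent = phis[k],
                         name = sprintf("brush slice %d", k))
  .sliced(layers, n_slices, slice_thickness, extent, phis)
}

#' Specification of a solvent-penetrated lipid bilayer
#'
#' Four regions (inner heads, inner tails, outer tails, outer heads), each
#' with molecular scattering length `b` (Angstrom), molecular volume `V`
#' (Angstrom^3) and thickness `t` (Angstrom, numeric or parameter name);
#' `A_pm` is the surface area per molecule (Angstrom^2, numeric or parameter
#' name), shared by both leaflets.
#'
#' @param A_pm area per molecule, Angstrom^2, or a parameter name.
#' @param regions named list of four regions `inner_heads`, `inner_tails`,
#'   `outer_tails`, `outer_heads`; each a list/vector with elements `b`, `V`
#'   and `t`.
#' @return an object of class `refl_bilayer_spec`.
#' @export
bilayer_spec <- function(A_pm, regions) {
  need <- c("inner_heads", "inner_tails", "outer_tails", "outer_heads")
  if (!is.list(regions) || !identical(sort(names(regions)), sort(need)))
    stop("'regions' must be a named list with elements ",
         paste(need, collapse = ", "), call. = FALSE)
  regions <- regions[need]
  for (r in need) {
    x <- regions[[r]]
    if (!all(c("b", "V") %in% names(x)) || !("t" %in% names(x)))
      stop("region '", r, "' needs elements b, V and t", call. = FALSE)
    if (!is.numeric(x[["b"]]) || !is.numeric(x[["V"]]) || x[["V"]] < 0)
      stop("region '", r, "': b and V must be numeric, V >= 0", call. = FALSE)
  }
  if (is.numeric(A_pm) && A_pm <= 0)
    stop("A_pm must be positive", call. = FALSE)
  structure(list(A_pm = A_pm, regions = regions), class = "refl_bilayer_spec")
}

#' Layer stack for a solvent-penetrated lipid bilayer
#'
#' Each of the four lipid regions occupies volume `V` out of `A_pm * t`, so
#' its solvent volume fraction is `phi = 1 - V / (A_pm * t)`.  The layer's
#' sld entry is the *molecular* sld `b / V`, so that the engine's
#' volume-fraction mixing rule `(1 - phi) * rho + phi * rho_solv` yields the
#' volume-conserving hydrated sld `(b + (A_pm t - V) rho_solv)/(A_pm t)`;
#' its dry part equals the molecule's scattering length spread over the full
#' layer, `b / (A_pm * t)`.  When `A_pm` or a thickness is a parameter name
#' the solvent fractions are emitted symbolically and a positivity
#' constraint `1 - V/(A_pm*t) > 0` is generated for each region, to be
#' enforced during refinement.
#'
#' @param spec a [bilayer_spec()].
#' @param roughness roughness entry applied to every lipid interface
#'   (numeric or parameter name).
#' @param isld imaginary sld of the lipid material.
#' @return list with elements `layers` (four [layer()] objects, inner heads
#'   first) and `constraints` (character vector, possibly empty).
#' @examples
#' bs <- bilayer_spec(A_pm = 60, regions = list(
#'   inner_heads = c(b = 6.01e-4, V = 319, t = 8),
#'   inner_tails = c(b = -2.92e-4, V = 782, t = 14),
#'   outer_tails = c(b = -2.92e-4, V = 782, t = 14),
#'   outer_heads = c(b = 6.01e-4, V = 319, t = 8)))
#' bl <- bilayer_layers(bs, roughness = 3)
#' @export
bilayer_layers <- function(spec, roughness = 0, isld = 0) {
  stopifnot(inherits(spec, "refl_bilayer_spec"))
  A <- spec$A_pm
  layers <- list()
  constraints <- character(0)
  for (r in names(spec$regions)) {
    x <- spec$regions[[r]]
    b <- as.numeric(x[["b"]]); V <- as.numeric(x[["V"]]); t <- x[["t"]]
    sld <- if (V > 0) b / V else 0          # molecular sld of the region
    symbolic <- is.character(A) || is.character(t)
    if (symbolic) {
      phi <- sprintf("1 - %s/((%s)*(%s))", .fmt_num(V), .as_sym(A), .as_sym(t))
      constraints <- c(constraints,
                       sprintf("1 - %s/((%s)*(%s)) > 0", .fmt_num(V),
                               .as_sym(A), .as_sym(t)))
      th <- t
    } else {
      At <- A * t
      if (V > At)
        stop("region '", r, "': V exceeds A_pm * t (negative solvent",
             " fraction)", call. = FALSE)
      phi <- 1 - V / At
      th <- t
    }
    layers[[r]] <- layer(sld = sld, isld = isld, thickness = th,
                         roughness = roughness, solvent = phi, name = r)
  }
  list(layers = unname(layers), constraints = constraints)
}

# replace the layer-index symbol `n` by (n - offset) in one entry
.shift_index <- function(entry, offset) {
  if (!is.character(entry) || offset == 0) return(entry)
  ex <- .parse_entry(entry)
  repl <- call("-", as.name("n"), offset)
  sub <- function(e) {
    if (is.symbol(e)) {
      if (identical(e, as.name("n"))) repl else e
    } else if (is.call(e)) {
      as.call(lapply(as.list(e), sub))
    } else e
  }
  paste(deparse(sub(ex), width.cutoff = 500L), collapse = " ")
}

#' Repeat a unit of layers
#'
#' Concatenates `count` copies of a unit stack (for multilayers).  Entries
#' that use the layer-index symbol `n` are re-indexed so every copy sees the
#' same local indices as the first.
#'
#' @param unit list of [layer()] objects (or a `refl_sliced_profile`).
#' @param count number of repetitions (>= 1).
#' @return list of layers of length `count * length(unit)`.
#' @export
repeat_stack <- function(unit, count) {
  if (inherits(unit, "refl_sliced_profile")) unit <- unit$layers
  if (!is.list(unit) || !length(unit) ||
      !all(vapply(unit, inherits, logical(1), "refl_layer")))
    stop("'unit' must be a list of layer() objects", call. = FALSE)
  count <- as.integer(count)
  if (is.na(count) || count < 1L) stop("count must be >= 1", call. = FALSE)
  len <- length(unit)
  out <- vector("list", len * count)
  for (c_ in seq_len(count)) {
    off <- (c_ - 1L) * len
    for (i in seq_len(len)) {
      la <- unit[[i]]
      out[[off + i]] <- layer(sld = .shift_index(la$sld, off),
                              isld = .shift_index(la$isld, off),
                              thickness = .shift_index(la$thickness, off),
                              roughness = .shift_index(la$roughness, off),
                              solvent = .shift_index(la$solvent, off),
                              name = la$name)
    }
  }
  out
}
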