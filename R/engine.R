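# Specular reflectivity of resolved multi-patch systems: solvent mixing,
# Abelès transfer matrix with Névot-Croce roughness, incoherent patch
# averaging, Gaussian resolution smearing, scale and background.

#' Instrument settings for one reflectivity curve
#'
#' @param resolution constant dQ/Q (dimensionless, FWHM of a Gaussian
#'   resolution function divided by Q); `0` disables smearing.  A per-point
#'   `dQ` column on a data curve takes precedence over this constant.
#' @param background additive incoherent background (reflectivity units);
#'   may be a character expression naming a (multi-)parameter.
#' @param scale multiplicative scale factor for non-normalised reflectivity;
#'   may be a character expression naming a (multi-)parameter.
#' @param dq_is_sigma set `TRUE` if per-point `dQ` columns of data files hold
#'   the Gaussian standard deviation rather than the FWHM.
#' @return an object of class `refl_instrument`.
#' @export
instrument <- function(resolution = 0, background = 0, scale = 1,
                       dq_is_sigma = FALSE) {
  if (is.numeric(resolution) && (length(resolution) != 1L || resolution < 0))
    stop("'resolution' (dQ/Q) must be a single non-negative value",
         call. = FALSE)
  if (is.numeric(background) && background < 0)
    stop("'background' must be non-negative", call. = FALSE)
  if (is.numeric(scale) && scale <= 0)
    stop("'scale' must be strictly positive", call. = FALSE)
  structure(list(resolution = resolution, background = background,
                 scale = scale, dq_is_sigma = isTRUE(dq_is_sigma)),
            class = "refl_instrument")
}

#' Mix solvent into a layer sld
#'
#' Wet sld of a partially hydrated layer:
#' `(1 - phi) * layer_sld + phi * solvent_sld`.
#'
#' @param layer_sld complex (or real) dry layer sld, 1/Angstrom^2.
#' @param solvent_frac solvent volume fraction in `[0, 1]`.
#' @param solvent_sld sld of the penetrating solvent.
#' @return complex sld.
#' @export
mix_solvent <- function(layer_sld, solvent_frac, solvent_sld) {
  if (any(solvent_frac < 0 | solvent_frac > 1))
    stop("solvent fraction must lie in [0, 1]", call. = FALSE)
  (1 - solvent_frac) * layer_sld + solvent_frac * solvent_sld
}

# resolved patch (matrix/data.frame with sld, isld, thickness, roughness,
# solvent) -> slab table after solvent mixing
.slabify <- function(rp, solvent_from = "backing") {
  rp <- as.matrix(rp[, .FIELDS[1:5]])
  nl <- nrow(rp)
  src <- if (identical(solvent_from, "fronting")) 1L else nl
  sol <- complex(real = rp[src, "sld"], imaginary = rp[src, "isld"])
  dry <- complex(real = rp[, "sld"], imaginary = rp[, "isld"])
  wet <- mix_solvent(dry, rp[, "solvent"], sol)
  list(sld_re = Re(wet), sld_im = Im(wet),
       thickness = rp[, "thickness"], roughness = rp[, "roughness"])
}

#' Abelès reflectivity of a slab stack
#'
#' Specular reflectivity by the characteristic-matrix (Abelès) method with
#' Névot-Croce roughness damping `exp(-2 kz_j kz_{j+1} sigma_j^2)` of each
#' interfacial Fresnel coefficient.  `kz_j = sqrt((Q/2)^2 - 4*pi*(rho_j -
#' rho_0))` with the decaying-wave branch; `isld >= 0` means absorption.
#'
#' @param slabs data frame or matrix with columns `sld_re`, `sld_im`,
#'   `thickness`, `roughness` (roughness of row `j` belongs to the interface
#'   between rows `j` and `j + 1`); first row = fronting medium, last row =
#'   backing medium.
#' @param Q strictly positive momentum-transfer grid, 1/Angstrom.
#' @return numeric vector of reflectivities in `[0, 1]`.
#' @examples
#' s <- data.frame(sld_re = c(0, 6.36e-6), sld_im = 0,
#'                 thickness = 0, roughness = 0)
#' abeles_reflectivity(s, Q = c(0.01, 0.1))
#' @export
abeles_reflectivity <- function(slabs, Q) {
  slabs <- as.data.frame(slabs)
  need <- c("sld_re", "sld_im", "thickness", "roughness")
  if (!all(need %in% names(slabs)))
    stop("'slabs' needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(slabs) < 2L)
    stop("at least 2 slabs (fronting and backing) are required", call. = FALSE)
  if (any(!is.finite(Q)) || any(Q <= 0))
    stop("Q must be finite and strictly positive", call. = FALSE)
  nl <- nrow(slabs)
  .abeles_kernel(as.numeric(Q), slabs$sld_re, slabs$sld_im,
                 slabs$thickness, slabs$roughness[-nl])
}

#' Incoherent average of patch reflectivities
#'
#' @param R_per_patch list of reflectivity vectors on a common Q grid.
#' @param coverages surface coverages summing to 1.
#' @return element-wise weighted sum.
#' @export
mix_patches <- function(R_per_patch, coverages) {
  if (length(R_per_patch) != length(coverages))
    stop("one coverage per patch is required", call. = FALSE)
  n <- unique(vapply(R_per_patch, length, integer(1)))
  if (length(n) != 1L)
    stop("patch reflectivity arrays have mismatched lengths", call. = FALSE)
  if (abs(sum(coverages) - 1) > 1e-9)
    stop("coverages must sum to 1", call. = FALSE)
  out <- numeric(n)
  for (p in seq_along(R_per_patch))
    out <- out + coverages[p] * R_per_patch[[p]]
  out
}

# 17-point Gauss-Legendre rule on [-1, 1] (Golub-Welsch)
.gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (2 * e$vectors[1, ]^2)[ord])
}

.smear_quad <- local({
  gl <- NULL
  function() {
    if (is.null(gl)) {
      g <- .gauss_legendre(17L)
      u <- 2.5 * g$nodes                    # +/- 2.5 sigma window
      w <- 2.5 * g$weights * stats::dnorm(u)
      gl <<- list(u = u, w = w / sum(w))    # renormalised truncated Gaussian
    }
    gl
  }
})

.FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))  # 1/2.35482

#' Gaussian resolution smearing
#'
#' Convolves a model reflectivity with a Gaussian resolution function of
#' full width at half-maximum `dQ` (per point) or `resolution * Q`
#' (constant relative resolution).  Each smeared point is the
#' Gaussian-weighted average of the unsmeared model over a window of
#' +/- 2.5 standard deviations (`sigma = FWHM / 2.35482`), evaluated by a
#' 17-node Gauss-Legendre quadrature on a locally refined Q grid; the
#' truncated kernel is renormalised so constants are preserved exactly.
#'
#' @param Q momentum-transfer grid of the output.
#' @param R either a function `R(q)` returning model reflectivity (preferred;
#'   exact local refinement) or a numeric vector on `Q` (interpolated with
#'   natural splines onto the quadrature nodes).
#' @param settings an [instrument()] object supplying the constant `dQ/Q`.
#' @param dQ optional per-point resolution column (FWHM unless
#'   `settings$dq_is_sigma`); takes precedence over the constant `dQ/Q`.
#' @return smeared reflectivity on `Q`.
#' @export
smear <- function(Q, R, settings = instrument(), dQ = NULL) {
  stopifnot(inherits(settings, "refl_instrument"))
  res <- settings$resolution
  if (is.null(dQ) && (is.null(res) || !is.numeric(res) || res == 0)) {
    return(if (is.function(R)) R(Q) else R)
  }
  if (!is.null(dQ)) {
    if (length(dQ) != length(Q)) stop("dQ must match Q in length", call. = FALSE)
    if (any(dQ < 0)) stop("dQ must be non-negative", call. = FALSE)
    sigma <- if (settings$dq_is_sigma) dQ else dQ * .FWHM_TO_SIGMA
  } else {
    if (res < 0) stop("dQ/Q must be non-negative", call. = FALSE)
    sigma <- res * Q * .FWHM_TO_SIGMA
  }
  if (all(sigma == 0)) return(if (is.function(R)) R(Q) else R)
  f <- if (is.function(R)) R else {
    if (length(R) != length(Q)) stop("R must match Q in length", call. = FALSE)
    stats::splinefun(Q, R, method = "natural")
  }
  quad <- .smear_quad()
  nodes <- outer(Q, rep(1, length(quad$u))) + outer(sigma, quad$u)
  nodes <- pmax(nodes, .Machine$double.eps)
  Rm <- matrix(f(as.vector(nodes)), nrow = length(Q))
  drop(Rm %*% quad$w)
}

#' Apply scale and background
#'
#' `scale * R + background`, applied after smearing and patch mixing.
#' Symbolic scale/background entries are resolved against `values`.
#'
#' @param R reflectivity vector.
#' @param settings an [instrument()] object.
#' @param values parameter values used to resolve symbolic scale/background.
#' @param curve_index curve index for multi-parameters.
#' @return corrected reflectivity.
#' @export
finalize_reflectivity <- function(R, settings = instrument(),
                                  values = list(), curve_index = 1L) {
  stopifnot(inherits(settings, "refl_instrument"))
  vals <- .values_for_curve(values, curve_index)
  sc <- if (is.numeric(settings$scale)) settings$scale else
    evaluate_entry(settings$scale, vals)
  bg <- if (is.numeric(settings$background)) settings$background else
    evaluate_entry(settings$background, vals)
  if (!is.finite(sc) || sc <= 0) stop("scale must be > 0", call. = FALSE)
  if (!is.finite(bg) || bg < 0) stop("background must be >= 0", call. = FALSE)
  sc * R + bg
}

# unsmeared mixed-patch reflectivity as a function of q, for one curve
.reflectivity_fun <- function(resolved) {
  cov <- attr(resolved, "coverages")
  sfrom <- attr(resolved, "solvent_from")
  slabs <- lapply(seq_along(resolved), function(p)
    .slabify(resolved[[p]], sfrom[p]))
  function(q) {
    out <- numeric(length(q))
    for (p in seq_along(slabs)) {
      s <- slabs[[p]]
      out <- out + cov[p] * .abeles_kernel(q, s$sld_re, s$sld_im,
                                           s$thickness,
                                           s$roughness[-length(s$roughness)])
    }
    out
  }
}

#' Calculate a model reflectivity curve
#'
#' Full forward pipeline: resolve the model, mix solvent, compute the Abelès
#' reflectivity of every patch, average patches incoherently, smear with the
#' instrumental resolution, and apply scale and background.
#'
#' @param model a [system_model()].
#' @param values named parameter values (length-M entries = multi-parameters).
#' @param Q momentum-transfer grid, 1/Angstrom, strictly positive.
#' @param settings an [instrument()] object.
#' @param curve_index curve index for multi-parameters.
#' @param dQ optional per-point resolution column (FWHM).
#' @return data frame with columns `Q` and `R`.
#' @examples
#' m <- system_model(patch(list(
#'   layer(0, name = "air"),
#'   layer(2.07e-6, roughness = 3, name = "Si")), coverage = 1))
#' head(refl_calculate(m, Q = seq(0.01, 0.2, by = 0.01)))
#' @export
refl_calculate <- function(model, values = list(), Q,
                           settings = instrument(), curve_index = 1L,
                           dQ = NULL) {
  if (any(Q <= 0)) stop("Q must be strictly positive", call. = FALSE)
  resolved <- resolve_system(model, values, curve_index)
  f <- .reflectivity_fun(resolved)
  R <- smear(Q, f, settings, dQ)
  R <- finalize_reflectivity(R, settings, values, curve_index)
  data.frame(Q = as.numeric(Q), R = R)
}

#' Real-space sld and solvent profiles of a resolved model
#'
#' Error-function-smoothed depth profiles (wet sld and solvent volume
#' fraction) for each patch, as plotted alongside reflectivity curves.
#'
#' @param model a [system_model()].
#' @param values named parameter values.
#' @param curve_index curve index for multi-parameters.
#' @param dz depth-grid spacing, Angstrom.
#' @param pad extension into the fronting/backing media, Angstrom.
#' @return data frame with columns `z`, `sld_re`, `sld_im`, `phi_solv`,
#'   `patch`.
#' @export
sld_profile <- function(model, values = list(), curve_index = 1L,
                        dz = 0.5, pad = 25) {
  resolved <- resolve_system(model, values, curve_index)
  sfrom <- attr(resolved, "solvent_from")
  out <- NULL
  for (p in seq_along(resolved)) {
    rp <- resolved[[p]]
    s <- .slabify(rp, sfrom[p])
    nl <- nrow(rp)
    zb <- cumsum(c(0, s$thickness[-c(1L, nl)]))  # interface positions
    z <- seq(-pad, max(zb) + pad, by = dz)
    wet_re <- s$sld_re; wet_im <- s$sld_im
    phi <- rp$solvent
    phi[c(1L, nl)] <- c(if (sfrom[p] == "fronting") 1 else 0,
                        if (sfrom[p] == "backing") 1 else 0)
    prof_re <- rep(wet_re[1], length(z))
    prof_im <- rep(wet_im[1], length(z))
    prof_phi <- rep(phi[1], length(z))
    for (j in seq_len(nl - 1L)) {
      sg <- max(s$roughness[j], 1e-6)
      stp <- 0.5 * (1 + erf((z - zb[j]) / (sqrt(2) * sg)))
      prof_re <- prof_re + (wet_re[j + 1] - wet_re[j]) * stp
      prof_im <- prof_im + (wet_im[j + 1] - wet_im[j]) * stp
      prof_phi <- prof_phi + (phi[j + 1] - phi[j]) * stp
    }
    out <- rbind(out, data.frame(z = z, sld_re = prof_re, sld_im = prof_im,
                                 phi_solv = prof_phi, patch = p))
  }
  out
}
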