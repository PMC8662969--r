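# S3 methods for refl_fit objects.

#' @export
print.refl_fit <- function(x, ...) {
  cat("Reflectivity co-refinement (", length(x$curves), " curve",
      if (length(x$curves) > 1) "s", ", ", x$n_free, " free parameter",
      if (x$n_free > 1) "s", ")\n", sep = "")
  cat(sprintf("  FOM (%s): %.6g", x$fom_mode, x$fom))
  if (!is.null(x$chi2_red))
    cat(sprintf("   reduced chi-squared: %.4g", x$chi2_red))
  cat("\n  best fit:\n")
  for (i in seq_along(x$best))
    cat(sprintf("    %-18s %- .6g%s\n", names(x$best)[i], x$best[i],
                if (!is.null(x$sd) && is.finite(x$sd[i]))
                  sprintf("  +/- %.3g", x$sd[i]) else ""))
  invisible(x)
}

#' @export
summary.refl_fit <- function(object, ...) {
  tab <- data.frame(estimate = unname(object$best),
                    sd = if (is.null(object$sd)) NA_real_ else
                      unname(object$sd),
                    lower = object$lower, upper = object$upper,
                    row.names = names(object$best))
  structure(list(coefficients = tab, fom = object$fom,
                 fom_mode = object$fom_mode, chi2_red = object$chi2_red,
                 n_free = object$n_free, n_curves = length(object$curves),
                 n_points = sum(vapply(object$curves,
                                       function(cv) length(cv$Q),
                                       integer(1))),
                 converged = object$converged,
                 iterations = object$iterations, seed = object$seed,
                 uncertainty = if (is.null(object$uncertainty)) "none" else
                   object$uncertainty$method),
            class = "summary.refl_fit")
}

#' @export
print.summary.refl_fit <- function(x, ...) {
  cat("Reflectivity co-refinement summary\n")
  cat(sprintf("  %d curve(s), %d points, %d free parameter(s)\n",
              x$n_curves, x$n_points, x$n_free))
  cat(sprintf("  FOM (%s) = %.6g", x$fom_mode, x$fom))
  if (!is.null(x$chi2_red))
    cat(sprintf(",  reduced chi-squared = %.4g", x$chi2_red))
  cat(sprintf("\n  differential evolution: %d generations (%s), seed %s\n",
              x$iterations, if (x$converged) "converged" else
                "generation limit", format(x$seed)))
  cat(sprintf("  uncertainty method: %s\n\n", x$uncertainty))
  print(x$coefficients, digits = 5)
  invisible(x)
}

#' @export
coef.refl_fit <- function(object, ...) object$best

#' @export
vcov.refl_fit <- function(object, ...) {
  u <- object$uncertainty
  if (is.null(u)) return(NULL)
  s <- if (!is.null(u$chain)) u$chain else u$samples
  if (!is.null(s)) return(stats::cov(s))
  if (!is.null(u$sd)) return(diag(u$sd^2, length(u$sd)))
  NULL
}

#' Model reflectivity at new momentum transfers
#'
#' @param object a [refl_fit()].
#' @param Q momentum-transfer grid (default: the curve's own grid).
#' @param curve curve index.
#' @param smeared apply the instrumental resolution.
#' @param ... unused.
#' @return data frame with columns `Q` and `R`.
#' @export
predict.refl_fit <- function(object, Q = NULL, curve = 1L, smeared = TRUE,
                             ...) {
  cv <- object$curves[[curve]]
  use_own_grid <- is.null(Q)
  if (use_own_grid) Q <- cv$Q
  st <- object$settings[[curve]]
  if (!smeared) st$resolution <- 0
  refl_calculate(object$model, object$values, Q, st, curve_index = curve,
                 dQ = if (use_own_grid && smeared) cv$dQ else NULL)
}

#' @export
fitted.refl_fit <- function(object, ...)
  lapply(object$per_curve_model, `[[`, "R")

#' Fit residuals
#'
#' @param object a [refl_fit()].
#' @param type `"pearson"` (`(R_e - R_m)/dR`; requires `dR`) or `"raw"`.
#' @param ... unused.
#' @return list of residual vectors, one per curve.
#' @export
residuals.refl_fit <- function(object, type = c("pearson", "raw"), ...) {
  type <- match.arg(type)
  lapply(seq_along(object$curves), function(i) {
    cv <- object$curves[[i]]
    r <- cv$R - object$per_curve_model[[i]]$R
    if (type == "pearson") {
      if (is.null(cv$dR))
        stop("pearson residuals require dR", call. = FALSE)
      r <- r / cv$dR
    }
    r
  })
}

#' Plot a reflectivity fit
#'
#' Data and fitted curves on a log-R scale, optionally with the sld /
#' solvent-fraction depth profile.
#'
#' @param x a [refl_fit()].
#' @param what `"reflectivity"`, `"rq4"` (R Q^4 representation) or
#'   `"profile"`.
#' @param ... further graphical arguments (ignored).
#' @return `x`, invisibly.
#' @export
plot.refl_fit <- function(x, what = c("reflectivity", "rq4", "profile"),
                          ...) {
  what <- match.arg(what)
  M <- length(x$curves)
  cols <- seq_len(M)
  if (what == "profile") {
    pr <- sld_profile(x$model, x$values, curve_index = 1L)
    op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    on.exit(par(op), add = TRUE)
    plot(pr$z, pr$sld_re, type = "n", xlab = "z (Angstrom)",
         ylab = "sld (1/Angstrom^2)")
    for (p in unique(pr$patch))
      lines(pr$z[pr$patch == p], pr$sld_re[pr$patch == p], col = p, lty = p)
    plot(pr$z, pr$phi_solv, type = "n", ylim = c(0, 1),
         xlab = "z (Angstrom)", ylab = "solvent fraction")
    for (p in unique(pr$patch))
      lines(pr$z[pr$patch == p], pr$phi_solv[pr$patch == p], col = p,
            lty = p)
    return(invisible(x))
  }
  tr <- if (what == "rq4") function(q, r) r * q^4 else function(q, r) r
  ylim <- range(unlist(lapply(seq_len(M), function(i) {
    v <- tr(x$curves[[i]]$Q, pmax(x$curves[[i]]$R, 1e-12))
    v[v > 0]
  })))
  plot(NA, xlim = range(unlist(lapply(x$curves, `[[`, "Q"))), ylim = ylim,
       log = "y", xlab = "Q (1/Angstrom)",
       ylab = if (what == "rq4") "R Q^4" else "R")
  for (i in seq_len(M)) {
    cv <- x$curves[[i]]
    points(cv$Q, tr(cv$Q, pmax(cv$R, 1e-12)), col = cols[i], pch = 20,
           cex = 0.5)
    lines(x$per_curve_model[[i]]$Q,
          tr(x$per_curve_model[[i]]$Q, x$per_curve_model[[i]]$R),
          col = cols[i])
  }
  invisible(x)
}

#' Simulate replicate data sets from a fitted model
#'
#' Draws `nsim` noisy replicas of every curve from the fitted model using
#' each curve's own `dR` as the Gaussian noise scale (parametric
#' simulation).
#'
#' @param object a [refl_fit()]; curves must carry `dR`.
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param ... unused.
#' @return list of length `nsim`; each element a list of [refl_curve()]
#'   replicas.
#' @export
simulate.refl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(s)
    lapply(seq_along(object$curves), function(i) {
      cv <- object$curves[[i]]
      if (is.null(cv$dR))
        stop("simulate() requires dR on every curve", call. = FALSE)
      cv$R <- object$per_curve_model[[i]]$R +
        rnorm(length(cv$Q), 0, cv$dR)
      cv$source_path <- sprintf("simulated replicate %d of curve %d", s, i)
      cv
    }))
}

#' Confidence intervals of fitted parameters
#'
#' Central percentile intervals from the posterior/bootstrap samples when
#' available, else normal-theory intervals from the Hessian sds.
#'
#' @param object a [refl_fit()] with an uncertainty estimate.
#' @param parm parameter names or indices (default: all).
#' @param level confidence level.
#' @param ... unused.
#' @return matrix with one row per parameter.
#' @export
confint.refl_fit <- function(object, parm = NULL, level = 0.6827, ...) {
  u <- object$uncertainty
  if (is.null(u)) stop("fit carries no uncertainty estimate", call. = FALSE)
  a <- (1 - level) / 2
  s <- if (!is.null(u$chain)) u$chain else u$samples
  ci <- if (!is.null(s)) {
    t(apply(s, 2L, stats::quantile, probs = c(a, 1 - a)))
  } else {
    z <- stats::qnorm(1 - a)
    cbind(object$best - z * u$sd, object$best + z * u$sd)
  }
  rownames(ci) <- names(object$best)
  colnames(ci) <- sprintf("%.1f %%", 100 * c(a, 1 - a))
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
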