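# Parameter uncertainty: (1) Hessian curvature of the reduced chi-squared,
# (2) bootstrap resampling of the data, (3) affine-invariant ensemble MCMC
# with autocorrelation-based chain management.

#' Hessian-based parameter standard deviations
#'
#' Numerically estimates the diagonal elements `H_kk` of the Hessian of the
#' reduced chi-squared at the best fit by central finite differences with an
#' adaptive step, and reports `sigma_k = sqrt(2 * chi2_red_min / H_kk)`.
#' Non-positive curvature (a flat or ill-conditioned direction) yields `NA`
#' with a warning — this estimate is fast but can be numerically unstable.
#'
#' @param fn callable returning the reduced chi-squared for a free-parameter
#'   vector.
#' @param best the best-fit free-parameter vector (a local minimum).
#' @param chi2_red_min reduced chi-squared at `best` (computed if omitted).
#' @param rel_step initial relative step of the finite differences.
#' @return named numeric vector of standard deviations (attribute
#'   `"hessian"` holds the diagonal curvature estimates).
#' @export
hessian_sd <- function(fn, best, chi2_red_min = NULL, rel_step = 0.01) {
  d <- length(best)
  f0 <- fn(best)
  if (!is.finite(f0))
    stop("objective not evaluable at the best fit", call. = FALSE)
  if (is.null(chi2_red_min)) chi2_red_min <- f0
  H <- numeric(d)
  sds <- rep(NA_real_, d)
  for (k in seq_len(d)) {
    h <- rel_step * max(abs(best[k]), 1e-8)
    est_prev <- NA_real_
    est <- NA_real_
    for (it in 1:7) {
      xp <- best; xp[k] <- best[k] + h
      xm <- best; xm[k] <- best[k] - h
      fp <- fn(xp); fm <- fn(xm)
      if (!is.finite(fp) || !is.finite(fm))
        stop("objective failed near the best fit for parameter ",
             if (!is.null(names(best))) names(best)[k] else k, call. = FALSE)
      est <- (fp - 2 * f0 + fm) / h^2
      if (is.finite(est_prev) && est_prev != 0 &&
          abs(est - est_prev) <= 0.02 * abs(est_prev)) {
        est <- 0.5 * (est + est_prev)
        break
      }
      est_prev <- est
      h <- h / 2
    }
    H[k] <- est
    if (!is.finite(est) || est <= 0) {
      warning("non-positive curvature for parameter ",
              if (!is.null(names(best))) names(best)[k] else k,
              "; standard deviation undefined", call. = FALSE)
    } else {
      sds[k] <- sqrt(2 * chi2_red_min / est)
    }
  }
  names(sds) <- names(best)
  attr(sds, "hessian") <- H
  sds
}

#' Hessian uncertainty of a fit
#'
#' Convenience wrapper applying [hessian_sd()] to the chi-squared landscape
#' of a [refl_fit()] (requires `dR` on every curve): the curvature is taken
#' on the plain chi-squared, and the reduced chi-squared at the minimum
#' scales the covariance (`sigma_k = sqrt(2 chi2_red_min / H_kk)`), the
#' usual scaled-covariance convention that makes the estimate agree with
#' bootstrap and MCMC when the residuals are consistent with `dR`.
#'
#' @param fit a [refl_fit()] object.
#' @param rel_step finite-difference step (relative).
#' @return list with `method`, `sd` and `chi2_red_min`.
#' @export
hessian_uncertainty <- function(fit, rel_step = 0.01) {
  stopifnot(inherits(fit, "refl_fit"))
  if (is.null(fit$chi2_red))
    stop("Hessian uncertainty requires dR on every curve", call. = FALSE)
  dof <- sum(vapply(fit$curves, function(cv) length(cv$Q), integer(1))) -
    fit$n_free
  chi2_fn <- function(x) fit$chi2_red_fn(x) * max(dof, 1L)
  sds <- hessian_sd(chi2_fn, unname(fit$best),
                    chi2_red_min = fit$chi2_red, rel_step = rel_step)
  names(sds) <- names(fit$best)
  list(method = "hessian", sd = sds, chi2_red_min = fit$chi2_red)
}

#' Bootstrap uncertainty of a fit
#'
#' Each experimental curve is replicated `K` times by replacing every
#' `[R, dR]` point with `[R + delta, dR]`, `delta ~ Normal(0, dR)`, and the
#' minimisation is repeated independently on every replica.  The mean and
#' standard deviation of each free parameter over the `K` re-fits are
#' reported, together with the sample matrix for corner plots.  By default
#' re-fits search a reduced box (best fit +/- 20% of each parameter range,
#' clipped to the original bounds) to bound runtime; set
#' `full_search = TRUE` to re-search the full bounds.
#'
#' @param fit a [refl_fit()] object (all curves must carry `dR`).
#' @param K number of replicas (default 1000; must be >= 2).
#' @param seed RNG seed (default: the fit's seed + 1).
#' @param full_search search the original bounds instead of the reduced box.
#' @param popsize,maxiter,reltol differential-evolution settings for the
#'   re-fits.
#' @return list of class `refl_boot` with `method`, `mean`, `sd`, `samples`
#'   (`K x n_free`) and `K`.
#' @export
bootstrap_fit <- function(fit, K = 1000, seed = NULL, full_search = FALSE,
                          popsize = 8, maxiter = 150, reltol = 1e-6) {
  stopifnot(inherits(fit, "refl_fit"))
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  if (!all(vapply(fit$curves, function(cv) !is.null(cv$dR), logical(1))))
    stop("bootstrap requires dR on every curve", call. = FALSE)
  if (is.null(seed)) seed <- fit$seed + 1
  set.seed(seed)
  d <- fit$n_free
  if (full_search) {
    lo <- fit$lower; hi <- fit$upper
  } else {
    half <- 0.2 * (fit$upper - fit$lower)
    lo <- pmax(fit$lower, unname(fit$best) - half)
    hi <- pmin(fit$upper, unname(fit$best) + half)
  }
  samples <- matrix(NA_real_, K, d, dimnames = list(NULL, names(fit$best)))
  for (k in seq_len(K)) {
    reps <- lapply(fit$curves, function(cv) {
      cv$R <- cv$R + rnorm(length(cv$R), 0, cv$dR)
      cv
    })
    mk <- .make_objective(fit$model, fit$layout, fit$constraints, reps,
                          fit$settings, fit$fom_mode, fit$weights)
    de <- de_minimize(mk$obj, lo, hi, seed = NULL, popsize = popsize,
                      maxiter = maxiter, reltol = reltol,
                      init = rbind(unname(fit$best)))
    samples[k, ] <- de$par
  }
  structure(list(method = "bootstrap",
                 mean = colMeans(samples),
                 sd = apply(samples, 2L, stats::sd),
                 samples = samples, K = K, seed = seed),
            class = "refl_boot")
}

# ---- affine-invariant ensemble sampler -------------------------------------

#' Affine-invariant ensemble MCMC (stretch move)
#'
#' Goodman-Weare stretch-move ensemble sampler: each walker proposes
#' `Y = X_c + z (X_k - X_c)` with a complementary walker `X_c` and
#' `z ~ g(z) propto 1/sqrt(z)` on `[1/a, a]`; proposals are invariant under
#' affine transformations of parameter space.
#'
#' @param log_post callable returning the log posterior density (may be
#'   `-Inf`).
#' @param init walkers-by-dimension matrix of starting positions (every row
#'   must have finite log posterior).
#' @param steps number of ensemble steps.
#' @param a stretch scale (> 1).
#' @return list with `chain` (`steps x walkers x d` array), `log_prob`
#'   (`steps x walkers`) and `acceptance` rate.
#' @export
ensemble_mcmc <- function(log_post, init, steps, a = 2) {
  init <- as.matrix(init)
  W <- nrow(init); d <- ncol(init)
  if (W < max(2 * d + 2, 4))
    stop("need at least max(2*d + 2, 4) walkers", call. = FALSE)
  lp <- apply(init, 1L, log_post)
  if (any(!is.finite(lp)))
    stop("every initial walker must have finite log posterior", call. = FALSE)
  chain <- array(NA_real_, c(steps, W, d))
  lpm <- matrix(NA_real_, steps, W)
  X <- init
  accepted <- 0L
  halves <- list(1:(W %/% 2), (W %/% 2 + 1L):W)
  for (s in seq_len(steps)) {
    for (hh in 1:2) {
      mine <- halves[[hh]]
      other <- halves[[3 - hh]]
      for (k in mine) {
        j <- other[sample.int(length(other), 1L)]
        z <- ((a - 1) * runif(1) + 1)^2 / a
        y <- X[j, ] + z * (X[k, ] - X[j, ])
        lpy <- log_post(y)
        logq <- (d - 1) * log(z) + lpy - lp[k]
        if (is.finite(lpy) && log(runif(1)) < logq) {
          X[k, ] <- y
          lp[k] <- lpy
          accepted <- accepted + 1L
        }
      }
    }
    chain[s, , ] <- X
    lpm[s, ] <- lp
  }
  list(chain = chain, log_prob = lpm, acceptance = accepted / (steps * W))
}

# FFT autocorrelation function of one series, normalised to rho_0 = 1
.acf_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  m <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)]
  if (ac[1] <= 0) return(rep(0, n))
  ac / ac[1]
}

#' Integrated autocorrelation time of an ensemble chain
#'
#' Per-parameter integrated autocorrelation time `tau = 1 + 2 sum rho_t`
#' with automatic windowing (smallest `M` with `M >= c * tau(M)`), with the
#' autocorrelation function averaged over walkers.
#'
#' @param chain `steps x walkers x d` array (or `steps x walkers` matrix).
#' @param c windowing constant (default 5).
#' @return numeric vector of length `d`.
#' @export
integrated_autocorr_time <- function(chain, c = 5) {
  if (length(dim(chain)) == 2L) dim(chain) <- c(dim(chain), 1L)
  steps <- dim(chain)[1]; W <- dim(chain)[2]; d <- dim(chain)[3]
  tau <- numeric(d)
  for (p in seq_len(d)) {
    rho <- rowMeans(vapply(seq_len(W),
                           function(w) .acf_fft(chain[, w, p]),
                           numeric(steps)))
    cum <- 1 + 2 * cumsum(rho[-1])
    taus <- c(1, cum)
    M <- which(seq_along(taus) - 1 >= c * taus)[1]
    tau[p] <- if (is.na(M)) taus[length(taus)] else taus[M]
    if (!is.finite(tau[p]) || tau[p] < 1) tau[p] <- 1
  }
  tau
}

#' MCMC posterior sampling of a fit
#'
#' Bayesian sampling of the free parameters with the Gaussian likelihood
#' `log L = -1/2 * sum[ ((R_e - R_m)/dR)^2 + ln(2 pi dR^2) ]` (measurement
#' uncertainties assumed normal) and priors: uniform within bounds, normal
#' for normally declared parameters, `-Inf` outside the constraints.  A
#' pilot run of `pilot_steps` samples per walker estimates the integrated
#' autocorrelation time `tau`; `10 * max(tau)` samples are then discarded as
#' burn-in and the production run continues until the retained chain is at
#' least `60 * max(tau)` steps long.
#'
#' @param fit a [refl_fit()] object; every curve must carry `dR`.
#' @param seed RNG seed (default: the fit's seed + 2).
#' @param walkers ensemble size; default `max(2 * n_free + 2, 50)`.
#' @param pilot_steps pilot-chain length (default 500 samples).
#' @param burn_factor burn-in length in units of `max(tau)` (default 10).
#' @param production_factor minimum retained chain length in units of
#'   `max(tau)` (default 60).
#' @param max_steps hard cap on total steps; exceeding it raises an error
#'   advising revision of the parameter bounds.
#' @param a stretch scale of the ensemble moves.
#' @param ball relative radius of the initial walker ball around the best
#'   fit.
#' @return object of class `refl_mcmc`: `chain` (flattened samples x n_free
#'   matrix), `log_prob`, `tau` (per parameter), `burn_in`, `mean`, `sd`,
#'   `walkers`, `steps_total`, `acceptance`.
#' @export
mcmc_fit <- function(fit, seed = NULL, walkers = NULL, pilot_steps = 500,
                     burn_factor = 10, production_factor = 60,
                     max_steps = 50000, a = 2, ball = 1e-4) {
  stopifnot(inherits(fit, "refl_fit"))
  if (!all(vapply(fit$curves, function(cv) !is.null(cv$dR), logical(1))))
    stop("MCMC requires dR on every curve", call. = FALSE)
  if (is.null(seed)) seed <- fit$seed + 2
  set.seed(seed)
  d <- fit$n_free
  if (is.null(walkers)) walkers <- max(2 * d + 2, 50)
  walkers <- max(as.integer(walkers), 2 * d + 2, 4L)
  if (walkers %% 2L == 1L) walkers <- walkers + 1L

  layout <- fit$layout
  tab <- layout$table
  free <- which(!tab$fixed)
  lo <- fit$lower; hi <- fit$upper
  normal <- tab$kind[free] == "normal"
  mu <- tab$b1[free]; pr_sd <- tab$b2[free]
  check <- .compile_constraints(fit$constraints)
  forward <- fit$forward
  curves <- fit$curves
  M <- length(curves)
  const_term <- 0
  for (cv in curves) const_term <- const_term + sum(log(2 * pi * cv$dR^2))

  log_post <- function(x) {
    if (any(x < lo | x > hi)) return(-Inf)
    values <- .layout_values(layout, x)
    for (i in seq_len(M))
      if (!isTRUE(tryCatch(check(.values_for_curve(values, i)),
                           error = function(e) FALSE)))
        return(-Inf)
    models <- forward(values)
    if (is.null(models)) return(-Inf)
    chi2 <- 0
    for (i in seq_len(M))
      chi2 <- chi2 + sum(((curves[[i]]$R - models[[i]]) / curves[[i]]$dR)^2)
    lp <- -0.5 * (chi2 + const_term)
    if (any(normal))
      lp <- lp - 0.5 * sum(((x[normal] - mu[normal]) / pr_sd[normal])^2)
    if (!is.finite(lp)) return(-Inf)
    lp
  }

  # initial ball around the best fit, resampled until finite
  span <- hi - lo
  init <- matrix(NA_real_, walkers, d)
  for (w in seq_len(walkers)) {
    for (try_ in 1:200) {
      x <- unname(fit$best) + rnorm(d, 0, ball * span)
      x <- pmin(pmax(x, lo + 1e-12 * span), hi - 1e-12 * span)
      if (is.finite(log_post(x))) { init[w, ] <- x; break }
    }
    if (any(is.na(init[w, ])))
      stop("could not initialise walkers at the best fit", call. = FALSE)
  }

  pilot <- ensemble_mcmc(log_post, init, steps = pilot_steps, a = a)
  tau_pilot <- integrated_autocorr_time(pilot$chain)
  burn_in <- ceiling(burn_factor * max(tau_pilot))
  target <- function(tau) ceiling(production_factor * max(tau))

  X <- pilot$chain[pilot_steps, , ]
  steps_total <- pilot_steps
  prod_chain <- NULL
  prod_lp <- NULL
  acc <- pilot$acceptance
  tau <- tau_pilot
  repeat {
    done <- !is.null(prod_chain) &&
      (dim(prod_chain)[1] - burn_in) >= target(tau)
    if (done) break
    chunk <- max(target(tau) + burn_in -
                   (if (is.null(prod_chain)) 0L else dim(prod_chain)[1]),
                 200L)
    if (steps_total + chunk > max_steps)
      stop("autocorrelation time did not converge within ", max_steps,
           " steps; consider revising the parameter bounds", call. = FALSE)
    run <- ensemble_mcmc(log_post, X, steps = chunk, a = a)
    X <- run$chain[chunk, , ]
    steps_total <- steps_total + chunk
    prod_chain <- if (is.null(prod_chain)) run$chain else {
      comb <- array(NA_real_, c(dim(prod_chain)[1] + chunk, walkers, d))
      comb[seq_len(dim(prod_chain)[1]), , ] <- prod_chain
      comb[dim(prod_chain)[1] + seq_len(chunk), , ] <- run$chain
      comb
    }
    prod_lp <- rbind(prod_lp, run$log_prob)
    acc <- run$acceptance
    kept <- dim(prod_chain)[1] - burn_in
    if (kept > 10)
      tau <- integrated_autocorr_time(
        prod_chain[(burn_in + 1):dim(prod_chain)[1], , , drop = FALSE])
  }
  keep <- (burn_in + 1):dim(prod_chain)[1]
  flat <- matrix(aperm(prod_chain[keep, , , drop = FALSE], c(2, 1, 3)),
                 ncol = d)
  colnames(flat) <- names(fit$best)
  lp_flat <- as.vector(t(prod_lp[keep, , drop = FALSE]))
  structure(list(method = "mcmc", chain = flat, log_prob = lp_flat,
                 tau = stats::setNames(tau, names(fit$best)),
                 tau_pilot = stats::setNames(tau_pilot, names(fit$best)),
                 burn_in = burn_in,
                 production_steps = dim(prod_chain)[1] - burn_in,
                 mean = colMeans(flat), sd = apply(flat, 2L, stats::sd),
                 walkers = walkers, steps_total = steps_total,
                 acceptance = acc, seed = seed),
            class = "refl_mcmc")
}

#' Marginal and pairwise statistics of a posterior/bootstrap sample
#'
#' @param samples samples-by-parameters matrix (>= 100 rows).
#' @param bins_1d,bins_2d histogram bin counts.
#' @return list of class `refl_corner` with per-parameter means, sds,
#'   marginal histograms, pairwise 2D histograms and the Pearson correlation
#'   matrix (symmetric, unit diagonal).
#' @export
corner_stats <- function(samples, bins_1d = 40L, bins_2d = 25L) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 100L)
    stop("at least 100 samples are required", call. = FALSE)
  d <- ncol(samples)
  nm <- colnames(samples)
  if (is.null(nm)) nm <- paste0("p", seq_len(d))
  marginals <- lapply(seq_len(d), function(k)
    graphics::hist(samples[, k], breaks = bins_1d, plot = FALSE))
  names(marginals) <- nm
  pairs <- list()
  if (d > 1L) {
    for (i in 1:(d - 1)) for (j in (i + 1):d) {
      bx <- seq(min(samples[, i]), max(samples[, i]), length.out = bins_2d + 1)
      by <- seq(min(samples[, j]), max(samples[, j]), length.out = bins_2d + 1)
      cnt <- table(cut(samples[, i], bx, include.lowest = TRUE),
                   cut(samples[, j], by, include.lowest = TRUE))
      pairs[[paste(nm[i], nm[j], sep = ":")]] <-
        list(x = bx, y = by, counts = unclass(cnt))
    }
  }
  cm <- if (d > 1L) {
    sds <- apply(samples, 2L, stats::sd)
    cc <- diag(1, d)
    ok <- sds > 0
    if (sum(ok) > 1L) cc[ok, ok] <- stats::cor(samples[, ok, drop = FALSE])
    dimnames(cc) <- list(nm, nm)
    cc
  } else matrix(1, 1, 1, dimnames = list(nm, nm))
  structure(list(mean = stats::setNames(colMeans(samples), nm),
                 sd = stats::setNames(apply(samples, 2L, stats::sd), nm),
                 marginals = marginals, pairs = pairs, correlation = cm,
                 n = nrow(samples)),
            class = "refl_corner")
}

#' Corner plot of a posterior/bootstrap sample
#'
#' Diagonal panels: 1D marginal histograms with a line at the mean;
#' off-diagonal panels: 2D histogram projections of each parameter pair.
#'
#' @param samples samples-by-parameters matrix or a `refl_corner`.
#' @param ... passed to [corner_stats()] when `samples` is a matrix.
#' @return the `refl_corner` object, invisibly.
#' @export
plot_corner <- function(samples, ...) {
  cs <- if (inherits(samples, "refl_corner")) samples else
    corner_stats(samples, ...)
  d <- length(cs$mean)
  nm <- names(cs$mean)
  op <- par(mfrow = c(d, d), mar = c(2, 2, 0.5, 0.5))
  on.exit(par(op), add = TRUE)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (i == j) {
      h <- cs$marginals[[i]]
      plot(h, main = "", xlab = nm[i], ylab = "", col = grey(0.85))
      abline(v = cs$mean[i], col = "blue")
    } else if (i > j) {
      key <- paste(nm[j], nm[i], sep = ":")
      pp <- cs$pairs[[key]]
      image(pp$x, pp$y, pp$counts, col = grey(seq(1, 0.2, length.out = 32)),
            xlab = nm[j], ylab = nm[i])
    } else {
      plot.new()
    }
  }
  invisible(cs)
}

#' Point-wise confidence bands of model curves
#'
#' Evaluates the forward model over a thinned subset of posterior or
#' bootstrap samples and reports per-curve point-wise percentile envelopes
#' (central 68.27% by default, i.e. the 15.87/84.13 percentiles).
#'
#' @param samples samples-by-parameters matrix ([mcmc_fit()] chain or
#'   [bootstrap_fit()] samples); at least `n_draws` rows.
#' @param fit the [refl_fit()] the samples belong to.
#' @param level central coverage of the band (default 0.6827, i.e. 1 sigma).
#' @param n_draws number of draws evaluated (evenly thinned; default 200).
#' @param profiles also compute sld/solvent profile envelopes.
#' @return list with element `reflectivity`: per curve a data frame
#'   `Q, lo, best, hi`; and (optionally) `profile`: per curve a data frame
#'   `z, sld_lo, sld_best, sld_hi, phi_lo, phi_best, phi_hi` (first patch).
#' @export
confidence_band <- function(samples, fit, level = 0.6827, n_draws = 200,
                            profiles = FALSE) {
  stopifnot(inherits(fit, "refl_fit"))
  samples <- as.matrix(samples)
  if (nrow(samples) < n_draws)
    stop("insufficient samples: need at least ", n_draws, call. = FALSE)
  idx <- unique(round(seq(1, nrow(samples), length.out = n_draws)))
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  M <- length(fit$curves)
  acc <- vector("list", M)
  for (i in seq_len(M)) acc[[i]] <- matrix(NA_real_, length(idx),
                                           length(fit$curves[[i]]$Q))
  prof_acc <- NULL
  zgrid <- NULL
  for (s in seq_along(idx)) {
    values <- .layout_values(fit$layout, samples[idx[s], ])
    models <- fit$forward(values)
    if (is.null(models)) next
    for (i in seq_len(M)) acc[[i]][s, ] <- models[[i]]
    if (profiles) {
      pr <- sld_profile(fit$model, values, curve_index = 1L)
      pr <- pr[pr$patch == 1L, ]
      if (is.null(prof_acc)) {
        zgrid <- pr$z
        prof_acc <- list(sld = matrix(NA_real_, length(idx), length(zgrid)),
                         phi = matrix(NA_real_, length(idx), length(zgrid)))
      }
      if (length(pr$z) == length(zgrid)) {
        prof_acc$sld[s, ] <- pr$sld_re
        prof_acc$phi[s, ] <- pr$phi_solv
      }
    }
  }
  out <- list(reflectivity = lapply(seq_len(M), function(i) {
    qq <- apply(acc[[i]], 2L, stats::quantile, probs = qs, na.rm = TRUE)
    data.frame(Q = fit$curves[[i]]$Q, lo = qq[1, ],
               best = fit$per_curve_model[[i]]$R, hi = qq[2, ])
  }))
  if (profiles && !is.null(prof_acc)) {
    sq <- apply(prof_acc$sld, 2L, stats::quantile, probs = qs, na.rm = TRUE)
    pq <- apply(prof_acc$phi, 2L, stats::quantile, probs = qs, na.rm = TRUE)
    best_pr <- sld_profile(fit$model, fit$values, curve_index = 1L)
    best_pr <- best_pr[best_pr$patch == 1L, ]
    out$profile <- data.frame(z = zgrid, sld_lo = sq[1, ],
                              sld_best = best_pr$sld_re, sld_hi = sq[2, ],
                              phi_lo = pq[1, ], phi_best = best_pr$phi_solv,
                              phi_hi = pq[2, ])
  }
  out
}
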