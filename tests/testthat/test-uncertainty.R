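# Hessian, bootstrap, MCMC uncertainty and their summaries.

test_that("Hessian sd matches the quadratic closed form", {
  # chi2_red(a) = chi0 + (a - a0)^2 / s^2  ->  sd = s * sqrt(chi0)
  for (chi0 in c(1, 2.5)) {
    for (s in c(0.5, 3)) {
      fn <- function(x) chi0 + (x[1] - 2)^2 / s^2
      sd_est <- hessian_sd(fn, best = 2, chi2_red_min = chi0)
      expect_equal(as.numeric(sd_est), s * sqrt(chi0), tolerance = 1e-6)
    }
  }
})

test_that("flat directions give undefined sd with a warning", {
  fn <- function(x) 1 + (x[1] - 1)^2   # second coordinate is flat
  expect_warning(sd_est <- hessian_sd(fn, best = c(1, 0),
                                      chi2_red_min = 1),
                 "non-positive curvature")
  expect_false(is.na(sd_est[1]))
  expect_true(is.na(sd_est[2]))
})

test_that("Hessian sd agrees with the analytic least-squares covariance", {
  set.seed(33)
  n <- 2000
  x <- runif(n, 0.5, 2)
  delta <- 0.1 * x
  a_true <- 1.7
  y <- a_true * x + rnorm(n, 0, delta)
  chi2 <- function(a) sum(((y - a[1] * x) / delta)^2)
  a_hat <- sum(y * x / delta^2) / sum(x^2 / delta^2)
  sd_analytic <- 1 / sqrt(sum(x^2 / delta^2))
  chi2_red_min <- chi2(a_hat) / (n - 1)
  sd_est <- hessian_sd(chi2, best = a_hat, chi2_red_min = chi2_red_min)
  expect_lt(abs(unname(sd_est) / sd_analytic - 1), 0.05)
})

test_that("bootstrap reproduces the analytic sd of a linear estimator", {
  # R = scale * R0 is linear in the scale parameter: weighted least squares
  # has a closed-form sd the bootstrap must match within 10% at K = 1000
  m <- system_model(patch(list(
    layer(0), layer(4e-6, thickness = 60, roughness = 3), layer(6.36e-6))))
  Q <- seq(0.02, 0.2, length.out = 10)
  st <- instrument(scale = "sc")
  R0 <- refl_calculate(m, Q = Q)$R
  set.seed(44)
  dR <- 0.05 * R0
  cv <- refl_curve(Q = Q, R = R0 + rnorm(10, 0, dR), dR = dR)
  fit <- refl_fit(m, parameter_set(par_uniform("sc", 0.5, 1.5)), cv,
                  settings = st, fom = "linear_err", seed = 10,
                  maxiter = 200)
  sd_analytic <- 1 / sqrt(sum(R0^2 / dR^2))
  bt <- bootstrap_fit(fit, K = 1000, seed = 15)
  expect_lt(abs(bt$sd[[1]] / sd_analytic - 1), 0.10)
  expect_equal(unname(bt$mean[1]), coef(fit)[[1]], tolerance = 3 * sd_analytic)
  expect_equal(dim(bt$samples), c(1000L, 1L))
})

test_that("bootstrap edge cases: zero dR and K validation", {
  # degenerate noise: dR == 0 -> all replicas identical -> vanishing sd
  # (fit on a log FOM so zero errors never enter the objective)
  fx <- single_layer_fixture(npts = 15, noise = 0, seed = 3)
  cv0 <- suppressWarnings(refl_curve(Q = fx$curve$Q, R = fx$curve$R,
                                     dR = rep(0, length(fx$curve$Q))))
  fit0 <- refl_fit(fx$model, fx$params, cv0, fom = "log_noerr",
                   seed = 2, maxiter = 200)
  bt <- bootstrap_fit(fit0, K = 5, seed = 1)
  expect_lt(unname(bt$sd[1]), 1e-3)
  expect_error(bootstrap_fit(fit0, K = 1), ">= 2")
  expect_equal(eval(formals(bootstrap_fit)$K), 1000)
})

test_that("ensemble sampler reproduces a Gaussian toy posterior", {
  mu <- c(1, -2); sig <- c(0.5, 1.5)
  log_post <- function(x) -0.5 * sum(((x - mu) / sig)^2)
  set.seed(55)
  init <- cbind(rnorm(12, mu[1], 0.1), rnorm(12, mu[2], 0.1))
  run <- ensemble_mcmc(log_post, init, steps = 4000)
  tau <- integrated_autocorr_time(run$chain)
  flat <- matrix(aperm(run$chain[-(1:500), , ], c(2, 1, 3)), ncol = 2)
  n_eff <- nrow(flat) / max(tau)
  for (k in 1:2) {
    expect_lt(abs(mean(flat[, k]) - mu[k]), 3 * sig[k] / sqrt(n_eff))
    expect_equal(sd(flat[, k]), sig[k], tolerance = 0.1)
  }
  expect_gt(run$acceptance, 0.1)
})

test_that("flat likelihood recovers the uniform prior", {
  log_post <- function(x) if (x >= 0 && x <= 1) 0 else -Inf
  set.seed(66)
  init <- matrix(runif(8), ncol = 1)
  run <- ensemble_mcmc(log_post, init, steps = 6000)
  draws <- as.vector(run$chain[seq(1000, 6000, by = 25), , 1])
  ks <- suppressWarnings(stats::ks.test(draws, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("chain management follows the pilot/burn-in/production rules", {
  fx <- single_layer_fixture(npts = 20, seed = 3)
  fit <- refl_fit(fx$model, fx$params, fx$curve, fom = "linear_err",
                  seed = 2, maxiter = 60)
  expect_equal(eval(formals(mcmc_fit)$pilot_steps), 500)
  expect_equal(eval(formals(mcmc_fit)$burn_factor), 10)
  expect_equal(eval(formals(mcmc_fit)$production_factor), 60)
  mc <- mcmc_fit(fit, seed = 4, walkers = 6)
  expect_identical(mc$burn_in, ceiling(10 * max(mc$tau_pilot)))
  expect_gte(mc$production_steps, 60 * max(mc$tau))
  expect_equal(nrow(mc$chain), mc$production_steps * mc$walkers)
  # truth recovered within a few posterior sds
  expect_lt(abs(mc$mean[[1]] - fx$truth[["t1"]]), 4 * mc$sd[[1]])
  # a hopeless cap triggers the non-convergence error
  expect_error(mcmc_fit(fit, seed = 4, walkers = 6, max_steps = 600),
               "revising the parameter bounds")
})

test_that("corner statistics behave as sampling theory dictates", {
  set.seed(77)
  s <- cbind(a = rnorm(1e4), b = rnorm(1e4))
  cs <- corner_stats(s)
  expect_lt(abs(cs$correlation["a", "b"]), 0.1)
  expect_equal(diag(cs$correlation), c(a = 1, b = 1))
  expect_equal(cs$correlation, t(cs$correlation))
  s2 <- cbind(x = rnorm(500))
  s2 <- cbind(s2, y = 2 * s2[, 1] + 3)
  cs2 <- corner_stats(s2)
  expect_equal(cs2$correlation["x", "y"], 1, tolerance = 1e-12)
  cs1 <- corner_stats(matrix(rnorm(200), ncol = 1))
  expect_length(cs1$pairs, 0L)
  expect_length(cs1$marginals, 1L)
  expect_error(corner_stats(matrix(rnorm(50), ncol = 1)), "100")
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f)
  plot_corner(s)
  grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("confidence bands: degenerate width, containment, linear case", {
  m <- system_model(patch(list(
    layer(0), layer(4e-6, thickness = 60, roughness = 3), layer(6.36e-6))))
  Q <- seq(0.02, 0.2, length.out = 12)
  st <- instrument(scale = "sc")
  R0 <- refl_calculate(m, Q = Q)$R
  set.seed(88)
  dR <- 0.05 * R0
  cv <- refl_curve(Q = Q, R = R0 + rnorm(12, 0, dR), dR = dR)
  fit <- refl_fit(m, parameter_set(par_uniform("sc", 0.5, 1.5)), cv,
                  settings = st, fom = "linear_err", seed = 10,
                  maxiter = 150)
  s_hat <- coef(fit)[[1]]
  # zero-variance samples give a zero-width band containing the best fit
  s0 <- matrix(s_hat, nrow = 300, ncol = 1,
               dimnames = list(NULL, names(coef(fit))))
  b0 <- confidence_band(s0, fit)
  expect_equal(b0$reflectivity[[1]]$lo, b0$reflectivity[[1]]$hi)
  expect_equal(b0$reflectivity[[1]]$lo, b0$reflectivity[[1]]$best,
               tolerance = 1e-12)
  # Gaussian samples: half-width matches linear error propagation
  sig <- 0.03
  sg <- matrix(rnorm(4000, s_hat, sig), ncol = 1,
               dimnames = list(NULL, names(coef(fit))))
  bg <- confidence_band(sg, fit, n_draws = 2000)
  half <- 0.5 * (bg$reflectivity[[1]]$hi - bg$reflectivity[[1]]$lo)
  expect_equal(half, sig * R0, tolerance = 0.1)
  expect_true(all(bg$reflectivity[[1]]$lo <= bg$reflectivity[[1]]$best +
                    1e-12))
  expect_true(all(bg$reflectivity[[1]]$hi >= bg$reflectivity[[1]]$best -
                    1e-12))
  expect_error(confidence_band(sg[1:50, , drop = FALSE], fit),
               "insufficient samples")
})
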