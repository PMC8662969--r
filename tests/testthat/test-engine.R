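# Reflectivity engine: Abelès kernel, solvent mixing, patch averaging,
# smearing, scale/background.

Qgrid <- seq(0.005, 0.5, length.out = 60)

test_that("solvent mixing is the linear volume-fraction rule", {
  expect_equal(mix_solvent(4e-6 + 0i, 0, 6.36e-6 + 0i), 4e-6 + 0i)
  expect_equal(mix_solvent(4e-6 + 0i, 1, 6.36e-6 + 0i), 6.36e-6 + 0i)
  expect_equal(mix_solvent(0 + 0i, 0.5, 6.36e-6 + 0i), 3.18e-6 + 0i)
  expect_error(mix_solvent(1e-6, 1.2, 2e-6), "\\[0, 1\\]")
})

test_that("zero contrast gives zero reflectivity", {
  s <- data.frame(sld_re = c(2e-6, 2e-6), sld_im = 0, thickness = 0,
                  roughness = 0)
  expect_equal(abeles_reflectivity(s, Qgrid), rep(0, length(Qgrid)))
})

test_that("total external reflection below the critical edge", {
  dsld <- 6.36e-6
  Qc <- 4 * sqrt(pi * dsld)
  s <- data.frame(sld_re = c(0, dsld), sld_im = 0, thickness = 0,
                  roughness = 0)
  Qbelow <- seq(0.2, 0.98, by = 0.2) * Qc
  expect_equal(abeles_reflectivity(s, Qbelow), rep(1, length(Qbelow)),
               tolerance = 1e-12)
})

test_that("single sharp interface matches the closed-form Fresnel result", {
  for (contrast in c(6.36e-6, 2.07e-6, -1.5e-6, 1.2e-4)) {
    s <- data.frame(sld_re = c(0, contrast), sld_im = 0, thickness = 0,
                    roughness = 0)
    R <- abeles_reflectivity(s, Qgrid)
    Rf <- fresnel_reflectivity(0, contrast, Qgrid)
    expect_equal(R, Rf, tolerance = 1e-12)
  }
})

test_that("Névot-Croce damping matches its closed form above the edge", {
  dsld <- 4e-6
  sig <- 3
  Qc <- 4 * sqrt(pi * dsld)
  Q <- seq(3 * Qc, 0.5, length.out = 40)
  s0 <- data.frame(sld_re = c(0, dsld), sld_im = 0, thickness = 0,
                   roughness = 0)
  ss <- s0; ss$roughness <- c(sig, 0)
  k0 <- Q / 2
  k1 <- sqrt(k0^2 - 4 * pi * dsld)
  ratio <- abeles_reflectivity(ss, Q) / abeles_reflectivity(s0, Q)
  expect_equal(ratio, exp(-4 * k0 * k1 * sig^2), tolerance = 1e-8)
})

test_that("engine matches an independent Parratt recursion on random stacks", {
  set.seed(101)
  for (rep in 1:25) {
    st <- random_stack(10L)
    R <- abeles_reflectivity(st, Qgrid)
    Rp <- parratt_reflectivity(st$sld_re, st$sld_im, st$thickness,
                               st$roughness[-nrow(st)], Qgrid)
    expect_lt(max(abs(R - Rp) / pmax(Rp, 1e-300)), 1e-10)
  }
})

test_that("splitting a uniform layer into sub-slabs leaves R unchanged", {
  s <- data.frame(sld_re = c(0, 4e-6, 6.36e-6), sld_im = c(0, 2e-8, 0),
                  thickness = c(0, 120, 0), roughness = c(3, 2, 0))
  R1 <- abeles_reflectivity(s, Qgrid)
  for (k in c(3, 7)) {
    sk <- data.frame(sld_re = c(0, rep(4e-6, k), 6.36e-6),
                     sld_im = c(0, rep(2e-8, k), 0),
                     thickness = c(0, rep(120 / k, k), 0),
                     roughness = c(3, rep(0, k - 1), 2, 0))
    expect_lt(max(abs(abeles_reflectivity(sk, Qgrid) - R1) / R1), 1e-12)
  }
})

test_that("kinematic limit: R Q^4 -> 16 pi^2 dsld^2 at large Q", {
  dsld <- 6e-6
  s <- data.frame(sld_re = c(0, dsld), sld_im = 0, thickness = 0,
                  roughness = 0)
  Q <- 1.0
  R <- abeles_reflectivity(s, Q)
  expect_equal(R * Q^4 / (16 * pi^2 * dsld^2), 1, tolerance = 1e-3)
})

test_that("absorption keeps reflectivity passive (R <= 1)", {
  s <- data.frame(sld_re = c(0, 6.36e-6), sld_im = c(0, 5e-7),
                  thickness = 0, roughness = 0)
  Q <- seq(0.001, 0.1, length.out = 200)
  R <- abeles_reflectivity(s, Q)
  expect_true(all(R <= 1 + 1e-12))
  expect_lt(max(R), 1)  # absorption removes total reflection
})

test_that("engine input validation", {
  s <- data.frame(sld_re = c(0, 6e-6), sld_im = 0, thickness = 0,
                  roughness = 0)
  expect_error(abeles_reflectivity(s[1, ], 0.1), "at least 2")
  expect_error(abeles_reflectivity(s, c(0.1, 0)), "positive")
  expect_error(abeles_reflectivity(s, -0.1), "positive")
})

test_that("patch mixing is the coverage-weighted sum and is symmetric", {
  R1 <- rep(1, 5); R2 <- rep(0, 5)
  expect_identical(mix_patches(list(R1), 1), R1)
  expect_equal(mix_patches(list(R1, R2), c(0.7, 0.3)), rep(0.7, 5))
  expect_equal(mix_patches(list(R2, R1), c(0.3, 0.7)), rep(0.7, 5))
  a <- runif(8); b <- runif(8)
  expect_equal(mix_patches(list(a, b), c(0.4, 0.6)),
               mix_patches(list(b, a), c(0.6, 0.4)))
  expect_error(mix_patches(list(R1, R2[-1]), c(0.5, 0.5)), "mismatched")
  expect_error(mix_patches(list(R1, R2), c(0.5, 0.3)), "sum to 1")
})

test_that("smearing: identity at zero width, constants preserved", {
  R <- runif(20, 0.1, 1)
  Q <- seq(0.01, 0.2, length.out = 20)
  expect_identical(smear(Q, R, instrument(resolution = 0)), R)
  con <- function(q) rep(0.42, length(q))
  expect_equal(smear(Q, con, instrument(resolution = 0.05)), rep(0.42, 20),
               tolerance = 1e-14)
  expect_error(smear(Q, R, instrument(), dQ = rep(-1, 20)), "non-negative")
})

test_that("quadrature smearing matches a dense numerical convolution", {
  m <- system_model(patch(list(
    layer(0), layer(4e-6, thickness = 100), layer(6.36e-6))))
  f <- local({
    res <- resolve_system(m)
    specular:::.reflectivity_fun(res)
  })
  Q <- seq(0.02, 0.3, length.out = 120)
  sm <- smear(Q, f, instrument(resolution = 0.05))
  oracle <- dense_smear_oracle(Q, f, 0.05)
  expect_lt(max(abs(sm - oracle) / oracle), 1e-4)
})

test_that("per-point dQ takes precedence over constant dQ/Q", {
  f <- function(q) q  # linear test function: smearing preserves it
  Q <- seq(0.05, 0.2, length.out = 10)
  out <- smear(Q, f, instrument(resolution = 0.5), dQ = rep(0, 10))
  expect_equal(out, f(Q))  # dQ = 0 wins over the large constant
})

test_that("scale and background apply after everything else", {
  R <- c(1, 0.5, 0)
  expect_identical(finalize_reflectivity(R, instrument()), R)
  expect_equal(finalize_reflectivity(rep(0, 3),
                                     instrument(background = 1e-6)),
               rep(1e-6, 3))
  expect_equal(finalize_reflectivity(1, instrument(scale = 0.95)), 0.95)
  # symbolic scale/background resolved from parameter values
  st <- instrument(scale = "sc", background = "bg")
  expect_equal(finalize_reflectivity(c(1, 0), st,
                                     values = list(sc = 0.9, bg = 1e-7)),
               c(0.9 + 1e-7, 1e-7))
  expect_error(finalize_reflectivity(1, instrument(), values = list()),
               NA)
})

test_that("full pipeline composes (calculate, patches, profile)", {
  l2 <- list(layer(2.07e-6, name = "Si"), layer(6.36e-6, name = "D2O"))
  np <- nanoparticle_layers(A = 0.91, D = 150, n_slices = 50, sld = 1.41e-6)
  m <- system_model(
    patch(l2, coverage = 0.3),
    patch(c(list(layer(2.07e-6, roughness = 3, name = "Si")), np$layers,
            list(layer(6.36e-6, name = "D2O"))), coverage = 0.7))
  rq <- refl_calculate(m, Q = seq(0.01, 0.2, length.out = 50),
                       settings = instrument(resolution = 0.05,
                                             background = 1e-7))
  expect_true(all(is.finite(rq$R)) && all(rq$R > 0))
  # manual composition agrees
  res <- resolve_system(m)
  f <- specular:::.reflectivity_fun(res)
  Q <- rq$Q
  manual <- smear(Q, f, instrument(resolution = 0.05)) + 1e-7
  expect_equal(rq$R, manual, tolerance = 1e-12)
  pr <- sld_profile(m)
  expect_true(all(c("z", "sld_re", "sld_im", "phi_solv", "patch") %in%
                    names(pr)))
  expect_equal(sort(unique(pr$patch)), c(1, 2))
})
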