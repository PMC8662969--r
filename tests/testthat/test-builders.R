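# Analytic profile builders.

test_that("nanoparticle slicing arithmetic and boundary behaviour", {
  np <- nanoparticle_layers(A = 0.91, D = 150, n_slices = 100,
                            sld = 1.41e-6)
  expect_equal(np$slice_thickness, 1.5)
  expect_equal(np$n_slices, 100L)
  expect_length(np$layers, 100L)
  # direct evaluation at a slice mid-plane, independent arithmetic
  z <- 37.5
  expect_equal(1 - (4 * 0.91 / 150^2) * (150 * z - z^2), 0.3175,
               tolerance = 1e-12)
  np4 <- nanoparticle_layers(A = 0.91, D = 150, n_slices = 2000,
                             sld = 1.41e-6)
  k <- round(37.5 / np4$slice_thickness + 0.5)
  zk <- (k - 0.5) * np4$slice_thickness  # actual mid-plane of slice k
  expect_equal(np4$phi_solv[k],
               1 - (4 * 0.91 / 150^2) * (150 * zk - zk^2),
               tolerance = 1e-12)
  expect_equal(np4$phi_solv[k], 0.3175, tolerance = 2e-3)
  # profile tends to pure solvent at both layer boundaries
  expect_gt(np$phi_solv[1], 0.95)
  expect_gt(np$phi_solv[100], 0.95)
  expect_error(nanoparticle_layers(A = 1.3, D = 150, sld = 1e-6), "\\(0, 1]")
})

test_that("monodisperse sphere profile is symmetric about the mid-plane", {
  np <- nanoparticle_layers(A = 0.91, D = 150, n_slices = 100, sld = 1.41e-6)
  expect_equal(np$phi_solv, rev(np$phi_solv), tolerance = 1e-12)
})

test_that("symbolic nanoparticle layers resolve to the numeric profile", {
  npn <- nanoparticle_layers(A = 0.91, D = 150, n_slices = 20, sld = 1.41e-6)
  nps <- nanoparticle_layers(A = "A", D = "D", n_slices = 20, sld = 1.41e-6)
  phi <- vapply(seq_len(20), function(k)
    evaluate_entry(nps$layers[[k]]$solvent, c(A = 0.91, D = 150)),
    numeric(1))
  expect_equal(phi, npn$phi_solv, tolerance = 1e-12)
  expect_equal(evaluate_entry(nps$layers[[1]]$thickness, c(D = 150)),
               7.5)
})

test_that("polydisperse profile: degenerate limit, MC oracle, tail monotone", {
  mono <- nanoparticle_layers(A = 0.91, D = 150, n_slices = 100,
                              sld = 1.41e-6)
  degen <- nanoparticle_layers_polydisperse(A = 0.91, D = 150, sigma_D = 0,
                                            n_slices = 100, sld = 1.41e-6)
  expect_lt(max(abs(degen$phi_solv - mono$phi_solv)), 1e-9)

  pd <- nanoparticle_layers_polydisperse(A = 0.91, D = 150, sigma_D = 15,
                                         n_slices = 100, sld = 1.41e-6)
  expect_equal(pd$extent, 150 + 4 * 15)
  # Monte-Carlo oracle at the reference mid-height
  set.seed(77)
  ndraw <- 1e6
  Ds <- rnorm(ndraw, 150, 15)
  Ds <- Ds[Ds > 150 - 4 * 15 & Ds < 150 + 4 * 15]
  k <- which.min(abs((seq_len(100) - 0.5) * pd$slice_thickness - 75))
  z <- (k - 0.5) * pd$slice_thickness
  phm <- (4 * 0.91 / Ds^2) * (Ds * z - z^2)
  phm[z > Ds | phm < 0] <- 0
  mc <- 1 - mean(phm)
  mc_se <- sd(phm) / sqrt(length(phm))
  expect_lt(abs(pd$phi_solv[k] - mc), 3 * mc_se + 1e-6)
  # solvent fraction non-decreasing beyond the profile minimum
  jmin <- which.min(pd$phi_solv)
  expect_true(all(diff(pd$phi_solv[jmin:100]) >= -1e-12))
  expect_error(nanoparticle_layers_polydisperse(A = 0.91, D = 150,
                                                sigma_D = -1, sld = 1e-6),
               ">= 0")
})

test_that("brush profile boundary values and interior point", {
  # phi_solv(0) = 1 - phi0 and phi_solv(L) = 1, by construction
  br <- brush_layers(phi0 = 0.10, L = 480, n_exp = 2, n_slices = 4000,
                     sld = 1.41e-6)
  expect_equal(br$phi_solv[1], 1 - 0.10, tolerance = 1e-4)
  expect_equal(br$phi_solv[4000], 1, tolerance = 1e-4)
  k <- round(240 / br$slice_thickness + 0.5)
  expect_equal(br$phi_solv[k], 1 - 0.10 * (1 - 0.25), tolerance = 1e-3)
  expect_equal(br$slice_thickness, 480 / 4000)
  # symbolic form matches
  brs <- brush_layers(phi0 = "p", L = "L", n_exp = "m", n_slices = 10,
                      sld = 1.41e-6)
  brn <- brush_layers(phi0 = 0.2, L = 100, n_exp = 1.5, n_slices = 10,
                      sld = 1.41e-6)
  phi <- vapply(seq_len(10), function(k)
    evaluate_entry(brs$layers[[k]]$solvent, c(p = 0.2, L = 100, m = 1.5)),
    numeric(1))
  expect_equal(phi, brn$phi_solv, tolerance = 1e-12)
})

test_that("bilayer slab algebra: sld, solvent fraction, constraints", {
  # dry per-layer sld = b/(A_pm t): direct arithmetic
  expect_equal(6.0e-4 / (60 * 15), 6.667e-7, tolerance = 1e-3)
  bs <- bilayer_spec(A_pm = 60, regions = list(
    inner_heads = list(b = 6.0e-4, V = 60 * 15, t = 15),
    inner_tails = list(b = -2.92e-4, V = 0, t = 14),
    outer_tails = list(b = -2.92e-4, V = 782, t = 14),
    outer_heads = list(b = 6.0e-4, V = 319, t = 8)))
  bl <- bilayer_layers(bs, roughness = 3)
  expect_length(bl$layers, 4L)
  # molecular-sld entry; dry part of the resolved layer = b/(A_pm t)
  expect_equal(bl$layers[[1]]$sld, 6.0e-4 / 900)
  expect_equal(bl$layers[[1]]$sld * (1 - bl$layers[[1]]$solvent),
               6.0e-4 / (60 * 15))
  expect_equal(bl$layers[[4]]$sld * (1 - bl$layers[[4]]$solvent),
               6.0e-4 / (60 * 8))
  expect_equal(bl$layers[[1]]$solvent, 0)   # V = A_pm t: space filling
  expect_equal(bl$layers[[2]]$solvent, 1)   # V = 0
  expect_length(bl$constraints, 0L)         # numeric spec: checked eagerly
  expect_error(bilayer_layers(bilayer_spec(A_pm = 10, regions = list(
    inner_heads = list(b = 6.0e-4, V = 319, t = 8),
    inner_tails = list(b = -2.92e-4, V = 782, t = 14),
    outer_tails = list(b = -2.92e-4, V = 782, t = 14),
    outer_heads = list(b = 6.0e-4, V = 319, t = 8)))), "exceeds")
  # symbolic spec emits one positivity constraint per region
  bss <- bilayer_spec(A_pm = "apm", regions = list(
    inner_heads = list(b = 6.0e-4, V = 319, t = 8),
    inner_tails = list(b = -2.92e-4, V = 782, t = "tt"),
    outer_tails = list(b = -2.92e-4, V = 782, t = "tt"),
    outer_heads = list(b = 6.0e-4, V = 319, t = 8)))
  bls <- bilayer_layers(bss, roughness = 3)
  expect_length(bls$constraints, 4L)
  expect_true(check_constraints(bls$constraints, c(apm = 60, tt = 14)))
  expect_false(check_constraints(bls$constraints, c(apm = 60, tt = 5)))
})

test_that("wet bilayer sld obeys volume conservation for random specs", {
  set.seed(5)
  for (rep in 1:20) {
    A <- runif(1, 40, 80); t <- runif(1, 6, 20)
    V <- runif(1, 0.2, 0.99) * A * t
    b <- runif(1, -5e-4, 8e-4)
    rho_solv <- runif(1, -0.56e-6, 6.36e-6)
    dry <- b / V                      # molecular sld, as the builder emits
    phi <- 1 - V / (A * t)
    wet <- Re(mix_solvent(dry + 0i, phi, rho_solv + 0i))
    # volume-conservation identity: (V*(b/V) + (A t - V)*rho_solv)/(A t)
    expect_equal(wet, (b + (A * t - V) * rho_solv) / (A * t),
                 tolerance = 1e-12)
  }
})

test_that("repeat_stack concatenates, re-indexes, and preserves physics", {
  unit <- list(layer(2e-6, thickness = 10), layer(5e-6, thickness = 20))
  expect_identical(repeat_stack(unit, 1), unit)
  r3 <- repeat_stack(unit, 3)
  expect_length(r3, 6L)
  expect_equal(vapply(r3, `[[`, numeric(1), "thickness"),
               rep(c(10, 20), 3))
  expect_error(repeat_stack(unit, 0), ">= 1")
  # layer-index expressions see local indices in every copy
  u <- list(layer("1e-6*n", thickness = 5))
  r <- repeat_stack(u, 3)
  m <- system_model(patch(c(list(layer(0)), r, list(layer(6e-6)))))
  df <- resolve_system(m)[[1]]
  expect_equal(df$sld[2:4], rep(1e-6 * 1, 3))  # all copies at local n = 1
  # uniform 5x repeat equals one thick slab of the same sld
  Q <- seq(0.01, 0.3, length.out = 40)
  un <- list(layer(4e-6, thickness = 30))
  m5 <- system_model(patch(c(list(layer(0, roughness = 2)),
                             repeat_stack(un, 5), list(layer(6.36e-6)))))
  m1 <- system_model(patch(list(layer(0, roughness = 2),
                                layer(4e-6, thickness = 150),
                                layer(6.36e-6))))
  R5 <- refl_calculate(m5, Q = Q)$R
  R1 <- refl_calculate(m1, Q = Q)$R
  expect_lt(max(abs(R5 - R1) / R1), 1e-12)
})

test_that("finer slicing converges for the nanoparticle geometry", {
  mk <- function(n) {
    np <- nanoparticle_layers(A = 0.91, D = 150, n_slices = n, sld = 1.41e-6)
    system_model(patch(c(list(layer(2.07e-6, roughness = 3)), np$layers,
                         list(layer(6.36e-6)))))
  }
  Q <- seq(0.01, 0.15, length.out = 80)   # fitted Q range of this geometry
  R100 <- refl_calculate(mk(100), Q = Q)$R
  R400 <- refl_calculate(mk(400), Q = Q)$R
  expect_lt(max(abs(R100 - R400) / R400), 0.005)
})
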