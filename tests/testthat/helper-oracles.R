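# Independent oracles, kept deliberately separate from the package
# implementation.

# Parratt recursion for specular reflectivity (bottom-up recursive
# amplitude), with Névot-Croce damping.  rough[j] belongs to the interface
# between layers j and j+1.
parratt_reflectivity <- function(sld_re, sld_im, thickness, rough, Q) {
  nl <- length(sld_re)
  vapply(Q, function(q) {
    k0 <- q / 2
    kz <- sqrt(complex(real = k0^2 - 4 * pi * (sld_re - sld_re[1]),
                       imaginary = 4 * pi * (sld_im - sld_im[1])))
    flip <- Im(kz) < 0
    kz[flip] <- -kz[flip]
    r <- (kz[-nl] - kz[-1]) / (kz[-nl] + kz[-1]) *
      exp(-2 * kz[-nl] * kz[-1] * rough^2)
    X <- r[nl - 1]
    if (nl > 2) {
      for (j in (nl - 2):1) {
        ph <- exp(2i * kz[j + 1] * thickness[j + 1])
        X <- (r[j] + X * ph) / (1 + r[j] * X * ph)
      }
    }
    Mod(X)^2
  }, numeric(1))
}

# closed-form Fresnel reflectivity of one sharp interface
fresnel_reflectivity <- function(sld0, sld1, Q) {
  k0 <- Q / 2
  k1 <- sqrt(complex(real = k0^2 - 4 * pi * (sld1 - sld0), imaginary = 0))
  k1[Im(k1) < 0] <- -k1[Im(k1) < 0]
  Mod((k0 - k1) / (k0 + k1))^2
}

# brute-force dense convolution with the same truncated (+/- 2.5 sigma),
# renormalised Gaussian kernel used by the engine
dense_smear_oracle <- function(Q, f, dq_over_q, n_nodes = 4001) {
  sigma <- dq_over_q * Q / (2 * sqrt(2 * log(2)))
  u <- seq(-2.5, 2.5, length.out = n_nodes)
  w <- dnorm(u)
  w <- w / sum(w)
  vapply(seq_along(Q), function(i)
    sum(w * f(pmax(Q[i] + sigma[i] * u, 1e-12))), numeric(1))
}

# random slab stack generator for engine cross-checks
random_stack <- function(n_interior, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nl <- n_interior + 2L
  data.frame(
    sld_re = c(0, runif(n_interior, -2e-6, 1e-5), runif(1, 2e-6, 8e-6)),
    sld_im = c(0, runif(n_interior, 0, 5e-7), runif(1, 0, 2e-7)),
    thickness = c(0, runif(n_interior, 5, 200), 0),
    roughness = c(runif(nl - 1, 0, 10), 0))
}
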