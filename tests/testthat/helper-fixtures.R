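# Shared synthetic fixtures with known ground truth.

# single supported film at the solid/liquid interface, thickness free
single_layer_fixture <- function(truth = 60, npts = 40, noise = 0.02,
                                 seed = 11) {
  model <- system_model(patch(list(
    layer(0, name = "substrate"),
    layer(4.0e-6, thickness = "t1", roughness = 3, name = "film"),
    layer(6.36e-6, name = "solvent"))))
  Q <- seq(0.01, 0.25, length.out = npts)
  curve <- generate_curve(model, list(t1 = truth), Q, instrument(),
                          noise_spec(noise), seed = seed)
  list(model = model, curve = curve, truth = c(t1 = truth),
       params = parameter_set(par_uniform("t1", 20, 120)))
}

# polymer brush at the quartz/deuterated-toluene interface
brush_fixture <- function(truth = c(phi0 = 0.10, L = 480, nexp = 2),
                          n_slices = 50, npts = 100, noise = 0.02,
                          seed = 21) {
  br <- brush_layers(phi0 = "phi0", L = "L", n_exp = "nexp",
                     n_slices = n_slices, sld = 1.41e-6, roughness = 0)
  model <- system_model(patch(c(
    list(layer(4.18e-6, roughness = 3, name = "quartz")),
    br$layers,
    list(layer(5.86e-6, name = "d-toluene"))), coverage = 1))
  Q <- seq(0.008, 0.1, length.out = npts)
  curve <- generate_curve(model, as.list(truth), Q, instrument(),
                          noise_spec(noise), seed = seed)
  params <- parameter_set(par_uniform("phi0", 0.02, 0.30),
                          par_uniform("L", 300, 700),
                          par_uniform("nexp", 1, 4))
  list(model = model, curve = curve, truth = truth, params = params)
}

# solvent-penetrated lipid bilayer at the Si/water interface,
# three solvent contrasts sharing one structural model
bilayer_fixture <- function(truth = c(apm = 60, t_tail = 14),
                            solvent_slds = c(6.36e-6, 2.07e-6, -0.56e-6),
                            npts = 60, noise = 0.02, seed = 31) {
  bs <- bilayer_spec(A_pm = "apm", regions = list(
    inner_heads = list(b = 6.01e-4, V = 319, t = 8),
    inner_tails = list(b = -2.92e-4, V = 782, t = "t_tail"),
    outer_tails = list(b = -2.92e-4, V = 782, t = "t_tail"),
    outer_heads = list(b = 6.01e-4, V = 319, t = 8)))
  bl <- bilayer_layers(bs, roughness = 3)
  model <- system_model(patch(c(
    list(layer(2.07e-6, roughness = 3, name = "Si"),
         layer(3.47e-6, thickness = 12, roughness = 3, name = "SiO2"),
         layer("rho_solv", thickness = 4, roughness = 3, solvent = 1,
               name = "water layer")),
    bl$layers,
    list(layer("rho_solv", name = "bulk solvent"))), coverage = 1))
  Q <- seq(0.01, 0.25, length.out = npts)
  vals <- c(as.list(truth), list(rho_solv = solvent_slds))
  curves <- generate_contrast_series(model, as.list(truth), "rho_solv",
                                     solvent_slds, Q, instrument(),
                                     noise_spec(noise), seed = seed)
  params <- parameter_set(
    par_uniform("apm", 40, 80),
    par_uniform("t_tail", 10, 20),
    par_multi("rho_solv", bounds = lapply(solvent_slds, function(s)
      c(s, s))))
  list(model = model, curves = curves, truth = truth, values = vals,
       params = params, constraints = bl$constraints)
}
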