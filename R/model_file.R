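# Declarative YAML model files mirroring the hierarchical list structure:
# patches -> layers -> six-element entries (values or expression strings),
# plus parameter declarations, constraints and instrument settings.

.layer_from_list <- function(x) {
  layer(sld = if (is.null(x$sld)) 0 else x$sld,
        isld = if (is.null(x$isld)) 0 else x$isld,
        thickness = if (is.null(x$thickness)) 0 else x$thickness,
        roughness = if (is.null(x$roughness)) 0 else x$roughness,
        solvent = if (is.null(x$solvent)) 0 else x$solvent,
        name = if (is.null(x$name)) "" else x$name)
}

.par_from_list <- function(x) {
  kind <- if (is.null(x$kind)) "uniform" else x$kind
  if (!is.null(x$per_curve)) {
    return(par_multi(x$name, bounds = lapply(x$per_curve, as.numeric),
                     kind = kind,
                     description = if (is.null(x$description)) "" else
                       x$description))
  }
  desc <- if (is.null(x$description)) "" else x$description
  switch(kind,
         uniform = par_uniform(x$name, x$bounds[[1]], x$bounds[[2]], desc),
         normal = par_normal(x$name, x$bounds[[1]], x$bounds[[2]], desc),
         fixed = par_fixed(x$name, x$value, desc),
         stop("unknown parameter kind '", kind, "'", call. = FALSE))
}

#' Read a declarative model file
#'
#' YAML layout: top-level keys `patches` (each with `coverage`, optional
#' `solvent_from`, and `layers`, each layer a mapping with `sld`, `isld`,
#' `thickness`, `roughness`, `solvent`, `name`), optional `parameters`
#' (each with `name`, `kind` in uniform/normal/fixed, `bounds` or `value`,
#' or `per_curve` pairs for multi-parameters), optional `constraints`
#' (list of inequality strings) and optional `instrument` (`resolution`,
#' `background`, `scale`).
#'
#' @param path YAML file path.
#' @return list with `model` ([system_model()]), `parameters`
#'   ([parameter_set()] or `NULL`), `constraints` (character) and
#'   `settings` ([instrument()]).
#' @export
read_model_file <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$patches)) stop("model file has no 'patches' key",
                               call. = FALSE)
  patches <- lapply(y$patches, function(p) {
    patch(lapply(p$layers, .layer_from_list),
          coverage = if (is.null(p$coverage)) 1 else p$coverage,
          solvent_from = if (is.null(p$solvent_from)) "backing" else
            p$solvent_from)
  })
  params <- if (!is.null(y$parameters))
    parameter_set(lapply(y$parameters, .par_from_list)) else NULL
  inst <- y$instrument
  settings <- instrument(
    resolution = if (is.null(inst$resolution)) 0 else inst$resolution,
    background = if (is.null(inst$background)) 0 else inst$background,
    scale = if (is.null(inst$scale)) 1 else inst$scale)
  list(model = system_model(patches), parameters = params,
       constraints = if (is.null(y$constraints)) character(0) else
         as.character(y$constraints),
       settings = settings)
}
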