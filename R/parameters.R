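# Parameter declarations for refinement: global parameters (one value for
# all curves) and multi-parameters (one value/prior per co-refined curve).
# A parameter is declared uniform (min/max bounds), normal (mean/sd prior)
# or fixed; identical bounds or zero sd also signify a fixed parameter.

.par_row <- function(name, kind, b1, b2, curve = NA_integer_,
                     description = "") {
  data.frame(name = name, curve = curve, kind = kind, b1 = b1, b2 = b2,
             description = description, stringsAsFactors = FALSE)
}

#' Declare a uniform (bounded) parameter
#'
#' @param name parameter name as used inside model expressions.
#' @param min,max bounds of the uniform search interval; equal values fix
#'   the parameter.
#' @param description free text.
#' @return object of class `refl_par`.
#' @export
par_uniform <- function(name, min, max, description = "") {
  if (min > max) stop("par_uniform('", name, "'): min > max", call. = FALSE)
  structure(.par_row(name, "uniform", min, max, description = description),
            class = c("refl_par", "data.frame"))
}

#' Declare a normally distributed parameter
#'
#' During differential evolution the parameter is searched within
#' `mean +/- 5 sd` and contributes an additive Gaussian penalty
#' `((x - mean)/sd)^2` to the figure of merit; during MCMC it carries a
#' `Normal(mean, sd)` prior.  `sd = 0` fixes the parameter.
#'
#' @param name parameter name.
#' @param mean,sd prior mean and standard deviation (`sd >= 0`).
#' @param description free text.
#' @return object of class `refl_par`.
#' @export
par_normal <- function(name, mean, sd, description = "") {
  if (sd < 0) stop("par_normal('", name, "'): sd must be >= 0", call. = FALSE)
  structure(.par_row(name, "normal", mean, sd, description = description),
            class = c("refl_par", "data.frame"))
}

#' Declare a fixed parameter
#'
#' @param name parameter name.
#' @param value fixed value.
#' @param description free text.
#' @return object of class `refl_par`.
#' @export
par_fixed <- function(name, value, description = "") {
  structure(.par_row(name, "uniform", value, value, description = description),
            class = c("refl_par", "data.frame"))
}

#' Declare a multi-parameter (one declaration per co-refined curve)
#'
#' A multi-parameter adopts a distinct value (or prior) for each input
#' curve: solvent sld per contrast, +/- magnetic sld per polarisation,
#' per-curve scale and background.
#'
#' @param name parameter name.
#' @param bounds list of length `M` (number of curves); each element a
#'   numeric pair: min/max for `kind = "uniform"`, mean/sd for
#'   `kind = "normal"`.
#' @param kind `"uniform"` or `"normal"`, recycled to length `M`.
#' @param description free text.
#' @return object of class `refl_par`.
#' @examples
#' par_multi("rho_solv", bounds = list(c(6.0e-6, 6.4e-6),
#'                                     c(2.0e-6, 2.3e-6),
#'                                     c(-0.6e-6, -0.4e-6)))
#' @export
par_multi <- function(name, bounds, kind = "uniform", description = "") {
  if (!is.list(bounds) || !length(bounds))
    stop("'bounds' must be a non-empty list of numeric pairs", call. = FALSE)
  kind <- rep_len(match.arg(kind, c("uniform", "normal"), several.ok = FALSE),
                  length(bounds))
  rows <- NULL
  for (i in seq_along(bounds)) {
    b <- as.numeric(bounds[[i]])
    if (length(b) != 2L)
      stop("each element of 'bounds' must be a numeric pair", call. = FALSE)
    if (kind[i] == "uniform" && b[1] > b[2])
      stop("par_multi('", name, "') curve ", i, ": min > max", call. = FALSE)
    if (kind[i] == "normal" && b[2] < 0)
      stop("par_multi('", name, "') curve ", i, ": sd must be >= 0",
           call. = FALSE)
    rows <- rbind(rows, .par_row(name, kind[i], b[1], b[2], curve = i,
                                 description = description))
  }
  structure(rows, class = c("refl_par", "data.frame"))
}

#' Collect parameter declarations
#'
#' @param ... [par_uniform()], [par_normal()], [par_fixed()] and
#'   [par_multi()] declarations (or a single list of them).
#' @return object of class `refl_parameters`.
#' @export
parameter_set <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1]]) && !inherits(ps[[1]], "refl_par"))
    ps <- ps[[1]]
  if (!length(ps) || !all(vapply(ps, inherits, logical(1), "refl_par")))
    stop("parameter_set() takes par_*() declarations", call. = FALSE)
  tab <- do.call(rbind, lapply(ps, as.data.frame))
  dup <- unique(tab$name[duplicated(paste(tab$name, tab$curve))])
  if (length(dup))
    stop("duplicated parameter declaration(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  structure(list(table = tab), class = "refl_parameters")
}

#' @export
print.refl_parameters <- function(x, ...) {
  t <- x$table
  cat("Parameter set (", length(unique(t$name)), " parameters)\n", sep = "")
  for (i in seq_len(nrow(t))) {
    tag <- if (is.na(t$curve[i])) "" else sprintf(" [curve %d]", t$curve[i])
    fixed <- (t$kind[i] == "uniform" && t$b1[i] == t$b2[i]) ||
      (t$kind[i] == "normal" && t$b2[i] == 0)
    cat(sprintf("  %-14s%s %-8s %-12g %-12g%s\n", t$name[i], tag,
                if (fixed) "fixed" else t$kind[i], t$b1[i], t$b2[i],
                if (nzchar(t$description[i])) paste(" ", t$description[i])
                else ""))
  }
  invisible(x)
}

# ---- free-parameter layout --------------------------------------------------
# A multi-parameter counts once per distinct per-curve declaration left free.
.par_layout <- function(params, n_curves) {
  stopifnot(inherits(params, "refl_parameters"))
  tab <- params$table
  multis <- unique(tab$name[!is.na(tab$curve)])
  for (m in multis) {
    nc <- sum(tab$name == m)
    if (nc != n_curves)
      stop("multi-parameter '", m, "' declares ", nc, " per-curve entries",
           " but there are ", n_curves, " curves", call. = FALSE)
  }
  tab$fixed <- (tab$kind == "uniform" & tab$b1 == tab$b2) |
    (tab$kind == "normal" & tab$b2 == 0)
  tab$value_fixed <- ifelse(tab$fixed, tab$b1, NA_real_)
  free <- which(!tab$fixed)
  tab$slot <- NA_integer_
  tab$slot[free] <- seq_along(free)
  # DE search box: uniform -> [min, max]; normal -> mean +/- 5 sd
  tab$lower <- ifelse(tab$kind == "normal", tab$b1 - 5 * tab$b2, tab$b1)
  tab$upper <- ifelse(tab$kind == "normal", tab$b1 + 5 * tab$b2, tab$b2)
  lab <- ifelse(is.na(tab$curve), tab$name,
                sprintf("%s[%d]", tab$name, tab$curve))
  structure(list(table = tab, n_free = length(free),
                 free_names = lab[free], n_curves = n_curves),
            class = "refl_layout")
}

# x (free vector) -> named values list (multi entries become length-M vectors)
.layout_values <- function(layout, x) {
  tab <- layout$table
  v <- tab$value_fixed
  v[!tab$fixed] <- x[tab$slot[!tab$fixed]]
  out <- list()
  for (nm in unique(tab$name)) {
    rows <- which(tab$name == nm)
    if (length(rows) == 1L && is.na(tab$curve[rows])) {
      out[[nm]] <- v[rows]
    } else {
      out[[nm]] <- v[rows[order(tab$curve[rows])]]
    }
  }
  out
}

# additive Gaussian penalty for free normal parameters
.layout_penalty <- function(layout, x) {
  tab <- layout$table
  i <- which(!tab$fixed & tab$kind == "normal")
  if (!length(i)) return(0)
  sum(((x[tab$slot[i]] - tab$b1[i]) / tab$b2[i])^2)
}

# mid-point start values (prior mean / interval centre)
.layout_start <- function(layout) {
  tab <- layout$table
  i <- which(!tab$fixed)
  ifelse(tab$kind[i] == "normal", tab$b1[i], 0.5 * (tab$b1[i] + tab$b2[i]))
}
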