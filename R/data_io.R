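# Reading and writing reflectivity data and fit reports.
# Experimental curves come as 2/3/4-column ASCII (Q, R[, dR[, dQ FWHM]]),
# whitespace- or comma-delimited, '#' comments, Q in 1/Angstrom or 1/nm.

#' Construct a reflectivity curve object
#'
#' @param Q momentum transfer, 1/Angstrom, strictly positive.
#' @param R reflectivity.
#' @param dR optional 1-sigma uncertainty of `R` (non-negative; zero entries
#'   trigger a warning since error-weighted statistics become degenerate).
#' @param dQ optional per-point resolution (FWHM, 1/Angstrom).
#' @param source_path provenance label.
#' @param fit_weight relative weight of this curve in co-refinements (> 0).
#' @return object of class `refl_curve`.
#' @export
refl_curve <- function(Q, R, dR = NULL, dQ = NULL, source_path = "",
                       fit_weight = 1) {
  Q <- as.numeric(Q); R <- as.numeric(R)
  if (!length(Q) || length(R) != length(Q))
    stop("Q and R must be non-empty and of equal length", call. = FALSE)
  if (any(!is.finite(Q)) || any(Q <= 0))
    stop("Q must be finite and strictly positive", call. = FALSE)
  if (!is.null(dR)) {
    dR <- as.numeric(dR)
    if (length(dR) != length(Q)) stop("dR length mismatch", call. = FALSE)
    if (any(dR < 0)) stop("dR must be non-negative", call. = FALSE)
    if (any(dR == 0))
      warning("dR contains zeros; error-weighted statistics will be",
              " degenerate", call. = FALSE)
  }
  if (!is.null(dQ)) {
    dQ <- as.numeric(dQ)
    if (length(dQ) != length(Q)) stop("dQ length mismatch", call. = FALSE)
    if (any(dQ < 0)) stop("dQ must be non-negative", call. = FALSE)
  }
  if (!is.numeric(fit_weight) || fit_weight <= 0)
    stop("fit_weight must be > 0", call. = FALSE)
  if (is.unsorted(Q, strictly = FALSE)) {
    warning("Q was not sorted; sorting", call. = FALSE)
    o <- order(Q)
    Q <- Q[o]; R <- R[o]
    if (!is.null(dR)) dR <- dR[o]
    if (!is.null(dQ)) dQ <- dQ[o]
  }
  structure(list(Q = Q, R = R, dR = dR, dQ = dQ,
                 source_path = source_path, fit_weight = fit_weight),
            class = "refl_curve")
}

#' @export
print.refl_curve <- function(x, ...) {
  cat(sprintf(
    "Reflectivity curve: %d points, Q in [%.5g, %.5g] 1/Angstrom%s%s\n",
    length(x$Q), min(x$Q), max(x$Q),
    if (!is.null(x$dR)) ", with dR" else "",
    if (!is.null(x$dQ)) ", with dQ" else ""))
  if (nzchar(x$source_path)) cat("  source:", x$source_path, "\n")
  invisible(x)
}

#' Read a reflectivity data file
#'
#' Accepts 2-, 3- or 4-column ASCII (`Q, R, dR, dQ`), whitespace or comma
#' delimited, `#` comment lines skipped.  `Q` (and `dQ`) are converted to
#' 1/Angstrom when given in 1/nm.  `dQ` is interpreted as the FWHM of a
#' Gaussian resolution function unless `dq_is_sigma`.
#'
#' @param path file path.
#' @param units `"inv_angstrom"` or `"inv_nanometre"`.
#' @param fit_weight relative co-refinement weight of this curve.
#' @param dq_is_sigma interpret the 4th column as sigma instead of FWHM.
#' @return object of class `refl_curve`.
#' @export
read_curve <- function(path, units = c("inv_angstrom", "inv_nanometre"),
                       fit_weight = 1, dq_is_sigma = FALSE) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("format error: '", path, "' holds no data rows",
                          call. = FALSE)
  rows <- lapply(keep, function(i) {
    toks <- strsplit(trimws(gsub(",", " ", lines[i])), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (any(is.na(vals)))
      stop("parse error: non-numeric entry on line ", i, " of '", path, "'",
           call. = FALSE)
    vals
  })
  ncol <- unique(vapply(rows, length, integer(1)))
  if (length(ncol) != 1L)
    stop("format error: inconsistent column count in '", path, "'",
         call. = FALSE)
  if (ncol < 2L || ncol > 4L)
    stop("format error: '", path, "' must have 2-4 columns (Q, R[, dR[, dQ]])",
         call. = FALSE)
  m <- do.call(rbind, rows)
  conv <- if (units == "inv_nanometre") 0.1 else 1
  cv <- refl_curve(Q = m[, 1] * conv, R = m[, 2],
                   dR = if (ncol >= 3L) m[, 3] else NULL,
                   dQ = if (ncol >= 4L) m[, 4] * conv else NULL,
                   source_path = path, fit_weight = fit_weight)
  if (isTRUE(dq_is_sigma) && !is.null(cv$dQ))
    cv$dQ <- cv$dQ / .FWHM_TO_SIGMA  # store FWHM internally
  cv
}

#' Write a reflectivity curve as ASCII
#'
#' Columns `Q R [dR [dQ]]`, full double precision, suitable for re-reading
#' with [read_curve()].
#'
#' @param curve a `refl_curve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "refl_curve"))
  cols <- list(curve$Q, curve$R)
  if (!is.null(curve$dR)) cols <- c(cols, list(curve$dR))
  if (!is.null(curve$dQ)) {
    if (is.null(curve$dR)) cols <- c(cols, list(rep(0, length(curve$Q))))
    cols <- c(cols, list(curve$dQ))
  }
  m <- do.call(cbind, cols)
  txt <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c("# Q R dR dQ"[length(cols) == 4L],
               "# Q R dR"[length(cols) == 3L],
               "# Q R"[length(cols) == 2L], txt), path)
  invisible(path)
}

#' Write a full fit report
#'
#' Writes, into `path`: `fit_log.txt` (best-fit parameters with
#' uncertainties, figure of merit, reduced chi-squared, and per-curve
#' resolved layer tables), `parameters.txt` (machine-readable key-value
#' table), one `curve_<i>_fit.dat` per curve (Q, R_model at full precision)
#' and one `profile_<i>_patch<p>.dat` per curve and patch (z, sld_re,
#' sld_im, phi_solv).
#'
#' @param result a [refl_fit()] object.
#' @param path output directory (created if absent).
#' @return invisible character vector of the files written.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "refl_fit"))
  if (!dir.exists(path))
    if (!dir.create(path, recursive = TRUE))
      stop("cannot create report directory '", path, "'", call. = FALSE)
  files <- character(0)
  sds <- result$sd
  tab <- data.frame(name = names(result$best), value = unname(result$best),
                    sd = if (is.null(sds)) NA_real_ else unname(sds),
                    lower = result$lower, upper = result$upper)

  log_file <- file.path(path, "fit_log.txt")
  con <- file(log_file, "w"); on.exit(close(con), add = TRUE)
  writeLines(sprintf("specular fit report  (seed %s, %d iterations)",
                     format(result$seed), result$iterations), con)
  writeLines(sprintf("FOM (%s): %.10g", result$fom_mode, result$fom), con)
  if (!is.null(result$chi2_red))
    writeLines(sprintf("reduced chi-squared: %.10g", result$chi2_red), con)
  writeLines(sprintf("free parameters: %d", result$n_free), con)
  writeLines("", con)
  writeLines("best-fit parameters:", con)
  for (i in seq_len(nrow(tab)))
    writeLines(sprintf("  %-18s %- .10g %s  [%g, %g]", tab$name[i],
                       tab$value[i],
                       if (is.na(tab$sd[i])) "(sd n/a)" else
                         sprintf("+/- %.4g", tab$sd[i]),
                       tab$lower[i], tab$upper[i]), con)
  for (i in seq_along(result$curves)) {
    writeLines(sprintf("\ncurve %d (%s), resolved layers:", i,
                       result$curves[[i]]$source_path), con)
    res <- resolve_system(result$model, result$values, curve_index = i)
    for (p in seq_along(res)) {
      writeLines(sprintf("  patch %d (coverage %.3f):", p,
                         attr(res, "coverages")[p]), con)
      df <- res[[p]]
      writeLines(sprintf("    %-3s %-12s %-12s %-10s %-10s %-8s %s", "idx",
                         "sld", "isld", "thick", "rough", "phi", "name"), con)
      for (j in seq_len(nrow(df)))
        writeLines(sprintf("    %-3d %-12.5g %-12.5g %-10.4g %-10.4g %-8.4g %s",
                           j - 1L, df$sld[j], df$isld[j], df$thickness[j],
                           df$roughness[j], df$solvent[j], df$name[j]), con)
    }
  }
  files <- c(files, log_file)

  par_file <- file.path(path, "parameters.txt")
  writeLines(c("# name value sd lower upper",
               sprintf("%s %.17g %s %.17g %.17g", tab$name, tab$value,
                       ifelse(is.na(tab$sd), "NA", sprintf("%.17g", tab$sd)),
                       tab$lower, tab$upper)), par_file)
  files <- c(files, par_file)

  for (i in seq_along(result$curves)) {
    f <- file.path(path, sprintf("curve_%d_fit.dat", i))
    m <- result$per_curve_model[[i]]
    writeLines(c("# Q R_model",
                 sprintf("%.17g %.17g", m$Q, m$R)), f)
    files <- c(files, f)
    prof <- sld_profile(result$model, result$values, curve_index = i)
    for (p in unique(prof$patch)) {
      pf <- file.path(path, sprintf("profile_%d_patch%d.dat", i, p))
      pp <- prof[prof$patch == p, ]
      writeLines(c("# z sld_re sld_im phi_solv",
                   sprintf("%.17g %.17g %.17g %.17g", pp$z, pp$sld_re,
                           pp$sld_im, pp$phi_solv)), pf)
      files <- c(files, pf)
    }
  }
  invisible(files)
}
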