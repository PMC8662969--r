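# Figures of merit for refinement.  Four variants over linear/log scale,
# with or without experimental errors:
#   linear_err : sum ((R_e - R_m)/dR)^2
#   log_err    : sum ((log10 R_e - log10 R_m) * R_e * ln10 / dR)^2
#                (error propagation: d(log10 R)^2 = [dR / (R ln10)]^2)
#   linear_noerr: sum (R_e - R_m)^2 / R_e          (1/R weighting)
#   log_noerr  : sum (log10 R_e - log10 R_m)^2
# Each curve contributes w_i * (1/p_i) * sum_j term_ij, with p_i the number
# of points of curve i.  Log modes drop points with non-positive R_e (count
# reported via a message); non-positive model values make the log terms
# non-finite and are treated as candidate rejections by the fitter.

.fom_modes <- c("linear_err", "log_err", "linear_noerr", "log_noerr")

#' Figure of merit of model curves against data
#'
#' @param curves list of [refl_curve()] objects (or a single curve).
#' @param models list of model reflectivity vectors evaluated on each
#'   curve's Q grid (already smeared, scaled and background-corrected).
#' @param mode one of `"linear_err"`, `"log_err"`, `"linear_noerr"`,
#'   `"log_noerr"`.
#' @param weights optional per-curve weights (default: each curve's
#'   `fit_weight`).
#' @param quiet suppress the dropped-point message for log modes.
#' @return the figure-of-merit value (non-negative scalar; may be `Inf`
#'   when a log mode meets a non-positive model value).
#' @export
compute_fom <- function(curves, models, mode = "linear_err", weights = NULL,
                        quiet = FALSE) {
  mode <- match.arg(mode, .fom_modes)
  if (inherits(curves, "refl_curve")) curves <- list(curves)
  if (is.numeric(models)) models <- list(models)
  if (length(curves) != length(models))
    stop("one model vector per curve is required", call. = FALSE)
  if (is.null(weights))
    weights <- vapply(curves, `[[`, numeric(1), "fit_weight")
  if (length(weights) != length(curves) || any(weights <= 0))
    stop("weights must be positive, one per curve", call. = FALSE)
  total <- 0
  dropped <- 0L
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    Rm <- models[[i]]
    if (length(Rm) != length(cv$Q))
      stop("model vector ", i, " does not match curve ", i, " in length",
           call. = FALSE)
    Re_ <- cv$R
    p_i <- length(Re_)
    if (mode %in% c("linear_err", "log_err")) {
      if (is.null(cv$dR))
        stop("FOM mode '", mode, "' requires dR on every curve",
             call. = FALSE)
      dR <- cv$dR
    }
    keep <- rep(TRUE, p_i)
    if (mode %in% c("log_err", "log_noerr", "linear_noerr"))
      keep <- Re_ > 0
    dropped <- dropped + sum(!keep)
    Re_k <- Re_[keep]
    Rm_k <- Rm[keep]
    if (mode %in% c("log_err", "log_noerr") && any(Rm_k <= 0)) {
      # a non-positive model value has no log: reject this candidate
      total <- Inf
      break
    }
    dR_k <- if (mode %in% c("linear_err", "log_err")) dR[keep] else NULL
    term <- switch(mode,
      linear_err = ((Re_k - Rm_k) / dR_k)^2,
      log_err = ((log10(Re_k) - log10(Rm_k)) * Re_k * log(10) / dR_k)^2,
      linear_noerr = (Re_k - Rm_k)^2 / Re_k,
      log_noerr = (log10(Re_k) - log10(Rm_k))^2)
    total <- total + weights[i] * sum(term) / p_i
  }
  if (dropped > 0L && !quiet)
    message("compute_fom: dropped ", dropped,
            " non-positive data point(s) in a log/1-over-R mode")
  total
}

# plain chi-squared statistic and point count over all curves (needs dR)
.chi2_stat <- function(curves, models) {
  chi2 <- 0; n <- 0L
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    if (is.null(cv$dR)) return(NULL)
    chi2 <- chi2 + sum(((cv$R - models[[i]]) / cv$dR)^2)
    n <- n + length(cv$Q)
  }
  list(chi2 = chi2, n = n)
}
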