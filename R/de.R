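# Differential evolution (rand/1/bin) global minimizer.

#' Differential-evolution minimisation
#'
#' rand/1/bin strategy: for each member a mutant
#' `v = x_r1 + F * (x_r2 - x_r3)` is built from three distinct random
#' members, mixed into the member by binomial crossover with rate `CR`, and
#' accepted when not worse.  Convergence when the population spread
#' satisfies `sd(f) <= reltol * |mean(f)| + reltol`.
#'
#' @param fn objective; must return a finite scalar (penalise internally).
#' @param lower,upper bounds (equal length, `lower <= upper`).
#' @param seed optional RNG seed.
#' @param popsize population size per dimension (population is
#'   `popsize * length(lower)`, at least 5).
#' @param F differential weight.
#' @param CR crossover rate.
#' @param maxiter maximum number of generations.
#' @param reltol relative convergence tolerance on the population spread.
#' @param init optional matrix of initial members (rows), e.g. to seed a
#'   restart; missing members are drawn uniformly.
#' @param trace set `TRUE` to record every accepted candidate (matrix
#'   attribute `"accepted"` with the objective value in the last column).
#' @return list with `par`, `value`, `iter`, `converged`, `nfev` (and the
#'   acceptance trace when requested).
#' @export
de_minimize <- function(fn, lower, upper, seed = NULL, popsize = 15,
                        F = 0.7, CR = 0.9, maxiter = 2000, reltol = 1e-8,
                        init = NULL, trace = FALSE) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(lower <= upper))
  if (!is.null(seed)) set.seed(seed)
  np <- max(5L, as.integer(popsize * d))
  pop <- matrix(runif(np * d, rep(lower, each = np), rep(upper, each = np)),
                np, d)
  if (!is.null(init)) {
    init <- rbind(init)
    k <- min(nrow(init), np)
    pop[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                   rep(lower, each = k)),
                              rep(upper, each = k))
  }
  f <- apply(pop, 1L, fn)
  nfev <- np
  acc <- if (trace) vector("list", 0L) else NULL
  converged <- FALSE
  iter <- 0L
  while (iter < maxiter) {
    iter <- iter + 1L
    for (i in seq_len(np)) {
      r <- sample.int(np - 1L, 3L)
      r <- r + (r >= i)                    # three distinct members != i
      v <- pop[r[1], ] + F * (pop[r[2], ] - pop[r[3], ])
      jrand <- sample.int(d, 1L)
      cross <- runif(d) < CR
      cross[jrand] <- TRUE
      u <- ifelse(cross, v, pop[i, ])
      u <- pmin(pmax(u, lower), upper)
      fu <- fn(u)
      nfev <- nfev + 1L
      if (fu <= f[i]) {
        pop[i, ] <- u
        f[i] <- fu
        if (trace) acc[[length(acc) + 1L]] <- c(u, fu)
      }
    }
    if (stats::sd(f) <= reltol * (abs(mean(f)) + reltol)) {
      converged <- TRUE
      break
    }
  }
  b <- which.min(f)
  out <- list(par = pop[b, ], value = f[b], iter = iter,
              converged = converged, nfev = nfev)
  if (trace)
    out$accepted <- if (length(acc)) do.call(rbind, acc) else
      matrix(numeric(0), 0L, d + 1L)
  out
}
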