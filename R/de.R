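#' Bounded differential evolution
#'
#' Global minimizer used as the first stage of parameter fitting, in the
#' best/1/bin flavour: each candidate is mutated around the current best
#' member with a difference vector scaled by a factor redrawn each
#' generation (dithering), then binomially recombined with the candidate.
#' The population is initialized by latin-hypercube sampling over the
#' bounds ([lhs::randomLHS()]), with the user-supplied initial point
#' injected as one member. Convergence is declared when the population
#' energies collapse (`sd <= tol * |mean|`).
#'
#' Randomness comes from R's global RNG stream, so a `set.seed()` before the
#' call makes the search fully reproducible.
#'
#' @param fn Objective, `function(par) -> numeric(1)`; non-finite values are
#'   treated as infinitely bad.
#' @param lower,upper Finite bound vectors.
#' @param init Optional initial point, injected into the starting population.
#' @param popmult Population size per free dimension (population is
#'   `popmult * d`, at least 15).
#' @param mutation Length-2 range for the per-generation dither of the
#'   mutation factor F.
#' @param recombination Crossover probability CR.
#' @param tol Relative convergence tolerance on the population energies.
#' @param maxiter Generation cap.
#' @return List with `par`, `value`, `iterations`, `nfev`, `converged`, and
#'   the final `population` matrix with its `energies` (useful for seeding
#'   several local refinements from distinct basins).
#' @export
differential_evolution <- function(fn, lower, upper, init = NULL,
                                   popmult = 15, mutation = c(0.5, 1),
                                   recombination = 0.7, tol = 0.01,
                                   maxiter = 200) {
  d <- length(lower)
  stopifnot(length(upper) == d, d >= 1L, all(is.finite(lower)), all(is.finite(upper)),
            all(lower <= upper))
  np <- max(as.integer(popmult * d), 15L)
  span <- upper - lower
  pop <- sweep(sweep(lhs::randomLHS(np, d), 2L, span, `*`), 2L, lower, `+`)
  if (!is.null(init)) pop[1L, ] <- pmin(pmax(init, lower), upper)
  safe_fn <- function(par) {
    v <- fn(par)
    if (!is.finite(v)) Inf else v
  }
  energies <- apply(pop, 1L, safe_fn)
  nfev <- np
  best_i <- which.min(energies)
  converged <- FALSE
  iter <- 0L
  while (iter < maxiter) {
    iter <- iter + 1L
    if (stats::sd(energies) <= 1e-12 + tol * abs(mean(energies))) {
      converged <- TRUE
      break
    }
    f_dither <- stats::runif(1L, mutation[1L], mutation[2L])
    for (i in seq_len(np)) {
      r <- sample(seq_len(np)[-i], 2L)
      mutant <- pop[best_i, ] + f_dither * (pop[r[1L], ] - pop[r[2L], ])
      cross <- stats::runif(d) < recombination
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      e_trial <- safe_fn(trial)
      nfev <- nfev + 1L
      if (e_trial <= energies[i]) {
        pop[i, ] <- trial
        energies[i] <- e_trial
        if (e_trial < energies[best_i]) best_i <- i
      }
    }
  }
  list(par = pop[best_i, ], value = energies[best_i],
       iterations = iter, nfev = nfev, converged = converged,
       population = pop, energies = energies)
}
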