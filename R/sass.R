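# SASS (Solis-Wets) stochastic hill climbing: the local-search component
# launched inside every species. Operates entirely in the normalized unit
# box; the maximum displacement is bounded by the species radius.

#' Construct a species
#'
#' A species couples a candidate solution (its center, a point in the
#' normalized unit box), the cached objective value at that center, and an
#' attraction radius: the Euclidean size of the region the species is
#' responsible for exploring.
#'
#' @param center numeric vector in `[0,1]^d`
#' @param fitness objective value at `center`
#' @param radius Euclidean radius in normalized space, > 0
#' @return a `uego_species` object
#' @export
new_species <- function(center, fitness, radius) {
  stopifnot(is.numeric(center), all(center >= 0 & center <= 1),
            is.finite(fitness), radius > 0)
  structure(list(center = center, fitness = fitness, radius = radius),
            class = "uego_species")
}

#' Solis-Wets stochastic hill climbing within a species
#'
#' Starting at the species center, repeatedly proposes
#' `center + radius * sigma * g` with `g` a standard Gaussian vector, the
#' displacement norm capped at `step_bound`, and the result clipped to the
#' unit box. A strictly better candidate moves the center (a success);
#' otherwise the move fails. The step scale `sigma` starts at the upper
#' bound 1, doubles after 5 consecutive successes, halves after 3
#' consecutive failures, and is clamped to `[1e-5, 1]`. The search stops
#' when the evaluation budget is exhausted or after 32 consecutive failed
#' or discarded moves. Proposals whose clipped displacement is zero are
#' discarded: they count toward the termination streak but consume no
#' evaluation.
#'
#' @param species a `uego_species`
#' @param objective function mapping a unit-box point to a finite value
#'   (lower is better)
#' @param budget maximum objective evaluations, >= 0
#' @param step_bound cap on the displacement norm; defaults to the species
#'   radius
#' @param sigma_init initial step scale
#' @return list with the updated `species`, `evals` (evaluations used) and
#'   `sigma` (final step scale)
#' @export
sass_search <- function(species, objective, budget,
                        step_bound = species$radius, sigma_init = 1) {
  stopifnot(inherits(species, "uego_species"), budget >= 0)
  center <- species$center
  best <- species$fitness
  d <- length(center)
  sigma <- min(max(sigma_init, 1e-5), 1)
  succ <- 0L; fail <- 0L; streak <- 0L; evals <- 0L

  while (evals < budget && streak < 32L) {
    step <- species$radius * sigma * rnorm(d)
    nrm <- sqrt(sum(step^2))
    if (nrm > step_bound) step <- step * (step_bound / nrm)
    cand <- pmin(pmax(center + step, 0), 1)
    if (all(cand == center)) {
      # fully clipped away: discarded move, no evaluation spent
      streak <- streak + 1L
      succ <- 0L
      fail <- fail + 1L
    } else {
      f <- objective(cand)
      evals <- evals + 1L
      if (is.finite(f) && f < best) {
        center <- cand; best <- f
        streak <- 0L; fail <- 0L
        succ <- succ + 1L
        if (succ >= 5L) { sigma <- min(sigma * 2, 1); succ <- 0L }
      } else {
        streak <- streak + 1L
        succ <- 0L
        fail <- fail + 1L
      }
    }
    if (fail >= 3L) { sigma <- max(sigma / 2, 1e-5); fail <- 0L }
  }
  list(species = new_species(center, best, species$radius),
       evals = evals, sigma = sigma)
}
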