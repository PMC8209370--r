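# UEGO: a multimodal memetic optimizer. A population of species (center +
# attraction radius) is evolved over levels whose creation radii cool
# geometrically from the search-space diameter down to a user minimum;
# each level creates species by a midpoint test, fuses overlapping ones,
# trims the population, and locally optimizes every species with SASS.

#' UEGO configuration
#'
#' @param M maximum number of species kept in the population
#' @param N maximum total objective evaluations
#' @param r_min minimum species radius in normalized space; final species
#'   are at least this far apart
#' @param levels number of search levels (radius-cooling cycles)
#' @param seed integer RNG seed; `NULL` leaves the current stream untouched
#' @return a `uego_config` object
#' @export
uego_config <- function(M = 100, N = 1e7, r_min = 0.7, levels = 50,
                        seed = NULL) {
  stopifnot(M >= 1, N >= 1, levels >= 1, r_min > 0)
  structure(list(M = as.integer(M), N = N, r_min = r_min,
                 levels = as.integer(levels), seed = seed),
            class = "uego_config")
}

#' Radius and evaluation-budget schedule across levels
#'
#' Radii cool geometrically from the search-space diameter (level 1) to
#' `r_min` (last level). The creation budget is `3 * M` evaluations at
#' every level from 2 on. The local-optimization budget ramps linearly
#' with the level index — later levels, which refine previously found
#' regions, receive more evaluations — and the whole schedule sums to at
#' most `N` (one evaluation is reserved for initialization).
#'
#' @param config a `uego_config`
#' @param diameter search-space diameter (Euclidean length of the unit-box
#'   main diagonal, `sqrt(d)`)
#' @return data.frame with columns `level`, `radius`, `creation_budget`,
#'   `optimization_budget`
#' @export
level_schedule <- function(config, diameter) {
  stopifnot(inherits(config, "uego_config"), diameter > 0)
  if (config$r_min > diameter)
    stop("r_min must not exceed the search-space diameter")
  l <- config$levels
  if (l == 1) {
    return(data.frame(level = 1L, radius = diameter, creation_budget = 0,
                      optimization_budget = max(config$N - 1, 0)))
  }
  radius <- diameter * (config$r_min / diameter)^((seq_len(l) - 1) / (l - 1))
  creation <- c(0, rep(3 * config$M, l - 1))
  B <- config$N - sum(creation) - 1
  if (B < 0) stop("N too small for the creation budgets (need > 3*M*(levels-1))")
  opt <- floor(B * seq_len(l) / sum(seq_len(l)))
  data.frame(level = seq_len(l), radius = radius, creation_budget = creation,
             optimization_budget = opt)
}

# Uniform draw inside a d-ball of radius R centered at `center`, clipped to
# the unit box: direction uniform on the sphere, length R * U^(1/d).
.sample_in_ball <- function(center, R) {
  d <- length(center)
  g <- rnorm(d)
  u <- runif(1)
  pt <- center + g / sqrt(sum(g^2)) * R * u^(1 / d)
  pmin(pmax(pt, 0), 1)
}

#' Create new species inside the regions of existing ones
#'
#' The creation budget is divided evenly among the current species. Within
#' each species' ball, random candidate points are drawn and evaluated, and
#' the midpoints of all pairs among them are evaluated too; the per-species
#' allotment covers both kinds of evaluation. When a midpoint is strictly
#' worse than both endpoints, the pair is assumed to straddle a valley
#' between two basins and both endpoints become new species with the
#' current level radius. Any evaluated point (sample or midpoint) strictly
#' better than the parent's center replaces it.
#'
#' @param population list of `uego_species`
#' @param level_radius radius assigned to newly created species
#' @param creation_budget total evaluations available for creation
#' @param objective the objective function on the unit box
#' @return list with the enlarged `population` and `evals` used
#' @export
create_species <- function(population, level_radius, creation_budget,
                           objective) {
  n_old <- length(population)
  evals <- 0L
  if (creation_budget < n_old) return(list(population = population,
                                           evals = 0L))
  allot <- floor(creation_budget / n_old)
  # largest m with m samples + choose(m, 2) midpoints within the allotment
  m <- floor((sqrt(1 + 8 * allot) - 1) / 2)
  newcomers <- list()
  for (si in seq_len(n_old)) {
    sp <- population[[si]]
    if (m < 1) next
    pts <- lapply(seq_len(m), function(i) .sample_in_ball(sp$center, sp$radius))
    fits <- vapply(pts, objective, numeric(1))
    evals <- evals + m
    best_i <- which.min(fits)
    if (fits[best_i] < sp$fitness)
      sp <- new_species(pts[[best_i]], fits[best_i], sp$radius)
    if (m >= 2) {
      for (i in seq_len(m - 1)) {
        for (j in (i + 1):m) {
          mid <- (pts[[i]] + pts[[j]]) / 2
          fmid <- objective(mid)
          evals <- evals + 1L
          if (fmid < sp$fitness)
            sp <- new_species(mid, fmid, sp$radius)
          if (fmid > fits[i] && fmid > fits[j]) {
            newcomers[[length(newcomers) + 1]] <-
              new_species(pts[[i]], fits[i], level_radius)
            newcomers[[length(newcomers) + 1]] <-
              new_species(pts[[j]], fits[j], level_radius)
          }
        }
      }
    }
    population[[si]] <- sp
  }
  list(population = c(population, newcomers), evals = evals)
}

#' Fuse species whose centers overlap at the current level radius
#'
#' While any two centers lie closer than `level_radius`, the pair is
#' replaced by a single species keeping the better (lower-fitness) center
#' and the larger of the two radii, so the explored region stays as broad
#' as possible. Scanning follows creation order; on equal fitness the
#' earlier-created center is kept. On return all pairwise center distances
#' are at least `level_radius`.
#'
#' @param population list of `uego_species`
#' @param level_radius fusion distance threshold
#' @return the fused population
#' @export
fuse_population <- function(population, level_radius) {
  repeat {
    fused <- FALSE
    n <- length(population)
    for (i in seq_len(max(n - 1, 0))) {
      for (j in (i + 1):n) {
        a <- population[[i]]; b <- population[[j]]
        if (sqrt(sum((a$center - b$center)^2)) < level_radius) {
          keep <- if (b$fitness < a$fitness) b else a
          population[[i]] <- new_species(keep$center, keep$fitness,
                                         max(a$radius, b$radius))
          population[[j]] <- NULL
          fused <- TRUE
          break
        }
      }
      if (fused) break
    }
    if (!fused) break
  }
  population
}

#' Trim the population to at most M species
#'
#' Species with the shortest radius are removed first (ties broken by
#' removing the worse fitness first) until the size is within range. The
#' full-diameter species always survives, so any point of the search space
#' stays reachable.
#'
#' @param population list of `uego_species`
#' @param M maximum population size
#' @return the trimmed population
#' @export
shorten_population <- function(population, M) {
  if (length(population) <= M) return(population)
  radii <- vapply(population, `[[`, numeric(1), "radius")
  fits <- vapply(population, `[[`, numeric(1), "fitness")
  # survivors: largest radius first; among equal radii, better fitness first
  keep <- order(-radii, fits)[seq_len(M)]
  population[sort(keep)]
}

#' Run the UEGO multimodal optimizer
#'
#' Executes the full level loop: a single random full-diameter species is
#' created and locally optimized (level 1); every later level computes its
#' cooled radius and budgets, creates species by the midpoint test, fuses
#' overlapping species, trims the population to `M`, locally optimizes
#' every species with [sass_search()] (budget split evenly), and fuses
#' again. Runs are bit-reproducible for a fixed `config$seed`.
#'
#' @param objective function on the unit box `[0,1]^d`, lower is better;
#'   non-finite values are treated as "never an improvement"
#' @param d dimension of the search space
#' @param config a `uego_config`
#' @param verbose print a one-line summary per level?
#' @return a `uego_result`: list with `population` (list of
#'   `uego_species`), `ledger` (data.frame per level: radius, species
#'   count, evaluations used, best fitness) and `evaluations` (total)
#' @export
run_uego <- function(objective, d, config = uego_config(), verbose = FALSE) {
  stopifnot(is.function(objective), d >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  diameter <- sqrt(d)
  sched <- level_schedule(config, diameter)

  count <- local({
    n <- 0L
    function(add = 0L) { n <<- n + add; n }
  })
  # every evaluation is counted; errors and non-finite values are mapped to
  # the divergence penalty so the search always sees a total ordering
  obj <- function(x) {
    count(1L)
    val <- tryCatch(objective(x), error = function(e) DIVERGENCE_PENALTY)
    if (!is.finite(val)) DIVERGENCE_PENALTY else val
  }

  center0 <- runif(d)
  population <- list(new_species(center0, obj(center0), diameter))

  ledger <- data.frame(level = integer(), radius = numeric(),
                       species = integer(), evaluations = numeric(),
                       best = numeric(), best_so_far = numeric())
  best_so_far <- population[[1]]$fitness
  for (lev in seq_len(nrow(sched))) {
    radius <- sched$radius[lev]
    ev0 <- count()
    if (lev > 1) {
      cr <- create_species(population, radius, sched$creation_budget[lev], obj)
      population <- fuse_population(cr$population, radius)
      population <- shorten_population(population, config$M)
    }
    opt_budget <- sched$optimization_budget[lev]
    share <- floor(opt_budget / length(population))
    for (si in seq_along(population)) {
      sr <- sass_search(population[[si]], obj, share)
      population[[si]] <- sr$species
    }
    population <- fuse_population(population, radius)
    best <- min(vapply(population, `[[`, numeric(1), "fitness"))
    best_so_far <- min(best_so_far, best)
    ledger <- rbind(ledger, data.frame(
      level = lev, radius = radius, species = length(population),
      evaluations = count() - ev0, best = best, best_so_far = best_so_far))
    if (verbose)
      message(sprintf("level %3d  radius %.4f  species %3d  evals %8d  best %.6g",
                      lev, radius, length(population), count() - ev0, best))
  }
  structure(list(population = population, ledger = ledger,
                 evaluations = count()),
            class = "uego_result")
}

#' @export
print.uego_result <- function(x, ...) {
  fits <- vapply(x$population, `[[`, numeric(1), "fitness")
  cat(sprintf("UEGO result: %d species, best fitness %.6g, %d evaluations\n",
              length(x$population), min(fits), x$evaluations))
  invisible(x)
}

#' Fit AdEx parameters to reference features with UEGO
#'
#' Convenience wrapper composing the whole pipeline: the objective maps a
#' unit-box point through [denormalize_parameters()], [extract_features()]
#' and [total_score()], and [run_uego()] searches it. The returned
#' candidates carry physical-unit parameters and score breakdowns.
#'
#' @param reference a `reference_features` object
#' @param suite the `protocol_suite` to stimulate with
#' @param bounds parameter bounds (defaults to the standard search box)
#' @param weights a `feature_weights` object
#' @param sim_config a `simulation_config`
#' @param uego a `uego_config`
#' @param n_cycles sinusoidal cycles analyzed per condition
#' @param verbose print per-level progress?
#' @return an `adex_fit`: the `uego_result` plus `candidates`, a
#'   data.frame with one row per surviving species (parameters in physical
#'   units, component scores, total, radius), sorted by ascending total
#' @export
fit_adex <- function(reference, suite, bounds = default_parameter_bounds(),
                     weights = feature_weights(),
                     sim_config = simulation_config(),
                     uego = uego_config(), n_cycles = 10, verbose = FALSE) {
  bounds <- validate_parameter_bounds(bounds)
  validate_reference(reference, suite)
  objective <- function(x) {
    p <- denormalize_parameters(x, bounds)
    fs <- extract_features(p, suite, sim_config, n_cycles)
    total_score(fs, reference, weights)$total
  }
  res <- run_uego(objective, d = nrow(bounds), config = uego,
                  verbose = verbose)
  res$candidates <- rank_candidates(res$population, reference, suite,
                                    bounds, weights, sim_config, n_cycles)
  class(res) <- c("adex_fit", class(res))
  res
}
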