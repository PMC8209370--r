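test_that("normalization maps bound corners to box corners and round-trips", {
  b <- default_parameter_bounds()
  lower <- as_adex_parameters(setNames(b$lower, b$parameter))
  upper <- as_adex_parameters(setNames(b$upper, b$parameter))
  expect_equal(normalize_parameters(lower), rep(0, 10))
  expect_equal(normalize_parameters(upper), rep(1, 10))
  expect_equal(sqrt(sum((rep(1, 10))^2)), sqrt(10))

  set.seed(1)
  for (i in 1:20) {
    x <- runif(10)
    back <- normalize_parameters(denormalize_parameters(x))
    expect_lt(max(abs(back - x)), 1e-12)
  }
  expect_error(denormalize_parameters(c(rep(0.5, 9), 1.5)), "unit box")
})

test_that("the level schedule cools geometrically from diameter to r_min", {
  cfg <- uego_config(M = 100, N = 1e7, r_min = 0.7, levels = 50)
  sched <- level_schedule(cfg, sqrt(10))
  expect_equal(sched$radius[1], sqrt(10))
  expect_equal(sched$radius[50], 0.7)
  ratios <- sched$radius[-1] / sched$radius[-50]
  expect_lt(max(abs(ratios - ratios[1])), 1e-12)
  expect_true(all(diff(sched$radius) < 0))
  expect_true(all(sched$creation_budget[-1] == 300))
  expect_true(all(diff(sched$optimization_budget) >= 0))
  expect_lte(sum(sched$creation_budget) + sum(sched$optimization_budget) + 1,
             cfg$N)
})

test_that("a single-level run degenerates to one locally optimized species", {
  res <- run_uego(sphere_objective, d = 2,
                  uego_config(M = 10, N = 500, r_min = 0.05, levels = 1,
                              seed = 7))
  expect_length(res$population, 1)
  expect_equal(res$population[[1]]$radius, sqrt(2))
  # local search improved on the random initial point
  expect_lt(res$population[[1]]$fitness, res$ledger$best_so_far[1] + 1e-12)
})

test_that("the midpoint test creates species across wells but not on convex bowls", {
  # species spanning both wells of the bimodal objective
  sp <- list(new_species(0.5, bimodal_objective(0.5), 1))
  created <- 0
  for (seed in 1:10) {
    set.seed(seed)
    out <- create_species(sp, level_radius = 0.2, creation_budget = 40,
                          objective = bimodal_objective)
    created <- created + (length(out$population) > 1)
    expect_gt(out$evals, 0)
  }
  expect_gte(created, 9)

  # a convex bowl never triggers the midpoint test
  for (seed in 1:10) {
    set.seed(seed)
    out <- create_species(list(new_species(c(0.5, 0.5), 0.0, 1)),
                          level_radius = 0.2, creation_budget = 40,
                          objective = sphere_objective)
    expect_length(out$population, 1)
  }
})

test_that("creation moves the parent center to strictly better points", {
  set.seed(5)
  sp <- list(new_species(c(0.9, 0.9), sphere_objective(c(0.9, 0.9)), 1))
  out <- create_species(sp, 0.2, 40, sphere_objective)
  expect_lt(out$population[[1]]$fitness, sphere_objective(c(0.9, 0.9)))
})

test_that("starved creation budgets leave the population unchanged", {
  pop <- replicate(5, new_species(runif(2), 1, 0.5), simplify = FALSE)
  out <- create_species(pop, 0.2, creation_budget = 3,
                        objective = sphere_objective)
  expect_identical(out$population, pop)
  expect_identical(out$evals, 0L)
})

test_that("fusion keeps the better center and the larger radius", {
  a <- new_species(c(0.5, 0.5), 5, sqrt(10))
  b <- new_species(c(0.5 + 0.3, 0.5), 3, 0.9)
  fused <- fuse_population(list(a, b), level_radius = 0.7)
  expect_length(fused, 1)
  expect_equal(fused[[1]]$center, b$center)
  expect_equal(fused[[1]]$fitness, 3)
  expect_equal(fused[[1]]$radius, sqrt(10))

  # non-overlapping species are untouched
  a2 <- new_species(c(0.1, 0.1), 5, 1)
  c2 <- new_species(c(0.9, 0.9), 1, 0.5)
  kept <- fuse_population(list(a2, c2), level_radius = 0.7)
  expect_length(kept, 2)
})

test_that("after fusion all pairwise center distances reach the level radius", {
  for (seed in 1:10) {
    set.seed(seed)
    pop <- random_population(15, 3)
    out <- fuse_population(pop, level_radius = 0.4)
    if (length(out) >= 2) {
      centers <- t(vapply(out, `[[`, numeric(3), "center"))
      D <- as.matrix(dist(centers))
      expect_gte(min(D[upper.tri(D)]), 0.4)
    }
  }
})

test_that("shortening removes the shortest radii and keeps the full-diameter species", {
  set.seed(6)
  pop <- random_population(103, 2, radii = runif(103, 0.1, 0.6))
  pop[[50]] <- new_species(runif(2), 0.9, sqrt(2))  # full-diameter species
  out <- shorten_population(pop, 100)
  expect_length(out, 100)
  removed_radii <- sort(vapply(pop, `[[`, numeric(1), "radius"))[1:3]
  kept_radii <- vapply(out, `[[`, numeric(1), "radius")
  expect_gte(min(kept_radii), max(removed_radii))
  expect_true(any(kept_radii == sqrt(2)))
  expect_identical(shorten_population(pop[1:10], 100), pop[1:10])
})

test_that("full runs respect the population, radius and budget invariants", {
  cfg <- uego_config(M = 10, N = 5000, r_min = 0.05, levels = 5, seed = 11)
  res <- run_uego(sphere_objective, d = 2, cfg)
  expect_lte(min(vapply(res$population, `[[`, numeric(1), "fitness")), 1e-3)
  expect_true(all(res$ledger$species <= cfg$M))
  expect_lte(res$evaluations, cfg$N)
  expect_equal(sum(res$ledger$evaluations) + 1, res$evaluations)
  # a full-diameter species always survives
  expect_equal(max(vapply(res$population, `[[`, numeric(1), "radius")),
               sqrt(2))
  # best-so-far is monotone and the per-level best never worsens
  expect_true(all(diff(res$ledger$best_so_far) <= 0))
  expect_true(all(diff(res$ledger$best) <= 1e-12))
  # final population spaced at least the last-level radius apart
  if (length(res$population) >= 2) {
    centers <- t(vapply(res$population, `[[`, numeric(2), "center"))
    D <- as.matrix(dist(centers))
    expect_gte(min(D[upper.tri(D)]), cfg$r_min)
  }
  # seeded runs are bit-identical
  res2 <- run_uego(sphere_objective, d = 2, cfg)
  expect_identical(res$population, res2$population)
  expect_identical(res$ledger, res2$ledger)
})

test_that("two equal wells separated beyond r_min are both represented", {
  res <- run_uego(bimodal_objective, d = 1,
                  uego_config(M = 10, N = 4000, r_min = 0.05, levels = 6,
                              seed = 3))
  centers <- vapply(res$population, `[[`, numeric(1), "center")
  expect_true(any(abs(centers - 0.2) < 0.025))
  expect_true(any(abs(centers - 0.8) < 0.025))
})

test_that("erroring objectives are absorbed as penalties, not raised", {
  flaky <- function(x) if (x[1] > 0.9) stop("boom") else sphere_objective(x)
  res <- run_uego(flaky, d = 1,
                  uego_config(M = 5, N = 500, r_min = 0.1, levels = 3,
                              seed = 2))
  expect_true(is.finite(min(vapply(res$population, `[[`, numeric(1),
                                   "fitness"))))
})
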