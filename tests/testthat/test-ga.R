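test_that("GA configuration defaults and count validation", {
  cfg <- ga_config()
  expect_equal(cfg$population_size, 100L)
  expect_equal(cfg$iterations, 25L)
  expect_equal(cfg$n_best, 5L)
  expect_equal(cfg$n_random, 25L)
  expect_equal(cfg$n_cross, 30L)
  expect_equal(cfg$n_mutate, 2L)
  expect_equal(cfg$fitness_metric, "rmse")
  expect_error(ga_config(population_size = 50), "exceeds")
  expect_error(ga_config(fitness_metric = "nope"), "unknown")
  path <- withr::local_tempfile(fileext = ".json")
  write_ga_config(ga_config(iterations = 7, rng_seed = 3), path)
  back <- read_ga_config(path)
  expect_equal(back$iterations, 7L)
  expect_equal(back$rng_seed, 3)
})

test_that("fitness metrics behave on simple spectra", {
  expect_equal(fitness_rmse(c(0, 0, 0), c(0.1, 0.1, 0.1)), 0.1)
  x <- runif(10)
  expect_equal(fitness_alternates(x, x, "gfc"), 1)
  expect_equal(fitness_alternates(x, 2 * x, "gfc"), 1)
  expect_equal(fitness_alternates(c(1, 0), c(0, 1), "gfc"), 0)
})

test_that("initial population is in bounds, sized, and seed-reproducible", {
  b <- param_bounds()
  pop <- init_population(b, 100, seed = 42)
  expect_equal(nrow(pop$genes), 100)
  expect_true(all(pop$genes >= matrix(b[, 1], 100, 5, byrow = TRUE)))
  expect_true(all(pop$genes <= matrix(b[, 2], 100, 5, byrow = TRUE)))
  pop2 <- init_population(b, 100, seed = 42)
  expect_identical(pop$genes, pop2$genes)
})

test_that("evolution is elitist and tracks the generation counter", {
  m <- forward_spectrum(mid_params, default_ctx)
  cfg <- ga_config()
  set.seed(1)
  pop <- init_population(n = cfg$population_size)
  best <- Inf
  for (i in 1:25) {
    pop <- evolve_step(pop, m, cfg, default_ctx)
    expect_lte(pop$cost[1], best + 1e-15)
    best <- pop$cost[1]
  }
  expect_equal(pop$generation, 25L)
  b <- param_bounds()
  expect_true(all(pop$genes >= matrix(b[, 1], 100, 5, byrow = TRUE) - 1e-12))
  expect_true(all(pop$genes <= matrix(b[, 2], 100, 5, byrow = TRUE) + 1e-12))
})

test_that("inversion is deterministic under a fixed seed and stays in bounds", {
  m <- forward_spectrum(mid_params, default_ctx)
  cfg <- ga_config(rng_seed = 5)
  f1 <- invert_spectrum(m, cfg, default_ctx)
  f2 <- invert_spectrum(m, cfg, default_ctx)
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$fitness, f2$fitness)
  # arbitrary (even unphysical) input still yields in-bounds output
  junk <- rep(0.42, 37)
  fj <- invert_spectrum(junk, ga_config(rng_seed = 1), default_ctx)
  expect_silent(skinoptics:::check_in_bounds(unclass(fj$params),
                                             param_bounds()))
})

test_that("noise-free spectra are recovered within 2% at a generous budget", {
  cfg <- ga_config(population_size = 200, iterations = 100, n_best = 10,
                   n_random = 50, n_cross = 60, n_mutate = 4,
                   rng_seed = 4)
  m <- forward_spectrum(mid_params, default_ctx)
  fit <- invert_spectrum(m, cfg, default_ctx)
  rel <- 100 * abs(unclass(fit$params) - unclass(mid_params)) /
    unclass(mid_params)
  expect_lt(max(rel), 2)
  expect_lt(fit$fitness, 1e-3)
})

test_that("recovery error decreases with iteration budget (median over seeds)", {
  m <- forward_spectrum(mid_params, default_ctx)
  err_at <- function(iters, seed) {
    cfg <- ga_config(iterations = iters, rng_seed = seed)
    fit <- invert_spectrum(m, cfg, default_ctx)
    mean(100 * abs(unclass(fit$params) - unclass(mid_params)) /
           unclass(mid_params))
  }
  seeds <- 1:5
  small <- median(sapply(seeds, function(s) err_at(2, s)))
  large <- median(sapply(seeds, function(s) err_at(40, s)))
  expect_lt(large, small)
})

test_that("best-fitness trace is non-increasing over a full run", {
  m <- forward_spectrum(mid_params, default_ctx)
  fit <- invert_spectrum(m, ga_config(rng_seed = 9), default_ctx,
                         trace = TRUE)
  expect_true(all(diff(fit$trace) <= 1e-15))
  expect_equal(fit$fitness, fit$trace[length(fit$trace)])
})

test_that("accuracy experiment reports per-parameter errors and clean-limit behaviour", {
  # noise-free, generous budget: errors approach zero
  cfg <- ga_config(population_size = 200, iterations = 100, n_best = 10,
                   n_random = 50, n_cross = 60, n_mutate = 4)
  ae <- accuracy_experiment(param_sets = list(mid = mid_params),
                            cfg = cfg, noise_amplitude = 0,
                            n_repeats = 2, seed = 3)
  expect_s3_class(ae, "accuracy_experiment")
  expect_named(ae$mean_error,
               c("f_mel", "d_epi", "f_blood", "c_oxy", "d_dermis"))
  expect_lt(ae$overall_mean_error, 2)
  expect_lt(ae$mean_best_rmse, 1e-3)
  expect_equal(nrow(ae$results), 2 * 5)
})
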