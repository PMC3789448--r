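#' Genetic-algorithm configuration
#'
#' Settings of the bounded real-coded GA that inverts the two-layer
#' Kubelka-Munk model.  The defaults are the empirically selected
#' configuration used throughout: population 100, 25 generations, RMSE
#' fitness, 5 elite copies, 25 randomly kept individuals, 30 crossover
#' operations (each producing two offspring) and 2 mutations per
#' generation.  5 + 25 + 60 offspring leave 10 slots, refilled with
#' fresh uniform-random individuals each generation to keep the
#' population size constant and preserve diversity.
#'
#' @param population_size individuals per generation.
#' @param iterations number of generations (the termination criterion).
#' @param n_best elite individuals copied unchanged.
#' @param n_random individuals kept by random selection.
#' @param n_cross crossover operations per generation (2 offspring each).
#' @param n_mutate offspring receiving a one-gene uniform mutation.
#' @param fitness_metric one of `"rmse"`, `"gfc"`, `"recp"`, `"msas"`,
#'   `"ssv"`; similarity-type metrics are internally converted to costs.
#' @param creep_factor scale of the recombination creep noise relative
#'   to the per-gene spread of the best quarter of the population (see
#'   [evolve_step()]).
#' @param creep_floor minimum creep, as a fraction of each gene's bound
#'   range.
#' @param rng_seed optional integer seed for reproducible runs.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 100, iterations = 25,
                      n_best = 5, n_random = 25, n_cross = 30,
                      n_mutate = 2, fitness_metric = "rmse",
                      creep_factor = 0.5, creep_floor = 1e-6,
                      rng_seed = NULL) {
  cfg <- list(population_size = as.integer(population_size),
              iterations = as.integer(iterations),
              n_best = as.integer(n_best),
              n_random = as.integer(n_random),
              n_cross = as.integer(n_cross),
              n_mutate = as.integer(n_mutate),
              fitness_metric = fitness_metric,
              creep_factor = creep_factor,
              creep_floor = creep_floor,
              rng_seed = rng_seed)
  if (cfg$creep_factor < 0 || cfg$creep_floor < 0)
    stop("creep_factor and creep_floor must be non-negative")
  if (cfg$population_size < 1 || cfg$iterations < 0)
    stop("population_size must be >= 1 and iterations >= 0")
  n_fixed <- cfg$n_best + cfg$n_random + 2L * cfg$n_cross
  if (n_fixed > cfg$population_size)
    stop("n_best + n_random + 2*n_cross exceeds population_size")
  if (cfg$n_mutate > 2L * cfg$n_cross)
    stop("cannot mutate more offspring than crossover produces")
  fitness_cost(cfg$fitness_metric)  # validate metric name
  structure(cfg, class = "ga_config")
}

#' Read / write a GA configuration as JSON
#'
#' @param path JSON file path.
#' @param cfg a [ga_config()].
#' @return `read_ga_config` returns a [ga_config()].
#' @export
read_ga_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(ga_config, cfg[intersect(names(cfg), names(formals(ga_config)))])
}

#' @rdname read_ga_config
#' @export
write_ga_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' RMSE fitness between measured and simulated spectra
#'
#' The default GA fitness: [spectral_rmse()] with a grid check.  Lower
#' is better.
#'
#' @param measured,simulated spectra on the same grid
#'   (numeric vectors or [spectrum_on_grid()] objects).
#' @return Non-negative RMSE.
#' @export
fitness_rmse <- function(measured, simulated) {
  spectral_rmse(measured, simulated)
}

#' Alternate fitness metrics
#'
#' Evaluates one of the similarity metrics considered for the GA
#' fitness: `"gfc"`, `"recp"`, `"msas"` or `"ssv"` (see
#' [spectral_rmse()] for definitions).  Returned on the metric's own
#' scale (e.g. GFC in \[0, 1\], larger better); the GA converts to a
#' minimisable cost internally.
#'
#' @inheritParams fitness_rmse
#' @param metric metric name.
#' @return Metric value.
#' @export
fitness_alternates <- function(measured, simulated,
                               metric = c("gfc", "recp", "msas", "ssv")) {
  metric <- match.arg(metric)
  switch(metric,
         gfc = spectral_gfc(measured, simulated),
         recp = spectral_recp(measured, simulated),
         msas = spectral_msas(measured, simulated),
         ssv = spectral_ssv(measured, simulated))
}

#' Initial GA population
#'
#' Each individual is a real-valued vector of the five skin parameters,
#' every gene drawn uniformly within its physical bound.
#'
#' @param bounds a [param_bounds()].
#' @param n population size.
#' @param seed optional integer seed.
#' @return A list of class `ga_population`: `genes` (n x 5 matrix),
#'   `cost` (`NULL` until evaluated), `generation` (0).
#' @export
init_population <- function(bounds = param_bounds(), n = 100,
                            seed = NULL) {
  stopifnot(n > 0)
  if (!is.null(seed)) set.seed(seed)
  genes <- random_genes(n, bounds)
  structure(list(genes = genes, cost = NULL, generation = 0L),
            class = "ga_population")
}

random_genes <- function(n, bounds) {
  lo <- bounds[, "min"]; hi <- bounds[, "max"]
  g <- matrix(runif(n * 5), n, 5)
  g <- sweep(g, 2, hi - lo, "*")
  g <- sweep(g, 2, lo, "+")
  colnames(g) <- param_names
  g
}

# Cost of every individual against the measured spectrum.  RMSE has a
# fully vectorised fast path; other metrics loop over columns.
population_cost <- function(genes, measured, cfg, ctx) {
  if (NROW(genes) == 0) return(numeric(0))
  sims <- km_reflectance_batch(genes, ctx)
  m <- as_values(measured)
  if (length(m) != nrow(sims))
    stop("measured spectrum is not on the model grid")
  if (cfg$fitness_metric == "rmse") {
    sqrt(colMeans((sims - m)^2))
  } else {
    cost <- fitness_cost(cfg$fitness_metric)
    apply(sims, 2, function(s) cost(m, s))
  }
}

evaluate_population <- function(pop, measured, cfg, ctx) {
  cost <- population_cost(pop$genes, measured, cfg, ctx)
  ord <- order(cost)
  pop$genes <- pop$genes[ord, , drop = FALSE]
  pop$cost <- cost[ord]
  pop
}

#' One GA generation
#'
#' Assembles the next generation from an evaluated (cost-sorted)
#' population in four groups:
#'
#' * `n_cross` crossover operations, each swapping one randomly chosen
#'   gene between two rank-weighted randomly chosen parents to produce
#'   two offspring.  Every offspring gene then receives a small
#'   zero-mean Gaussian "creep" perturbation whose scale adapts to the
#'   per-gene spread of the best quarter of the population
#'   (`creep_factor` times that spread, floored at `creep_floor` of
#'   the bound range, clipped to the bounds).  The creep is what lets
#'   a real-coded population refine continuous genes: gene swapping
#'   alone can only rearrange values already present and stalls once
#'   the population has concentrated.
#' * `n_mutate` of those offspring additionally get one gene redrawn
#'   uniformly within its full bound (exploration).
#' * Survivor selection: the best `n_best + 2 n_cross` individuals of
#'   the union of the current population and the offspring are kept,
#'   so elites survive and offspring must compete with their parents.
#' * Diversity: `n_random` individuals drawn at random from the
#'   current population plus fresh uniform-random individuals filling
#'   the remaining slots join unconditionally (they are protected from
#'   survivor selection for one generation).
#'
#' The new generation is evaluated and sorted before return; with
#' `n_best >= 1` the best fitness is non-increasing across steps.
#'
#' @param pop an evaluated `ga_population` (see [init_population()];
#'   unevaluated populations are evaluated first).
#' @param measured target spectrum on the context grid.
#' @param cfg a [ga_config()].
#' @param ctx a [km_context()].
#' @param bounds a [param_bounds()].
#' @return The evaluated next-generation `ga_population`.
#' @export
evolve_step <- function(pop, measured, cfg = ga_config(),
                        ctx = km_context(), bounds = param_bounds()) {
  stopifnot(inherits(pop, "ga_population"))
  n <- cfg$population_size
  if (nrow(pop$genes) != n)
    stop("population size does not match cfg$population_size")
  if (is.null(pop$cost))
    pop <- evaluate_population(pop, measured, cfg, ctx)

  lo <- bounds[, "min"]; hi <- bounds[, "max"]; rng <- hi - lo
  n_off <- 2L * cfg$n_cross

  kept <- pop$genes[sample.int(n, cfg$n_random), , drop = FALSE]

  # adaptive creep scale from the best quarter of the population
  topk <- max(2L, n %/% 4L)
  sig <- cfg$creep_factor * apply(pop$genes[seq_len(topk), , drop = FALSE],
                                  2, sd) + cfg$creep_floor * rng

  offspring <- matrix(NA_real_, 0, 5)
  if (cfg$n_cross > 0) {
    # rank-weighted parent choice: weight n..1 on the sorted population
    w <- rev(seq_len(n))
    i1 <- sample.int(n, cfg$n_cross, replace = TRUE, prob = w)
    i2 <- sample.int(n, cfg$n_cross, replace = TRUE, prob = w)
    gi <- sample.int(5, cfg$n_cross, replace = TRUE)
    A <- pop$genes[i1, , drop = FALSE]
    B <- pop$genes[i2, , drop = FALSE]
    for (i in seq_len(cfg$n_cross)) {
      tmp <- A[i, gi[i]]; A[i, gi[i]] <- B[i, gi[i]]; B[i, gi[i]] <- tmp
    }
    offspring <- rbind(A, B)
    offspring <- offspring +
      matrix(rnorm(n_off * 5), n_off, 5) *
      matrix(sig, n_off, 5, byrow = TRUE)
    offspring <- pmin(pmax(offspring,
                           matrix(lo, n_off, 5, byrow = TRUE)),
                      matrix(hi, n_off, 5, byrow = TRUE))
    if (cfg$n_mutate > 0) {
      for (i in sample.int(n_off, cfg$n_mutate)) {
        g <- sample.int(5, 1)
        offspring[i, g] <- runif(1, lo[g], hi[g])
      }
    }
  }

  # survivor selection over parents + offspring
  pool <- rbind(pop$genes, offspring)
  pool_cost <- c(pop$cost, population_cost(offspring, measured, cfg, ctx))
  keep_n <- cfg$n_best + nrow(offspring)
  ord <- order(pool_cost)
  survivors <- pool[ord[seq_len(keep_n)], , drop = FALSE]

  n_fill <- n - keep_n - cfg$n_random
  fresh <- random_genes(n_fill, bounds)

  genes <- rbind(survivors, kept, fresh)
  colnames(genes) <- param_names
  nxt <- structure(list(genes = genes, cost = NULL,
                        generation = pop$generation + 1L),
                   class = "ga_population")
  evaluate_population(nxt, measured, cfg, ctx)
}

#' Invert a reflectance spectrum into skin parameters
#'
#' Runs the genetic algorithm for `cfg$iterations` generations and
#' returns the best individual found.  All genes stay within `bounds`
#' by construction, so the retrieval can never produce unphysical
#' values.
#'
#' @param measured measured reflectance spectrum on the context grid
#'   (values in \[0, 1\]).
#' @inheritParams evolve_step
#' @param trace if `TRUE`, also return the best cost per generation.
#' @return A list of class `ga_fit`: `params` ([skin_params()]),
#'   `fitness` (best cost), `generation`, and optionally `trace`.
#' @examples
#' ctx <- km_context()
#' p0 <- skin_params(0.1, 0.05, 0.02, 0.7, 1.2)
#' sp <- forward_spectrum(p0, ctx)
#' fit <- invert_spectrum(sp, ga_config(rng_seed = 1), ctx = ctx)
#' fit$params
#' @export
invert_spectrum <- function(measured, cfg = ga_config(),
                            ctx = km_context(), bounds = param_bounds(),
                            trace = FALSE) {
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  pop <- init_population(bounds, cfg$population_size)
  pop <- evaluate_population(pop, measured, cfg, ctx)
  tr <- if (trace) numeric(cfg$iterations) else NULL
  for (it in seq_len(cfg$iterations)) {
    pop <- evolve_step(pop, measured, cfg, ctx, bounds)
    if (trace) tr[it] <- pop$cost[1]
  }
  best <- pop$genes[1, ]
  structure(list(
    params = skin_params(best[1], best[2], best[3], best[4], best[5],
                         bounds = bounds),
    fitness = pop$cost[1],
    generation = pop$generation,
    trace = tr
  ), class = "ga_fit")
}

#' @export
print.ga_fit <- function(x, ...) {
  cat(sprintf("<ga_fit> generation %d, fitness %.4g\n",
              x$generation, x$fitness))
  print(x$params)
  invisible(x)
}

#' Characteristic lightly / darkly pigmented parameter sets
#'
#' Two in-bounds parameter sets used by the retrieval accuracy
#' experiment: a lightly pigmented skin (low melanosome fraction, well
#' oxygenated) and a darkly pigmented one (high melanosome fraction,
#' thicker layers).
#'
#' @return A named list of two [skin_params()].
#' @export
characteristic_params <- function() {
  list(light = skin_params(0.055, 0.04, 0.012, 0.65, 1.0),
       dark = skin_params(0.41, 0.06, 0.010, 0.45, 2.0))
}

#' Retrieval accuracy experiment
#'
#' For each parameter set: simulate its forward spectrum, add white
#' Gaussian noise of the given amplitude (sigma = amplitude / 3,
#' clipped to \[0, 1\]), invert the noisy spectrum with the GA, and
#' record the per-parameter relative error (%) and the RMSE of the
#' best-fit spectrum against the *noise-free* ground truth.  The whole
#' test is repeated `n_repeats` times with derived seeds and averaged.
#'
#' @param param_sets list of [skin_params()]; defaults to
#'   [characteristic_params()].
#' @param cfg a [ga_config()].
#' @param noise_amplitude noise amplitude (3 sigma) in reflectance
#'   units.
#' @param n_repeats repetitions per parameter set.
#' @param seed master seed; per-repeat seeds are derived from it.
#' @param ctx a [km_context()].
#' @param bounds a [param_bounds()].
#' @return A list of class `accuracy_experiment`: `results` (long data
#'   frame of per-repeat errors), `mean_error` (per-parameter mean
#'   relative error, %), `overall_mean_error` (%), `mean_best_rmse`
#'   (mean RMSE of the best fit vs the noise-free spectrum).
#' @export
accuracy_experiment <- function(param_sets = characteristic_params(),
                                cfg = ga_config(),
                                noise_amplitude = 0.1, n_repeats = 10,
                                seed = 1, ctx = km_context(),
                                bounds = param_bounds()) {
  stopifnot(length(param_sets) >= 1, n_repeats >= 1)
  if (is.null(names(param_sets)))
    names(param_sets) <- paste0("set", seq_along(param_sets))
  rows <- list()
  rmses <- numeric(0)
  for (s in names(param_sets)) {
    p0 <- unclass(param_sets[[s]])[param_names]
    check_in_bounds(p0, bounds)
    clean <- forward_spectrum(param_sets[[s]], ctx, bounds = bounds)
    for (r in seq_len(n_repeats)) {
      rseed <- derive_seed(seed, match(s, names(param_sets)) * 1000L + r)
      noisy <- add_noise(clean$values, noise_amplitude, seed = rseed)
      cfg_r <- cfg
      cfg_r$rng_seed <- derive_seed(rseed, 77L)
      fit <- invert_spectrum(noisy, cfg_r, ctx, bounds)
      est <- unclass(fit$params)[param_names]
      best_sp <- forward_spectrum(fit$params, ctx, check_bounds = FALSE)
      rmses <- c(rmses, spectral_rmse(clean, best_sp))
      rows[[length(rows) + 1L]] <- data.frame(
        set = s, rep = r, param = param_names,
        true = unname(p0), estimated = unname(est),
        rel_error_pct = unname(100 * abs(est - p0) / p0),
        row.names = NULL)
    }
  }
  results <- do.call(rbind, rows)
  mean_error <- tapply(results$rel_error_pct, results$param, mean)
  mean_error <- mean_error[param_names]
  structure(list(results = results,
                 mean_error = mean_error,
                 overall_mean_error = mean(results$rel_error_pct),
                 mean_best_rmse = mean(rmses)),
            class = "accuracy_experiment")
}

#' @export
print.accuracy_experiment <- function(x, ...) {
  cat("<accuracy_experiment>\n  mean relative error (%):\n")
  for (p in names(x$mean_error))
    cat(sprintf("    %-9s %6.3f\n", p, x$mean_error[[p]]))
  cat(sprintf("  overall mean error: %.3f %%\n", x$overall_mean_error))
  cat(sprintf("  mean best RMSE vs noise-free spectrum: %.3g\n",
              x$mean_best_rmse))
  invisible(x)
}

# Deterministic, 32-bit-safe seed derivation (stated counter scheme:
# products stay well below 2^53 so doubles are exact).
derive_seed <- function(seed, counter) {
  as.integer(((seed %% 2147483647) * 131 + counter * 7919) %% 2147483647)
}
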