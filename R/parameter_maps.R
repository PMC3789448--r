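#' Invert a reflectance cube into skin parameter maps
#'
#' Runs the genetic-algorithm inversion independently at every
#' `stride`-th pixel of the cube, producing five co-registered
#' parameter maps plus a fitness map and a mask of inverted pixels.
#' Each pixel gets a deterministic seed derived from the master seed
#' and its *absolute* image coordinates, so a cropped sub-window
#' ([crop_cube()]) inverts to exactly the corresponding sub-window of
#' the full result, and stride/subset runs are composable.  Pixels
#' with `NA` spectra (flagged invalid during calibration) are skipped.
#'
#' @param cube a [reflectance_cube()].
#' @param cfg a [ga_config()]; its `rng_seed` is ignored in favour of
#'   the per-pixel scheme.
#' @param bounds a [param_bounds()].
#' @param stride invert every `stride`-th pixel in both directions.
#' @param seed master integer seed.
#' @param ctx optional [km_context()] on the cube grid (built if
#'   missing).
#' @param table,scattering used to build `ctx` when absent.
#' @return An object of class `parameter_maps`: `maps` (rows x cols x
#'   5, internal units, `NA` where masked), `fitness`, `mask`
#'   (TRUE = inverted), `stride`, `seed`, `grid`, `bounds`.
#' @export
invert_cube <- function(cube, cfg = ga_config(), bounds = param_bounds(),
                        stride = 1, seed = 1, ctx = NULL,
                        table = hemoglobin_table(),
                        scattering = scattering_model()) {
  stopifnot(inherits(cube, "reflectance_cube"), stride >= 1)
  if (is.null(ctx)) ctx <- km_context(cube$grid, table, scattering)
  if (!same_grid(ctx$grid, cube$grid))
    stop("context grid does not match cube grid")
  d <- dim(cube$data)
  maps <- array(NA_real_, c(d[1], d[2], 5),
                dimnames = list(NULL, NULL, param_names))
  fitness <- matrix(NA_real_, d[1], d[2])
  mask <- matrix(FALSE, d[1], d[2])
  rows <- seq(1, d[1], by = stride)
  cols <- seq(1, d[2], by = stride)
  for (i in rows) for (j in cols) {
    sp <- cube$data[i, j, ]
    if (anyNA(sp)) next
    abs_i <- cube$origin[1] + i - 1L
    abs_j <- cube$origin[2] + j - 1L
    cfg_px <- cfg
    cfg_px$rng_seed <- derive_seed(seed, (abs_i - 1) * 1048573 + abs_j)
    fit <- invert_spectrum(sp, cfg_px, ctx, bounds)
    maps[i, j, ] <- unclass(fit$params)[param_names]
    fitness[i, j] <- fit$fitness
    mask[i, j] <- TRUE
  }
  structure(list(maps = maps, fitness = fitness, mask = mask,
                 stride = as.integer(stride), seed = seed,
                 grid = cube$grid, bounds = bounds),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<parameter_maps> %d x %d, %d pixel(s) inverted (stride %d)\n",
              d[1], d[2], sum(x$mask), x$stride))
  for (p in param_names) {
    v <- x$maps[, , p][x$mask]
    cat(sprintf("  %-9s mean %.4g  sd %.3g\n", p, mean(v), sd(v)))
  }
  invisible(x)
}

#' Mean of a parameter map over a region
#'
#' Arithmetic mean of the map over the selected region, ignoring
#' pixels that were not inverted.
#'
#' @param map 2-D numeric matrix (one parameter map), `NA` where not
#'   inverted.
#' @param mask logical matrix selecting the region.
#' @return The mean value.
#' @export
region_mean <- function(map, mask) {
  stopifnot(is.matrix(map), is.logical(mask), all(dim(map) == dim(mask)))
  v <- map[mask]
  v <- v[!is.na(v)]
  if (length(v) == 0)
    stop("region contains no inverted pixels")
  mean(v)
}

#' Relative difference between a measured and a reference region
#'
#' `measured_mean / ref_mean`: the factor by which a lesion parameter
#' differs from healthy skin (e.g. ~2 for melasma melanin, ~0.27 for
#' vitiligo melanin).  Unitless.
#'
#' @param ref_mean reference (healthy) region mean, > 0.
#' @param measured_mean measured (lesion) region mean.
#' @return The ratio.
#' @export
relative_difference <- function(ref_mean, measured_mean) {
  if (any(ref_mean <= 0)) stop("reference mean must be positive")
  measured_mean / ref_mean
}

#' Percentage change from a baseline acquisition
#'
#' `100 * (acq_mean - baseline_mean) / baseline_mean`, the signed
#' percentage change of a parameter between two acquisitions (e.g.
#' baseline vs occlusion in the ischemia protocol).
#'
#' @param baseline_mean baseline region mean, non-zero.
#' @param acq_mean later-acquisition region mean.
#' @return Percentage change.
#' @examples
#' percentage_difference(1.6, 2.8)    # 75
#' percentage_difference(71.9, 55.4)  # -22.9
#' @export
percentage_difference <- function(baseline_mean, acq_mean) {
  if (any(baseline_mean == 0)) stop("baseline mean must be non-zero")
  100 * (acq_mean - baseline_mean) / baseline_mean
}

# fractions -> % for reporting
to_reported_units <- function(v, param) {
  if (param %in% c("f_mel", "f_blood", "c_oxy")) 100 * v else v
}

#' Region comparison table (lesion vs healthy)
#'
#' Per-parameter means over a reference (healthy) and a measured
#' (lesion) region, with their relative difference.  Fractions are
#' reported in percent, thicknesses in mm.
#'
#' @param pm a [parameter_maps()] result ([invert_cube()]).
#' @param ref_mask,measured_mask logical region masks.
#' @return A data frame with columns `param`, `ref_mean`,
#'   `measured_mean`, `r_diff`.
#' @export
compare_regions <- function(pm, ref_mask, measured_mask) {
  stopifnot(inherits(pm, "parameter_maps"))
  rows <- lapply(param_names, function(p) {
    rv <- to_reported_units(region_mean(pm$maps[, , p], ref_mask), p)
    mv <- to_reported_units(region_mean(pm$maps[, , p], measured_mask), p)
    data.frame(param = p, ref_mean = rv, measured_mean = mv,
               r_diff = relative_difference(rv, mv))
  })
  do.call(rbind, rows)
}

#' Acquisition comparison table (percentage change vs baseline)
#'
#' Per-parameter percentage change between a baseline and a later
#' acquisition over the same region.
#'
#' @param pm_baseline,pm_acq [parameter_maps()] results from two
#'   acquisitions of the same scene.
#' @param mask logical region mask applied to both.
#' @return A data frame with columns `param`, `baseline_mean`,
#'   `acq_mean`, `p_diff_pct`.
#' @export
compare_acquisitions <- function(pm_baseline, pm_acq, mask = NULL) {
  stopifnot(inherits(pm_baseline, "parameter_maps"),
            inherits(pm_acq, "parameter_maps"))
  if (is.null(mask)) mask <- pm_baseline$mask
  rows <- lapply(param_names, function(p) {
    bv <- to_reported_units(region_mean(pm_baseline$maps[, , p], mask), p)
    av <- to_reported_units(region_mean(pm_acq$maps[, , p], mask), p)
    data.frame(param = p, baseline_mean = bv, acq_mean = av,
               p_diff_pct = percentage_difference(bv, av))
  })
  do.call(rbind, rows)
}

#' Export parameter maps
#'
#' Writes one 32-bit float TIFF per parameter (values scaled to
#' \[0, 1\] by the parameter's physical bounds, with the scaling
#' recorded in a JSON sidecar) plus a tab-separated summary of
#' per-parameter means and standard deviations in reported units.
#'
#' @param pm a [parameter_maps()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_parameter_maps <- function(pm, dir) {
  stopifnot(inherits(pm, "parameter_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list()
  for (p in param_names) {
    m <- pm$maps[, , p]
    lo <- pm$bounds[p, "min"]; hi <- pm$bounds[p, "max"]
    scaled <- (m - lo) / (hi - lo)
    scaled[is.na(scaled)] <- 0
    tiff::writeTIFF(scaled, file.path(dir, paste0(p, ".tif")),
                    bits.per.sample = 32)
    meta[[p]] <- list(min = lo, max = hi,
                      note = "pixel = min + value * (max - min); masked pixels written as 0")
  }
  jsonlite::write_json(meta, file.path(dir, "map_scaling.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  summ <- do.call(rbind, lapply(param_names, function(p) {
    v <- pm$maps[, , p][pm$mask]
    data.frame(param = p,
               mean = to_reported_units(mean(v), p),
               sd = to_reported_units(sd(v), p),
               units = if (p %in% c("f_mel", "f_blood", "c_oxy"))
                 "percent" else "mm")
  }))
  write.table(summ, file.path(dir, "summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}
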