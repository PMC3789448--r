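#' Interference filter bank
#'
#' Gaussian-profile bandpass transmittance curves for the spectral
#' selection stage.  The default bank is ten filters with centres
#' equally spaced from 420 to 960 nm and 80 nm full width at half
#' maximum, so neighbouring passbands overlap -- as the physical
#' filter set does to tolerate centre-wavelength manufacturing error.
#'
#' @param centres filter centre wavelengths (nm), sorted increasing.
#' @param fwhm full width at half maximum (nm), scalar or per filter.
#' @return An object of class `filter_bank`.
#' @examples
#' bank <- make_filterbank()
#' filter_transmittance(bank, 460)[1]  # 0.5 at centre + fwhm/2
#' @export
make_filterbank <- function(centres = seq(420, 960, length.out = 10),
                            fwhm = 80) {
  stopifnot(length(centres) >= 1, all(fwhm > 0),
            !is.unsorted(centres, strictly = TRUE))
  fwhm <- rep_len(fwhm, length(centres))
  structure(list(centres = centres, fwhm = fwhm,
                 n = length(centres)),
            class = "filter_bank")
}

#' @rdname make_filterbank
#' @param bank a `filter_bank`.
#' @param lambda wavelength(s) in nm.
#' @return `filter_transmittance` returns an `n_filters` x
#'   `length(lambda)` matrix of transmittances in \[0, 1\] (peak 1).
#' @export
filter_transmittance <- function(bank, lambda) {
  stopifnot(inherits(bank, "filter_bank"))
  t(vapply(seq_len(bank$n), function(k) {
    exp(-4 * log(2) * ((lambda - bank$centres[k]) / bank$fwhm[k])^2)
  }, numeric(length(lambda))))
}

#' Spectral and electronic model of the acquisition chain
#'
#' Everything between the scene reflectance and the raw 12-bit counts:
#' illuminant radiance `I(lambda)`, optics transmittance `o(lambda)`,
#' sensor sensitivity `alpha(lambda)`, a per-pixel gain field
#' (vignetting x a mild linear gradient, the non-uniformity that
#' flat-fielding removes), a per-pixel dark offset field, read noise
#' and 12-bit quantisation.  Per-band exposure is set automatically so
#' a 99 %-reflectance target fills `full_scale_fraction` of the
#' dynamic range.  The default spectral curves are smooth broadband
#' shapes emulating a xenon-arc source and a visible/NIR CMOS sensor;
#' all three are injectable.
#'
#' @param wavelengths internal integration grid (nm); must stay within
#'   the haemoglobin table coverage when skin phantoms are imaged.
#' @param illuminant,optics,sensor functions of wavelength returning
#'   non-negative relative spectral curves.
#' @param bit_depth sensor bit depth (8--16; 12 default, DR 4096).
#' @param dark_level mean dark offset (counts).
#' @param read_noise_sd read noise standard deviation (counts).
#' @param vignetting relative gain loss at the image corner.
#' @param gain_gradient relative left-to-right gain slope.
#' @param full_scale_fraction flat-field target level as a fraction of
#'   full scale.
#' @param n_calib_frames frames averaged into each calibration frame.
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(
    wavelengths = seq(400, 1000, by = 2),
    illuminant = function(l) 0.85 + 0.3 * exp(-((l - 520) / 350)^2),
    optics = function(l) 0.88 + 0.1 * exp(-((l - 560) / 300)^2),
    sensor = function(l) 0.95 * exp(-((l - 620) / 380)^2),
    bit_depth = 12, dark_level = 80, read_noise_sd = 2,
    vignetting = 0.25, gain_gradient = 0.05,
    full_scale_fraction = 0.8, n_calib_frames = 10) {
  stopifnot(bit_depth %in% 8:16, dark_level >= 0, read_noise_sd >= 0,
            vignetting >= 0, vignetting < 1,
            full_scale_fraction > 0, full_scale_fraction <= 1,
            n_calib_frames >= 1)
  for (f in list(illuminant, optics, sensor))
    if (any(f(wavelengths) < 0))
      stop("spectral curves must be non-negative over the model grid")
  structure(list(wavelengths = wavelengths, illuminant = illuminant,
                 optics = optics, sensor = sensor,
                 bit_depth = as.integer(bit_depth),
                 dark_level = dark_level, read_noise_sd = read_noise_sd,
                 vignetting = vignetting, gain_gradient = gain_gradient,
                 full_scale_fraction = full_scale_fraction,
                 n_calib_frames = as.integer(n_calib_frames)),
            class = "acquisition_model")
}

# Smooth per-pixel gain and offset fields.
gain_field <- function(model, nr, nc) {
  x <- if (nc > 1) (seq_len(nc) - (nc + 1) / 2) / (nc / 2) else 0
  y <- if (nr > 1) (seq_len(nr) - (nr + 1) / 2) / (nr / 2) else 0
  r2 <- outer(y^2, x^2, "+") / 2
  grad <- matrix(rep(x, each = nr), nr, nc)
  (1 - model$vignetting * r2) * (1 + model$gain_gradient * grad / 2)
}

offset_field <- function(model, nr, nc) {
  y <- if (nr > 1) (seq_len(nr) - 1) / (nr - 1) else 0
  matrix(model$dark_level, nr, nc) +
    model$dark_level * 0.1 * matrix(rep(y, nc), nr, nc)
}

# Band weights: w_k(lambda) = I * Phi_k * o * alpha * dlambda,
# integration weights for each filter on the model grid.
band_weights <- function(model, bank) {
  wl <- model$wavelengths
  dl <- c(diff(wl), wl[length(wl)] - wl[length(wl) - 1])
  phi <- filter_transmittance(bank, wl)
  base <- model$illuminant(wl) * model$optics(wl) * model$sensor(wl) * dl
  sweep(phi, 2, base, "*")   # n_filters x n_lambda
}

#' Simulate a raw multispectral acquisition
#'
#' Images a reflectance cube through the acquisition chain: for filter
#' `k` and pixel `(i, j)` the clean signal is
#' `e_k g_ij sum_lambda I Phi_k r o alpha dlambda`; dark offset, read
#' noise and 12-bit quantisation are then applied.  Matching offset
#' (2 %-reflectance target) and flat-field (99 %-reflectance target)
#' calibration frames are simulated through the same chain, each
#' averaged over `model$n_calib_frames` noisy frames.
#'
#' Input spectra are interpolated onto the model grid; outside their
#' support they are extended with their edge value (the reconstruction
#' grid stops at 780 nm while the NIR filters see up to ~1000 nm).
#'
#' @param cube a [reflectance_cube()] (any grid).
#' @param model an [acquisition_model()].
#' @param bank a [make_filterbank()] filter bank.
#' @param seed optional integer seed for the noise.
#' @return A list of class `ms_acquisition`: `raw` (rows x cols x
#'   n_filters integer counts), `frames` (class `calibration_frames`
#'   with 3-D arrays `offset`, `flat`), `exposure` (per band),
#'   `saturation_fraction`, `band_centres`, `dr`.
#' @export
simulate_acquisition <- function(cube, model = acquisition_model(),
                                 bank = make_filterbank(), seed = NULL) {
  stopifnot(inherits(cube, "reflectance_cube"),
            inherits(model, "acquisition_model"))
  if (!is.null(seed)) set.seed(seed)
  d <- dim(cube$data)
  nr <- d[1]; nc <- d[2]; npix <- nr * nc
  wl <- model$wavelengths

  # resample pixel spectra onto the model grid (edge extension)
  src_wl <- cube$grid$wavelengths
  R <- matrix(cube$data, npix, d[3])
  Rfine <- t(apply(R, 1, function(r)
    approx(src_wl, r, xout = wl, rule = 2)$y))

  W <- band_weights(model, bank)              # n_filters x n_lambda
  signal <- Rfine %*% t(W)                    # npix x n_filters

  maxc <- 2^model$bit_depth - 1
  flat_level <- 0.99 * rowSums(W)
  exposure <- model$full_scale_fraction * (maxc - model$dark_level) /
    flat_level

  g <- as.vector(gain_field(model, nr, nc))
  o <- as.vector(offset_field(model, nr, nc))

  shoot <- function(sig_px_band, n_frames = 1) {
    # sig_px_band: npix x n_filters clean signal (pre-exposure)
    acc <- 0
    for (f in seq_len(n_frames)) {
      counts <- sweep(sig_px_band, 2, exposure, "*") * g + o
      counts <- counts + rnorm(length(counts), 0, model$read_noise_sd)
      acc <- acc + pmin(pmax(round(counts), 0), maxc)
    }
    acc / n_frames
  }

  raw <- shoot(signal)
  sat <- mean(raw >= maxc)

  flat_sig <- matrix(0.99 * rowSums(W), npix, bank$n, byrow = TRUE)
  off_sig <- matrix(0.02 * rowSums(W), npix, bank$n, byrow = TRUE)
  frames <- structure(
    list(offset = array(shoot(off_sig, model$n_calib_frames),
                        c(nr, nc, bank$n)),
         flat = array(shoot(flat_sig, model$n_calib_frames),
                      c(nr, nc, bank$n)),
         dr = maxc + 1),
    class = "calibration_frames")

  structure(list(raw = array(raw, c(nr, nc, bank$n)),
                 frames = frames, exposure = exposure,
                 saturation_fraction = sat,
                 band_centres = bank$centres, dr = maxc + 1),
            class = "ms_acquisition")
}

#' Synthetic 24-patch training chart spectra
#'
#' Deterministic stand-in for the colour chart used to train the
#' reconstruction: 8 skin-like spectra spanning the pigmentation and
#' oxygenation range of the forward model, plus 16 smooth generic
#' curves (neutral greys, sigmoid edges, Gaussian bands).  All values
#' lie in \[0.02, 0.98\].
#'
#' @param wavelengths wavelengths (nm) to evaluate on (within the
#'   haemoglobin table coverage).
#' @param table a [hemoglobin_table()] for the skin-like patches.
#' @return A 24 x `length(wavelengths)` matrix.
#' @export
synthetic_chart_spectra <- function(wavelengths,
                                    table = hemoglobin_table()) {
  wl <- wavelengths
  g <- spectral_grid_from(wl)
  ctx <- km_context(g, table)
  skin_sets <- list(
    c(0.02, 0.03, 0.010, 0.80, 1.0), c(0.06, 0.04, 0.015, 0.70, 1.2),
    c(0.12, 0.05, 0.020, 0.60, 1.5), c(0.20, 0.06, 0.030, 0.50, 1.8),
    c(0.30, 0.07, 0.040, 0.40, 2.2), c(0.40, 0.09, 0.055, 0.30, 2.6),
    c(0.08, 0.12, 0.065, 0.85, 0.8), c(0.25, 0.02, 0.005, 0.28, 2.9))
  skin <- t(km_reflectance_batch(do.call(rbind, skin_sets), ctx))

  sig <- function(c0, w, lo, hi) lo + (hi - lo) / (1 + exp(-(wl - c0) / w))
  bump <- function(c0, w, lo, hi) lo + (hi - lo) * exp(-((wl - c0) / w)^2)
  generic <- rbind(
    rep(0.05, length(wl)), rep(0.20, length(wl)), rep(0.45, length(wl)),
    rep(0.70, length(wl)), rep(0.90, length(wl)),
    sig(520, 30, 0.05, 0.85), sig(600, 40, 0.08, 0.80),
    sig(680, 35, 0.10, 0.75), sig(560, 25, 0.85, 0.08),
    sig(640, 45, 0.75, 0.12),
    bump(470, 60, 0.08, 0.70), bump(540, 50, 0.10, 0.75),
    bump(610, 70, 0.06, 0.80), bump(720, 90, 0.10, 0.70),
    bump(850, 110, 0.12, 0.65), 0.5 + 0.3 * sin((wl - 420) / 90))
  out <- rbind(skin, generic)
  pmin(pmax(out, 0.02), 0.98)
}

# Build a (possibly non-exported-constructor) grid from an arbitrary
# uniform wavelength vector.
spectral_grid_from <- function(wl) {
  stopifnot(length(wl) >= 2)
  step <- diff(wl)
  if (max(abs(step - step[1])) > 1e-9)
    stop("wavelength vector is not uniform")
  spectral_grid(wl[1], wl[length(wl)], step[1])
}

#' Simulated training set through the acquisition chain
#'
#' Images each chart patch as a small uniform tile through
#' [simulate_acquisition()], calibrates the raw counts and averages
#' the per-band response over the tile, pairing it with the patch's
#' known spectrum on `grid`.
#'
#' @param model an [acquisition_model()].
#' @param bank a filter bank.
#' @param grid output [spectral_grid()] for the known spectra.
#' @param chart patch spectra on the model grid (rows = patches);
#'   default [synthetic_chart_spectra()].
#' @param patch_px tile side in pixels.
#' @param seed integer seed.
#' @param table haemoglobin table for the default chart.
#' @return A [training_set()].
#' @export
make_training_set <- function(model = acquisition_model(),
                              bank = make_filterbank(),
                              grid = spectral_grid(), chart = NULL,
                              patch_px = 4, seed = 1,
                              table = hemoglobin_table()) {
  if (is.null(chart))
    chart <- synthetic_chart_spectra(model$wavelengths, table)
  n_patch <- nrow(chart)
  fine_grid <- spectral_grid_from(model$wavelengths)
  responses <- matrix(NA_real_, n_patch, bank$n)
  spectra <- matrix(NA_real_, n_patch, n_bands(grid))
  for (i in seq_len(n_patch)) {
    tile <- reflectance_cube(
      array(rep(chart[i, ], each = patch_px^2),
            c(patch_px, patch_px, length(model$wavelengths))),
      fine_grid)
    acq <- simulate_acquisition(tile, model, bank,
                                seed = derive_seed(seed, i))
    cal <- calibrate_stack(acq$raw, acq$frames, acq$dr)
    responses[i, ] <- apply(cal, 3, mean, na.rm = TRUE)
    spectra[i, ] <- approx(model$wavelengths, chart[i, ],
                           xout = grid$wavelengths)$y
  }
  training_set(responses, pmin(pmax(spectra, 0), 1), grid)
}

#' Skin phantom with ground-truth parameter maps
#'
#' Generates spatially smooth maps of the five skin parameters around a
#' base parameter set (low-order random cosine fields, relative
#' amplitude `smoothness`), optionally stamps an elliptical lesion
#' where the melanosome fraction is multiplied by `factor`
#' (`"melasma"`: hyperpigmented, factor > 1; `"vitiligo"`:
#' hypopigmented, factor < 1), clips everything to the physical
#' bounds, and renders the reflectance cube pixel by pixel with the
#' forward Kubelka-Munk model.
#'
#' @param base a [skin_params()]; defaults to the bundled baseline
#'   reference means (see [ischemia_reference_means()]).
#' @param lesion `"none"`, `"vitiligo"` or `"melasma"`.
#' @param factor lesion melanin multiplier; defaults 0.27 (vitiligo)
#'   or 2.06 (melasma), the characteristic ratios of the two diseases.
#' @param shape image size `c(rows, cols)`.
#' @param seed integer seed for the spatial fields.
#' @param grid spectral grid of the rendered cube.
#' @param smoothness relative amplitude of the smooth spatial
#'   variation.
#' @param table,scattering,bounds forward-model ingredients.
#' @return An object of class `skin_phantom`: `maps` (rows x cols x 5,
#'   internal units), `mask` (lesion logical matrix), `cube`
#'   ([reflectance_cube()]), plus provenance fields.
#' @examples
#' ph <- make_skin_phantom(lesion = "vitiligo", shape = c(16, 16),
#'                         seed = 1)
#' mean(ph$maps[, , "f_mel"][ph$mask]) /
#'   mean(ph$maps[, , "f_mel"][!ph$mask])  # ~0.27
#' @export
make_skin_phantom <- function(base = NULL,
                              lesion = c("none", "vitiligo", "melasma"),
                              factor = NULL, shape = c(48, 48), seed = 1,
                              grid = spectral_grid(), smoothness = 0.04,
                              table = hemoglobin_table(),
                              scattering = scattering_model(),
                              bounds = param_bounds()) {
  lesion <- match.arg(lesion)
  if (is.null(base)) base <- reference_baseline_params()
  if (is.null(factor))
    factor <- switch(lesion, none = 1, vitiligo = 0.27, melasma = 2.06)
  if (lesion == "vitiligo" && factor >= 1)
    stop("vitiligo is hypopigmented: factor must be < 1")
  if (lesion == "melasma" && factor <= 1)
    stop("melasma is hyperpigmented: factor must be > 1")
  nr <- shape[1]; nc <- shape[2]
  set.seed(seed)

  maps <- array(NA_real_, c(nr, nc, 5), dimnames = list(NULL, NULL,
                                                        param_names))
  for (k in seq_len(5))
    maps[, , k] <- unclass(base)[[param_names[k]]] *
      (1 + smoothness * smooth_field(nr, nc))

  mask <- matrix(FALSE, nr, nc)
  if (lesion != "none") {
    ii <- (seq_len(nr) - (nr + 1) / 2) / (nr * 0.30)
    jj <- (seq_len(nc) - (nc + 1) / 2) / (nc * 0.30)
    mask <- outer(ii^2, jj^2, "+") <= 1
    fm <- maps[, , "f_mel"]
    fm[mask] <- fm[mask] * factor
    maps[, , "f_mel"] <- fm
  }

  clipped <- 0L
  for (k in seq_len(5)) {
    m <- maps[, , k]
    cl <- pmin(pmax(m, bounds[k, "min"]), bounds[k, "max"])
    clipped <- clipped + sum(cl != m)
    maps[, , k] <- cl
  }
  if (clipped > 0)
    warning(sprintf("%d map value(s) clipped to the physical bounds",
                    clipped))

  cube <- render_phantom_cube(maps, grid, table, scattering)
  structure(list(maps = maps, mask = mask, cube = cube, base = base,
                 lesion = lesion, factor = factor, seed = seed,
                 grid = grid),
            class = "skin_phantom")
}

# Low-order random cosine field scaled to [-1, 1].
smooth_field <- function(nr, nc, order = 2) {
  x <- seq(0, 1, length.out = nc); y <- seq(0, 1, length.out = nr)
  f <- matrix(0, nr, nc)
  for (p in 0:order) for (q in 0:order) {
    if (p == 0 && q == 0) next
    a <- rnorm(1) / (1 + p + q)
    ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
    f <- f + a * outer(cos(pi * q * y + ph1), cos(pi * p * x + ph2))
  }
  mx <- max(abs(f))
  if (mx == 0) f else f / mx
}

render_phantom_cube <- function(maps, grid, table, scattering) {
  ctx <- km_context(grid, table, scattering)
  d <- dim(maps)
  P <- matrix(maps, d[1] * d[2], 5)
  refl <- t(km_reflectance_batch(P, ctx))
  reflectance_cube(array(refl, c(d[1], d[2], n_bands(grid))), grid)
}

#' @export
print.skin_phantom <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<skin_phantom> %d x %d, lesion %s (factor %.3g), seed %d\n",
              d[1], d[2], x$lesion, x$factor, x$seed))
  invisible(x)
}

#' Bundled reference mean parameters (cuff-occlusion protocol)
#'
#' Mean retrieved skin parameters for a three-acquisition
#' cuff-occlusion protocol on healthy volunteers (baseline; during
#' occlusion; one minute after release), bundled as reference data.
#' Used as the worked example for the comparison statistics and as
#' defaults for the ischemia phantom series.
#'
#' @return A data frame with columns `acquisition`, `f_mel_pct`,
#'   `d_epi_mm`, `f_blood_pct`, `c_oxy_pct`, `d_dermis_mm`.
#' @export
ischemia_reference_means <- function() {
  read.delim(system.file("extdata", "ischemia_reference_means.tsv",
                         package = "skinoptics", mustWork = TRUE))
}

reference_baseline_params <- function() {
  m <- ischemia_reference_means()
  b <- m[m$acquisition == "baseline", ]
  skin_params(b$f_mel_pct / 100, b$d_epi_mm, b$f_blood_pct / 100,
              b$c_oxy_pct / 100, b$d_dermis_mm)
}

#' Three-acquisition ischemia phantom series
#'
#' Emulates the cuff-occlusion protocol: a baseline phantom; an
#' occlusion phantom with the haemoglobin fraction scaled up and the
#' oxygenated fraction scaled down (blood pooling, deoxygenation); and
#' a near-baseline reperfusion phantom.  All three share the same
#' seeded spatial fields, so parameter differences between
#' acquisitions are purely the applied scalings.  Default scalings are
#' derived from the bundled reference means
#' ([ischemia_reference_means()]): occlusion 2.8/1.6 = 1.75 for blood
#' and 55.4/71.9 for oxygenation; reperfusion 1.7/1.6 and 76.7/71.9.
#'
#' @param baseline a [skin_params()]; defaults to the bundled baseline
#'   means.
#' @param occl_blood_scale,occl_oxy_scale occlusion scalings of
#'   `f_blood` and `c_oxy`.
#' @param reperf_blood_scale,reperf_oxy_scale reperfusion scalings.
#' @inheritParams make_skin_phantom
#' @return A named list of three [make_skin_phantom()] phantoms
#'   (`baseline`, `occlusion`, `reperfusion`), class `ischemia_series`.
#' @export
make_ischemia_series <- function(baseline = NULL,
                                 occl_blood_scale = NULL,
                                 occl_oxy_scale = NULL,
                                 reperf_blood_scale = NULL,
                                 reperf_oxy_scale = NULL,
                                 shape = c(32, 32), seed = 1,
                                 grid = spectral_grid(),
                                 smoothness = 0.04,
                                 table = hemoglobin_table(),
                                 scattering = scattering_model(),
                                 bounds = param_bounds()) {
  ref <- ischemia_reference_means()
  pick <- function(a, col) ref[ref$acquisition == a, col]
  if (is.null(baseline)) baseline <- reference_baseline_params()
  if (is.null(occl_blood_scale))
    occl_blood_scale <- pick("occlusion", "f_blood_pct") /
      pick("baseline", "f_blood_pct")
  if (is.null(occl_oxy_scale))
    occl_oxy_scale <- pick("occlusion", "c_oxy_pct") /
      pick("baseline", "c_oxy_pct")
  if (is.null(reperf_blood_scale))
    reperf_blood_scale <- pick("reperfusion", "f_blood_pct") /
      pick("baseline", "f_blood_pct")
  if (is.null(reperf_oxy_scale))
    reperf_oxy_scale <- pick("reperfusion", "c_oxy_pct") /
      pick("baseline", "c_oxy_pct")

  base_ph <- make_skin_phantom(baseline, "none", shape = shape,
                               seed = seed, grid = grid,
                               smoothness = smoothness, table = table,
                               scattering = scattering, bounds = bounds)
  rescale <- function(ph, blood_scale, oxy_scale) {
    maps <- ph$maps
    maps[, , "f_blood"] <- pmin(pmax(maps[, , "f_blood"] * blood_scale,
                                     bounds["f_blood", "min"]),
                                bounds["f_blood", "max"])
    maps[, , "c_oxy"] <- pmin(pmax(maps[, , "c_oxy"] * oxy_scale,
                                   bounds["c_oxy", "min"]),
                              bounds["c_oxy", "max"])
    ph$maps <- maps
    ph$cube <- render_phantom_cube(maps, grid, table, scattering)
    ph
  }
  structure(list(baseline = base_ph,
                 occlusion = rescale(base_ph, occl_blood_scale,
                                     occl_oxy_scale),
                 reperfusion = rescale(base_ph, reperf_blood_scale,
                                       reperf_oxy_scale)),
            class = "ischemia_series")
}

#' Add bounded white Gaussian noise
#'
#' Zero-mean Gaussian noise with `sigma = amplitude / 3`, so ~99.7 % of
#' draws lie within the stated `±amplitude`; the result is clipped to
#' `range`.  `amplitude = 0` returns the input unchanged.
#'
#' @param x numeric vector, matrix or array (e.g. a spectrum).
#' @param amplitude noise amplitude (3 sigma), >= 0.
#' @param seed optional integer seed.
#' @param range clipping range; `NULL` to disable clipping.
#' @return A noisy copy of `x` with the same shape.
#' @export
add_noise <- function(x, amplitude, seed = NULL, range = c(0, 1)) {
  stopifnot(amplitude >= 0)
  if (amplitude == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  vals <- if (inherits(x, "skin_spectrum")) x$values else x
  noisy <- vals + rnorm(length(vals), 0, amplitude / 3)
  if (!is.null(range)) noisy <- pmin(pmax(noisy, range[1]), range[2])
  if (inherits(x, "skin_spectrum")) {
    x$values <- as.numeric(noisy)
    x
  } else {
    if (!is.null(dim(vals))) dim(noisy) <- dim(vals)
    noisy
  }
}
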