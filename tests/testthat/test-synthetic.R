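test_that("default filter bank: ten overlapping 80-nm bandpass filters", {
  bank <- make_filterbank()
  expect_equal(bank$n, 10)
  expect_equal(bank$centres[1], 420)
  expect_equal(bank$centres[10], 960)
  # FWHM definition: transmittance 0.5 at centre +/- fwhm/2
  tr <- filter_transmittance(bank, bank$centres[3] + 40)
  expect_equal(tr[3], 0.5)
  expect_equal(filter_transmittance(bank, bank$centres[7])[7], 1)
  # neighbours overlap above zero at the midpoint between centres
  mid <- (bank$centres[4] + bank$centres[5]) / 2
  trm <- filter_transmittance(bank, mid)
  expect_gt(trm[4], 0.05)
  expect_gt(trm[5], 0.05)
  expect_error(make_filterbank(c(500, 450)))
})

test_that("acquisition of the offset-target scene reproduces the offset frame", {
  fine <- spectral_grid(400, 1000, 20)
  dark_cube <- reflectance_cube(
    array(0.02, c(4, 4, length(fine$wavelengths))), fine)
  model <- acquisition_model(read_noise_sd = 0, n_calib_frames = 1)
  acq <- simulate_acquisition(dark_cube, model, seed = 1)
  expect_equal(acq$raw, acq$frames$offset)
})

test_that("narrowband filters with flat optics sample the scene reflectance", {
  flat1 <- function(l) rep(1, length(l))
  model <- acquisition_model(wavelengths = seq(400, 1000, 1),
                             illuminant = flat1, optics = flat1,
                             sensor = flat1, read_noise_sd = 0,
                             vignetting = 0, gain_gradient = 0,
                             n_calib_frames = 1)
  bank <- make_filterbank(centres = seq(450, 900, length.out = 10),
                          fwhm = 2)
  fine <- spectral_grid(400, 1000, 10)
  vals <- seq(0.1, 0.7, length.out = length(fine$wavelengths))
  cube <- reflectance_cube(array(rep(vals, each = 4),
                                 c(2, 2, length(vals))), fine)
  acq <- simulate_acquisition(cube, model, bank, seed = 1)
  cal <- calibrate_stack(acq$raw, acq$frames, acq$dr)
  r_at_centres <- approx(fine$wavelengths, vals, bank$centres)$y
  # calibrated counts are affine in r (2%/99% targets): invert that map
  est <- 0.02 + cal[1, 1, ] / acq$dr * 0.97
  expect_equal(est, r_at_centres, tolerance = 0.01)
})

test_that("phantoms honour their lesion contrast, bounds, and seed", {
  ph <- make_skin_phantom(lesion = "vitiligo", shape = c(20, 20), seed = 4)
  expect_s3_class(ph$cube, "reflectance_cube")
  expect_true(any(ph$mask))
  ratio <- mean(ph$maps[, , "f_mel"][ph$mask]) /
    mean(ph$maps[, , "f_mel"][!ph$mask])
  # approximate: the smooth spatial field differs between regions
  expect_equal(ratio, 0.27, tolerance = 0.05)
  mel <- make_skin_phantom(lesion = "melasma", shape = c(20, 20), seed = 4)
  ratio2 <- mean(mel$maps[, , "f_mel"][mel$mask]) /
    mean(mel$maps[, , "f_mel"][!mel$mask])
  expect_equal(ratio2, 2.06, tolerance = 0.05)
  # reproducibility and bounds
  ph2 <- make_skin_phantom(lesion = "vitiligo", shape = c(20, 20), seed = 4)
  expect_identical(ph$maps, ph2$maps)
  expect_identical(ph$cube$data, ph2$cube$data)
  b <- param_bounds()
  for (k in 1:5) {
    expect_true(all(ph$maps[, , k] >= b[k, "min"]))
    expect_true(all(ph$maps[, , k] <= b[k, "max"]))
  }
  none <- make_skin_phantom(lesion = "none", shape = c(8, 8), seed = 1)
  expect_false(any(none$mask))
  expect_error(make_skin_phantom(lesion = "vitiligo", factor = 2),
               "hypopigmented")
})

test_that("ischemia series encodes the occlusion physiology in ground truth", {
  ser <- make_ischemia_series(shape = c(10, 10), seed = 2)
  gt_pdiff <- function(p) {
    100 * (mean(ser$occlusion$maps[, , p]) -
             mean(ser$baseline$maps[, , p])) /
      mean(ser$baseline$maps[, , p])
  }
  expect_equal(gt_pdiff("f_blood"), 75, tolerance = 0.5)
  expect_equal(gt_pdiff("c_oxy"), -22.9, tolerance = 0.5)
  # melanin and thicknesses unaffected by the cuff
  for (p in c("f_mel", "d_epi", "d_dermis"))
    expect_equal(gt_pdiff(p), 0, tolerance = 1e-9)
  # unit scalings give three identical phantoms
  ser0 <- make_ischemia_series(occl_blood_scale = 1, occl_oxy_scale = 1,
                               reperf_blood_scale = 1,
                               reperf_oxy_scale = 1,
                               shape = c(6, 6), seed = 2)
  expect_identical(ser0$baseline$maps, ser0$occlusion$maps)
  expect_identical(ser0$baseline$cube$data, ser0$reperfusion$cube$data)
})

test_that("bounded Gaussian noise has the stated amplitude convention", {
  x <- rep(0.5, 1e5)
  expect_identical(add_noise(x, 0), x)
  noisy <- add_noise(x, 0.1, seed = 6, range = NULL)
  delta <- noisy - x
  expect_equal(mean(delta), 0, tolerance = 5e-4)
  expect_equal(sd(delta), 0.1 / 3, tolerance = 1e-2)
  expect_gt(mean(abs(delta) <= 0.1), 0.99)
  # reproducible and clipped
  n1 <- add_noise(x[1:100], 0.3, seed = 1)
  n2 <- add_noise(x[1:100], 0.3, seed = 1)
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0 & n1 <= 1))
})

test_that("synthetic chart provides 24 smooth in-range patches", {
  wl <- seq(400, 1000, 5)
  chart <- synthetic_chart_spectra(wl)
  expect_equal(dim(chart), c(24, length(wl)))
  expect_true(all(chart >= 0.02 & chart <= 0.98))
  # smoothness: bounded step-to-step change
  expect_lt(max(abs(t(diff(t(chart))))), 0.06)
})
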