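test_that("melanin absorption follows the power law", {
  # scaling ratio is exact for any wavelength
  for (wl in c(430, 550, 700))
    expect_equal(melanin_absorption(2 * wl) / melanin_absorption(wl),
                 2^(-3.33))
  expect_equal(melanin_absorption(550), 494.4657097946, tolerance = 1e-10)
  expect_gt(melanin_absorption(420), melanin_absorption(960))
  expect_error(melanin_absorption(0), "positive")
  expect_error(melanin_absorption(-5), "positive")
})

test_that("baseline absorption has the stated anchor and asymptote", {
  expect_equal(baseline_absorption(164), 85.544)
  expect_equal(baseline_absorption(1e8), 0.244, tolerance = 1e-12)
  expect_equal(baseline_absorption(420), 2.0284405845354, tolerance = 1e-10)
})

test_that("epidermis absorption mixes melanin and baseline linearly", {
  wl <- seq(420, 780, 60)
  expect_equal(epidermis_absorption(wl, 0), baseline_absorption(wl))
  expect_equal(epidermis_absorption(wl, 1), melanin_absorption(wl))
  expect_equal(epidermis_absorption(wl, 0.5),
               (melanin_absorption(wl) + baseline_absorption(wl)) / 2)
  expect_error(epidermis_absorption(550, 1.2), "\\[0, 1\\]")
})

test_that("dermis absorption reduces correctly at the edge cases", {
  wl <- c(450, 578, 700)
  expect_equal(dermis_absorption(wl, 0, 0.5, hb_tab),
               baseline_absorption(wl))
  # fully oxygenated blood: deoxy term vanishes
  full <- dermis_absorption(578, 0.03, 1, hb_tab)
  oxy578 <- hb_tab$mu_a_oxy_cm1[hb_tab$wavelength_nm == 578]
  expect_equal(full, 0.03 * oxy578 + 0.97 * baseline_absorption(578))
  expect_error(dermis_absorption(350, 0.03, 0.5, hb_tab), "outside")
})

test_that("absorption and scattering are affine in their fraction arguments", {
  # two-point linearity oracle: f(a) + f(b) = 2 f((a+b)/2)
  wl <- seq(420, 980, 40)
  for (fr in list(c(0.1, 0.6), c(0, 1))) {
    expect_equal(epidermis_absorption(wl, fr[1]) +
                   epidermis_absorption(wl, fr[2]),
                 2 * epidermis_absorption(wl, mean(fr)))
    expect_equal(dermis_absorption(wl, fr[1], 0.4, hb_tab) +
                   dermis_absorption(wl, fr[2], 0.4, hb_tab),
                 2 * dermis_absorption(wl, mean(fr), 0.4, hb_tab))
  }
})

test_that("all coefficient models are finite and positive across the band", {
  wl <- seq(400, 1000, 4)  # haemoglobin table coverage
  m <- scattering_model()
  for (v in list(melanin_absorption(wl), baseline_absorption(wl),
                 epidermis_absorption(wl, 0.3),
                 dermis_absorption(wl, 0.05, 0.7, hb_tab),
                 layer_scattering(wl, "epidermis", m),
                 layer_scattering(wl, "dermis", m))) {
    expect_true(all(is.finite(v)))
    expect_true(all(v > 0))
  }
})

test_that("oxygen saturation is the oxy fraction of total haemoglobin", {
  expect_equal(oxygen_saturation(2, 2), 0.5)
  expect_equal(oxygen_saturation(5, 0), 1)
  expect_equal(oxygen_saturation(1, 3), 0.25)
  expect_error(oxygen_saturation(0, 0), "undefined")
  expect_error(oxygen_saturation(-1, 2), "non-negative")
})

test_that("scattering law honours its coefficients", {
  flat <- scattering_model(epidermis = list(a_mie = 12, b_mie = 0,
                                            a_ray = 0))
  expect_equal(layer_scattering(c(420, 700, 960), "epidermis", flat),
               rep(12, 3))
  m <- scattering_model()
  expect_equal(layer_scattering(500, "dermis", m),
               m$dermis$a_mie + m$dermis$a_ray)
  expect_gt(layer_scattering(420, "dermis", m),
            layer_scattering(960, "dermis", m))
  expect_error(scattering_model(epidermis = list(a_mie = -1, b_mie = 1,
                                                 a_ray = 0)))
})

test_that("parameter bounds default to the physical limits and are enforced", {
  b <- param_bounds()
  expect_equal(unname(b["f_mel", ]), c(0.013, 0.45))
  expect_equal(unname(b["d_epi", ]), c(0.01, 0.15))
  expect_equal(unname(b["f_blood", ]), c(0.002, 0.07))
  expect_equal(unname(b["c_oxy", ]), c(0.25, 0.90))
  expect_equal(unname(b["d_dermis", ]), c(0.6, 3))
  expect_error(param_bounds(f_mel = c(0.5, 0.1)), "min < max")
  expect_error(skin_params(0.5, 0.05, 0.02, 0.7, 1.2), "f_mel")
  expect_silent(skin_params(0.013, 0.01, 0.002, 0.25, 0.6))
})

test_that("model config JSON round-trips bounds and scattering overrides", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    bounds = list(f_mel = c(0.02, 0.3), d_epi = c(0.01, 0.15),
                  f_blood = c(0.002, 0.07), c_oxy = c(0.25, 0.9),
                  d_dermis = c(0.6, 3)),
    scattering = list(epidermis = list(a_mie = 30, b_mie = 1, a_ray = 10),
                      dermis = list(a_mie = 40, b_mie = 1.2, a_ray = 5))),
    path, auto_unbox = TRUE)
  cfg <- read_model_config(path)
  expect_equal(unname(cfg$bounds["f_mel", ]), c(0.02, 0.3))
  expect_equal(cfg$scattering$dermis$a_mie, 40)
  expect_equal(layer_scattering(500, "epidermis", cfg$scattering), 40)
})
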