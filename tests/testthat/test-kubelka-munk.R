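test_that("flux variables match their closed forms and limits", {
  fv <- flux_variables(1, 1)
  expect_equal(fv$K, sqrt(12))
  expect_equal(fv$beta, sqrt(2 / 6))
  # pure absorber: beta = 1, K = k = 2 mu_a
  fa <- flux_variables(3, 0)
  expect_equal(fa$beta, 1)
  expect_equal(fa$K, 6)
  # pure scatterer: beta = 0, K = 0
  fs <- flux_variables(0, 5)
  expect_equal(fs$beta, 0)
  expect_equal(fs$K, 0)
  expect_error(flux_variables(0, 0), "both")
  expect_error(flux_variables(-1, 1), "non-negative")
})

test_that("single layer limits: empty slab, Beer-Lambert, semi-infinite", {
  l0 <- layer_rt(2, 10, 0)
  expect_equal(l0$R, 0)
  expect_equal(l0$T, 1)
  # no scattering: R = 0, T = exp(-2 mu_a d)
  lb <- layer_rt(2.5, 0, 0.4)
  expect_equal(lb$R, 0)
  expect_equal(lb$T, exp(-2 * 2.5 * 0.4))
  # deep slab: T -> 0, R -> (1 - beta)/(1 + beta)
  beta <- sqrt(4 / (4 + 120))
  ld <- layer_rt(2, 30, 500)
  expect_equal(ld$T, 0)
  expect_equal(ld$R, (1 - beta) / (1 + beta), tolerance = 1e-12)
  expect_error(layer_rt(1, 1, -0.1), "non-negative")
})

test_that("energy is conserved: R + T <= 1 whenever absorption is positive", {
  set.seed(11)
  mu_a <- runif(500, 1e-4, 50)
  mu_s <- runif(500, 0, 100)
  d <- runif(500, 0, 2)
  l <- layer_rt(mu_a, mu_s, d)
  expect_true(all(l$R >= 0 & l$T >= 0))
  expect_true(all(l$R + l$T <= 1 + 1e-12))
})

test_that("two-layer stack equals the inter-reflection geometric series", {
  # brute-force truncated series oracle
  series_stack <- function(R1, T1, R2, T2, n = 200) {
    s <- sum((R1 * R2)^(0:n))
    list(R_total = R1 + T1^2 * R2 * s, T_total = T1 * T2 * s)
  }
  set.seed(7)
  for (i in 1:25) {
    R1 <- runif(1, 0, 0.6); T1 <- runif(1, 0, 1 - R1)
    R2 <- runif(1, 0, 0.6); T2 <- runif(1, 0, 1 - R2)
    got <- stack_two(list(R = R1, T = T1), list(R = R2, T = T2))
    want <- series_stack(R1, T1, R2, T2)
    expect_equal(got$R_total, want$R_total, tolerance = 1e-12)
    expect_equal(got$T_total, want$T_total, tolerance = 1e-12)
  }
  # identity layers pass the other layer through
  id <- list(R = 0, T = 1)
  l <- list(R = 0.3, T = 0.45)
  expect_equal(stack_two(l, id)$R_total, l$R)
  expect_equal(stack_two(l, id)$T_total, l$T)
  expect_equal(stack_two(id, l)$R_total, l$R)
  expect_equal(stack_two(id, l)$T_total, l$T)
  expect_error(stack_two(list(R = 1, T = 0), list(R = 1, T = 0)),
               "diverges")
  expect_error(stack_two(list(R = 1.2, T = 0), list(R = 0.1, T = 0.2)),
               "\\[0, 1\\]")
})

test_that("forward spectrum matches an independent scalar reimplementation", {
  for (p in list(mid_params, skin_params(0.02, 0.012, 0.06, 0.85, 0.9),
                 skin_params(0.4, 0.12, 0.004, 0.3, 2.8))) {
    got <- forward_spectrum(p, default_ctx)
    want <- oracle_forward(unclass(p), spectral_grid())
    expect_equal(got$values, want, tolerance = 1e-12)
  }
})

test_that("reflectance lies in [0, 1] and decreases with melanin", {
  set.seed(3)
  P <- random_inbounds_params(40)
  refl <- skinoptics:::km_reflectance_batch(P, default_ctx)
  expect_true(all(refl >= 0 & refl <= 1))
  # strict monotone decrease in f_mel at every visible wavelength
  base <- unclass(mid_params)
  fm <- seq(0.05, 0.40, 0.05)
  Pm <- matrix(base, length(fm), 5, byrow = TRUE)
  Pm[, 1] <- fm
  Rm <- skinoptics:::km_reflectance_batch(Pm, default_ctx)
  expect_true(all(diff(t(Rm)) < 0))
})

test_that("high blood content produces the oxyhaemoglobin W shape", {
  p <- skin_params(0.013, 0.01, 0.07, 0.9, 1.0)
  sp <- forward_spectrum(p, default_ctx)
  v <- sp$values
  wl <- sp$wavelengths
  i540 <- match(540, wl); i560 <- match(560, wl); i580 <- match(580, wl)
  # two local minima around 542 and 578 with a bump between
  expect_lt(v[i540], v[i540 - 1]); expect_lt(v[i540], v[i560])
  expect_lt(v[i580], v[i560]); expect_lt(v[i580], v[i580 + 1])
})

test_that("with no scattering the stack obeys the two-layer Beer-Lambert limit", {
  grid <- spectral_grid()
  ctx0 <- default_ctx
  ctx0$mus_epi[] <- 0
  ctx0$mus_der[] <- 0
  p <- unclass(mid_params)
  mua1 <- epidermis_absorption(grid$wavelengths, p[["f_mel"]])
  mua2 <- dermis_absorption(grid$wavelengths, p[["f_blood"]],
                            p[["c_oxy"]], hb_tab)
  l1 <- layer_rt(mua1, 0, p[["d_epi"]] / 10)
  l2 <- layer_rt(mua2, 0, p[["d_dermis"]] / 10)
  st <- stack_two(l1, l2)
  expect_equal(st$T_total,
               exp(-2 * (mua1 * p[["d_epi"]] / 10 +
                           mua2 * p[["d_dermis"]] / 10)),
               tolerance = 1e-12)
  expect_equal(st$R_total, rep(0, 37))
})

test_that("reflectance is continuous in every parameter", {
  base <- unclass(mid_params)
  for (k in 1:5) {
    h <- base[k] * 1e-5
    up <- base; up[k] <- base[k] + h
    dn <- base; dn[k] <- base[k] - h
    Ru <- skinoptics:::km_reflectance_batch(matrix(up, 1), default_ctx)
    Rd <- skinoptics:::km_reflectance_batch(matrix(dn, 1), default_ctx)
    expect_lt(max(abs(Ru - Rd)), 1e-3)
  }
})

test_that("out-of-bounds parameters are rejected by the forward model", {
  expect_error(forward_spectrum(skin_params(0.5, 0.05, 0.02, 0.7, 1.2,
                                            bounds = NULL), default_ctx),
               "bounds")
})
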