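# Shared fixtures: built once per test run, in code.

hb_tab <- hemoglobin_table()
default_ctx <- km_context(spectral_grid(), hb_tab, scattering_model())

mid_params <- skin_params(0.1, 0.05, 0.02, 0.7, 1.2)

# Straight-line scalar reimplementation of the two-layer model,
# independent of the vectorised implementation under test.
oracle_forward <- function(p, grid, table = hb_tab,
                           scattering = scattering_model()) {
  sapply(grid$wavelengths, function(wl) {
    mua1 <- p[["f_mel"]] * 6.6e11 * wl^(-3.33) +
      (1 - p[["f_mel"]]) * (0.244 + 85.3 * exp(-(wl - 164) / 66.2))
    oxy <- approx(table$wavelength_nm, table$mu_a_oxy_cm1, wl)$y
    deo <- approx(table$wavelength_nm, table$mu_a_deoxy_cm1, wl)$y
    mua2 <- p[["f_blood"]] * (p[["c_oxy"]] * oxy +
                                (1 - p[["c_oxy"]]) * deo) +
      (1 - p[["f_blood"]]) * (0.244 + 85.3 * exp(-(wl - 164) / 66.2))
    sc <- scattering$epidermis
    mus <- sc$a_mie * (wl / 500)^(-sc$b_mie) + sc$a_ray * (wl / 500)^(-4)
    one_layer <- function(mua, mus, d) {
      k <- 2 * mua; s <- 2 * mus
      K <- sqrt(k * (k + 2 * s)); beta <- sqrt(k / (k + 2 * s))
      den <- (1 + beta)^2 * exp(K * d) - (1 - beta)^2 * exp(-K * d)
      list(R = (1 - beta^2) * (exp(K * d) - exp(-K * d)) / den,
           T = 4 * beta / den)
    }
    l1 <- one_layer(mua1, mus, p[["d_epi"]] / 10)
    l2 <- one_layer(mua2, mus, p[["d_dermis"]] / 10)
    l1$R + l1$T^2 * l2$R / (1 - l1$R * l2$R)
  })
}

random_inbounds_params <- function(n, bounds = param_bounds()) {
  lo <- bounds[, "min"]; hi <- bounds[, "max"]
  t(replicate(n, lo + runif(5) * (hi - lo)))
}
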