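#' Kubelka-Munk flux variables
#'
#' The two-flux variables of a homogeneous layer: `k = 2 mu_a`,
#' `s = 2 mu_s`, attenuation `K = sqrt(k (k + 2 s))` and flux ratio
#' `beta = sqrt(k / (k + 2 s))`.  `K` and `beta` are the square-root
#' forms required by the hyperbolic layer solution (the exponent `K d`
#' must carry dimension cm^-1 * cm).
#'
#' @param mu_a,mu_s absorption / scattering coefficients (cm^-1),
#'   non-negative, not both zero; vectors recycle elementwise.
#' @return A list with components `k`, `s`, `K`, `beta`.
#' @examples
#' flux_variables(1, 1)  # K = sqrt(12), beta = sqrt(1/3)
#' @export
flux_variables <- function(mu_a, mu_s) {
  if (any(mu_a < 0) || any(mu_s < 0))
    stop("coefficients must be non-negative")
  if (any(mu_a == 0 & mu_s == 0))
    stop("mu_a and mu_s cannot both be zero")
  k <- 2 * mu_a
  s <- 2 * mu_s
  list(k = k, s = s,
       K = sqrt(k * (k + 2 * s)),
       beta = sqrt(k / (k + 2 * s)))
}

# Vectorised layer solution on precomputed flux variables; d in cm.
# Overflow guard: beyond kd_max the semi-infinite limits are exact to
# double precision.
.layer_rt_core <- function(K, beta, s, d, kd_max = 350) {
  Kd <- K * d
  R <- T <- numeric(length(Kd))

  deep <- Kd > kd_max
  zeroK <- K == 0 & !deep          # pure scattering: mu_a = 0
  reg <- !deep & !zeroK

  if (any(reg)) {
    ep <- exp(Kd[reg]); em <- exp(-Kd[reg])
    b <- beta[reg]
    den <- (1 + b)^2 * ep - (1 - b)^2 * em
    R[reg] <- (1 - b^2) * (ep - em) / den
    T[reg] <- 4 * b / den
  }
  if (any(zeroK)) {
    sd <- s[zeroK] * d[zeroK]
    R[zeroK] <- sd / (1 + sd)
    T[zeroK] <- 1 / (1 + sd)
  }
  if (any(deep)) {
    b <- beta[deep]
    R[deep] <- (1 - b) / (1 + b)
    T[deep] <- 0
  }
  list(R = R, T = T)
}

#' Single-layer diffuse reflectance and transmittance
#'
#' Classical Kubelka-Munk hyperbolic solution for a slab of thickness
#' `d`:
#' \deqn{R = \frac{(1-\beta^2)(e^{Kd} - e^{-Kd})}
#'            {(1+\beta)^2 e^{Kd} - (1-\beta)^2 e^{-Kd}}, \quad
#'       T = \frac{4\beta}{(1+\beta)^2 e^{Kd} - (1-\beta)^2 e^{-Kd}}.}
#' Limits are handled explicitly: `d = 0` gives (0, 1); `mu_s = 0`
#' gives Beer-Lambert transmission `exp(-2 mu_a d)`; for `K d > 350`
#' the semi-infinite forms `R = (1-beta)/(1+beta)`, `T = 0` are used to
#' avoid overflow.
#'
#' @inheritParams flux_variables
#' @param d layer thickness in cm, >= 0; recycles elementwise.
#' @return A list of class `layer_rt` with numeric components `R`, `T`.
#' @export
layer_rt <- function(mu_a, mu_s, d) {
  if (any(d < 0)) stop("thickness must be non-negative")
  n <- max(length(mu_a), length(mu_s), length(d))
  mu_a <- rep_len(mu_a, n); mu_s <- rep_len(mu_s, n); d <- rep_len(d, n)
  fv <- flux_variables(mu_a, mu_s)
  out <- .layer_rt_core(fv$K, fv$beta, fv$s, d)
  structure(out, class = "layer_rt")
}

#' Two-layer stack by inter-reflection summation
#'
#' Combines the diffuse reflectance/transmittance of an upper layer
#' (epidermis) and a lower layer (dermis) through the closed form of
#' the infinite inter-reflection series:
#' `R_total = R1 + T1^2 R2 / (1 - R1 R2)`,
#' `T_total = T1 T2 / (1 - R1 R2)`.
#'
#' @param layer1,layer2 lists with components `R` and `T` in \[0, 1\]
#'   (e.g. from [layer_rt()]); vectors recycle elementwise.
#' @return A list of class `stack_rt` with components `R_total`,
#'   `T_total`.
#' @export
stack_two <- function(layer1, layer2) {
  R1 <- layer1$R; T1 <- layer1$T; R2 <- layer2$R; T2 <- layer2$T
  vals <- c(R1, T1, R2, T2)
  if (any(vals < 0) || any(vals > 1))
    stop("layer R and T must lie in [0, 1]")
  if (any(R1 * R2 >= 1))
    stop("R1 * R2 >= 1: inter-reflection series diverges")
  den <- 1 - R1 * R2
  structure(list(R_total = R1 + T1^2 * R2 / den,
                 T_total = T1 * T2 / den),
            class = "stack_rt")
}

#' Precomputed forward-model context
#'
#' Evaluates every wavelength-dependent ingredient of the two-layer
#' skin model once on a grid (melanin, baseline, oxy/deoxy haemoglobin
#' absorption; per-layer reduced scattering) so that repeated forward
#' evaluations -- e.g. inside the genetic algorithm -- reduce to a few
#' vector operations.
#'
#' @param grid a [spectral_grid()].
#' @param table a [hemoglobin_table()].
#' @param scattering a [scattering_model()].
#' @return An object of class `km_context`.
#' @export
km_context <- function(grid = spectral_grid(),
                       table = hemoglobin_table(),
                       scattering = scattering_model()) {
  wl <- grid$wavelengths
  hb <- hemoglobin_at(wl, table)
  structure(list(
    grid = grid,
    mu_mel = melanin_absorption(wl),
    mu_base = baseline_absorption(wl),
    mu_oxy = hb$oxy,
    mu_deoxy = hb$deoxy,
    mus_epi = layer_scattering(wl, "epidermis", scattering),
    mus_der = layer_scattering(wl, "dermis", scattering)
  ), class = "km_context")
}

# Batch forward model: P is an n x 5 matrix (columns f_mel, d_epi[mm],
# f_blood, c_oxy, d_dermis[mm]); returns an n_lambda x n reflectance
# matrix.  Thicknesses convert mm -> cm here, at the model boundary.
km_reflectance_batch <- function(P, ctx) {
  P <- matrix(P, ncol = 5)
  nl <- n_bands(ctx$grid)
  n <- nrow(P)
  mua_epi <- ctx$mu_mel %o% P[, 1] + ctx$mu_base %o% (1 - P[, 1])
  blood <- ctx$mu_oxy %o% (P[, 3] * P[, 4]) +
    ctx$mu_deoxy %o% (P[, 3] * (1 - P[, 4]))
  mua_der <- blood + ctx$mu_base %o% (1 - P[, 3])
  mus_epi <- matrix(ctx$mus_epi, nl, n)
  mus_der <- matrix(ctx$mus_der, nl, n)
  d_epi <- matrix(P[, 2] / 10, nl, n, byrow = TRUE)
  d_der <- matrix(P[, 5] / 10, nl, n, byrow = TRUE)

  fv1 <- flux_variables(mua_epi, mus_epi)
  l1 <- .layer_rt_core(fv1$K, fv1$beta, fv1$s, d_epi)
  fv2 <- flux_variables(mua_der, mus_der)
  l2 <- .layer_rt_core(fv2$K, fv2$beta, fv2$s, d_der)

  den <- 1 - l1$R * l2$R
  matrix(l1$R + l1$T^2 * l2$R / den, nl, n)
}

#' Two-layer skin reflectance spectrum
#'
#' The forward model: per wavelength, build the epidermis layer from
#' (`f_mel`, `d_epi`) and the dermis layer from (`f_blood`, `c_oxy`,
#' `d_dermis`), solve each with [layer_rt()] and stack with
#' [stack_two()]; the stack's total reflectance is the model spectrum.
#' The subcutis is ignored: little visible light reaches it.
#'
#' @param p a [skin_params()] (fractions in \[0, 1\], thicknesses mm).
#' @param ctx a [km_context()]; build one per grid/table/scattering
#'   combination and reuse it.
#' @param check_bounds validate `p` against `bounds` first.
#' @param bounds a [param_bounds()].
#' @return A [spectrum_on_grid()] with values in \[0, 1\].
#' @examples
#' ctx <- km_context()
#' sp <- forward_spectrum(skin_params(0.1, 0.05, 0.02, 0.7, 1.2), ctx)
#' range(sp$values)
#' @export
forward_spectrum <- function(p, ctx = km_context(), check_bounds = TRUE,
                             bounds = param_bounds()) {
  stopifnot(inherits(ctx, "km_context"))
  p <- unclass(p)[param_names]
  if (check_bounds) check_in_bounds(p, bounds)
  vals <- km_reflectance_batch(matrix(p, nrow = 1), ctx)[, 1]
  spectrum_on_grid(vals, ctx$grid)
}
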