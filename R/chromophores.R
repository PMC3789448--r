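#' Melanin absorption coefficient
#'
#' Power-law approximation of the melanosome interior absorption,
#' `6.6e11 * lambda^-3.33` in cm^-1 with `lambda` in nm: a steep,
#' featureless decrease across the visible range.
#'
#' @param lambda wavelength(s) in nm, > 0.
#' @return Absorption coefficient(s) in cm^-1.
#' @examples
#' melanin_absorption(550)  # about 4.9e2
#' @export
melanin_absorption <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("wavelength must be positive and finite")
  6.6e11 * lambda^(-3.33)
}

#' Baseline skin absorption coefficient
#'
#' Residual absorption of skin free of the major chromophores
#' (keratin, collagen, carotene lumped together):
#' `0.244 + 85.3 * exp(-(lambda - 164) / 66.2)` in cm^-1.
#' Shared by epidermis and dermis.
#'
#' @inheritParams melanin_absorption
#' @return Absorption coefficient(s) in cm^-1.
#' @export
baseline_absorption <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("wavelength must be positive and finite")
  0.244 + 85.3 * exp(-(lambda - 164) / 66.2)
}

#' Epidermis absorption coefficient
#'
#' Volume-fraction mixture of melanosome and baseline absorption:
#' `f_mel * mu_melanin + (1 - f_mel) * mu_baseline`.  The epidermis and
#' stratum corneum are treated as one layer whose pigmentation is set
#' entirely by `f_mel`.
#'
#' @inheritParams melanin_absorption
#' @param f_mel melanosome volume fraction in \[0, 1\].
#' @return Absorption coefficient(s) in cm^-1.
#' @export
epidermis_absorption <- function(lambda, f_mel) {
  if (any(f_mel < 0 | f_mel > 1))
    stop("f_mel must lie in [0, 1]")
  f_mel * melanin_absorption(lambda) +
    (1 - f_mel) * baseline_absorption(lambda)
}

#' Whole-blood haemoglobin absorption table
#'
#' Loads the bundled whole-blood absorption coefficients for oxy- and
#' deoxyhaemoglobin (cm^-1, 150 g/L haemoglobin), tabulated every 2 nm
#' from 400 to 1000 nm.  The bundled file is a synthetic stand-in built
#' from literature-typical molar extinction anchor values (Soret band,
#' the 542/578 nm oxyhaemoglobin doublet responsible for the "W" shaped
#' skin reflectance, the 555 nm deoxy band and 760 nm deoxy shoulder)
#' splined in log space and converted with 150 g/L, 64500 g/mol and the
#' ln(10) factor; it reproduces the shape and magnitude of the public
#' compilations, not their digit-level values.
#'
#' @param path optional path to a user-supplied table with columns
#'   `wavelength_nm`, `mu_a_oxy_cm1`, `mu_a_deoxy_cm1`.
#' @return A data frame of class `hemoglobin_table`.
#' @export
hemoglobin_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hemoglobin_synthetic.tsv",
                        package = "skinoptics", mustWork = TRUE)
  d <- read.delim(path)
  need <- c("wavelength_nm", "mu_a_oxy_cm1", "mu_a_deoxy_cm1")
  if (!all(need %in% names(d)))
    stop("haemoglobin table needs columns: ", paste(need, collapse = ", "))
  if (any(d$mu_a_oxy_cm1 <= 0) || any(d$mu_a_deoxy_cm1 <= 0))
    stop("haemoglobin absorption must be positive")
  if (is.unsorted(d$wavelength_nm, strictly = TRUE))
    stop("haemoglobin table wavelengths must be strictly increasing")
  class(d) <- c("hemoglobin_table", "data.frame")
  d
}

# Interpolate the table onto arbitrary wavelengths (exact at knots).
hemoglobin_at <- function(lambda, table = hemoglobin_table()) {
  list(oxy   = interp_wavelengths(table$wavelength_nm,
                                  table$mu_a_oxy_cm1, lambda),
       deoxy = interp_wavelengths(table$wavelength_nm,
                                  table$mu_a_deoxy_cm1, lambda))
}

#' Dermis absorption coefficient
#'
#' Blood-fraction mixture of saturation-weighted haemoglobin and
#' baseline absorption:
#' `f_blood * (c_oxy * mu_oxy + (1 - c_oxy) * mu_deoxy) +
#'  (1 - f_blood) * mu_baseline`.
#' Blood is assumed evenly distributed through the dermis.
#'
#' @inheritParams melanin_absorption
#' @param f_blood haemoglobin volume fraction in \[0, 1\].
#' @param c_oxy oxygenated haemoglobin fraction in \[0, 1\].
#' @param table a [hemoglobin_table()].
#' @return Absorption coefficient(s) in cm^-1.
#' @export
dermis_absorption <- function(lambda, f_blood, c_oxy,
                              table = hemoglobin_table()) {
  if (any(f_blood < 0 | f_blood > 1)) stop("f_blood must lie in [0, 1]")
  if (any(c_oxy < 0 | c_oxy > 1)) stop("c_oxy must lie in [0, 1]")
  hb <- hemoglobin_at(lambda, table)
  f_blood * (c_oxy * hb$oxy + (1 - c_oxy) * hb$deoxy) +
    (1 - f_blood) * baseline_absorption(lambda)
}

#' Oxygen saturation from haemoglobin concentrations
#'
#' `c_hbo2 / (c_hbo2 + c_hb)`: the fraction of total haemoglobin that
#' is oxygenated (often written RSO2 when mapped over tissue).
#'
#' @param c_hbo2,c_hb non-negative oxy-/deoxyhaemoglobin
#'   concentrations (any common unit); not both zero.
#' @return Saturation fraction in \[0, 1\].
#' @export
oxygen_saturation <- function(c_hbo2, c_hb) {
  if (any(c_hbo2 < 0) || any(c_hb < 0))
    stop("concentrations must be non-negative")
  tot <- c_hbo2 + c_hb
  if (any(tot == 0))
    stop("oxygen saturation undefined when both concentrations are zero")
  c_hbo2 / tot
}

#' Reduced-scattering model for the skin layers
#'
#' Per-layer reduced scattering as a Mie + Rayleigh power law,
#' `mu_s(lambda) = a_mie * (lambda/500)^(-b_mie) +
#'  a_ray * (lambda/500)^(-4)` (cm^-1, lambda in nm).  Defaults are
#' literature-typical coefficients for skin (Mie amplitude 27.2 cm^-1,
#' Mie power 0.702, Rayleigh amplitude 18.8 cm^-1), shared by epidermis
#' and dermis; either layer can be overridden.
#'
#' @param epidermis,dermis named lists with elements `a_mie`, `b_mie`,
#'   `a_ray` (cm^-1 amplitudes; dimensionless power).
#' @return An object of class `scattering_model`.
#' @examples
#' m <- scattering_model()
#' layer_scattering(500, "dermis", m)  # a_mie + a_ray at the anchor
#' @export
scattering_model <- function(epidermis = list(a_mie = 27.2, b_mie = 0.702,
                                              a_ray = 18.8),
                             dermis = epidermis) {
  chk <- function(l, nm) {
    stopifnot(all(c("a_mie", "b_mie", "a_ray") %in% names(l)))
    if (l$a_mie < 0 || l$a_ray < 0 || l$a_mie + l$a_ray <= 0)
      stop("scattering amplitudes must be non-negative, not both zero (",
           nm, ")")
    l
  }
  structure(list(epidermis = chk(epidermis, "epidermis"),
                 dermis = chk(dermis, "dermis")),
            class = "scattering_model")
}

#' @rdname scattering_model
#' @param lambda wavelength(s) in nm, > 0.
#' @param layer `"epidermis"` or `"dermis"`.
#' @param model a `scattering_model`.
#' @export
layer_scattering <- function(lambda, layer = c("epidermis", "dermis"),
                             model = scattering_model()) {
  layer <- match.arg(layer)
  if (any(lambda <= 0)) stop("wavelength must be positive")
  cf <- model[[layer]]
  x <- lambda / 500
  cf$a_mie * x^(-cf$b_mie) + cf$a_ray * x^(-4)
}

#' Skin parameter vector
#'
#' The five parameters the forward model and inversion operate on.
#' Fractions are stored in \[0, 1\] (presented as percent at I/O
#' boundaries); thicknesses in mm.
#'
#' @param f_mel melanosome volume fraction (fraction).
#' @param d_epi epidermis thickness (mm).
#' @param f_blood haemoglobin volume fraction (fraction).
#' @param c_oxy oxygenated haemoglobin fraction (fraction).
#' @param d_dermis dermis thickness (mm).
#' @param bounds a [param_bounds()] to validate against, or `NULL` to
#'   skip validation.
#' @return A named numeric vector of class `skin_params`.
#' @examples
#' skin_params(0.1, 0.05, 0.02, 0.7, 1.2)
#' @export
skin_params <- function(f_mel, d_epi, f_blood, c_oxy, d_dermis,
                        bounds = param_bounds()) {
  p <- c(f_mel = unname(f_mel), d_epi = unname(d_epi),
         f_blood = unname(f_blood), c_oxy = unname(c_oxy),
         d_dermis = unname(d_dermis))
  if (any(!is.finite(p))) stop("skin parameters must be finite")
  if (!is.null(bounds)) check_in_bounds(p, bounds)
  structure(p, class = "skin_params")
}

param_names <- c("f_mel", "d_epi", "f_blood", "c_oxy", "d_dermis")

#' @export
print.skin_params <- function(x, ...) {
  cat(sprintf(
    "<skin_params> f_mel %.3g%%, d_epi %.3g mm, f_blood %.3g%%, c_oxy %.3g%%, d_dermis %.3g mm\n",
    100 * x[["f_mel"]], x[["d_epi"]], 100 * x[["f_blood"]],
    100 * x[["c_oxy"]], x[["d_dermis"]]))
  invisible(x)
}

#' Physical bounds of the skin parameters
#'
#' Literature-derived box constraints that the genetic algorithm never
#' leaves: melanosome fraction 1.3--45 %, epidermis thickness
#' 0.01--0.15 mm, haemoglobin fraction 0.2--7 %, oxygenated haemoglobin
#' 25--90 %, dermis thickness 0.6--3 mm.  The low epidermis bound
#' admits the epidermal thinning seen in melasma.
#'
#' @param f_mel,d_epi,f_blood,c_oxy,d_dermis length-2 `c(min, max)`
#'   overrides; fractions in \[0, 1\], thicknesses in mm.
#' @return A 5 x 2 numeric matrix (`min`, `max` columns) of class
#'   `param_bounds`.
#' @export
param_bounds <- function(f_mel = c(0.013, 0.45),
                         d_epi = c(0.01, 0.15),
                         f_blood = c(0.002, 0.07),
                         c_oxy = c(0.25, 0.90),
                         d_dermis = c(0.6, 3)) {
  b <- rbind(f_mel = f_mel, d_epi = d_epi, f_blood = f_blood,
             c_oxy = c_oxy, d_dermis = d_dermis)
  colnames(b) <- c("min", "max")
  if (any(b[, "min"] >= b[, "max"]))
    stop("each bound must have min < max")
  structure(b, class = c("param_bounds", class(b)))
}

check_in_bounds <- function(p, bounds) {
  lo <- bounds[, "min"]; hi <- bounds[, "max"]
  bad <- p[param_names] < lo - 1e-12 | p[param_names] > hi + 1e-12
  if (any(bad))
    stop("parameter(s) outside physical bounds: ",
         paste(param_names[bad], collapse = ", "))
  invisible(TRUE)
}

clip_to_bounds <- function(p, bounds) {
  pmin(pmax(p, bounds[, "min"]), bounds[, "max"])
}

#' Read bounds and scattering overrides from a JSON config
#'
#' The config may contain a `bounds` object (per-parameter
#' `[min, max]`, fractions in \[0, 1\], thickness in mm) and a
#' `scattering` object (`epidermis` / `dermis` lists with `a_mie`,
#' `b_mie`, `a_ray`).
#'
#' @param path JSON file path.
#' @return A list with elements `bounds` ([param_bounds()]) and
#'   `scattering` ([scattering_model()]); missing sections fall back to
#'   the defaults.
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  bounds <- if (!is.null(cfg$bounds)) {
    do.call(param_bounds, lapply(cfg$bounds[param_names], as.numeric))
  } else param_bounds()
  scattering <- if (!is.null(cfg$scattering)) {
    args <- lapply(cfg$scattering, function(l) lapply(l, as.numeric))
    do.call(scattering_model, args)
  } else scattering_model()
  list(bounds = bounds, scattering = scattering)
}
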