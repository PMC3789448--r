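#' Spectral similarity metrics
#'
#' Metrics comparing a measured and a simulated reflectance spectrum,
#' used as genetic-algorithm fitness functions and for reconstruction
#' validation.
#'
#' * `spectral_rmse`: root mean squared difference (default GA fitness).
#' * `spectral_gfc`: goodness of fit coefficient
#'   \eqn{|\sum m s| / (\|m\| \|s\|)}, in \[0, 1\]; 1 for identical
#'   shapes and invariant to positive scaling.  A reconstruction is
#'   conventionally called good when GFC > 0.99.
#' * `spectral_recp`: reconstruction percentage,
#'   \eqn{100 (1 - \|m - s\| / \|m\|)}; 100 for identity.
#' * `spectral_msas`: modified spectral angle similarity -- the angle
#'   (radians) between the mean-centred spectra; 0 for identical shapes
#'   up to offset and scale.
#' * `spectral_ssv`: spectral similarity value,
#'   \eqn{\sqrt{\mathrm{RMSE}^2 + (1 - r^2)^2}} with \eqn{r} the Pearson
#'   correlation; 0 for identity.
#'
#' @param measured,simulated numeric vectors or [spectrum_on_grid()]
#'   objects on the same grid.
#' @return A single numeric value.
#' @examples
#' spectral_rmse(c(0, 0, 0), c(0.1, 0.1, 0.1))  # 0.1
#' spectral_gfc(1:5, 2 * (1:5))                 # 1
#' @export
spectral_rmse <- function(measured, simulated) {
  m <- as_values(measured); s <- as_values(simulated)
  check_same_length(m, s, measured, simulated)
  sqrt(mean((m - s)^2))
}

check_same_length <- function(m, s, measured, simulated) {
  if (length(m) != length(s))
    stop("spectra have different lengths")
  if (inherits(measured, "skin_spectrum") &&
      inherits(simulated, "skin_spectrum") &&
      !same_grid(measured$grid, simulated$grid))
    stop("spectra are on different wavelength grids")
  invisible(TRUE)
}

#' @rdname spectral_rmse
#' @export
spectral_gfc <- function(measured, simulated) {
  m <- as_values(measured); s <- as_values(simulated)
  check_same_length(m, s, measured, simulated)
  nm <- sqrt(sum(m^2)); ns <- sqrt(sum(s^2))
  if (nm == 0 || ns == 0) stop("GFC undefined for a zero spectrum")
  abs(sum(m * s)) / (nm * ns)
}

#' @rdname spectral_rmse
#' @export
spectral_recp <- function(measured, simulated) {
  m <- as_values(measured); s <- as_values(simulated)
  check_same_length(m, s, measured, simulated)
  nm <- sqrt(sum(m^2))
  if (nm == 0) stop("RecP undefined for a zero measured spectrum")
  100 * (1 - sqrt(sum((m - s)^2)) / nm)
}

#' @rdname spectral_rmse
#' @export
spectral_msas <- function(measured, simulated) {
  m <- as_values(measured); s <- as_values(simulated)
  check_same_length(m, s, measured, simulated)
  mc <- m - mean(m); sc <- s - mean(s)
  nm <- sqrt(sum(mc^2)); ns <- sqrt(sum(sc^2))
  if (nm == 0 || ns == 0)
    stop("MSAS undefined for a constant spectrum")
  acos(max(-1, min(1, sum(mc * sc) / (nm * ns))))
}

#' @rdname spectral_rmse
#' @export
spectral_ssv <- function(measured, simulated) {
  m <- as_values(measured); s <- as_values(simulated)
  check_same_length(m, s, measured, simulated)
  r <- if (sd(m) == 0 || sd(s) == 0) 0 else cor(m, s)
  sqrt(spectral_rmse(m, s)^2 + (1 - r^2)^2)
}

# Cost orientation: the GA minimises; similarity-type metrics are
# flipped so that smaller is always better.
fitness_cost <- function(metric) {
  switch(metric,
    rmse = spectral_rmse,
    gfc  = function(m, s) 1 - spectral_gfc(m, s),
    recp = function(m, s) 100 - spectral_recp(m, s),
    msas = spectral_msas,
    ssv  = spectral_ssv,
    stop("unknown fitness metric: ", metric)
  )
}
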