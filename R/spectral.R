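#' Uniform wavelength grid
#'
#' The spectral axis shared by spectra, reflectance cubes and the
#' forward model.  The default grid, 420--780 nm in 10 nm steps
#' (37 samples), is the range over which the camera's reflectance
#' reconstruction is trained; the acquisition simulator works on a
#' finer, wider grid internally.
#'
#' @param from,to first and last wavelength in nm.
#' @param step grid step in nm; `to - from` must be a multiple of it.
#' @return An object of class `spectral_grid`: a list with
#'   `wavelengths` (numeric vector, strictly increasing, uniform) and
#'   `step` (nm).
#' @examples
#' g <- spectral_grid()
#' length(g$wavelengths)  # 37
#' @export
spectral_grid <- function(from = 420, to = 780, step = 10) {
  stopifnot(is.numeric(from), is.numeric(to), is.numeric(step),
            step > 0, to > from)
  wl <- seq(from, to, by = step)
  if (abs(wl[length(wl)] - to) > 1e-9)
    stop("`to - from` must be a multiple of `step`")
  structure(list(wavelengths = wl, step = step), class = "spectral_grid")
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("<spectral_grid> %g-%g nm, step %g nm (%d samples)\n",
              min(x$wavelengths), max(x$wavelengths), x$step,
              length(x$wavelengths)))
  invisible(x)
}

n_bands <- function(grid) length(grid$wavelengths)

same_grid <- function(a, b) {
  length(a$wavelengths) == length(b$wavelengths) &&
    all(abs(a$wavelengths - b$wavelengths) < 1e-9)
}

#' Reflectance spectrum on a grid
#'
#' Light-weight container pairing reflectance (or coefficient) values
#' with their [spectral_grid()].
#'
#' @param values numeric vector, one value per grid wavelength.
#' @param grid a [spectral_grid()].
#' @return An object of class `skin_spectrum`.
#' @export
spectrum_on_grid <- function(values, grid) {
  stopifnot(inherits(grid, "spectral_grid"),
            length(values) == n_bands(grid), is.numeric(values))
  structure(list(wavelengths = grid$wavelengths, values = as.numeric(values),
                 grid = grid),
            class = "skin_spectrum")
}

as_values <- function(x) {
  if (inherits(x, "skin_spectrum")) x$values else as.numeric(x)
}

#' @export
print.skin_spectrum <- function(x, ...) {
  cat(sprintf("<skin_spectrum> %d bands, %g-%g nm, range [%.4g, %.4g]\n",
              length(x$values), min(x$wavelengths), max(x$wavelengths),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.skin_spectrum <- function(x, ..., xlab = "wavelength (nm)",
                               ylab = "reflectance", type = "l") {
  plot(x$wavelengths, x$values, xlab = xlab, ylab = ylab, type = type, ...)
}

#' Write / read a spectrum as a delimited text file
#'
#' Two-column tab-separated format: `wavelength_nm`, `reflectance`.
#'
#' @param x a `skin_spectrum` (or numeric vector with `grid` supplied).
#' @param path file path.
#' @param grid grid to attach when `x` is a bare numeric vector.
#' @return `read_spectrum` returns a `skin_spectrum`;
#'   `write_spectrum` returns `path` invisibly.
#' @export
write_spectrum <- function(x, path, grid = NULL) {
  if (!inherits(x, "skin_spectrum")) {
    stopifnot(!is.null(grid))
    x <- spectrum_on_grid(x, grid)
  }
  write.table(data.frame(wavelength_nm = x$wavelengths,
                         reflectance = x$values),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  d <- read.delim(path)
  stopifnot(all(c("wavelength_nm", "reflectance") %in% names(d)))
  step <- diff(d$wavelength_nm)
  if (length(step) && max(abs(step - step[1])) > 1e-9)
    stop("spectrum file is not on a uniform grid")
  g <- spectral_grid(min(d$wavelength_nm), max(d$wavelength_nm),
                     if (length(step)) step[1] else 1)
  spectrum_on_grid(d$reflectance, g)
}

# Linear interpolation onto a target wavelength vector; exact at knots,
# error outside the source support.
interp_wavelengths <- function(wl_src, val_src, wl_out) {
  if (min(wl_out) < min(wl_src) - 1e-9 || max(wl_out) > max(wl_src) + 1e-9)
    stop(sprintf("wavelengths %g-%g nm outside tabulated range %g-%g nm",
                 min(wl_out), max(wl_out), min(wl_src), max(wl_src)))
  approx(wl_src, val_src, xout = wl_out)$y
}
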