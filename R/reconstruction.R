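#' Training set for spectral reconstruction
#'
#' Pairs calibrated camera responses of chart patches with their known
#' reflectance spectra.  The standard protocol images a 24-patch
#' colour chart; any number of patches >= 2 is accepted.
#'
#' @param responses n x n_bands matrix of calibrated band responses.
#' @param spectra n x n_wavelengths matrix of known reflectance spectra
#'   in \[0, 1\].
#' @param grid the [spectral_grid()] of the spectra.
#' @return An object of class `training_set`.
#' @export
training_set <- function(responses, spectra, grid = spectral_grid()) {
  responses <- as.matrix(responses); spectra <- as.matrix(spectra)
  stopifnot(nrow(responses) == nrow(spectra),
            ncol(spectra) == n_bands(grid), nrow(responses) >= 2)
  if (any(spectra < -1e-9) || any(spectra > 1 + 1e-9))
    stop("training spectra must lie in [0, 1]")
  if (any(apply(responses, 1, function(r) all(r == 0))))
    stop("degenerate all-zero camera response in training set")
  structure(list(responses = responses, spectra = spectra, grid = grid),
            class = "training_set")
}

#' Learn the heteroassociative reconstruction map
#'
#' Trains a single-layer linear heteroassociative memory (with bias)
#' associating camera responses to reflectance spectra, by iterative
#' batch delta-rule descent on the ridge-regularised squared error
#' `||X W - Y||^2 + lambda ||W||^2`.  The ridge term is the
#' noise-robustness mechanism: a plain pseudoinverse amplifies sensor
#' noise.  The step size is set from the largest eigenvalue of the
#' (regularised) normal matrix, so descent is stable; training stops at
#' `tol` relative cost change or `max_epochs`.
#'
#' @param train a [training_set()].
#' @param lambda ridge penalty (on the response scale; responses are
#'   internally scaled by `response_scale`).
#' @param response_scale divisor bringing responses to order 1
#'   (the sensor dynamic range by default).
#' @param max_epochs,tol iteration budget and relative-change tolerance.
#' @return An object of class `coefficient_matrix`: `W` (the
#'   (n_bands + 1) x n_wavelengths affine map), `grid`,
#'   `response_scale`, `training_rmse`, `epochs`.
#' @export
learn_map <- function(train, lambda = 1e-8, response_scale = 4096,
                      max_epochs = 50000, tol = 1e-13) {
  stopifnot(inherits(train, "training_set"))
  X <- cbind(train$responses / response_scale, 1)
  Y <- train$spectra
  n <- nrow(X); p <- ncol(X)
  G <- crossprod(X) / n + lambda * diag(p)
  B <- crossprod(X, Y) / n
  step <- 1 / max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  W <- matrix(0, p, ncol(Y))
  cost_prev <- Inf
  epochs <- max_epochs
  for (e in seq_len(max_epochs)) {
    grad <- G %*% W - B
    W <- W - step * grad
    if (e %% 50 == 0) {
      cost <- mean((X %*% W - Y)^2) + lambda * mean(W^2)
      if (is.finite(cost_prev) &&
          abs(cost_prev - cost) <= tol * max(cost_prev, 1e-300)) {
        epochs <- e
        break
      }
      cost_prev <- cost
    }
  }
  rmse <- sqrt(mean((X %*% W - Y)^2))
  structure(list(W = W, grid = train$grid,
                 response_scale = response_scale,
                 lambda = lambda, training_rmse = rmse, epochs = epochs),
            class = "coefficient_matrix")
}

#' @export
print.coefficient_matrix <- function(x, ...) {
  cat(sprintf(
    "<coefficient_matrix> %d bands (+bias) -> %d wavelengths, training RMSE %.3g (%d epochs)\n",
    nrow(x$W) - 1, ncol(x$W), x$training_rmse, x$epochs))
  invisible(x)
}

# Affine application of the learned map to an n x n_bands response
# matrix; returns n x n_wavelengths spectra (unclipped).
apply_map <- function(responses, W) {
  responses <- matrix(responses, ncol = nrow(W$W) - 1)
  cbind(responses / W$response_scale, 1) %*% W$W
}

#' Reconstruct a reflectance spectrum from one camera response
#'
#' @param response calibrated band-response vector.
#' @param W a [learn_map()] coefficient matrix.
#' @param clip clip the result to \[0, 1\].
#' @return A [spectrum_on_grid()].
#' @export
reconstruct_spectrum <- function(response, W, clip = TRUE) {
  stopifnot(inherits(W, "coefficient_matrix"),
            length(response) == nrow(W$W) - 1)
  v <- drop(apply_map(rbind(response), W))
  if (clip) v <- pmin(pmax(v, 0), 1)
  spectrum_on_grid(v, W$grid)
}

#' Reconstruct a reflectance cube from a calibrated multispectral image
#'
#' Applies the learned coefficient matrix at every pixel (one matrix
#' product for the whole image) and clips to \[0, 1\].  Pixels with any
#' `NA` band (flagged invalid in calibration) come out all-`NA`.
#'
#' @param msi calibrated stack, rows x cols x n_bands.
#' @param W a [learn_map()] coefficient matrix.
#' @return A [reflectance_cube()] with the same spatial dimensions.
#' @export
reconstruct_cube <- function(msi, W) {
  stopifnot(length(dim(msi)) == 3, inherits(W, "coefficient_matrix"))
  nb <- nrow(W$W) - 1
  if (dim(msi)[3] != nb)
    stop(sprintf("image has %d bands but the map expects %d",
                 dim(msi)[3], nb))
  d <- dim(msi)
  resp <- matrix(msi, d[1] * d[2], d[3])
  spec <- apply_map(resp, W)
  spec[!is.finite(spec)] <- NA_real_
  bad <- rowSums(is.na(resp)) > 0
  spec[bad, ] <- NA_real_
  spec <- pmin(pmax(spec, 0), 1)
  reflectance_cube(array(spec, c(d[1], d[2], ncol(spec))), W$grid)
}

#' Goodness of fit coefficient
#'
#' `gfc(a, b) = |sum(a*b)| / (||a|| ||b||)`: the normalised absolute
#' inner product of two spectra.  1 means identical shape; a
#' reconstruction is conventionally considered good above 0.99.
#'
#' @param a,b spectra on the same grid.
#' @return Value in \[0, 1\].
#' @export
gfc <- function(a, b) spectral_gfc(a, b)

#' Reflectance cube
#'
#' A 3-D array (rows x cols x wavelengths) of reflectance in \[0, 1\]
#' with its [spectral_grid()] and an `origin` (absolute row/col of the
#' top-left pixel) so that cropped sub-cubes keep a consistent
#' coordinate frame for seeded per-pixel processing.
#'
#' @param data numeric 3-D array.
#' @param grid the spectral grid; its length must equal `dim(data)[3]`.
#' @param origin absolute (row, col) of `data[1, 1, ]`.
#' @return An object of class `reflectance_cube`.
#' @export
reflectance_cube <- function(data, grid, origin = c(1L, 1L)) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            inherits(grid, "spectral_grid"),
            dim(data)[3] == n_bands(grid), length(origin) == 2)
  structure(list(data = data, grid = grid,
                 origin = as.integer(origin)),
            class = "reflectance_cube")
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<reflectance_cube> %d x %d pixels, %d bands (%g-%g nm)\n",
              d[1], d[2], d[3], min(x$grid$wavelengths),
              max(x$grid$wavelengths)))
  invisible(x)
}

#' Crop a reflectance cube
#'
#' Extracts a spatial sub-window; the `origin` is updated so that
#' seeded per-pixel inversion of the crop matches the same pixels of
#' the full cube.
#'
#' @param cube a [reflectance_cube()].
#' @param rows,cols integer index vectors (contiguous).
#' @return A [reflectance_cube()].
#' @export
crop_cube <- function(cube, rows, cols) {
  stopifnot(inherits(cube, "reflectance_cube"),
            all(diff(rows) == 1), all(diff(cols) == 1))
  reflectance_cube(cube$data[rows, cols, , drop = FALSE], cube$grid,
                   origin = cube$origin + c(rows[1], cols[1]) - 1L)
}

# Spectrum at one pixel.
pixel_spectrum <- function(cube, i, j) {
  spectrum_on_grid(cube$data[i, j, ], cube$grid)
}
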