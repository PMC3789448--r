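#' Per-pixel gain frame from flat-field and offset frames
#'
#' Under the linear sensor model `R = O + U * S`, the per-pixel gain is
#' estimated from an offset frame `O` (dark/2 %-reflectance target) and
#' a flat-field frame `F` (99 %-reflectance target) as
#' `S = (F - O) / DR`, with `DR` the sensor dynamic range (4096 for the
#' 12-bit camera).  Pixels where `F <= O` have no usable gain and are
#' flagged `NA`; downstream correction and inversion skip them.
#'
#' @param flat,offset per-band 2-D matrices of equal dimension.
#' @param dr dynamic range (counts).
#' @return Gain matrix `S`, `NA` at invalid pixels, with attribute
#'   `n_invalid`.
#' @export
gain_frame <- function(flat, offset, dr = 4096) {
  stopifnot(is.matrix(flat), is.matrix(offset),
            all(dim(flat) == dim(offset)), dr > 0)
  s <- (flat - offset) / dr
  bad <- s <= 0
  s[bad] <- NA_real_
  attr(s, "n_invalid") <- sum(bad)
  s
}

#' Offset and gain correction of a raw monoband image
#'
#' Inverts the linear sensor model: `U = (R - O) / S`.  `NA` gain
#' pixels propagate as `NA` in the corrected image.
#'
#' @param raw raw monoband image (matrix).
#' @param offset offset frame (matrix, same dimension).
#' @param gain gain frame from [gain_frame()].
#' @return Corrected image `U` (matrix, same dimension; on the dynamic
#'   range scale: a pixel at the flat-field level maps to `dr`).
#' @export
correct_image <- function(raw, offset, gain) {
  stopifnot(is.matrix(raw),
            all(dim(raw) == dim(offset)), all(dim(raw) == dim(gain)))
  (raw - offset) / gain
}

#' Average a stack of frames
#'
#' Per-pixel arithmetic mean over repeated acquisitions of the same
#' scene; used to build low-noise offset and flat-field frames.
#'
#' @param stack a 3-D array (rows x cols x frames) or list of matrices.
#' @return The averaged frame (matrix).
#' @export
average_frames <- function(stack) {
  if (is.list(stack)) {
    stopifnot(length(stack) >= 1)
    d <- dim(stack[[1]])
    stack <- array(unlist(stack), dim = c(d, length(stack)))
  }
  stopifnot(is.array(stack), length(dim(stack)) == 3, dim(stack)[3] >= 1)
  apply(stack, c(1, 2), mean)
}

#' Calibrate a raw multispectral stack
#'
#' Applies [gain_frame()] and [correct_image()] band by band.  Each
#' band carries its own offset and flat-field frame: exposure differs
#' per filter and dust on a filter affects only its own band.
#'
#' @param raw raw 10-band stack (rows x cols x bands).
#' @param frames a `calibration_frames` object (see
#'   [simulate_acquisition()]) or a list with 3-D arrays `offset` and
#'   `flat` of the same dimension as `raw`.
#' @param dr dynamic range (counts).
#' @return Calibrated stack (rows x cols x bands), `NA` at invalid
#'   pixels.
#' @export
calibrate_stack <- function(raw, frames, dr = 4096) {
  stopifnot(length(dim(raw)) == 3,
            all(dim(frames$offset) == dim(raw)),
            all(dim(frames$flat) == dim(raw)))
  out <- array(NA_real_, dim(raw))
  for (b in seq_len(dim(raw)[3])) {
    s <- gain_frame(frames$flat[, , b], frames$offset[, , b], dr)
    out[, , b] <- correct_image(raw[, , b], frames$offset[, , b], s)
  }
  out
}
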