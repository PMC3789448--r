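#' Write / read a reflectance cube
#'
#' Two on-disk formats:
#' * `"envi"` (default): band-sequential 32-bit float binary with a
#'   plain-text ENVI header carrying the wavelength list (files
#'   `<path>` and `<path>.hdr`).
#' * `"tiff"`: one 32-bit float page per band in a multi-page TIFF,
#'   with a JSON sidecar (`<path>.json`) holding the wavelengths.
#'
#' `NA` pixels are stored as NaN (ENVI) or 0 with a mask page omitted
#' (TIFF); round-tripping through ENVI preserves them.
#'
#' @param cube a [reflectance_cube()].
#' @param path output path (data file).
#' @param format `"envi"` or `"tiff"`.
#' @return `write_cube` returns `path` invisibly; `read_cube` returns
#'   a [reflectance_cube()].
#' @export
write_cube <- function(cube, path, format = c("envi", "tiff")) {
  stopifnot(inherits(cube, "reflectance_cube"))
  format <- match.arg(format)
  d <- dim(cube$data)
  if (format == "envi") {
    hdr <- c(
      "ENVI",
      "description = {skinoptics reflectance cube}",
      sprintf("samples = %d", d[2]),
      sprintf("lines = %d", d[1]),
      sprintf("bands = %d", d[3]),
      "header offset = 0",
      "file type = ENVI Standard",
      "data type = 4",
      "interleave = bsq",
      "byte order = 0",
      "wavelength units = Nanometers",
      sprintf("wavelength = {%s}",
              paste(cube$grid$wavelengths, collapse = ", ")))
    writeLines(hdr, paste0(path, ".hdr"))
    con <- file(path, "wb")
    on.exit(close(con))
    for (b in seq_len(d[3]))
      writeBin(as.numeric(t(cube$data[, , b])), con, size = 4,
               endian = "little")
  } else {
    pages <- lapply(seq_len(d[3]), function(b) {
      m <- cube$data[, , b]
      m[is.na(m)] <- 0
      m
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 32)
    jsonlite::write_json(list(wavelengths = cube$grid$wavelengths,
                              step = cube$grid$step),
                         paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path, format = c("envi", "tiff")) {
  format <- match.arg(format)
  if (format == "envi") {
    hdr <- readLines(paste0(path, ".hdr"))
    grab <- function(key) {
      ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)
      if (!length(ln)) stop("missing ENVI header field: ", key)
      sub(paste0("^", key, " *= *"), "", ln[1])
    }
    samples <- as.integer(grab("samples"))
    lines_n <- as.integer(grab("lines"))
    bands <- as.integer(grab("bands"))
    if (as.integer(grab("data type")) != 4L)
      stop("only 32-bit float ENVI cubes are supported")
    if (tolower(grab("interleave")) != "bsq")
      stop("only BSQ interleave is supported")
    wl_txt <- paste(hdr[grep("wavelength *=", hdr)[1]:length(hdr)],
                    collapse = " ")
    wl_txt <- sub(".*\\{", "", sub("\\}.*", "", wl_txt))
    wl <- as.numeric(strsplit(wl_txt, ",")[[1]])
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, numeric(), n = samples * lines_n * bands,
                    size = 4, endian = "little")
    data <- array(NA_real_, c(lines_n, samples, bands))
    per <- samples * lines_n
    for (b in seq_len(bands))
      data[, , b] <- matrix(vals[((b - 1) * per + 1):(b * per)],
                            lines_n, samples, byrow = TRUE)
    reflectance_cube(data, spectral_grid_from(wl))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    meta <- jsonlite::read_json(paste0(path, ".json"),
                                simplifyVector = TRUE)
    d <- dim(pages[[1]])
    data <- array(unlist(pages), c(d[1], d[2], length(pages)))
    reflectance_cube(data, spectral_grid_from(meta$wavelengths))
  }
}

#' Write / read a learned coefficient matrix
#'
#' The matrix itself as a tab-separated file, its metadata (grid,
#' response scale, ridge penalty, training error) in a JSON sidecar.
#'
#' @param W a [learn_map()] coefficient matrix.
#' @param path output path for the matrix file.
#' @return `read_coefficient_matrix` returns a `coefficient_matrix`.
#' @export
write_coefficient_matrix <- function(W, path) {
  stopifnot(inherits(W, "coefficient_matrix"))
  write.table(W$W, path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  jsonlite::write_json(
    list(grid = list(from = min(W$grid$wavelengths),
                     to = max(W$grid$wavelengths), step = W$grid$step),
         response_scale = W$response_scale, lambda = W$lambda,
         training_rmse = W$training_rmse, epochs = W$epochs),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_coefficient_matrix
#' @export
read_coefficient_matrix <- function(path) {
  mat <- as.matrix(read.delim(path, header = FALSE))
  dimnames(mat) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  structure(list(W = mat,
                 grid = spectral_grid(meta$grid$from, meta$grid$to,
                                      meta$grid$step),
                 response_scale = meta$response_scale,
                 lambda = meta$lambda,
                 training_rmse = meta$training_rmse,
                 epochs = meta$epochs),
            class = "coefficient_matrix")
}

#' Write / read a raw or calibrated multispectral stack as TIFF
#'
#' One page per band.  Raw 12-bit counts are stored as 16-bit integer
#' pages; calibrated (floating point) stacks as 32-bit float pages
#' scaled by `scale`.
#'
#' @param stack rows x cols x bands array.
#' @param path file path.
#' @param scale divisor applied before writing floats (default the
#'   12-bit dynamic range).
#' @return `read_stack` returns the array.
#' @export
write_stack <- function(stack, path, scale = 4096) {
  stopifnot(length(dim(stack)) == 3)
  pages <- lapply(seq_len(dim(stack)[3]), function(b) {
    m <- stack[, , b] / scale
    m[is.na(m)] <- 0
    pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, scale = 4096) {
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- dim(pages[[1]])
  array(unlist(pages), c(d[1], d[2], length(pages))) * scale
}
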