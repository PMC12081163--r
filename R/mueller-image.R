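#' Mueller matrix image container
#'
#' A `mueller_image` holds one 4 x 4 Mueller matrix per pixel as an
#' `height x width x 16` array. Planes are ordered row-major in the matrix
#' element indices: plane `p` holds element `m_ij` with `i = (p-1) %/% 4 + 1`
#' and `j = (p-1) %% 4 + 1`, i.e. `m11, m12, m13, m14, m21, ...`. That plane
#' order is part of the on-disk file contract.
#'
#' @param planes `h x w x 16` numeric array in the plane order above.
#' @param wavelength_nm illumination wavelength (metadata only).
#' @param normalized logical: are the per-pixel matrices m11-normalized?
#' @param pixel_pitch_um physical pixel pitch (metadata only, may be NA).
#' @return object of class `mueller_image`.
#' @export
mueller_image <- function(planes, wavelength_nm = 625, normalized = TRUE,
                          pixel_pitch_um = NA_real_) {
  if (!is.array(planes) || length(dim(planes)) != 3L || dim(planes)[3] != 16L)
    stop("'planes' must be an h x w x 16 array", call. = FALSE)
  structure(list(planes = planes,
                 height = dim(planes)[1], width = dim(planes)[2],
                 wavelength_nm = wavelength_nm,
                 normalized = isTRUE(normalized),
                 pixel_pitch_um = pixel_pitch_um),
            class = "mueller_image")
}

#' @export
print.mueller_image <- function(x, ...) {
  cat(sprintf("<mueller_image> %d x %d pixels, 16 planes (m11..m44), %s, %g nm\n",
              x$height, x$width,
              if (x$normalized) "m11-normalized" else "unnormalized",
              x$wavelength_nm))
  invisible(x)
}

#' @export
dim.mueller_image <- function(x) c(x$height, x$width)

#' Extract the Mueller matrix at one pixel
#'
#' @param img a [mueller_image()].
#' @param row,col pixel indices (1-based).
#' @return 4 x 4 numeric matrix.
#' @export
pixel_mueller <- function(img, row, col) {
  stopifnot(inherits(img, "mueller_image"))
  matrix(img$planes[row, col, ], 4, 4, byrow = TRUE)
}

#' Build a Mueller image from a per-pixel generator
#'
#' @param height,width image size in pixels.
#' @param fun `function(row, col)` returning a 4 x 4 Mueller matrix.
#' @param ... metadata passed to [mueller_image()].
#' @return a [mueller_image()].
#' @export
mueller_image_from_fun <- function(height, width, fun, ...) {
  planes <- array(NA_real_, c(height, width, 16))
  for (r in seq_len(height))
    for (cc in seq_len(width))
      planes[r, cc, ] <- as.vector(t(fun(r, cc)))
  mueller_image(planes, ...)
}

#' Read and write Mueller images
#'
#' Storage format: a 16-page grayscale TIFF (pages in the documented
#' `m11..m44` row-major plane order) plus a JSON sidecar
#' (`<file>.json`) recording `wavelength_nm`, `normalized`, `height`,
#' `width`, `pixel_order` and the per-plane affine scaling. Pages are stored
#' at 32 bits per sample; values are mapped affinely onto the sample range
#' via the sidecar's `scale_min`/`scale_max`, so a write/read round trip
#' reproduces every plane to better than `(max - min) * 2^-32` (about 5e-10
#' for normalized matrices).
#'
#' @param img a [mueller_image()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `write_mueller_image` returns `path` invisibly;
#'   `read_mueller_image` returns a [mueller_image()].
#' @name mueller_image_io
NULL

#' @rdname mueller_image_io
#' @export
write_mueller_image <- function(img, path) {
  stopifnot(inherits(img, "mueller_image"))
  lo <- min(img$planes); hi <- max(img$planes)
  if (hi <= lo) hi <- lo + 1
  pages <- lapply(1:16, function(p) (img$planes[, , p] - lo) / (hi - lo))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(format = "mmdepth-mueller-image",
               wavelength_nm = img$wavelength_nm,
               normalized = img$normalized,
               height = img$height, width = img$width,
               pixel_pitch_um = img$pixel_pitch_um,
               pixel_order = "row-major m11..m44",
               scale_min = lo, scale_max = hi)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname mueller_image_io
#' @export
read_mueller_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  planes <- array(NA_real_, c(meta$height, meta$width, 16))
  for (p in 1:16)
    planes[, , p] <- pages[[p]] * (meta$scale_max - meta$scale_min) + meta$scale_min
  mueller_image(planes, wavelength_nm = meta$wavelength_nm,
                normalized = meta$normalized,
                pixel_pitch_um = meta$pixel_pitch_um %||% NA_real_)
}

#' Read and write a single Mueller matrix as CSV
#'
#' Plain 4 x 4 comma-separated values, no header, full double precision.
#'
#' @param M 4 x 4 numeric Mueller matrix.
#' @param path file path.
#' @name mueller_csv_io
#' @return `write_mueller_csv` returns `path` invisibly; `read_mueller_csv`
#'   the matrix.
NULL

#' @rdname mueller_csv_io
#' @export
write_mueller_csv <- function(M, path) {
  check_mueller(M)
  utils::write.table(format(M, digits = 17, trim = TRUE), path, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname mueller_csv_io
#' @export
read_mueller_csv <- function(path) {
  M <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(M) <- NULL
  storage.mode(M) <- "double"
  check_mueller(M)
  M
}

`%||%` <- function(a, b) if (is.null(a)) b else a
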