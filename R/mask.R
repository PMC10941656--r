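#' Label mask and intensity image containers
#'
#' A label mask is an integer matrix (rows x cols, row 1 at top) whose values
#' are class codes from a declared vocabulary, e.g. `c(background = 0,
#' body = 1, tip = 2)`. An intensity image is a nonnegative numeric matrix of
#' the same shape carrying raw fluorescence values; it is never rescaled,
#' normalised or background-subtracted by this package, so all reported
#' ratios are ratios of raw values.
#'
#' @param grid Integer matrix of class codes.
#' @param classes Named integer vector mapping class names to codes.
#' @return `label_mask()` returns a `filo_mask`; `intensity_image()` a
#'   `filo_image`.
#' @examples
#' m <- label_mask(matrix(0L, 4, 4), classes = c(background = 0, body = 1, tip = 2))
#' dim(m$grid)
#' @export
label_mask <- function(grid, classes = c(background = 0, body = 1, tip = 2)) {
  if (!is.matrix(grid)) stop("grid must be a matrix", call. = FALSE)
  storage.mode(grid) <- "integer"
  bad <- setdiff(unique(as.vector(grid)), unname(classes))
  if (length(bad)) {
    stop("mask contains value(s) outside the class vocabulary {",
         paste(unname(classes), collapse = ","), "}: ",
         paste(sort(bad), collapse = ", "), call. = FALSE)
  }
  structure(list(grid = grid, classes = classes, shape = dim(grid)),
            class = "filo_mask")
}

#' @param reference Optional `filo_mask` whose shape the image must match.
#' @rdname label_mask
#' @export
intensity_image <- function(grid, reference = NULL) {
  if (!is.matrix(grid)) stop("grid must be a matrix", call. = FALSE)
  storage.mode(grid) <- "double"
  if (anyNA(grid)) stop("intensity image contains missing values", call. = FALSE)
  if (any(grid < 0)) stop("intensity image contains negative values", call. = FALSE)
  if (!is.null(reference) && !identical(dim(grid), dim(reference$grid))) {
    stop("image shape ", paste(dim(grid), collapse = "x"),
         " does not match mask shape ",
         paste(dim(reference$grid), collapse = "x"), call. = FALSE)
  }
  structure(list(grid = grid, shape = dim(grid)), class = "filo_image")
}

#' @export
print.filo_mask <- function(x, ...) {
  cnt <- table(factor(x$grid, levels = unname(x$classes)))
  cat("<filo_mask> ", paste(x$shape, collapse = " x "), " px; classes: ",
      paste(sprintf("%s(%d)=%d", names(x$classes), unname(x$classes),
                    as.integer(cnt)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.filo_image <- function(x, ...) {
  cat("<filo_image> ", paste(x$shape, collapse = " x "),
      " px; range [", format(min(x$grid)), ", ", format(max(x$grid)), "]\n",
      sep = "")
  invisible(x)
}

#' Read a label mask from a TIFF or PNG file
#'
#' The file must decode to a single-plane integer raster. Values are validated
#' against `expected_classes`; anything outside the vocabulary is an error
#' that names the offending values.
#'
#' @param path File path (TIFF; PNG also accepted for masks).
#' @param expected_classes Named integer vector of allowed class codes.
#' @return A `filo_mask`.
#' @export
read_label_mask <- function(path,
                            expected_classes = c(background = 0, body = 1,
                                                 tip = 2)) {
  grid <- read_raster(path, integer_values = TRUE)
  label_mask(grid, classes = expected_classes)
}

#' Read an intensity image
#'
#' Values are kept exactly as stored (16-bit images are not rescaled). The
#' shape must match the reference mask.
#'
#' @param path File path (TIFF).
#' @param reference A `filo_mask` giving the expected shape, or `NULL`.
#' @return A `filo_image`.
#' @export
read_intensity_image <- function(path, reference = NULL) {
  grid <- read_raster(path, integer_values = FALSE)
  intensity_image(grid, reference = reference)
}

# Decode a single-plane raster into a matrix of stored values.
# TIFF integer data are read with as.is so 8/16-bit values come back exactly;
# float TIFFs come back as stored floats. PNG (masks only) is mapped back to
# 0..255 / 0..65535 integers from R's 0-1 scale.
read_raster <- function(path, integer_values = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE, all = FALSE)
  } else if (ext == "png") {
    x <- png::readPNG(path)
    if (is.matrix(x)) {
      bits <- if (max(x) <= 1 && any(abs(x * 255 - round(x * 255)) > 1e-9)) 16L else 8L
      x <- round(x * (2^bits - 1))
    }
  } else {
    stop("unsupported raster format: .", ext, " (expected TIFF or PNG)",
         call. = FALSE)
  }
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] == 1L) {
      x <- x[, , 1L]
    } else {
      stop("multi-channel image (", dim(x)[3],
           " channels); a single-plane raster is required: ", path,
           call. = FALSE)
    }
  }
  if (!is.matrix(x)) stop("could not decode ", path, " as a 2-D raster",
                          call. = FALSE)
  if (integer_values && any(abs(x - round(x)) > 1e-6)) {
    stop("raster has non-integer values but an integer label mask was ",
         "expected: ", path, call. = FALSE)
  }
  x
}

#' Write a label mask or intensity image to TIFF
#'
#' Masks are stored as 8-bit (or 16-bit when codes exceed 255) integer TIFFs
#' and read back pixel-identical. Intensity images with fractional values are
#' rounded to the nearest integer before 16-bit storage (the native form of
#' camera data); integer-valued images round-trip exactly.
#'
#' @param x A `filo_mask` or `filo_image`.
#' @param path Output path ending in `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  grid <- round(x$grid)
  mx <- max(grid, 1)
  if (mx > 65535) stop("values exceed the 16-bit range; cannot write ", path,
                       call. = FALSE)
  bits <- if (mx <= 255) 8L else 16L
  tiff::writeTIFF(grid / (2^bits - 1), path, bits.per.sample = bits)
  invisible(path)
}
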