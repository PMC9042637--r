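# Grayscale image container and raster I/O (PGM / PNG / TIFF).
#
# Convention used throughout the package: a grayscale image is an integer
# matrix indexed [row, column], row 1 at the top, with intensities in
# 0..G_max (G_max = 255 for the 8-bit images this toolkit targets).

#' Construct and validate a grayscale image
#'
#' A grayscale image is stored as a plain integer matrix (rows = image rows,
#' row 1 at top) whose values lie in `0..g_max`. All toolkit operations
#' accept and return such matrices; this constructor validates and
#' normalises storage mode.
#'
#' @param pixels numeric or integer matrix of intensities
#' @param g_max maximum representable intensity (255 for 8-bit)
#' @return integer matrix of class `gray_image`
#' @examples
#' img <- gray_image(matrix(0:24, 5, 5) * 10)
#' dim(img)
#' @export
gray_image <- function(pixels, g_max = 255L) {
  if (!is.matrix(pixels)) stop_validation("'pixels' must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop_validation("image must have at least one row and one column")
  }
  if (anyNA(pixels)) stop_validation("image contains NA intensities")
  if (any(pixels != round(pixels))) {
    stop_validation("intensities must be integers")
  }
  if (any(pixels < 0) || any(pixels > g_max)) {
    stop_validation("intensities must lie in [0, ", g_max, "]")
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, class = c("gray_image", class(matrix())), g_max = as.integer(g_max))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%d, %d], G_max = %d>\n",
              nrow(x), ncol(x), min(x), max(x), attr(x, "g_max") %||% 255L))
  invisible(x)
}

#' Test whether an object is a valid grayscale image matrix
#' @param x object to test
#' @param g_max maximum representable intensity
#' @return logical scalar
#' @export
is_gray_image <- function(x, g_max = 255L) {
  is.matrix(x) && is.numeric(x) && !anyNA(x) &&
    nrow(x) >= 1L && ncol(x) >= 1L &&
    all(x == round(x)) && all(x >= 0) && all(x <= g_max)
}

# internal: validate or die, returning a plain integer matrix
as_pixels <- function(img, what = "image") {
  if (!is_gray_image(img)) stop_validation("'", what, "' is not a valid 8-bit grayscale image matrix")
  x <- unclass(img)
  attr(x, "g_max") <- NULL
  storage.mode(x) <- "integer"
  x
}

file_format <- function(path, format = NULL) {
  if (!is.null(format)) {
    format <- match.arg(tolower(format), c("pgm", "png", "tiff"))
    return(format)
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pgm = "pgm",
         png = "png",
         tif = ,
         tiff = "tiff",
         stop_validation("cannot infer image format from '", path,
                         "'; pass format = \"pgm\"/\"png\"/\"tiff\""))
}

#' Read a grayscale image from PGM, PNG, or TIFF
#'
#' Multi-channel (RGB/RGBA) inputs are converted to luminance grayscale with
#' the ITU-R BT.601 weights (0.299, 0.587, 0.114) and rescaled to 0..255;
#' equal channels therefore map to their common value. The alpha channel, if
#' present, is ignored.
#'
#' @param path file to read
#' @param format `"pgm"`, `"png"`, or `"tiff"`; default sniffs the extension
#' @return a [gray_image()] matrix with `G_max = 255`
#' @export
read_image <- function(path, format = NULL) {
  if (!file.exists(path)) stop_io("cannot read image: no such file '", path, "'")
  fmt <- file_format(path, format)
  arr <- switch(fmt,
    pgm  = read_pgm(path),
    png  = tryCatch(png::readPNG(path),
                    error = function(e) stop_io("failed to read PNG '", path, "': ", conditionMessage(e))),
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop_io("failed to read TIFF '", path, "': ", conditionMessage(e)))
  )
  if (fmt == "pgm") return(gray_image(arr))
  # png/tiff come back as [0,1] doubles, possibly with channels
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  if (length(arr) == 0L) stop_validation("zero-sized image in '", path, "'")
  gray_image(matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr)))
}

#' Write a grayscale image to PGM, PNG, or TIFF
#'
#' PGM and PNG round-trip bit-exactly through [read_image()].
#'
#' @param img grayscale image matrix
#' @param path destination; parent directory must exist
#' @param format `"pgm"`, `"png"`, or `"tiff"`; default sniffs the extension
#' @export
write_image <- function(img, path, format = NULL) {
  px <- as_pixels(img)
  if (!dir.exists(dirname(path))) {
    stop_io("cannot write image: directory '", dirname(path), "' does not exist")
  }
  fmt <- file_format(path, format)
  switch(fmt,
    pgm  = write_pgm(px, path),
    png  = png::writePNG(matrix(px / 255, nrow(px), ncol(px)), target = path),
    tiff = tiff::writeTIFF(matrix(px / 255, nrow(px), ncol(px)), where = path,
                           bits.per.sample = 8L)
  )
  invisible(path)
}

# Binary (P5) portable graymap, maxval <= 255. Minimal but standards-
# conforming reader/writer: none of the imported raster packages handle PGM,
# and the format is the lingua franca for label maps in this toolkit's CLI.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  if (length(magic) < 2L || magic[1] != charToRaw("P") || magic[2] != charToRaw("5")) {
    stop_io("'", path, "' is not a binary (P5) PGM file")
  }
  tok <- suppressWarnings(as.integer(pgm_tokens(con, 3L)))
  w <- tok[1]; h <- tok[2]; maxval <- tok[3]
  if (is.na(w) || is.na(h) || w < 1L || h < 1L) {
    stop_validation("zero-sized or malformed PGM '", path, "'")
  }
  if (is.na(maxval) || maxval < 1L || maxval > 255L) {
    stop_io("unsupported PGM maxval in '", path, "' (need 1..255)")
  }
  raw <- readBin(con, "raw", n = w * h)
  if (length(raw) < w * h) stop_io("truncated PGM data in '", path, "'")
  matrix(as.integer(raw), nrow = h, ncol = w, byrow = TRUE)
}

# byte-wise header tokenizer: whitespace-separated tokens, '#' comments
pgm_tokens <- function(con, n) {
  ws <- as.raw(c(9L, 10L, 13L, 32L))
  out <- character(0)
  buf <- raw(0)
  while (length(out) < n) {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) stop_io("unexpected end of PGM header")
    if (b == as.raw(35L)) { # '#': comment to end of line
      repeat {
        b <- readBin(con, "raw", n = 1L)
        if (length(b) == 0L || b == as.raw(10L)) break
      }
      b <- as.raw(32L)
    }
    if (b %in% ws) {
      if (length(buf)) { out <- c(out, rawToChar(buf)); buf <- raw(0) }
    } else {
      if (b > as.raw(127L)) stop_io("malformed PGM header (non-ASCII byte)")
      buf <- c(buf, b)
    }
  }
  out
}

write_pgm <- function(px, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(px), nrow(px)), con, eos = NULL)
  writeBin(as.raw(as.vector(t(px))), con)
  invisible(path)
}
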