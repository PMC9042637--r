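# Flat-structuring-element grayscale morphology and gradient operators.
#
# Dilation takes, at each pixel p, the maximum of the image over the
# reflected structuring element placed at p (output(p) = max_d g(p - d));
# erosion takes the minimum over the unreflected element
# (output(p) = min_d g(p + d)). With these conventions the adjunction and
# duality identities hold exactly for any anchor-containing flat SE.
# Borders use reflect padding, matching the impulse filter.

#' Flat (binary) structuring element
#'
#' @param mask logical or 0/1 matrix; `TRUE` cells belong to the element
#' @param anchor length-2 integer `(row, col)` origin inside the mask;
#'   default is the centre cell. The anchor cell must be part of the
#'   element.
#' @return list of class `structuring_element` with fields `mask`, `anchor`
#'   and the cell `offsets` relative to the anchor
#' @export
structuring_element <- function(mask, anchor = NULL) {
  if (!is.matrix(mask)) stop_validation("'mask' must be a matrix")
  mask <- mask != 0
  if (!any(mask)) stop_validation("structuring element must contain at least one cell")
  if (is.null(anchor)) {
    anchor <- c((nrow(mask) + 1L) %/% 2L, (ncol(mask) + 1L) %/% 2L)
  }
  anchor <- as.integer(anchor)
  if (length(anchor) != 2L || anchor[1] < 1L || anchor[1] > nrow(mask) ||
      anchor[2] < 1L || anchor[2] > ncol(mask)) {
    stop_validation("'anchor' must index a cell of the mask")
  }
  if (!mask[anchor[1], anchor[2]]) {
    stop_validation("the anchor cell must belong to the structuring element")
  }
  idx <- which(mask, arr.ind = TRUE)
  offsets <- cbind(idx[, 1] - anchor[1], idx[, 2] - anchor[2])
  structure(list(mask = mask, anchor = anchor, offsets = offsets),
            class = "structuring_element")
}

#' Square flat structuring element
#' @param side odd side length, default 3
#' @return a [structuring_element()]
#' @export
se_square <- function(side = 3L) {
  if (side < 1L || side %% 2L == 0L) stop_validation("'side' must be odd and positive")
  structuring_element(matrix(TRUE, side, side))
}

#' Read a structuring element from a text mask
#'
#' The file holds rows of `0`/`1` characters (whitespace ignored); a `*`
#' marks the anchor cell (and counts as a `1`). Without a `*` the centre
#' cell is the anchor.
#'
#' @param path text file to read
#' @return a [structuring_element()]
#' @export
read_se <- function(path) {
  if (!file.exists(path)) stop_io("cannot read structuring element: no such file '", path, "'")
  lines <- readLines(path, warn = FALSE)
  lines <- gsub("[ \t]", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_validation("empty structuring element file '", path, "'")
  chars <- strsplit(lines, "")
  width <- unique(lengths(chars))
  if (length(width) != 1L) stop_validation("ragged rows in structuring element file '", path, "'")
  grid <- do.call(rbind, chars)
  if (!all(grid %in% c("0", "1", "*"))) {
    stop_validation("structuring element file may contain only 0, 1 and * characters")
  }
  anchor <- which(grid == "*", arr.ind = TRUE)
  if (nrow(anchor) > 1L) stop_validation("multiple anchors in structuring element file")
  structuring_element(grid != "0",
                      anchor = if (nrow(anchor) == 1L) anchor[1, ] else NULL)
}

# internal: accumulate an extremum over SE-shifted copies of the image.
# sign = -1 gathers g(p - d) (dilation), +1 gathers g(p + d) (erosion).
morph_extremum <- function(px, se, fun, sign) {
  h <- nrow(px); w <- ncol(px)
  acc <- NULL
  for (i in seq_len(nrow(se$offsets))) {
    dr <- sign * se$offsets[i, 1]
    dc <- sign * se$offsets[i, 2]
    rows <- border_index(seq_len(h) + dr, h, "reflect")
    cols <- border_index(seq_len(w) + dc, w, "reflect")
    shifted <- px[rows, cols, drop = FALSE]
    acc <- if (is.null(acc)) shifted else fun(acc, shifted)
  }
  acc
}

#' Grayscale dilation by a flat structuring element
#' @param img grayscale image matrix
#' @param se a [structuring_element()]; default 3x3 square
#' @return dilated [gray_image()]
#' @export
dilate <- function(img, se = se_square(3L)) {
  px <- as_pixels(img)
  stopifnot(inherits(se, "structuring_element"))
  gray_image(morph_extremum(px, se, pmax, -1L))
}

#' Grayscale erosion by a flat structuring element
#' @inheritParams dilate
#' @return eroded [gray_image()]
#' @export
erode <- function(img, se = se_square(3L)) {
  px <- as_pixels(img)
  stopifnot(inherits(se, "structuring_element"))
  gray_image(morph_extremum(px, se, pmin, 1L))
}

#' Grayscale opening (erosion then dilation)
#' @inheritParams dilate
#' @export
opening <- function(img, se = se_square(3L)) {
  dilate(erode(img, se), se)
}

#' Grayscale closing (dilation then erosion)
#' @inheritParams dilate
#' @export
closing <- function(img, se = se_square(3L)) {
  erode(dilate(img, se), se)
}

GRADIENT_OPERATORS <- c("P1", "P2", "P3", "P4", "P5")

#' Morphological gradient edge image
#'
#' Five flat-SE gradient operators, written with `g` the image and `D` the
#' structuring element:
#' * `P1`: dilation minus closing, `(g (+) D) - (g . D)`
#' * `P2`: opening minus erosion, `(g o D) - (g (-) D)`
#' * `P3`: dilated opening minus eroded closing
#' * `P4`: dilated opening minus opening
#' * `P5`: closing minus eroded closing
#'
#' `P2`–`P5` build their differences from opened/closed images, which
#' suppresses the response to isolated impulses (the anti-noise property);
#' `P1` is the classical half-gradient pair. Negative differences (possible
#' only for `P3`) are clamped to 0.
#'
#' @param img grayscale image matrix
#' @param se a [structuring_element()]; default 3x3 square
#' @param operator one of `"P1"`..`"P5"`
#' @return [gray_image()] of gradient magnitudes with attribute
#'   `operator_id`
#' @export
morph_gradient <- function(img, se = se_square(3L),
                           operator = c("P1", "P2", "P3", "P4", "P5")) {
  operator <- match.arg(operator)
  px <- as_pixels(img)
  stopifnot(inherits(se, "structuring_element"))
  g <- gray_image(px)
  diffimg <- switch(operator,
    P1 = unclass(dilate(g, se)) - unclass(closing(g, se)),
    P2 = unclass(opening(g, se)) - unclass(erode(g, se)),
    P3 = unclass(dilate(opening(g, se), se)) - unclass(erode(closing(g, se), se)),
    P4 = unclass(dilate(opening(g, se), se)) - unclass(opening(g, se)),
    P5 = unclass(closing(g, se)) - unclass(erode(closing(g, se), se))
  )
  out <- gray_image(matrix(as.integer(clamp_intensity(diffimg)),
                           nrow(px), ncol(px)))
  attr(out, "operator_id") <- operator
  out
}
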