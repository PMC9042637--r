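# Seeded synthetic ultrasound phantom and impulse-noise injection.
#
# The phantom emulates the content of a display-domain (8-bit, post scan
# conversion) pelvic-floor B-mode image: a dark fan-shaped field border, a
# mid-gray tissue background, anechoic (dark) elliptical inclusions, bright
# curvilinear interfaces, and multiplicative speckle texture modelled as
# unit-mean gamma noise whose shape parameter ("looks") sets the speckle
# contrast (contrast = 1/sqrt(looks)).

#' Generate a synthetic ultrasound phantom
#'
#' Builds a piecewise-smooth anatomy layer (background at
#' `background_mean`, anechoic ellipses at 0.3x background, bright curves
#' at 1.8x background, optional dark fan border), multiplies it by
#' unit-mean gamma speckle with shape `speckle_looks`, and quantises to
#' 0..255. Deterministic for a fixed `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param height,width image size in pixels (each >= 32)
#' @param n_cysts number of anechoic elliptical inclusions
#' @param n_lines number of bright curvilinear structures
#' @param background_mean mean tissue intensity, in (0, 255)
#' @param speckle_looks positive integer; larger values give smoother
#'   speckle (texture standard deviation = mean / sqrt(looks)). The default
#'   16 corresponds to a display-domain speckle contrast of 0.25, typical
#'   of compounded, log-compressed B-mode images.
#' @param fan_mask apply the dark fan-shaped field border
#' @param seed RNG seed; `NULL` uses (and advances) the current RNG state
#' @return list with `image` (the speckled phantom, [gray_image()]),
#'   `anatomy` (the noise-free layer, [gray_image()]) and `structure_mask`
#'   (logical matrix marking cyst boundaries and line pixels — the
#'   ground-truth edge locations)
#' @examples
#' ph <- make_phantom(64, 64, seed = 7)
#' range(ph$image)
#' @export
make_phantom <- function(height = 128L, width = 128L, n_cysts = 3L,
                         n_lines = 2L, background_mean = 120,
                         speckle_looks = 16L, fan_mask = TRUE, seed = NULL) {
  if (height < 32L || width < 32L) stop_validation("phantom dimensions must be >= 32")
  if (background_mean <= 0 || background_mean >= 255) {
    stop_validation("'background_mean' must lie strictly between 0 and 255")
  }
  if (speckle_looks < 1 || speckle_looks != round(speckle_looks)) {
    stop_validation("'speckle_looks' must be a positive integer")
  }
  if (n_cysts < 0L || n_lines < 0L) stop_validation("counts must be non-negative")

  with_local_seed(seed, {
    rows <- matrix(seq_len(height), height, width)
    cols <- matrix(seq_len(width), height, width, byrow = TRUE)
    anatomy <- matrix(background_mean, height, width)
    structure_mask <- matrix(FALSE, height, width)

    for (i in seq_len(n_cysts)) {
      cy <- stats::runif(1, 0.35, 0.75) * height
      cx <- stats::runif(1, 0.30, 0.70) * width
      ax <- stats::runif(1, 0.06, 0.14) * min(height, width)
      bx <- stats::runif(1, 0.06, 0.14) * min(height, width)
      th <- stats::runif(1, 0, pi)
      u <- (rows - cy) * cos(th) + (cols - cx) * sin(th)
      v <- -(rows - cy) * sin(th) + (cols - cx) * cos(th)
      rq <- sqrt((u / ax)^2 + (v / bx)^2)
      anatomy[rq <= 1] <- 0.3 * background_mean
      structure_mask <- structure_mask | (rq <= 1 & rq >= 1 - 2 / min(ax, bx))
    }

    for (i in seq_len(n_lines)) {
      r0 <- stats::runif(1, 0.25, 0.85) * height
      s1 <- stats::runif(1, -0.3, 0.3)
      s2 <- stats::runif(1, -1, 1) * 2 / width
      curve_row <- r0 + s1 * (cols - width / 2) + s2 * (cols - width / 2)^2
      on_line <- abs(rows - curve_row) <= 1
      anatomy[on_line] <- min(1.8 * background_mean, 255)
      structure_mask <- structure_mask | on_line
    }

    if (fan_mask) {
      apex_r <- -0.10 * height
      apex_c <- width / 2
      dy <- rows - apex_r
      dx <- cols - apex_c
      radius <- sqrt(dx^2 + dy^2)
      theta <- atan2(dx, dy)  # 0 points straight down from the apex
      outside <- abs(theta) > 0.62 | radius < 0.15 * height | radius > 1.15 * height
      anatomy[outside] <- 8  # near-black noise floor outside the active fan
      structure_mask[outside] <- FALSE
    }

    speckle <- matrix(stats::rgamma(height * width, shape = speckle_looks,
                                    rate = speckle_looks), height, width)
    img <- clamp_intensity(round(anatomy * speckle))
    list(image = gray_image(matrix(as.integer(img), height, width)),
         anatomy = gray_image(matrix(as.integer(clamp_intensity(round(anatomy))),
                                     height, width)),
         structure_mask = structure_mask)
  })
}

#' Inject exact-count impulse (salt-and-pepper) noise
#'
#' Replaces exactly `round(density * G)` distinct pixels, drawn without
#' replacement: 0 for `"pepper"`, 255 for `"salt"`, a fair coin between
#' them for `"salt_and_pepper"`. Uncorrupted pixels are bit-identical to
#' the input.
#'
#' @param img grayscale image matrix
#' @param density fraction of pixels to corrupt, in \code{[0, 1]}
#' @param mode `"salt_and_pepper"` (default), `"salt"`, or `"pepper"`
#' @param seed RNG seed; `NULL` uses the current RNG state
#' @return list with `image` (corrupted [gray_image()]) and
#'   `corrupted_mask` (logical matrix marking replaced pixels)
#' @export
add_impulse_noise <- function(img, density,
                              mode = c("salt_and_pepper", "salt", "pepper"),
                              seed = NULL) {
  mode <- match.arg(mode)
  px <- as_pixels(img)
  if (length(density) != 1L || is.na(density) || density < 0 || density > 1) {
    stop_validation("'density' must lie in [0, 1]")
  }
  g <- length(px)
  k <- round(density * g)
  with_local_seed(seed, {
    mask <- matrix(FALSE, nrow(px), ncol(px))
    if (k > 0L) {
      idx <- sample.int(g, k)
      vals <- switch(mode,
        salt = rep(255L, k),
        pepper = rep(0L, k),
        salt_and_pepper = sample(c(0L, 255L), k, replace = TRUE))
      px[idx] <- vals
      mask[idx] <- TRUE
    }
    list(image = gray_image(px), corrupted_mask = mask)
  })
}
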