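# Edge-region-only enhancement: denoise -> morphological gradient ->
# edge mask -> additive sharpening on the mask. Non-edge pixels pass
# through bit-identically.

#' Parameters for the full enhancement pipeline
#'
#' @param filter_params impulse-filter parameters, see [filter_params()]
#' @param operator gradient operator id, `"P1"`..`"P5"`; default `"P4"`
#' @param se structuring element for the morphology stage
#' @param mask_method `"otsu"` (threshold chosen on the nonzero-gradient
#'   histogram) or `"fixed"`
#' @param fixed_threshold intensity threshold used when
#'   `mask_method = "fixed"`
#' @param gain non-negative edge gain `lambda`; enhanced pixels become
#'   `clip(denoised + lambda * edge)`
#' @param enhance_source `"denoised"` (default) applies the edge boost to
#'   the filtered image; `"raw"` applies it to the unfiltered input
#' @return list of class `enhance_params`
#' @export
enhance_params <- function(filter_params = usenhance::filter_params(),
                           operator = c("P4", "P1", "P2", "P3", "P5"),
                           se = se_square(3L),
                           mask_method = c("otsu", "fixed"),
                           fixed_threshold = 0L,
                           gain = 1.0,
                           enhance_source = c("denoised", "raw")) {
  operator <- match.arg(operator)
  mask_method <- match.arg(mask_method)
  enhance_source <- match.arg(enhance_source)
  stopifnot(inherits(filter_params, "filter_params"),
            inherits(se, "structuring_element"))
  if (gain < 0) stop_validation("'gain' must be non-negative")
  if (fixed_threshold < 0 || fixed_threshold > 255) {
    stop_validation("'fixed_threshold' must lie in [0, 255]")
  }
  structure(list(filter_params = filter_params, operator = operator, se = se,
                 mask_method = mask_method,
                 fixed_threshold = as.integer(fixed_threshold),
                 gain = gain, enhance_source = enhance_source),
            class = "enhance_params")
}

#' Binarise a gradient image into an edge-region mask
#'
#' `"otsu"` picks the threshold maximising the between-class variance of
#' the histogram of *nonzero* gradient values (flat regions produce exact
#' zeros that would otherwise swamp the histogram); the mask is
#' `edge > threshold`. `"fixed"` uses the supplied threshold directly. An
#' all-zero gradient image yields an all-`FALSE` mask.
#'
#' @param edge gradient image from [morph_gradient()]
#' @param method `"otsu"` or `"fixed"`
#' @param fixed_threshold intensity cut used by `"fixed"`
#' @return logical matrix, `TRUE` on edge regions
#' @export
edge_mask <- function(edge, method = c("otsu", "fixed"), fixed_threshold = 0L) {
  method <- match.arg(method)
  px <- as_pixels(edge, "edge")
  if (method == "fixed") return(px > fixed_threshold)
  nz <- px[px > 0]
  if (length(nz) == 0L) return(matrix(FALSE, nrow(px), ncol(px)))
  px > otsu_threshold(nz)
}

# Otsu's criterion on a vector of intensities in 1..255: returns the
# threshold t in 0..254 maximising between-class variance (smallest t on
# ties, so a single-valued histogram selects every nonzero pixel).
otsu_threshold <- function(values) {
  counts <- tabulate(values + 1L, nbins = 256L)  # bin v+1 holds count of v
  total <- sum(counts)
  levels <- 0:255
  w0 <- cumsum(counts)
  sum0 <- cumsum(counts * levels)
  sum_all <- sum0[256L]
  w1 <- total - w0
  m0 <- ifelse(w0 > 0, sum0 / w0, 0)
  m1 <- ifelse(w1 > 0, (sum_all - sum0) / w1, 0)
  between <- w0 * w1 * (m0 - m1)^2
  between <- between[1:255]  # thresholds 0..254
  which.max(between) - 1L
}

#' Additive edge-region enhancement
#'
#' On masked pixels, `output = clip(round(base + gain * edge), 0, 255)`;
#' off the mask the base image passes through bit-identically.
#'
#' @param base image to enhance (normally the denoised image)
#' @param edge gradient image
#' @param mask logical edge-region mask
#' @param gain non-negative edge gain
#' @return enhanced [gray_image()]
#' @export
enhance <- function(base, edge, mask, gain = 1.0) {
  b <- as_pixels(base, "base")
  e <- as_pixels(edge, "edge")
  if (!is.logical(mask) || !all(dim(mask) == dim(b))) {
    stop_validation("'mask' must be a logical matrix matching the image shape")
  }
  if (!all(dim(e) == dim(b))) stop_validation("'edge' shape must match 'base'")
  if (gain < 0) stop_validation("'gain' must be non-negative")
  out <- b
  boosted <- as.integer(clamp_intensity(round(b + gain * as.numeric(e))))
  out[mask] <- boosted[mask]
  gray_image(out)
}

#' Run the full enhancement pipeline
#'
#' Executes denoise -> morphological gradient -> edge mask -> edge-region
#' enhancement. When a noise-free `reference` is supplied, quality metrics
#' of both the input and the output against it are attached.
#'
#' @param img grayscale input image
#' @param params an [enhance_params()] object
#' @param reference optional noise-free image for metric reporting
#' @return list of class `enhance_result` with `denoised`, `labels`,
#'   `edge`, `mask`, `output`, `params`, and (given a reference) `metrics`
#'   containing `$input` and `$output` [quality_metrics()] records
#' @export
run_pipeline <- function(img, params = enhance_params(), reference = NULL) {
  stopifnot(inherits(params, "enhance_params"))
  px <- gray_image(as_pixels(img))
  den <- denoise(px, params$filter_params)
  edge <- morph_gradient(den$image, params$se, params$operator)
  mask <- edge_mask(edge, params$mask_method, params$fixed_threshold)
  base <- if (params$enhance_source == "denoised") den$image else px
  out <- enhance(base, edge, mask, params$gain)
  res <- list(denoised = den$image, labels = den$labels, edge = edge,
              mask = mask, output = out, params = params)
  if (!is.null(reference)) {
    res$metrics <- list(input = quality_metrics(reference, px),
                        output = quality_metrics(reference, out))
  }
  class(res) <- "enhance_result"
  res
}

#' @export
print.enhance_result <- function(x, ...) {
  cat(sprintf("<enhance_result %d x %d, operator %s, %d noise px, %d edge px>\n",
              nrow(x$output), ncol(x$output), x$params$operator,
              sum(x$labels == LABEL_NOISE), sum(x$mask)))
  if (!is.null(x$metrics)) {
    with(x$metrics, cat(sprintf(
      "  vs reference: PSNR %.2f -> %.2f dB, MSE %.1f -> %.1f, SSIM %.3f -> %.3f\n",
      input$psnr_db, output$psnr_db, input$mse, output$mse,
      input$ssim, output$ssim)))
  }
  invisible(x)
}
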