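# Full-reference image quality metrics: MSE, PSNR, SNR, global SSIM.
#
# All four operate on the whole image: means, variances and covariance are
# population statistics (divide by the pixel count G), and the logarithms
# are base 10 so SNR/PSNR are in decibels.

check_same_shape <- function(ri, rj) {
  a <- as_pixels(ri, "ri"); b <- as_pixels(rj, "rj")
  if (!all(dim(a) == dim(b))) {
    stop_validation("images must have identical dimensions (",
                    paste(dim(a), collapse = "x"), " vs ",
                    paste(dim(b), collapse = "x"), ")")
  }
  list(a = a, b = b)
}

#' Mean squared error between two images
#'
#' `MSE = sum((ri - rj)^2) / G` with `G` the pixel count.
#'
#' @param ri,rj grayscale image matrices of identical shape
#' @return non-negative squared-intensity value
#' @export
img_mse <- function(ri, rj) {
  p <- check_same_shape(ri, rj)
  d <- as.numeric(p$a) - as.numeric(p$b)
  sum(d * d) / length(d)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `PSNR = 10 * log10(G_max^2 / MSE)`, `+Inf` for identical images.
#'
#' @inheritParams img_mse
#' @param g_max peak representable intensity (255 for 8-bit)
#' @return decibel value, possibly `Inf`
#' @export
img_psnr <- function(ri, rj, g_max = 255) {
  m <- img_mse(ri, rj)
  if (m == 0) return(Inf)
  10 * log10(g_max^2 / m)
}

#' Signal-to-noise ratio in decibels
#'
#' `SNR = 10 * log10( sum((ri - mean(ri))^2) / sum((ri - rj)^2) )`: signal
#' power is the variance of the reference about its own mean, noise power
#' the residual against the test image. `+Inf` for identical images.
#'
#' @inheritParams img_mse
#' @return decibel value, possibly `Inf`
#' @export
img_snr <- function(ri, rj) {
  p <- check_same_shape(ri, rj)
  a <- as.numeric(p$a)
  resid <- a - as.numeric(p$b)
  noise <- sum(resid * resid)
  if (noise == 0) return(Inf)
  signal <- sum((a - mean(a))^2)
  if (signal == 0) {
    stop_validation("SNR undefined: constant reference image with nonzero residual")
  }
  10 * log10(signal / noise)
}

#' Stabilisation constants for SSIM
#'
#' `c1 = (k1 * G_max)^2`, `c2 = (k2 * G_max)^2`, `c3 = c2 / 2`, with the
#' conventional `k1 = 0.01`, `k2 = 0.03`. With `c3 = c2/2` the
#' three-factor product below reduces algebraically to the familiar
#' two-factor SSIM.
#'
#' @param k1,k2 small dimensionless constants
#' @param g_max peak representable intensity
#' @param c1,c2,c3 direct overrides of the stabilisers
#' @return list with positive `c1`, `c2`, `c3`
#' @export
ssim_params <- function(k1 = 0.01, k2 = 0.03, g_max = 255,
                        c1 = NULL, c2 = NULL, c3 = NULL) {
  c1 <- c1 %||% (k1 * g_max)^2
  c2 <- c2 %||% (k2 * g_max)^2
  c3 <- c3 %||% (c2 / 2)
  if (c1 <= 0 || c2 <= 0 || c3 <= 0) stop_validation("c1, c2, c3 must be positive")
  list(c1 = c1, c2 = c2, c3 = c3)
}

#' Global structural similarity index
#'
#' Whole-image three-factor SSIM: luminance
#' `(2*mu_i*mu_j + c1) / (mu_i^2 + mu_j^2 + c1)`, contrast
#' `(2*sd_i*sd_j + c2) / (sd_i^2 + sd_j^2 + c2)` and structure
#' `(cov + c3) / (sd_i*sd_j + c3)`, with population moments over all
#' pixels. A single window spans the full image; no sliding-window
#' averaging is applied.
#'
#' @inheritParams img_mse
#' @param params a [ssim_params()] list
#' @return dimensionless value in (-1, 1]; 1 for identical images
#' @export
img_ssim <- function(ri, rj, params = ssim_params()) {
  p <- check_same_shape(ri, rj)
  a <- as.numeric(p$a); b <- as.numeric(p$b)
  g <- length(a)
  mu_i <- mean(a); mu_j <- mean(b)
  var_i <- sum((a - mu_i)^2) / g
  var_j <- sum((b - mu_j)^2) / g
  sd_i <- sqrt(var_i); sd_j <- sqrt(var_j)
  cov_ij <- sum((a - mu_i) * (b - mu_j)) / g
  lum <- (2 * mu_i * mu_j + params$c1) / (mu_i^2 + mu_j^2 + params$c1)
  con <- (2 * sd_i * sd_j + params$c2) / (var_i + var_j + params$c2)
  str <- (cov_ij + params$c3) / (sd_i * sd_j + params$c3)
  lum * con * str
}

#' All four quality metrics at once
#'
#' @inheritParams img_mse
#' @param g_max peak representable intensity
#' @return list with `snr_db`, `psnr_db`, `mse`, `ssim`
#' @export
quality_metrics <- function(ri, rj, g_max = 255) {
  list(snr_db = img_snr(ri, rj),
       psnr_db = img_psnr(ri, rj, g_max),
       mse = img_mse(ri, rj),
       ssim = img_ssim(ri, rj, ssim_params(g_max = g_max)))
}
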