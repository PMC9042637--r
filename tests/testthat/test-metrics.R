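# Quality metrics: closed forms, fixed points, and agreement with an
# independently coded oracle.

# oracle metrics written from the textbook definitions, no shared code
oracle_metrics <- function(a, b, g_max = 255) {
  a <- as.numeric(a); b <- as.numeric(b)
  mse <- mean((a - b)^2)
  list(mse = mse,
       psnr = if (mse == 0) Inf else 20 * log10(g_max) - 10 * log10(mse),
       snr = if (all(a == b)) Inf else
         10 * (log10(sum((a - mean(a))^2)) - log10(sum((a - b)^2))))
}

# conventional two-factor SSIM (population moments, whole image)
two_factor_ssim <- function(a, b, c1, c2) {
  a <- as.numeric(a); b <- as.numeric(b); g <- length(a)
  mu_a <- mean(a); mu_b <- mean(b)
  va <- sum((a - mu_a)^2) / g; vb <- sum((b - mu_b)^2) / g
  cab <- sum((a - mu_a) * (b - mu_b)) / g
  (2 * mu_a * mu_b + c1) * (2 * cab + c2) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
}

test_that("MSE closed forms", {
  a <- gray_image(matrix(c(0L, 0L), 1, 2))
  b <- gray_image(matrix(c(0L, 2L), 1, 2))
  expect_equal(img_mse(a, a), 0)
  expect_equal(img_mse(a, b), 2.0)
  c1 <- gray_image(matrix(30L, 4, 4)); c2 <- gray_image(matrix(90L, 4, 4))
  expect_equal(img_mse(c1, c2), (30 - 90)^2)
  expect_error(img_mse(a, c1), class = "usenhance_validation")
})

test_that("PSNR fixed points and scaling law", {
  a <- gray_image(matrix(0L, 3, 3)); b <- gray_image(matrix(255L, 3, 3))
  expect_identical(img_psnr(a, a), Inf)
  expect_equal(img_psnr(a, b), 0)  # MSE == G_max^2
  # halving MSE raises PSNR by 10*log10(2)
  x <- gray_image(matrix(c(10L, 10L), 1, 2))
  y2 <- gray_image(matrix(c(10L, 12L), 1, 2))  # MSE 2
  y4 <- gray_image(matrix(c(12L, 12L), 1, 2))  # MSE 4
  expect_equal(img_psnr(x, y2) - img_psnr(x, y4), 10 * log10(2))
})

test_that("SNR substitution example and shift law", {
  ri <- gray_image(matrix(c(0L, 2L), 1, 2))
  rj <- gray_image(matrix(c(0L, 0L), 1, 2))
  expect_equal(img_snr(ri, rj), 10 * log10(0.5))  # ~ -3.0103 dB
  expect_identical(img_snr(ri, ri), Inf)
  # SNR is invariant under joint amplitude scaling of signal and residual
  ri2 <- gray_image(matrix(c(0L, 20L), 1, 2))
  rj2 <- gray_image(matrix(c(0L, 0L), 1, 2))
  expect_equal(img_snr(ri, rj), img_snr(ri2, rj2))
  expect_error(img_snr(gray_image(matrix(5L, 2, 2)), gray_image(matrix(6L, 2, 2))),
               class = "usenhance_validation")
})

test_that("metric oracles agree on random image pairs", {
  for (seed in 1:10) {
    a <- random_image(24, 24, seed)
    b <- random_image(24, 24, seed + 1000)
    o <- oracle_metrics(a, b)
    expect_equal(img_mse(a, b), o$mse, tolerance = 1e-12)
    expect_equal(img_psnr(a, b), o$psnr, tolerance = 1e-12)
    expect_equal(img_snr(a, b), o$snr, tolerance = 1e-12)
    expect_equal(img_mse(a, b), img_mse(b, a))  # symmetry
  }
})

test_that("PSNR is strictly decreasing in MSE", {
  base <- gray_image(matrix(100L, 8, 8))
  mses <- psnrs <- numeric(0)
  for (k in c(1L, 3L, 9L, 27L)) {
    pert <- gray_image(matrix(100L + k, 8, 8))
    mses <- c(mses, img_mse(base, pert))
    psnrs <- c(psnrs, img_psnr(base, pert))
  }
  expect_true(all(diff(mses) > 0))
  expect_true(all(diff(psnrs) < 0))
})

test_that("SSIM equals 1 exactly for identical images", {
  for (seed in 1:5) {
    a <- random_image(16, 16, seed)
    expect_equal(img_ssim(a, a), 1.0, tolerance = 1e-12)
  }
})

test_that("SSIM of independent noise images is near zero", {
  vals <- vapply(1:20, function(seed) {
    a <- random_image(64, 64, seed)
    b <- random_image(64, 64, seed + 5000)
    img_ssim(a, b)
  }, numeric(1))
  expect_true(all(abs(vals) < 0.2))
})

test_that("contrast inversion lowers SSIM through the structure term", {
  for (seed in 1:5) {
    a <- random_image(32, 32, seed)
    inv <- gray_image(255L - unclass(a))
    expect_lt(img_ssim(a, inv), img_ssim(a, a))
    expect_lt(img_ssim(a, inv), 0)  # negative covariance dominates
  }
})

test_that("three-factor SSIM with c3 = c2/2 equals the two-factor form", {
  p <- ssim_params()
  for (seed in 1:20) {
    a <- random_image(32, 32, seed)
    b <- gray_image(clamp_round(unclass(a) * 0.8 + seed))
    s3 <- img_ssim(a, b, p)
    s2 <- two_factor_ssim(a, b, p$c1, p$c2)
    expect_equal(s3, s2, tolerance = 1e-10)
  }
})

test_that("SSIM stays within (-1, 1] on arbitrary pairs", {
  for (seed in 1:10) {
    a <- random_image(16, 16, seed)
    b <- random_image(16, 16, seed + 77)
    s <- img_ssim(a, b)
    expect_true(s > -1 && s <= 1)
  }
})
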