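# Sorted-window statistics and the two-stage decision rules on hand-worked
# windows.

test_that("sorted window statistics match the hand-sorted worked example", {
  w <- sorted_window(worked_window_image(), 2, 2, 3)
  expect_equal(w$S, c(10L, 10L, 10L, 20L, 30L, 40L, 50L, 60L, 200L))
  expect_equal(w$center, 10L)
  expect_equal(w$s_min, 10L)
  expect_equal(w$s_max, 200L)
  expect_equal(w$s_med, 30L)
  expect_equal(w$n1, 3L)  # first entry above the minimum, 0-based
  expect_equal(w$n2, 7L)  # last entry below the maximum, 0-based
})

test_that("sorted window invariants hold on random windows", {
  for (seed in 1:25) {
    img <- random_image(9, 9, seed)
    w <- sorted_window(img, 5, 5, sample(c(3L, 5L, 7L), 1))
    mm <- w$M^2
    expect_length(w$S, mm)
    expect_true(all(diff(w$S) >= 0))
    expect_identical(w$S[1], w$s_min)
    expect_identical(w$S[mm], w$s_max)
    expect_identical(w$S[(mm + 1) %/% 2], w$s_med)
    if (w$s_min != w$s_max) {
      expect_true(w$S[w$n1 + 1] > w$s_min)
      expect_true(w$S[w$n2 + 1] < w$s_max)
      expect_true(w$n1 >= 1)
      expect_true(w$n2 <= mm - 2)
    }
  }
})

test_that("constant windows have undefined interior positions", {
  w <- sorted_window(gray_image(matrix(5L, 5, 5)), 3, 3, 3)
  expect_identical(w$s_min, 5L)
  expect_identical(w$s_max, 5L)
  expect_identical(w$s_med, 5L)
  expect_true(is.na(w$n1) && is.na(w$n2))
})

test_that("window validation rejects bad inputs", {
  img <- random_image(8, 8, 1)
  expect_error(sorted_window(img, 1, 1, 4), class = "usenhance_validation")
  expect_error(sorted_window(img, 1, 1, -3), class = "usenhance_validation")
  expect_error(sorted_window(img, 9, 1, 3), class = "usenhance_validation")
})

test_that("extremum screening follows the median-reliability rule", {
  w <- sorted_window(worked_window_image(), 2, 2, 3)
  expect_identical(classify_candidate(w), "quasi_noise")  # centre is the minimum

  # non-extreme centre is always signal
  img <- worked_window_image()
  img[2, 2] <- 30L
  expect_identical(classify_candidate(sorted_window(img, 2, 2, 3)), "signal")

  # constant window is signal
  expect_identical(
    classify_candidate(sorted_window(gray_image(matrix(5L, 3, 3)), 2, 2, 3)),
    "signal")

  # impulse-valued median means the median itself cannot be trusted
  img <- gray_image(matrix(c(rep(255L, 8), 10L), 3, 3))
  expect_identical(classify_candidate(sorted_window(img, 2, 2, 3)), "signal")

  # an impulse on a flat (but non-constant-window) background is a candidate
  img <- gray_image(matrix(50L, 3, 3)); img[2, 2] <- 255L
  expect_identical(classify_candidate(sorted_window(img, 2, 2, 3)), "quasi_noise")
})

test_that("K1 matches direct substitution on the worked window", {
  w <- sorted_window(worked_window_image(), 2, 2, 3)
  # minimum case: (S[N1] - F) / ((N1 + 1)/2) = (20 - 10) / 2
  expect_equal(slope_k1(w, "symmetric"), 5.0)
  expect_equal(slope_k1(w, "as_printed"), 5.0)  # variants differ only for maxima

  # maximum case: replace the centre by the maximum value
  img <- worked_window_image()
  img[img == 200L] <- 60L
  img[2, 2] <- 200L
  wmax <- sorted_window(img, 2, 2, 3)
  expect_identical(wmax$center, wmax$s_max)
  # as printed: (F - S[N1]) / (M*M - 1 - N2) = (200 - 20) / 1
  expect_equal(slope_k1(wmax, "as_printed"), 180.0)
  # symmetric: slope from N2 to the midpoint of the maxima = (200 - 60) / 1
  expect_equal(slope_k1(wmax, "symmetric"), 140.0)
})

test_that("K1 is undefined for constant windows", {
  w <- sorted_window(gray_image(matrix(7L, 3, 3)), 2, 2, 3)
  expect_error(slope_k1(w), class = "usenhance_validation")
})

test_that("K2 is the average interior slope with degenerate cases at 0", {
  w <- sorted_window(worked_window_image(), 2, 2, 3)
  expect_equal(slope_k2(w), (60 - 20) / (7 - 3))  # = 10

  # flat interior: S[N1] == S[N2]
  img <- gray_image(matrix(c(0L, rep(100L, 7L), 255L), 3, 3))
  expect_equal(slope_k2(sorted_window(img, 2, 2, 3)), 0)

  # two-valued window: no strict interior at all
  img <- gray_image(matrix(c(rep(0L, 8L), 255L), 3, 3))
  expect_equal(slope_k2(sorted_window(img, 2, 2, 3)), 0)
})

test_that("threshold Q scales the median by 1/epsilon", {
  expect_equal(threshold_q(30L, 3L), 10.0)
  expect_equal(threshold_q(0L, 5L), 0.0)
  expect_equal(threshold_q(113L, 1L), 113.0)
  expect_error(threshold_q(30L, 0L), class = "usenhance_validation")
})

test_that("confirmation combines K1, K2 and Q per the selected rule", {
  expect_false(confirm_noise(5, 10, 10, "k1_vs_q"))
  expect_true(confirm_noise(180, 10, 10, "k1_vs_q"))
  expect_true(confirm_noise(180, 10, 10, "k1_vs_k2_and_q"))
  expect_false(confirm_noise(8, 10, 5, "k1_vs_k2_and_q"))   # |K1| <= |K2|
  expect_true(confirm_noise(-12, 10, 11, "k1_vs_k2_and_q")) # absolute values
  expect_true(confirm_noise(0.5, 0, 0, "k1_vs_q"))          # zero threshold
})
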