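# Grayscale morphology: hand-checked filters, algebraic identities, and
# the gradient operators.

se3 <- se_square(3L)
se_h3 <- structuring_element(matrix(TRUE, 1, 3))  # 1x3 horizontal bar

row_img <- function(v) gray_image(matrix(as.integer(v), 1))

test_that("dilation and erosion match the hand-computed 1x5 examples", {
  g <- row_img(c(0, 0, 9, 0, 0))
  expect_equal(as.vector(dilate(g, se_h3)), c(0L, 9L, 9L, 9L, 0L))
  expect_equal(as.vector(erode(g, se_h3)), c(0L, 0L, 0L, 0L, 0L))
  expect_equal(as.vector(opening(g, se_h3)), c(0L, 0L, 0L, 0L, 0L))
})

test_that("constant images are fixed points of all four transforms", {
  g <- gray_image(matrix(77L, 6, 6))
  for (f in list(dilate, erode, opening, closing)) {
    expect_equal(unclass(f(g, se3)), unclass(unclass(g)), ignore_attr = TRUE)
  }
})

test_that("a single-pixel structuring element is the identity", {
  g <- random_image(12, 10, 3)
  se1 <- structuring_element(matrix(TRUE, 1, 1))
  expect_equal(as.vector(dilate(g, se1)), as.vector(g))
  expect_equal(as.vector(erode(g, se1)), as.vector(g))
})

test_that("ordering chain erode <= opening <= g <= closing <= dilate", {
  for (seed in 1:10) {
    g <- random_image(24, 24, seed)
    er <- erode(g, se3); op <- opening(g, se3)
    cl <- closing(g, se3); di <- dilate(g, se3)
    expect_true(all(er <= op))
    expect_true(all(op <= unclass(g)))
    expect_true(all(unclass(g) <= cl))
    expect_true(all(cl <= di))
  }
})

test_that("opening and closing are idempotent", {
  for (seed in 1:5) {
    g <- random_image(20, 20, seed)
    expect_equal(as.vector(opening(opening(g, se3), se3)),
                 as.vector(opening(g, se3)))
    expect_equal(as.vector(closing(closing(g, se3), se3)),
                 as.vector(closing(g, se3)))
  }
})

test_that("dilation and erosion are dual under complement for symmetric SEs", {
  for (seed in 1:5) {
    g <- random_image(16, 16, seed)
    comp <- gray_image(255L - unclass(g))
    expect_equal(as.vector(erode(g, se3)),
                 as.vector(255L - unclass(dilate(comp, se3))))
  }
})

test_that("empty or anchor-less structuring elements are rejected", {
  expect_error(structuring_element(matrix(FALSE, 3, 3)),
               class = "usenhance_validation")
  m <- matrix(TRUE, 3, 3); m[2, 2] <- FALSE
  expect_error(structuring_element(m),  # default anchor cell must be in D
               class = "usenhance_validation")
})

test_that("all five gradients vanish on constant images", {
  g <- gray_image(matrix(42L, 8, 8))
  for (op in c("P1", "P2", "P3", "P4", "P5")) {
    expect_true(all(morph_gradient(g, se3, op) == 0L), info = op)
  }
})

test_that("a vertical step responds only within SE reach of the step", {
  g <- step_image(12, 12, 0L, 200L)  # step between columns 6 and 7
  for (op in c("P1", "P2", "P3", "P4", "P5")) {
    e <- morph_gradient(g, se3, op)
    nonzero_cols <- which(colSums(unclass(e)) > 0)
    expect_true(length(nonzero_cols) > 0, info = op)
    # 3x3 pieces composed at most twice: reach <= 2 columns from the step
    expect_true(all(nonzero_cols >= 5 & nonzero_cols <= 8), info = op)
  }
  # P1 = dilate - closing responds on the dark side of the step only
  e1 <- morph_gradient(g, se3, "P1")
  expect_true(all(unclass(e1)[, 6] > 0))
  expect_true(all(unclass(e1)[, 7] == 0))
})

test_that("P2 suppresses an isolated impulse entirely", {
  g <- row_img(c(0, 0, 9, 0, 0))
  expect_true(all(morph_gradient(g, se_h3, "P2") == 0L))
})

test_that("opening/closing-based gradients respond less to impulses than
           the plain dilate-minus-erode gradient", {
  set.seed(11)
  px <- matrix(60L, 24, 24)
  idx <- sample(length(px), 8)
  px[idx] <- 255L  # isolated impulses on a flat field
  g <- gray_image(px)
  plain <- sum(unclass(dilate(g, se3)) - unclass(erode(g, se3)) > 0)
  for (op in c("P2", "P3", "P4", "P5")) {
    e <- morph_gradient(g, se3, op)
    expect_lt(sum(e > 0), plain)
  }
})

test_that("P1, P2, P4 and P5 are non-negative before clamping", {
  for (seed in 1:5) {
    g <- random_image(16, 16, seed)
    px <- unclass(g)
    d <- unclass(dilate(g, se3)); cl <- unclass(closing(g, se3))
    op <- unclass(opening(g, se3)); er <- unclass(erode(g, se3))
    expect_true(all(d - cl >= 0))
    expect_true(all(op - er >= 0))
    expect_true(all(unclass(dilate(opening(g, se3), se3)) - op >= 0))
    expect_true(all(cl - unclass(erode(closing(g, se3), se3)) >= 0))
  }
})

test_that("structuring elements load from text masks with anchors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("010", "1*1", "010"), path)
  se <- read_se(path)
  expect_true(se$mask[2, 2])
  expect_false(se$mask[1, 1])
  expect_equal(se$anchor, c(2L, 2L))
})
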