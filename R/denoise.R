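# Two-stage adaptive median impulse filter.
#
# Stage 1 (screening): at the initial window size, a pixel equal to the
# window extreme while the window median is strictly interior is a
# quasi-noise candidate; all other pixels are signal and are copied
# unchanged. Stage 2 (confirmation): the candidate's local slope K1 is
# compared against the window-average slope K2 and the adaptive threshold
# Q = S_med/epsilon. Confirmed noise is replaced by the median of the
# smallest window (growing M0 -> M0+2 -> ... -> M_max) whose median is not
# itself a window extreme; if none qualifies, the M_max median is used.

LABEL_SIGNAL <- 0L
LABEL_QUASI  <- 1L   # screened as candidate but not confirmed; unchanged
LABEL_NOISE  <- 2L   # confirmed and replaced

#' Adaptive median impulse-noise filtering
#'
#' Removes salt-and-pepper impulse noise while leaving signal pixels
#' bit-identical. See [filter_params()] for the tunable parameters and the
#' package vignette for the decision rules.
#'
#' @param img grayscale image matrix (0..255)
#' @param params a [filter_params()] object
#' @return list with `image` (the filtered [gray_image()]) and `labels`
#'   (integer matrix: 0 = signal, 1 = quasi-noise candidate left unchanged,
#'   2 = confirmed noise, replaced)
#' @examples
#' img <- gray_image(matrix(50L, 11, 11))
#' img[6, 6] <- 255L
#' out <- denoise(img, filter_params(epsilon = 2))
#' out$image[6, 6]
#' @export
denoise <- function(img, params = filter_params()) {
  px <- as_pixels(img)
  stopifnot(inherits(params, "filter_params"))
  res <- denoise_cpp(px, params$epsilon, params$M0, params$M_max,
                     match(params$k1_variant, c("symmetric", "as_printed")),
                     match(params$confirm_rule, c("k1_vs_q", "k1_vs_k2_and_q")),
                     match(params$border_mode, c("reflect", "edge_replicate")))
  list(image = gray_image(res$image), labels = res$labels)
}

#' Literal reference implementation of [denoise()]
#'
#' A direct, unoptimised per-pixel transcription of the decision rules,
#' built from [sorted_window()], [classify_candidate()], [slope_k1()],
#' [slope_k2()], [threshold_q()] and [confirm_noise()]. Intended for
#' verification on small images; agrees with [denoise()] pixel-for-pixel.
#'
#' @inheritParams denoise
#' @return same structure as [denoise()]
#' @export
brute_force_denoise <- function(img, params = filter_params()) {
  px <- as_pixels(img)
  stopifnot(inherits(params, "filter_params"))
  h <- nrow(px); w <- ncol(px)
  out <- px
  labels <- matrix(LABEL_SIGNAL, h, w)
  for (a in seq_len(h)) {
    for (b in seq_len(w)) {
      ws <- sorted_window(px, a, b, params$M0, params$border_mode)
      if (classify_candidate(ws) != "quasi_noise") next
      k1 <- slope_k1(ws, params$k1_variant)
      k2 <- slope_k2(ws)
      q <- threshold_q(ws$s_med, params$epsilon)
      if (!confirm_noise(k1, k2, q, params$confirm_rule)) {
        labels[a, b] <- LABEL_QUASI
        next
      }
      labels[a, b] <- LABEL_NOISE
      repl <- NA_integer_
      for (m in seq.int(params$M0, params$M_max, by = 2L)) {
        wm <- sorted_window(px, a, b, m, params$border_mode)
        if (wm$s_med > wm$s_min && wm$s_med < wm$s_max) {
          repl <- wm$s_med
          break
        }
        repl <- wm$s_med  # falls through to the M_max median
      }
      out[a, b] <- repl
    }
  }
  list(image = gray_image(out), labels = labels)
}
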