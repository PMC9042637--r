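# Per-window statistics and the two-stage impulse-noise decision rules.
#
# Terminology: for a pixel F(a,b) and an odd M x M window centred on it, S
# is the ascending array of all window intensities. S_min, S_max, S_med are
# its minimum, maximum and median; N1 is the position of the first entry
# strictly above S_min (the "maximum non-minimum" boundary) and N2 the
# position of the last entry strictly below S_max (the "minimum
# non-maximum" boundary). N1/N2 are 0-based positions so that the slope
# formulas below read exactly as defined.

#' Filter parameters for the adaptive median impulse filter
#'
#' @param epsilon positive integer; the confirmation threshold is
#'   `Q = S_med / epsilon`, so larger `epsilon` makes the detector more
#'   aggressive. Default 2.
#' @param M0 initial (odd) window side length, default 3
#' @param M_max maximum (odd) window side length for the adaptive growth
#'   stage, default 7
#' @param k1_variant `"symmetric"` (default) measures the maximum-case local
#'   slope against `S[N2]`, mirroring the minimum case; `"as_printed"`
#'   measures it against `S[N1]`. See the methods vignette for why the
#'   symmetric form is the default.
#' @param confirm_rule `"k1_vs_q"` (default): a candidate is noise iff
#'   `|K1| >= Q`; `"k1_vs_k2_and_q"`: noise iff `|K1| > |K2|` and
#'   `|K1| >= Q`.
#' @param border_mode `"reflect"` (default) or `"edge_replicate"` border
#'   extension for windows overlapping the image edge
#' @return list of class `filter_params`
#' @export
filter_params <- function(epsilon = 2L, M0 = 3L, M_max = 7L,
                          k1_variant = c("symmetric", "as_printed"),
                          confirm_rule = c("k1_vs_q", "k1_vs_k2_and_q"),
                          border_mode = c("reflect", "edge_replicate")) {
  k1_variant <- match.arg(k1_variant)
  confirm_rule <- match.arg(confirm_rule)
  border_mode <- match.arg(border_mode)
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon < 1 ||
      epsilon != round(epsilon)) {
    stop_validation("'epsilon' must be a positive integer")
  }
  check_window_side <- function(m, what) {
    if (length(m) != 1L || is.na(m) || m < 3L || m %% 2L == 0L) {
      stop_validation("'", what, "' must be an odd integer >= 3")
    }
  }
  check_window_side(M0, "M0")
  check_window_side(M_max, "M_max")
  if (M0 > M_max) stop_validation("'M0' must not exceed 'M_max'")
  structure(list(epsilon = as.integer(epsilon), M0 = as.integer(M0),
                 M_max = as.integer(M_max), k1_variant = k1_variant,
                 confirm_rule = confirm_rule, border_mode = border_mode),
            class = "filter_params")
}

#' Sorted-window statistics at one pixel
#'
#' Builds the ascending array S of the M x M window centred at `(a, b)` and
#' locates its minimum, maximum, median and the 0-based positions `n1`
#' (first entry strictly above the minimum) and `n2` (last entry strictly
#' below the maximum). For a constant window `n1`/`n2` are undefined and
#' returned as `NA`.
#'
#' @param img grayscale image matrix
#' @param a,b 1-based row and column of the centre pixel
#' @param M odd window side length
#' @param border_mode border extension, see [filter_params()]
#' @return list of class `window_stats` with fields `center`, `S`, `M`,
#'   `s_min`, `s_max`, `s_med`, `n1`, `n2`
#' @examples
#' img <- gray_image(matrix(c(10, 20, 30, 40, 10, 50, 60, 200, 10), 3, 3))
#' sorted_window(img, 2, 2, 3)
#' @export
sorted_window <- function(img, a, b, M = 3L,
                          border_mode = c("reflect", "edge_replicate")) {
  border_mode <- match.arg(border_mode)
  px <- as_pixels(img)
  if (length(M) != 1L || is.na(M) || M < 3L || M %% 2L == 0L) {
    stop_validation("'M' must be an odd integer >= 3")
  }
  if (a < 1L || a > nrow(px) || b < 1L || b > ncol(px)) {
    stop_validation("window centre (", a, ", ", b, ") lies outside the image")
  }
  k <- (M - 1L) %/% 2L
  rows <- border_index(seq.int(a - k, a + k), nrow(px), border_mode)
  cols <- border_index(seq.int(b - k, b + k), ncol(px), border_mode)
  vals <- px[rows, cols, drop = FALSE]
  window_stats(center = px[a, b], values = as.vector(vals), M = M)
}

# internal constructor shared by sorted_window and the brute-force filter
window_stats <- function(center, values, M) {
  S <- sort.int(as.integer(values), method = "radix")
  mm <- length(S)
  s_min <- S[1L]
  s_max <- S[mm]
  s_med <- S[(mm + 1L) %/% 2L]  # 0-based position (M*M - 1)/2
  if (s_min == s_max) {
    n1 <- NA_integer_
    n2 <- NA_integer_
  } else {
    n1 <- which(S > s_min)[1L] - 1L            # 0-based first above minimum
    n2 <- mm - which(rev(S) < s_max)[1L]       # 0-based last below maximum
  }
  structure(list(center = as.integer(center), S = S, M = as.integer(M),
                 s_min = s_min, s_max = s_max, s_med = s_med,
                 n1 = n1, n2 = n2),
            class = "window_stats")
}

#' First-stage screening: is the centre pixel a quasi-noise candidate?
#'
#' A pixel is a quasi-noise point iff it is the extreme point of its window
#' (equal to S_min or S_max, but not to the median — a centre tied with the
#' window median is the window's typical value, not its extreme point)
#' while the window median is itself "not noise", i.e. not an impulse
#' value: `0 < S_med < G_max`. The value-based reading of median
#' reliability is what lets the filter catch impulses sitting on flat
#' backgrounds, where the window median coincides with S_min or S_max yet
#' is perfectly trustworthy. Constant windows carry no contrast and are
#' always signal; signal pixels are never modified.
#'
#' @param w a [sorted_window()] result
#' @param g_max maximum representable intensity (255 for 8-bit)
#' @return `"quasi_noise"` or `"signal"`
#' @export
classify_candidate <- function(w, g_max = 255L) {
  stopifnot(inherits(w, "window_stats"))
  if (w$s_min == w$s_max) return("signal")  # constant window
  is_extreme <- (w$center == w$s_min || w$center == w$s_max) &&
    w$center != w$s_med
  med_clean <- w$s_med > 0L && w$s_med < g_max
  if (is_extreme && med_clean) "quasi_noise" else "signal"
}

#' Local slope K1 at an extreme-valued centre pixel
#'
#' For a minimum-valued centre, K1 is the slope from `S[N1]` down to the
#' midpoint of the run of minimum values: `K1 = (S[N1] - F) / ((N1 + 1)/2)`.
#' For a maximum-valued centre the `"symmetric"` variant mirrors this
#' exactly across the top of the sorted array — the slope from `S[N2]` up
#' to the midpoint of the run of maxima,
#' `K1 = (F - S[N2]) / ((M*M - N2)/2)` — while the `"as_printed"` variant
#' is `K1 = (F - S[N1]) / (M*M - 1 - N2)`. The two variants coincide in
#' denominator whenever the window maximum is unique.
#'
#' @param w a [sorted_window()] result whose centre is a window extreme
#' @param variant `"symmetric"` or `"as_printed"`
#' @return the real-valued slope
#' @export
slope_k1 <- function(w, variant = c("symmetric", "as_printed")) {
  variant <- match.arg(variant)
  stopifnot(inherits(w, "window_stats"))
  if (is.na(w$n1) || is.na(w$n2)) {
    stop_validation("K1 is undefined for a constant window (n1/n2 undefined)")
  }
  if (w$center == w$s_min) {
    (w$S[w$n1 + 1L] - w$center) / ((w$n1 + 1) / 2)
  } else if (w$center == w$s_max) {
    if (variant == "as_printed") {
      (w$center - w$S[w$n1 + 1L]) / (w$M * w$M - 1 - w$n2)
    } else {
      (w$center - w$S[w$n2 + 1L]) / ((w$M * w$M - w$n2) / 2)
    }
  } else {
    stop_validation("K1 requires the centre pixel to be a window extreme")
  }
}

#' Average interior slope K2 of the window
#'
#' `K2 = (S[N2] - S[N1]) / (N2 - N1)`, the mean slope of the sorted array
#' between the first above-minimum and last below-maximum entries. When the
#' interior collapses to a single point or is empty (`N2 <= N1`, as in a
#' two-valued window) the window carries no interior gradient and K2 is
#' defined as 0.
#'
#' @param w a [sorted_window()] result
#' @return the real-valued slope
#' @export
slope_k2 <- function(w) {
  stopifnot(inherits(w, "window_stats"))
  if (is.na(w$n1) || is.na(w$n2)) {
    stop_validation("K2 is undefined for a constant window (n1/n2 undefined)")
  }
  if (w$n2 <= w$n1) return(0)
  (w$S[w$n2 + 1L] - w$S[w$n1 + 1L]) / (w$n2 - w$n1)
}

#' Adaptive confirmation threshold Q
#'
#' `Q = S_med / epsilon`: the threshold scales with the window median, so
#' the detector demands steeper local slopes in bright regions than in dark
#' ones.
#'
#' @param s_med window median intensity
#' @param epsilon positive integer divisor
#' @return the real-valued threshold
#' @export
threshold_q <- function(s_med, epsilon) {
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon < 1 ||
      epsilon != round(epsilon)) {
    stop_validation("'epsilon' must be a positive integer")
  }
  s_med / as.numeric(epsilon)
}

#' Second-stage confirmation of a quasi-noise candidate
#'
#' @param k1,k2 local and window-average slopes
#' @param q threshold from [threshold_q()]
#' @param rule `"k1_vs_q"` (default): noise iff `|K1| >= Q`;
#'   `"k1_vs_k2_and_q"`: noise iff `|K1| > |K2|` and `|K1| >= Q`
#' @return logical: `TRUE` when the candidate is confirmed as noise
#' @export
confirm_noise <- function(k1, k2, q, rule = c("k1_vs_q", "k1_vs_k2_and_q")) {
  rule <- match.arg(rule)
  stopifnot(is.finite(k1), is.finite(k2), is.finite(q))
  if (rule == "k1_vs_q") {
    abs(k1) >= q
  } else {
    abs(k1) > abs(k2) && abs(k1) >= q
  }
}
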