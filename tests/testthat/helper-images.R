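# Shared fixtures, all generated in code.

random_image <- function(h, w, seed) {
  set.seed(seed)
  gray_image(matrix(sample(0:255, h * w, replace = TRUE), h, w))
}

# vertical step: left half `lo`, right half `hi`
step_image <- function(h, w, lo = 0L, hi = 200L) {
  px <- matrix(lo, h, w)
  px[, (w %/% 2 + 1):w] <- hi
  gray_image(px)
}

# the worked 3x3 window used throughout the filter tests:
# ascending array [10,10,10,20,30,40,50,60,200], centre 10
worked_window_image <- function() {
  gray_image(matrix(c(10, 20, 30, 40, 10, 50, 60, 200, 10), 3, 3))
}

clamp_round <- function(x) {
  matrix(as.integer(pmin(pmax(round(x), 0), 255)), nrow(x), ncol(x))
}

all_filter_params <- function(epsilons = c(1L, 2L, 4L, 8L)) {
  grid <- expand.grid(epsilon = epsilons,
                      k1_variant = c("symmetric", "as_printed"),
                      confirm_rule = c("k1_vs_q", "k1_vs_k2_and_q"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    filter_params(epsilon = grid$epsilon[i], k1_variant = grid$k1_variant[i],
                  confirm_rule = grid$confirm_rule[i])
  })
}
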