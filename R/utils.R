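# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map (possibly out-of-range) 1-based indices onto 1..n under a border rule
#'
#' `reflect` mirrors about the image edge with the edge pixel included
#' (..., 2, 1 | 1, 2, ...); `edge_replicate` clamps to the nearest valid
#' index. Vectorised; works for windows wider than the image.
#'
#' @param i integer vector of 1-based indices, may lie outside 1..n
#' @param n axis length
#' @param mode `"reflect"` or `"edge_replicate"`
#' @return integer vector of valid indices in 1..n
#' @keywords internal
border_index <- function(i, n, mode = c("reflect", "edge_replicate")) {
  mode <- match.arg(mode)
  if (mode == "edge_replicate") {
    return(pmin(pmax(i, 1L), n))
  }
  # symmetric reflection with period 2n, computed on 0-based indices
  r <- (i - 1L) %% (2L * n)
  r <- ifelse(r < 0L, r + 2L * n, r)
  ifelse(r < n, r + 1L, 2L * n - r)
}

#' Evaluate code under a fixed RNG seed without disturbing the caller's RNG
#' @keywords internal
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Clamp numeric values into the representable intensity range
#' @keywords internal
clamp_intensity <- function(x, g_max = 255L) {
  pmin(pmax(x, 0), g_max)
}

#' Stop with a validation error classed for programmatic handling
#' @keywords internal
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("usenhance_validation", "error")))
}

#' Stop with an I/O error classed for programmatic handling
#' @keywords internal
stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("usenhance_io", "error")))
}
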