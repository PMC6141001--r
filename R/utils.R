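# Cyclic mask utilities. Perimeter profiles are sampled on a closed curve, so
# every run-based operation must treat index n as adjacent to index 1.

#' Contiguous runs of TRUE in a cyclic mask
#'
#' Finds maximal runs of `TRUE` in a logical vector whose last element is
#' considered adjacent to its first (the mask lives on a closed fiber
#' perimeter). A run crossing the seam is reported once, with `end < start`.
#'
#' @param mask Logical vector.
#' @return A tibble with columns `start`, `end` (1-based sample indices,
#'   inclusive; `end < start` for a run wrapping the origin) and `length`.
#' @examples
#' cyclic_runs(c(TRUE, FALSE, TRUE, TRUE))  # one wrapped run 3..1
#' @export
cyclic_runs <- function(mask) {
  stopifnot(is.logical(mask))
  n <- length(mask)
  if (n == 0 || !any(mask)) {
    return(tibble::tibble(start = integer(), end = integer(), length = integer()))
  }
  if (all(mask)) {
    return(tibble::tibble(start = 1L, end = n, length = n))
  }
  # rotate so position 1 is FALSE, find runs, rotate back
  off <- which(!mask)[1] - 1L
  rot <- mask[((seq_len(n) - 1L + off) %% n) + 1L]
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- ((starts[keep] - 1L + off) %% n) + 1L
  ends <- ((ends[keep] - 1L + off) %% n) + 1L
  tibble::tibble(start = starts, end = ends, length = r$lengths[keep])
}

# Remove TRUE runs shorter than min_run (cyclically).
drop_short_runs <- function(mask, min_run) {
  if (min_run <= 1 || !any(mask)) return(mask)
  runs <- cyclic_runs(mask)
  n <- length(mask)
  for (i in seq_len(nrow(runs))) {
    if (runs$length[i] < min_run) {
      idx <- if (runs$end[i] >= runs$start[i]) {
        runs$start[i]:runs$end[i]
      } else {
        c(runs$start[i]:n, 1:runs$end[i])
      }
      mask[idx] <- FALSE
    }
  }
  mask
}

# Arc-fraction sampling grid: n equally spaced positions in [0, 1).
arc_fractions <- function(n) (seq_len(n) - 1) / n

# Logical mask over the n-sample grid covered by arc-fraction intervals
# [start, end); start > end wraps across the origin. Overlaps union.
mask_from_intervals <- function(start, end, n) {
  f <- arc_fractions(n)
  mask <- logical(n)
  for (i in seq_along(start)) {
    s <- start[i] %% 1; e <- end[i] %% 1
    if (s <= e) {
      mask <- mask | (f >= s & f < e)
    } else {
      mask <- mask | (f >= s | f < e)
    }
  }
  mask
}

# Circular arc distance between fractions a and b (in units of perimeter
# fraction, result in [0, 0.5]).
arc_distance <- function(a, b) {
  d <- abs(a - b) %% 1
  pmin(d, 1 - d)
}

# Run RNG-dependent code under a local seed without disturbing the caller's
# RNG state; seed = NULL runs as-is.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
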