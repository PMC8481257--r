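# Internal helpers shared across modules.

#' Logistic sigmoid
#' @param x numeric
#' @return 1 / (1 + exp(-x))
#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Rectified linear unit
#' @param x numeric
#' @return max(x, 0), elementwise
#' @keywords internal
relu <- function(x) pmax(x, 0)

# Deterministic 31-bit substream seed derived from a session seed and a
# stream name, so that independent randomness sources can be fanned out
# from one user-facing seed.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (cc in utf8ToInt(name)) h <- (h * 131 + cc) %% 2147483629
  as.integer((h + (as.numeric(seed) %% 2147483629) * 48271) %% 2147483629) + 1L
}

# Evaluate `expr` under a named substream of `seed`, restoring the caller's
# RNG state afterwards. If seed is NULL the global stream is used as-is.
with_substream <- function(seed, name, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}

# Maximal runs of TRUE in a logical vector, as a two-column matrix of
# (start, end) indices. Zero-row matrix when none.
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  cbind(start = starts[keep], end = ends[keep])
}
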