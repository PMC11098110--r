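#' Derive a reproducible child seed from a top-level seed
#'
#' Experiment drivers take a single top-level seed and expand it into one
#' child seed per replicate with a fixed multiplicative-congruential scheme,
#' so that replicate `k` can be re-run in isolation.  Child seeds stay below
#' 2^31 - 1.
#'
#' @param seed integer top-level seed.
#' @param k replicate counter (1-based); may be a vector.
#' @return integer vector of child seeds, same length as `k`.
#' @export
#' @examples
#' child_seed(1, 1:3)
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  s <- (abs(as.double(seed)) %% m) + 1
  as.integer((s * 48271 + as.double(k) * 16807) %% m + 1)
}

# wrap coordinates onto [0, L); guards against x %% L returning L itself
# for tiny negative floating-point inputs
wrap_torus <- function(x, L) {
  x <- x %% L
  x[x >= L] <- 0
  x
}

# 1-based cell row/col indices for continuous positions in [0, L)
cell_index <- function(x, L) {
  i <- floor(x) + 1L
  i[i > L] <- L  # safety against rounding at the upper boundary
  i
}

# linear (column-major) cell index for an N x 2 position matrix
cell_linear <- function(xy, L) {
  i <- cell_index(xy[, 1L], L)
  j <- cell_index(xy[, 2L], L)
  (j - 1L) * L + i
}

# positive scale parameter that may be Inf
check_scale <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number (Inf allowed), got %s",
                 name, deparse(x)), call. = FALSE)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
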