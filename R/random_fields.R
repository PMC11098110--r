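#' Torus (minimum-image) distance between points on a periodic lattice
#'
#' The landscape lives on an L x L torus: distances are measured under the
#' minimum-image convention, i.e. the Euclidean distance to the nearest of
#' the periodic copies of the second point.
#'
#' @param a,b numeric length-2 vectors or N x 2 matrices of coordinates
#'   (coordinates are reduced modulo `L` first).
#' @param L side length of the lattice.
#' @return numeric vector of distances; each is at most `L * sqrt(2) / 2`.
#' @export
#' @examples
#' torus_distance(c(0, 0), c(59, 0), 60)  # wraps around: 1, not 59
torus_distance <- function(a, b, L) {
  a <- matrix(a, ncol = 2L)
  b <- matrix(b, ncol = 2L)
  d <- abs(wrap_torus(a, L) - wrap_torus(b, L))
  d <- pmin(d, L - d)
  sqrt(d[, 1L]^2 + d[, 2L]^2)
}

# L x L matrix of minimum-image distances from cell (1,1) to every cell,
# i.e. the lag-distance grid used for stationary covariances on the torus
torus_lag_distances <- function(L) {
  lag <- pmin(0:(L - 1L), L - (0:(L - 1L)))
  sqrt(outer(lag^2, lag^2, "+"))
}

#' Spectral density of an exponential covariance on the periodic lattice
#'
#' Computes the 2-D discrete Fourier transform of the stationary covariance
#' `variance * exp(-d / scale)` evaluated at minimum-image lag distances `d`.
#' The wrapped exponential covariance is not guaranteed nonnegative-definite
#' on the torus, so slightly negative eigenvalues can occur; they are clamped
#' to zero and the removed mass is reported in the `"clamped_mass"` attribute
#' (as a fraction of the total spectral mass).
#'
#' @param L lattice side length.
#' @param scale correlation length in lattice units (> 0; `Inf` gives a
#'   constant field, handled separately in [grf_sample()]).
#' @param variance field variance (>= 0).
#' @return an L x L matrix of nonnegative spectral values with attribute
#'   `clamped_mass`.  `sum(spectrum) / L^2` equals `variance` up to the
#'   clamped mass (Parseval).
#' @export
spectral_density <- function(L, scale, variance = 1) {
  stopifnot(L >= 2, variance >= 0)
  check_scale(scale, "scale")
  if (variance == 0) {
    s <- matrix(0, L, L)
    attr(s, "clamped_mass") <- 0
    return(s)
  }
  d <- torus_lag_distances(L)
  cov <- if (is.infinite(scale)) matrix(variance, L, L) else
    variance * exp(-d / scale)
  s <- Re(stats::fft(cov))
  neg <- s < 0
  clamped <- -sum(s[neg])
  s[neg] <- 0
  attr(s, "clamped_mass") <- clamped / sum(s)
  s
}

#' Sample a stationary Gaussian random field on the torus
#'
#' Exact circulant (spectral) synthesis: the covariance
#' `variance * exp(-d/scale)` with minimum-image distance `d` is diagonalised
#' by the 2-D DFT, so a field is obtained by colouring white noise in the
#' frequency domain, at O(L^2 log L) per sample.  Negative spectral values
#' (a small wrap-around artifact, see [spectral_density()]) are clamped, so
#' the realised covariance deviates from the target by at most the clamped
#' mass.  `scale = Inf` is a dedicated branch: the field is spatially
#' constant, equal to a single Normal(0, variance) draw.
#'
#' Uses R's global random number generator; call `set.seed()` for
#' reproducibility.
#'
#' @inheritParams spectral_density
#' @param sqrt_spectrum optional precomputed `sqrt(spectral_density(...))`,
#'   for tight loops that draw many fields of the same specification.
#' @return an L x L numeric matrix, one zero-mean Gaussian field.
#' @export
#' @examples
#' set.seed(1)
#' f <- grf_sample(32, scale = 3)
#' round(var(as.vector(f)), 2)
grf_sample <- function(L, scale, variance = 1, sqrt_spectrum = NULL) {
  stopifnot(L >= 2, variance >= 0)
  check_scale(scale, "scale")
  if (variance == 0) return(matrix(0, L, L))
  if (is.infinite(scale))
    return(matrix(stats::rnorm(1L, 0, sqrt(variance)), L, L))
  if (is.null(sqrt_spectrum))
    sqrt_spectrum <- sqrt(spectral_density(L, scale, variance))
  w <- matrix(stats::rnorm(L * L), L, L)
  Re(stats::fft(sqrt_spectrum * stats::fft(w), inverse = TRUE)) / (L * L)
}
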