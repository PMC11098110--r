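# Shared helpers for the fragmeta test suite.

# brute-force minimum-image distance: enumerate the 9 periodic copies
enum_torus_distance <- function(a, b, L) {
  shifts <- expand.grid(sx = c(-L, 0, L), sy = c(-L, 0, L))
  min(sqrt((a[1] - b[1] - shifts$sx)^2 + (a[2] - b[2] - shifts$sy)^2))
}

# direct O(P^2) pairwise-sum oracle for the kernel-convolved local density:
# every propagule contributes its kernel weight at the minimum-image lag
# between cell centres
brute_force_density <- function(xy, alpha_c, L) {
  k <- fragmeta:::competition_kernel(L, alpha_c)
  ci <- floor(xy[, 1]) + 1L
  cj <- floor(xy[, 2]) + 1L
  p <- nrow(xy)
  n <- numeric(p)
  for (i in seq_len(p)) {
    di <- (ci - ci[i]) %% L + 1L
    dj <- (cj - cj[i]) %% L + 1L
    n[i] <- sum(k[cbind(di, dj)])
  }
  n
}

# small fragmented test landscape shared across experiment tests
test_fragmented_landscape <- function() {
  set.seed(101)
  make_fragmented(60, alpha_e = 3, threshold = 1.1)
}
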