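#' @title Landscape objects
#' @description A landscape is an L x L boolean habitat mask on a torus,
#'   together with a provenance record (how it was constructed).  Cells are
#'   unit squares; cell (i, j) covers coordinates `[i-1, i) x [j-1, j)`.
#' @param mask L x L logical matrix; `TRUE` = habitat, `FALSE` = matrix.
#' @param provenance named list recording construction type and parameters.
#' @return an object of class `"landscape"` with elements `L`, `mask`,
#'   `provenance`.
#' @export
landscape <- function(mask, provenance = list(type = "custom")) {
  mask <- as.matrix(mask)
  if (nrow(mask) != ncol(mask) || nrow(mask) < 2L)
    stop("`mask` must be a square matrix with side >= 2", call. = FALSE)
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("`mask` must not contain NA", call. = FALSE)
  structure(list(L = nrow(mask), mask = mask, provenance = provenance),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d torus, habitat cover %.3f (%d cells), type: %s\n",
              x$L, x$L, habitat_cover(x), sum(x$mask),
              x$provenance$type %||% "custom"))
  invisible(x)
}

#' @export
plot.landscape <- function(x, ...) {
  graphics::image(seq_len(x$L) - 0.5, seq_len(x$L) - 0.5, x$mask * 1,
                  col = grDevices::gray(c(0.95, 0.2)), asp = 1,
                  xlab = "x", ylab = "y",
                  main = x$provenance$type %||% "landscape", ...)
  invisible(x)
}

#' Proportional habitat cover
#'
#' @param x a [landscape()].
#' @return habitat cells divided by total cells, in `[0, 1]`.
#' @export
habitat_cover <- function(x) {
  stopifnot(inherits(x, "landscape"))
  mean(x$mask)
}

#' Homogeneous landscape (all habitat)
#'
#' @param L lattice side length (>= 2).
#' @return a [landscape()] with cover 1.
#' @export
make_homogeneous <- function(L) {
  stopifnot(L >= 2)
  landscape(matrix(TRUE, L, L), list(type = "homogeneous", L = L))
}

#' Irregularly fragmented landscape from a thresholded Gaussian random field
#'
#' A unit-variance Gaussian random field with exponential covariance
#' `exp(-d / alpha_e)` (minimum-image distance `d`) is sampled on the torus
#' and thresholded: a cell is habitat where the field exceeds `threshold`
#' (by default), so the expected cover is `1 - pnorm(threshold)`.  With
#' `alpha_e = 3` on a 60 x 60 lattice, thresholds 1.1 and 0.5 give the
#' "highly" (cover ~0.10-0.13) and "lowly" (~0.25-0.30) fragmented classes.
#'
#' @param L lattice side length.
#' @param alpha_e spatial scale of landscape heterogeneity (> 0).
#' @param threshold threshold applied to the unit-variance field.
#' @param direction `">"` (default) keeps the upper tail as habitat; `"<"`
#'   keeps the lower tail (then expected cover is `pnorm(threshold)`).
#' @param sqrt_spectrum optional precomputed square-root spectrum (see
#'   [grf_sample()]) for generating many landscapes of one specification.
#' @return a [landscape()]; provenance records the parameters.
#' @export
#' @examples
#' set.seed(7)
#' habitat_cover(make_fragmented(60, alpha_e = 3, threshold = 1.1))
make_fragmented <- function(L, alpha_e = 3, threshold, direction = ">",
                            sqrt_spectrum = NULL) {
  stopifnot(L >= 2, is.numeric(threshold), length(threshold) == 1L)
  check_scale(alpha_e, "alpha_e")
  direction <- match.arg(direction, c(">", "<"))
  eps <- grf_sample(L, scale = alpha_e, variance = 1,
                    sqrt_spectrum = sqrt_spectrum)
  mask <- if (direction == ">") eps > threshold else eps < threshold
  landscape(mask, list(type = "fragmented", L = L, alpha_e = alpha_e,
                       threshold = threshold, direction = direction))
}

#' Regular grid of equidistant identical square patches
#'
#' Places one `patch_side` x `patch_side` habitat patch in each
#' `spacing` x `spacing` block, anchored at the block origin, so all
#' nearest-neighbour patch distances equal `spacing` on the torus and the
#' cover is `(patch_side / spacing)^2`.  `spacing` must divide `L`, else
#' equidistance would break across the periodic boundary.
#'
#' @param L lattice side length.
#' @param patch_side patch side length in cells (<= `spacing`).
#' @param spacing distance between patch origins; must divide `L`.
#' @return a [landscape()].
#' @export
#' @examples
#' habitat_cover(make_regular_grid(60, 1, 3))  # 400/3600
make_regular_grid <- function(L, patch_side = 1, spacing = 3) {
  stopifnot(L >= 2, patch_side >= 1, spacing >= 1, patch_side <= spacing)
  if (L %% spacing != 0)
    stop("`spacing` must divide `L` to keep patches equidistant on the torus",
         call. = FALSE)
  offs <- seq_len(L) - 1L
  in_patch <- (offs %% spacing) < patch_side
  landscape(outer(in_patch, in_patch, "&"),
            list(type = "regular_grid", L = L, patch_side = patch_side,
                 spacing = spacing))
}

#' Subsample a square subregion and reset the periodic boundary
#'
#' Cuts an axis-aligned `size` x `size` window (wrapping around the torus)
#' at a uniformly random offset, and returns it as a new torus landscape of
#' side `size`.  Offsets may wrap, so sampling is unbiased with respect to
#' the original boundary.
#'
#' @param x a [landscape()].
#' @param size window side, `2 <= size <= L`.
#' @param offset optional integer length-2 cell offset (0-based) overriding
#'   the random draw, for reproducing a particular window.
#' @return a [landscape()] of side `size`; provenance records the offset.
#' @export
subsample_landscape <- function(x, size, offset = NULL) {
  stopifnot(inherits(x, "landscape"), size >= 2, size <= x$L)
  if (is.null(offset)) {
    offset <- c(sample.int(x$L, 1L), sample.int(x$L, 1L)) - 1L
  }
  stopifnot(length(offset) == 2L)
  offset <- as.integer(offset %% x$L)
  rows <- ((offset[1L] + seq_len(size) - 1L) %% x$L) + 1L
  cols <- ((offset[2L] + seq_len(size) - 1L) %% x$L) + 1L
  landscape(x$mask[rows, cols, drop = FALSE],
            c(list(type = "subsample", size = size, offset = offset),
              list(parent = x$provenance)))
}

#' Aggregate all habitat into one compact square patch
#'
#' Keeps lattice size and total habitat area fixed, but re-packs the `H`
#' habitat cells row-major into a block of side `ceiling(sqrt(H))` anchored
#' at cell (1, 1) (last row possibly partial).  This is the "habitat
#' aggregation" treatment used to isolate fragmentation per se: the same
#' amount of habitat, maximally compact.  On a torus the anchor position is
#' immaterial up to translation.  Idempotent.
#'
#' @param x a [landscape()].
#' @return a [landscape()] with identical habitat-cell count.
#' @export
aggregate_habitat <- function(x) {
  stopifnot(inherits(x, "landscape"))
  L <- x$L
  H <- sum(x$mask)
  mask <- matrix(FALSE, L, L)
  if (H > 0) {
    s <- ceiling(sqrt(H))
    full_rows <- H %/% s
    rem <- H %% s
    if (full_rows > 0) mask[seq_len(s), seq_len(full_rows)] <- TRUE
    if (rem > 0) mask[seq_len(rem), full_rows + 1L] <- TRUE
  }
  landscape(mask, c(list(type = "aggregated", H = H),
                    list(parent = x$provenance)))
}

#' Read and write landscape mask files
#'
#' Plain-text format: optional `#`-prefixed header lines of the form
#' `# key: value` carrying provenance, then `L` lines of `L` characters
#' `'0'`/`'1'` (one lattice row per line).  The round trip is bit-exact.
#'
#' @param x a [landscape()].
#' @param path file path.
#' @return `write_landscape()` returns `path` invisibly; `read_landscape()`
#'   returns a [landscape()].
#' @export
write_landscape <- function(x, path) {
  stopifnot(inherits(x, "landscape"))
  prov <- x$provenance
  keep <- vapply(prov, function(v) is.atomic(v) && length(v) <= 2L, logical(1))
  hdr <- sprintf("# %s: %s", names(prov)[keep],
                 vapply(prov[keep], function(v) paste(v, collapse = ","),
                        character(1)))
  rows <- apply(x$mask, 1L, function(r) paste(as.integer(r), collapse = ""))
  writeLines(c(sprintf("# L: %d", x$L), hdr, rows), path)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  prov <- list(type = "file")
  for (h in lines[is_hdr]) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) {
      val <- m[3L]
      num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1L]]))
      prov[[trimws(m[2L])]] <- if (anyNA(num)) val else num
    }
  }
  body <- lines[!is_hdr & nzchar(lines)]
  mask <- do.call(rbind, lapply(strsplit(body, ""), function(ch) ch == "1"))
  landscape(mask, prov)
}
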