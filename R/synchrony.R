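# Spatial synchrony: sampling-site grids, local occupancy/abundance, and
# across-replicate correlograms at the final generation.

#' Partition the landscape into m x m sampling sites
#'
#' Sites are contiguous m x m tiles covering the lattice exactly once;
#' neighbouring site edges are one lattice spacing apart, so site centres
#' are `m` apart (intersite distance ~2 for m = 2).  `m` must divide `L`.
#'
#' @param land a [landscape()].
#' @param m site side length in cells.
#' @return object of class `"site_grid"`: list with `m`, `n_side`,
#'   `n_sites`, `centers` (n_sites x 2 torus coordinates), `habitat_cells`
#'   (habitat cell count per site), and `site_of_cell` (L x L integer matrix
#'   mapping each cell to its site).
#' @export
build_site_grid <- function(land, m) {
  stopifnot(inherits(land, "landscape"), m >= 1)
  L <- land$L
  if (L %% m != 0)
    stop("`m` must divide the lattice side L", call. = FALSE)
  n_side <- L %/% m
  block <- (seq_len(L) - 1L) %/% m       # 0-based block index per row/col
  site_of_cell <- outer(block, block, function(i, j) j * n_side + i + 1L)
  habitat_cells <- as.integer(rowsum(as.numeric(land$mask),
                                     as.vector(site_of_cell))[, 1L])
  ctr <- block * m + m / 2
  centers <- cbind(rep(unique(ctr), times = n_side),
                   rep(unique(ctr), each = n_side))
  structure(list(m = m, n_side = n_side, n_sites = n_side^2,
                 centers = centers, habitat_cells = habitat_cells,
                 site_of_cell = site_of_cell),
            class = "site_grid")
}

#' Local occupancy per sampling site
#'
#' Fraction of a site's habitat cells that hold at least one individual.
#' Sites without habitat are `NA` (excluded from synchrony measures).
#'
#' @param pop a [population()].
#' @param sites a [build_site_grid()] result.
#' @param land the [landscape()] the sites were built on.
#' @return numeric vector of length `n_sites` in `[0, 1]`, `NA` for
#'   habitat-free sites.
#' @export
local_occupancy <- function(pop, sites, land) {
  stopifnot(inherits(pop, "population"), pop$L == land$L)
  occ_cell <- matrix(FALSE, land$L, land$L)
  if (nrow(pop$xy)) occ_cell[unique(cell_linear(pop$xy, land$L))] <- TRUE
  occ <- as.integer(rowsum(as.numeric(occ_cell & land$mask),
                           as.vector(sites$site_of_cell))[, 1L])
  out <- occ / sites$habitat_cells
  out[sites$habitat_cells == 0L] <- NA_real_
  out
}

#' Local abundance per sampling site
#'
#' Number of individuals in the site divided by the site's habitat cell
#' count; `NA` for habitat-free sites.  Summing `value * habitat_cells`
#' over sites recovers the global population size.
#'
#' @inheritParams local_occupancy
#' @return numeric vector of length `n_sites`, `NA` for habitat-free sites.
#' @export
local_abundance <- function(pop, sites, land) {
  stopifnot(inherits(pop, "population"), pop$L == land$L)
  counts <- integer(sites$n_sites)
  if (nrow(pop$xy)) {
    s <- sites$site_of_cell[cell_linear(pop$xy, land$L)]
    tab <- tabulate(s, nbins = sites$n_sites)
    counts <- tab
  }
  out <- counts / sites$habitat_cells
  out[sites$habitat_cells == 0L] <- NA_real_
  out
}

# Pairwise across-replicate Pearson correlations of per-site values, grouped
# into distance bins [l - 0.5, l + 0.5] around each requested intersite
# distance l.  `occ`/`abn` are n_sites x n_replicates matrices (NA rows =
# habitat-free sites, excluded); constant sites yield NA correlations,
# excluded from bin means.  Self-pairs are excluded; cor(i,j) = cor(j,i) so
# only the upper triangle is reported.
correlogram_pairs <- function(occ, abn, sites, L, distance_bins) {
  idx <- which(sites$habitat_cells > 0L)
  ctr <- sites$centers[idx, , drop = FALSE]
  dx <- abs(outer(ctr[, 1L], ctr[, 1L], "-")); dx <- pmin(dx, L - dx)
  dy <- abs(outer(ctr[, 2L], ctr[, 2L], "-")); dy <- pmin(dy, L - dy)
  dmat <- sqrt(dx^2 + dy^2)

  suppressWarnings({
    c_occ <- stats::cor(t(occ[idx, , drop = FALSE]))
    c_abn <- stats::cor(t(abn[idx, , drop = FALSE]))
  })

  up <- which(upper.tri(dmat), arr.ind = TRUE)
  d <- dmat[up]
  bin <- rep(NA_real_, length(d))
  for (l in distance_bins) bin[d >= l - 0.5 & d <= l + 0.5] <- l
  sel <- !is.na(bin)
  pairs <- data.frame(site_i = idx[up[sel, 1L]], site_j = idx[up[sel, 2L]],
                      distance = d[sel], bin = bin[sel],
                      cor_occupancy = c_occ[up][sel],
                      cor_abundance = c_abn[up][sel])
  agg <- do.call(rbind, lapply(split(pairs, pairs$bin), function(p) {
    data.frame(bin = p$bin[1L], n_pairs = nrow(p),
               mean_cor_occupancy = mean(p$cor_occupancy, na.rm = TRUE),
               mean_cor_abundance = mean(p$cor_abundance, na.rm = TRUE))
  }))
  rownames(agg) <- NULL
  list(pairs = pairs, summary = agg)
}

#' Distance-binned spatial synchrony correlogram
#'
#' Runs `reps` replicates for `generations` generations; at the final
#' generation computes per-site local occupancy and abundance, then, for
#' every pair of habitat-bearing sites, the Pearson correlation of each
#' measure across replicates (the synchrony of the two local populations).
#' Replicates extinct at the final generation are dropped (synchrony is
#' conditional on persistence).  Pairs are grouped into distance bins
#' `[l - 0.5, l + 0.5]` around each requested intersite distance `l`
#' (torus distance between site centres).
#'
#' @inheritParams run_persistence
#' @param generations generations to track before measuring (default 50).
#' @param m sampling-site side length (default 2).
#' @param distance_bins intersite distances of interest (default `c(2, 20)`).
#' @param init_density initial density (default `5000 / land$L^2`).
#' @return object of class `"synchrony_result"`: list with `pairs`
#'   (data.frame: site_i, site_j, distance, bin, cor_occupancy,
#'   cor_abundance), `summary` (per-bin mean correlations and pair counts),
#'   `n_replicates_used`, and config.
#' @export
synchrony_correlogram <- function(land, species, env, reps, generations = 50,
                                  m = 2, distance_bins = c(2, 20),
                                  init_density = NULL, seed = 1L) {
  stopifnot(reps >= 2)
  if (is.null(init_density)) init_density <- 5000 / land$L^2
  sites <- build_site_grid(land, m)
  plan <- make_sim_plan(land, species, env)
  occ <- matrix(NA_real_, sites$n_sites, reps)
  abn <- matrix(NA_real_, sites$n_sites, reps)
  alive <- logical(reps)
  for (k in seq_len(reps)) {
    set.seed(child_seed(seed, k))
    r <- run_one_replicate(land, species, env, plan, init_density,
                           generations)
    if (nrow(r$pop$xy) > 0L) {
      alive[k] <- TRUE
      occ[, k] <- local_occupancy(r$pop, sites, land)
      abn[, k] <- local_abundance(r$pop, sites, land)
    }
  }
  if (sum(alive) < 2L)
    stop("fewer than 2 replicates persisted to the final generation")
  occ <- occ[, alive, drop = FALSE]
  abn <- abn[, alive, drop = FALSE]

  cg <- correlogram_pairs(occ, abn, sites, land$L, distance_bins)
  structure(list(pairs = cg$pairs, summary = cg$summary,
                 n_replicates_used = sum(alive),
                 config = list(reps = reps, generations = generations, m = m,
                               distance_bins = distance_bins,
                               init_density = init_density, seed = seed,
                               species = unclass(species),
                               env = unclass(env),
                               landscape = land$provenance)),
            class = "synchrony_result")
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf("<synchrony_result> %d surviving replicates\n",
              x$n_replicates_used))
  print(x$summary)
  invisible(x)
}

#' @export
plot.synchrony_result <- function(x, measure = c("occupancy", "abundance"),
                                  ...) {
  measure <- match.arg(measure)
  col <- paste0("cor_", measure)
  graphics::plot(x$pairs$distance, x$pairs[[col]], pch = 16,
                 col = "#00000030", xlab = "intersite distance",
                 ylab = sprintf("correlation of local %s", measure), ...)
  graphics::abline(h = 0, lty = 2)
  graphics::points(x$summary$bin,
                   x$summary[[paste0("mean_cor_", measure)]],
                   col = "red", pch = 17, cex = 1.4)
  invisible(x)
}
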