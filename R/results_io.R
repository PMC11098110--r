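# Tabular result files: CSV with '#'-prefixed metadata header lines.

#' Write a result table with provenance metadata
#'
#' Writes `#`-prefixed header lines (`# key: value`) followed by a plain
#' CSV body.  Standard metadata are the config hash, the top-level seed and
#' the package version; arbitrary extra keys may be supplied.
#'
#' @param x a data.frame.
#' @param path output path.
#' @param meta named list of metadata values (scalars).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, meta = list()) {
  stopifnot(is.data.frame(x))
  meta <- c(list(package_version = as.character(utils::packageVersion("fragmeta"))),
            meta)
  hdr <- sprintf("# %s: %s", names(meta),
                 vapply(meta, function(v) paste(format(v), collapse = ","),
                        character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path file path.
#' @return data.frame with attribute `meta` (named character vector of the
#'   header metadata).  A missing metadata header produces a warning but
#'   the table still parses.
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  meta <- character(0)
  for (h in lines[is_hdr]) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) meta[trimws(m[2L])] <- m[3L]
  }
  if (!any(is_hdr))
    warning("no '#' metadata header found in ", path)
  body <- lines[!is_hdr]
  x <- utils::read.csv(text = paste(body, collapse = "\n"),
                       stringsAsFactors = FALSE)
  attr(x, "meta") <- meta
  x
}

#' Generate the deterministic test fixtures
#'
#' Writes three tiny named landscape masks (a 4 x 4 checkerboard, a 6 x 6
#' two-patch layout, an 8 x 8 single 3 x 3 square) plus a JSON manifest of
#' derived quantities (habitat covers, habitat-cell counts, and m = 2 site
#' habitat counts) that tests recompute from the masks and compare.
#'
#' @param out_dir output directory (created if missing).
#' @return character vector of the files written, invisibly.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  checker <- landscape(outer(1:4, 1:4, function(i, j) (i + j) %% 2 == 0),
                       list(type = "fixture_checkerboard_4x4"))
  two <- matrix(FALSE, 6, 6)
  two[1:2, 1:2] <- TRUE; two[4:5, 4:6] <- TRUE
  two_patch <- landscape(two, list(type = "fixture_two_patch_6x6"))
  sq <- matrix(FALSE, 8, 8)
  sq[3:5, 3:5] <- TRUE
  square <- landscape(sq, list(type = "fixture_single_square_8x8"))
  fixtures <- list(checkerboard_4x4 = checker, two_patch_6x6 = two_patch,
                   single_square_8x8 = square)
  files <- character(0)
  manifest <- list()
  for (nm in names(fixtures)) {
    f <- file.path(out_dir, paste0(nm, ".txt"))
    write_landscape(fixtures[[nm]], f)
    files <- c(files, f)
    land <- fixtures[[nm]]
    sites <- build_site_grid(land, 2)
    manifest[[nm]] <- list(L = land$L,
                           habitat_cells = sum(land$mask),
                           cover = habitat_cover(land),
                           site_habitat_cells_m2 = sites$habitat_cells)
  }
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf))
}
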