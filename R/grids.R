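#' Construct a trapping grid
#'
#' A trapping grid is a rectangular lattice of live-trap stations at fixed
#' spacing (30 m in the standard design). Coordinates are grid-local metres
#' with the origin at the south-west station; column/row indices are 1-based.
#'
#' @param grid_id Character identifier, e.g. `"wet"`.
#' @param habitat One of `"wet"`, `"mesic1"`, `"mesic2"`.
#' @param n_cols,n_rows Lattice dimensions (12 x 12 or 8 x 12 in the
#'   standard design).
#' @param spacing_m Station spacing in metres.
#' @param exclosure_years Integer vector of years in which the grid was
#'   fenced against predators. Only meaningful for the `mesic2` grid; in
#'   those years the grid contributes the fourth level (`"exclosure"`) of
#'   the trapping-grid covariate.
#'
#' @return An object of class `trap_grid`: a list with the arguments above
#'   plus `stations`, a data frame with columns `col`, `row`, `x`, `y`.
#' @export
make_grid <- function(grid_id, habitat = c("wet", "mesic1", "mesic2"),
                      n_cols = 12L, n_rows = 12L, spacing_m = 30,
                      exclosure_years = integer()) {
  habitat <- match.arg(habitat)
  stopifnot(n_cols >= 1L, n_rows >= 1L, spacing_m > 0)
  if (length(exclosure_years) > 0L && habitat != "mesic2")
    stop("exclosure_years can only be set on the mesic2 (fenced) grid")
  st <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows),
                    KEEP.OUT.ATTRS = FALSE)
  st$x <- (st$col - 1L) * spacing_m
  st$y <- (st$row - 1L) * spacing_m
  structure(
    list(grid_id = as.character(grid_id), habitat = habitat,
         n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
         spacing_m = spacing_m,
         exclosure_years = as.integer(exclosure_years),
         stations = st),
    class = "trap_grid")
}

#' @export
print.trap_grid <- function(x, ...) {
  cat(sprintf("trap_grid '%s' (%s): %d x %d stations @ %g m\n",
              x$grid_id, x$habitat, x$n_cols, x$n_rows, x$spacing_m))
  if (length(x$exclosure_years))
    cat("  exclosure years:", paste(range(x$exclosure_years), collapse = "-"), "\n")
  invisible(x)
}

#' Trapping-grid covariate level for a given year
#'
#' The fenced grid counts as its own level (`"exclosure"`) in years when the
#' predator exclosure was in place, otherwise each grid contributes its
#' habitat label.
#'
#' @param grid A `trap_grid`.
#' @param year Integer year (vectorised).
#' @return Character vector of covariate levels.
#' @export
grid_level <- function(grid, year) {
  stopifnot(inherits(grid, "trap_grid"))
  ifelse(year %in% grid$exclosure_years, "exclosure", grid$habitat)
}

#' Station coordinates as a matrix
#' @param grid A `trap_grid`.
#' @return Numeric matrix with columns `x`, `y`, one row per station.
#' @export
station_xy <- function(grid) {
  as.matrix(grid$stations[, c("x", "y")])
}

#' Read grid-geometry definitions from YAML or JSON
#'
#' The file holds a list of grid descriptions, each with fields `id`,
#' `habitat`, `n_cols`, `n_rows`, `spacing_m` and optional `exclosure_years`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of `trap_grid` objects.
#' @export
read_grids <- function(path) {
  defs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  grids <- lapply(defs, function(d) {
    make_grid(grid_id = d$id, habitat = d$habitat,
              n_cols = d$n_cols, n_rows = d$n_rows,
              spacing_m = if (is.null(d$spacing_m)) 30 else d$spacing_m,
              exclosure_years = as.integer(unlist(d$exclosure_years)))
  })
  names(grids) <- vapply(grids, `[[`, "", "grid_id")
  grids
}

#' Write grid-geometry definitions to YAML
#' @param grids Named list of `trap_grid` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grids <- function(grids, path) {
  defs <- lapply(grids, function(g) {
    list(id = g$grid_id, habitat = g$habitat, n_cols = g$n_cols,
         n_rows = g$n_rows, spacing_m = g$spacing_m,
         exclosure_years = as.list(g$exclosure_years))
  })
  yaml::write_yaml(unname(defs), path)
  invisible(path)
}

#' Default study grids
#'
#' The standard design: a 12 x 12 wet-tundra grid and a 12 x 12 mesic grid
#' trapped throughout, plus an 8 x 12 second mesic grid added later and
#' fenced against predators in its final years.
#'
#' @param years Study years (used to place the exclosure period).
#' @return Named list of `trap_grid` objects.
#' @export
default_grids <- function(years = 2004:2019) {
  excl <- years[years >= 2013]
  list(
    wet    = make_grid("wet", "wet", 12, 12),
    mesic1 = make_grid("mesic1", "mesic1", 12, 12),
    mesic2 = make_grid("mesic2", "mesic2", 8, 12, exclosure_years = excl)
  )
}
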