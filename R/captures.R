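#' @title Capture records
#' @description
#' Capture data are held in a plain data frame, one row per capture event,
#' with columns:
#' \describe{
#'   \item{individual_id}{character tag identifier}
#'   \item{year}{integer}
#'   \item{primary}{primary trapping period within the summer, 1..4
#'     (four periods in 2004-2007, three afterwards)}
#'   \item{occasion}{secondary occasion within the primary period, 1..10}
#'   \item{grid_id}{character, matching a `trap_grid`}
#'   \item{col, row}{1-based station indices on the grid lattice}
#'   \item{sex}{"M" or "F"}
#'   \item{mass_g}{body mass in grams, possibly `NA`}
#'   \item{repro}{"reproductive", "nonreproductive" or NA (females only;
#'     recorded from 2009 onward)}
#'   \item{pregnant}{logical}
#' }
#' @name captures
NULL

capture_cols <- c("individual_id", "year", "primary", "occasion", "grid_id",
                  "col", "row", "sex", "mass_g", "repro", "pregnant")

#' Number of primary periods and inter-period interval for a year
#'
#' The first four study years (2004-2007) had four primary periods separated
#' by 20 days; later years had three periods separated by 30 days.
#'
#' @param year Integer year (vectorised).
#' @return Integer vector.
#' @export
n_primaries <- function(year) ifelse(year <= 2007, 4L, 3L)

#' @rdname n_primaries
#' @export
interval_days <- function(year) ifelse(year <= 2007, 20L, 30L)

#' Validate a capture table against grid geometry
#'
#' Checks column presence, station indices against the lattice, factor
#' levels, the primary/occasion schedule, and that no individual appears on
#' more than one grid (inter-grid movement is never observed in this system
#' and is treated as a data error).
#'
#' @param captures Capture data frame (see [captures]).
#' @param grids Named list of `trap_grid` objects.
#' @return The validated data frame, invisibly, with `line` attribute
#'   stripped. Throws an error listing offending row numbers otherwise.
#' @export
validate_captures <- function(captures, grids) {
  missing_cols <- setdiff(capture_cols, names(captures))
  if (length(missing_cols))
    stop("capture table lacks columns: ", paste(missing_cols, collapse = ", "))
  probs <- character()
  bad_grid <- !(captures$grid_id %in% names(grids))
  if (any(bad_grid))
    probs <- c(probs, paste0("unknown grid_id at rows ",
                             paste(which(bad_grid), collapse = ",")))
  for (gid in intersect(unique(captures$grid_id), names(grids))) {
    g <- grids[[gid]]
    i <- which(captures$grid_id == gid)
    off <- captures$col[i] < 1L | captures$col[i] > g$n_cols |
           captures$row[i] < 1L | captures$row[i] > g$n_rows
    if (any(off))
      probs <- c(probs, paste0("station outside ", g$n_cols, "x", g$n_rows,
                               " lattice of grid '", gid, "' at rows ",
                               paste(i[off], collapse = ",")))
  }
  bad_sex <- !(captures$sex %in% c("M", "F"))
  if (any(bad_sex))
    probs <- c(probs, paste0("invalid sex at rows ",
                             paste(which(bad_sex), collapse = ",")))
  bad_p <- captures$primary < 1L | captures$primary > n_primaries(captures$year)
  if (any(bad_p))
    probs <- c(probs, paste0("primary period outside the year's schedule at rows ",
                             paste(which(bad_p), collapse = ",")))
  bad_o <- captures$occasion < 1L | captures$occasion > 10L
  if (any(bad_o))
    probs <- c(probs, paste0("occasion outside 1..10 at rows ",
                             paste(which(bad_o), collapse = ",")))
  ngrids <- tapply(captures$grid_id, captures$individual_id,
                   function(g) length(unique(g)))
  if (any(ngrids > 1L))
    probs <- c(probs, paste0("individuals on more than one grid: ",
                             paste(names(ngrids)[ngrids > 1L], collapse = ",")))
  if (length(probs)) stop(paste(probs, collapse = "\n"))
  invisible(captures)
}

#' Read a capture CSV
#'
#' Reads the documented capture-file dialect and validates every row against
#' the grid geometry. Missing values are empty fields; `mass_g` may be
#' missing (the event is kept), an unknown grid or off-lattice station is a
#' hard error.
#'
#' @param path CSV path.
#' @param grids Named list of `trap_grid` objects used for validation.
#' @return Capture data frame (see [captures]).
#' @export
read_captures <- function(path, grids) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(individual_id = "character",
                                      grid_id = "character",
                                      sex = "character", repro = "character"))
  x$year <- as.integer(x$year); x$primary <- as.integer(x$primary)
  x$occasion <- as.integer(x$occasion)
  x$col <- as.integer(x$col); x$row <- as.integer(x$row)
  x$mass_g <- as.numeric(x$mass_g)
  x$repro[!is.na(x$repro) & x$repro == ""] <- NA_character_
  x$pregnant <- as.logical(x$pregnant)
  validate_captures(x, grids)
  x
}

#' Write a capture CSV
#' @param captures Capture data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_captures <- function(captures, path) {
  utils::write.csv(captures[, capture_cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Classify age from body mass at first capture
#'
#' Adults are defined by mass thresholds: females >= 28 g, males >= 30 g
#' (boundary inclusive). Missing mass gives `"unknown"` and the individual
#' is excluded from class-specific analyses.
#'
#' @param sex "M" or "F" (vectorised).
#' @param mass_g Mass in grams.
#' @return Character vector: "adult", "juvenile" or "unknown".
#' @export
classify_age <- function(sex, mass_g) {
  thr <- ifelse(sex == "F", 28, 30)
  out <- ifelse(mass_g >= thr, "adult", "juvenile")
  out[is.na(mass_g)] <- "unknown"
  out
}

#' Sex-age class of each individual per year
#'
#' Class is assigned from mass at first capture within the year; an
#' individual crossing the mass threshold later in the same summer keeps its
#' first-capture class (transitions are allowed across years).
#'
#' @param captures Capture data frame.
#' @return Data frame with one row per individual x year: `individual_id`,
#'   `year`, `grid_id`, `sex`, `age`, `class` (e.g. "F.adult"), and
#'   `first_mass_g`.
#' @export
individual_classes <- function(captures) {
  ord <- order(captures$year, captures$primary, captures$occasion)
  x <- captures[ord, ]
  key <- paste(x$individual_id, x$year, sep = "\r")
  first <- x[!duplicated(key), ]
  age <- classify_age(first$sex, first$mass_g)
  data.frame(individual_id = first$individual_id, year = first$year,
             grid_id = first$grid_id, sex = first$sex, age = age,
             class = ifelse(age == "unknown", NA_character_,
                            paste(first$sex, age, sep = ".")),
             first_mass_g = first$mass_g,
             stringsAsFactors = FALSE)
}

#' Build within-session capture histories for SECR
#'
#' For one session (a single grid, year and primary period) this returns the
#' detection structure the spatial capture-recapture likelihood needs: for
#' each individual, the trap it was caught in (if any) on each occasion.
#' Single-capture live traps imply at most one detection per individual per
#' occasion; two detections of one animal in one occasion is an error.
#'
#' @param captures Capture rows from a single grid/year/primary.
#' @param grid The `trap_grid` trapped.
#' @param n_occasions Number of secondary occasions run in the session;
#'   defaults to the largest occasion index observed.
#' @return Object of class `session_history`: list with `ids`, `trap`
#'   (n_individuals x n_occasions matrix of station indices, 0 = not
#'   caught), `grid_id`, `year`, `primary`, `n_occasions`.
#' @export
build_session_histories <- function(captures, grid,
                                    n_occasions = max(captures$occasion, 1L)) {
  stopifnot(inherits(grid, "trap_grid"))
  if (nrow(captures) == 0L) {
    return(structure(list(ids = character(), trap = matrix(0L, 0L, n_occasions),
                          grid_id = grid$grid_id, year = NA_integer_,
                          primary = NA_integer_, n_occasions = n_occasions),
                     class = "session_history"))
  }
  stopifnot(length(unique(captures$grid_id)) == 1L,
            length(unique(captures$year)) == 1L,
            length(unique(captures$primary)) == 1L)
  dup <- duplicated(captures[, c("individual_id", "occasion")])
  if (any(dup))
    stop("individual detected twice in one occasion (violates single-capture ",
         "trap semantics): ",
         paste(unique(captures$individual_id[dup]), collapse = ","))
  ids <- sort(unique(captures$individual_id))
  trap <- matrix(0L, length(ids), n_occasions,
                 dimnames = list(ids, NULL))
  station <- match(paste(captures$col, captures$row),
                   paste(grid$stations$col, grid$stations$row))
  trap[cbind(match(captures$individual_id, ids), captures$occasion)] <- station
  structure(list(ids = ids, trap = trap, grid_id = grid$grid_id,
                 year = captures$year[1L], primary = captures$primary[1L],
                 n_occasions = n_occasions),
            class = "session_history")
}

#' Annual presence histories for survival analysis
#'
#' Collapses captures to one row per individual per year with a 0/1
#' detection vector over that year's primary periods — the open-population
#' (Cormack-Jolly-Seber) input. Summers are treated independently because
#' between-summer recaptures are negligible in this system.
#'
#' @param captures Capture data frame.
#' @return Data frame with columns `individual_id`, `year`, `grid_id`,
#'   `sex`, `age`, `class` and `h1`..`h4` (NA beyond the year's schedule).
#' @export
build_annual_histories <- function(captures) {
  cls <- individual_classes(captures)
  key <- paste(captures$individual_id, captures$year, sep = "\r")
  ukey <- paste(cls$individual_id, cls$year, sep = "\r")
  pres <- matrix(0L, nrow(cls), 4L,
                 dimnames = list(NULL, paste0("h", 1:4)))
  idx <- cbind(match(key, ukey), captures$primary)
  pres[idx] <- 1L
  out <- cbind(cls[, c("individual_id", "year", "grid_id", "sex", "age", "class")],
               as.data.frame(pres))
  out$h4[n_primaries(out$year) < 4L] <- NA_integer_
  out
}
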