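# Shared fixtures, all generated in code.

# A small capture table on a 12x12 grid: 3 individuals, 2 primaries.
tiny_captures <- function() {
  data.frame(
    individual_id = c("a", "a", "b", "b", "c", "a"),
    year = 2010L,
    primary = c(1L, 1L, 1L, 2L, 2L, 2L),
    occasion = c(1L, 4L, 2L, 1L, 3L, 2L),
    grid_id = "wet",
    col = c(1L, 2L, 5L, 5L, 8L, 1L),
    row = c(1L, 1L, 5L, 6L, 8L, 2L),
    sex = c("F", "F", "M", "M", "F", "F"),
    mass_g = c(35, 36, 29.9, 31, 20, 37),
    repro = c("reproductive", "reproductive", NA, NA, NA, "reproductive"),
    pregnant = FALSE,
    stringsAsFactors = FALSE)
}

tiny_grids <- function() list(wet = make_grid("wet", "wet", 12, 12))

# One simulated SECR session with known truth; returns history + grid + mask.
sim_session <- function(D = 5, g0 = 0.3, sigma = 15, n_occ = 6L,
                        seed = 1L, grid = make_grid("wet", "wet", 12, 12),
                        mask = build_mask(grid)) {
  set.seed(seed)
  xy <- station_xy(grid)
  xr <- range(xy[, 1]) + c(-100, 100)
  yr <- range(xy[, 2]) + c(-100, 100)
  N <- rpois(1, D * diff(xr) * diff(yr) / 1e4)
  pop <- data.frame(id = sprintf("i%04d", seq_len(N)),
                    x = runif(N, xr[1], xr[2]), y = runif(N, yr[1], yr[2]),
                    stringsAsFactors = FALSE)
  det <- simulate_detections(pop, grid, n_occ, g0, sigma)
  if (nrow(det) == 0L) return(NULL)
  ev <- data.frame(individual_id = det$id, year = 2010L, primary = 1L,
                   occasion = det$occasion, grid_id = grid$grid_id,
                   col = grid$stations$col[det$station],
                   row = grid$stations$row[det$station],
                   sex = "F", mass_g = 35, repro = NA_character_,
                   pregnant = FALSE, stringsAsFactors = FALSE)
  list(history = build_session_histories(ev, grid, n_occasions = n_occ),
       events = ev, grid = grid, mask = mask, N = N)
}

# Small-but-complete synthetic study used by several integration tests:
# 2 grids, 8 years, one full cycle amplitude, modest effort.
small_truth <- function(...) {
  yrs <- 2008:2015
  sim_truth(years = yrs,
            grids = list(wet = make_grid("wet", "wet", 12, 12),
                         mesic1 = make_grid("mesic1", "mesic1", 8, 12)),
            n_occasions = 5L, ...)
}
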