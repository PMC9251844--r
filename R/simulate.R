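#' Configuration of a synthetic cyclic-population study
#'
#' Bundles every generative parameter of the simulator: the density cycle,
#' population composition, detection, survival, movement, reproduction and
#' body-mass processes. Defaults emulate the standard study system: 3 grids
#' trapped over 16 summers, densities cycling ~100-fold with a 3-4 year
#' period between 0.05 and 9 animals/ha, half-normal detection, and sex-
#' and density-dependent survival and movement.
#'
#' @param years Integer vector of study years.
#' @param grids Named list of `trap_grid` objects.
#' @param cycle_period Cycle length in years (3 or 4).
#' @param density_peak,density_trough Cycle extremes, animals/ha.
#' @param year_noise_sd Lognormal sd of year-to-year deviations from the
#'   cyclic template (log scale).
#' @param female_prop_intercept,female_prop_slope Logit-scale intercept and
#'   per-unit-density slope of the adult-female share of total density. The
#'   default slope (0.05) makes the sex ratio male-biased at the trough and
#'   near 1:1 at the peak.
#' @param class_split_rest How the non-adult-female share is divided among
#'   `M.adult`, `F.juvenile`, `M.juvenile`.
#' @param g0 Per-occasion capture probability at distance zero.
#' @param sigma_m Half-normal detection scale at zero density, metres.
#' @param movement_density_slope Log-scale change of sigma per unit density
#'   (negative: animals range less widely at high density).
#' @param phi_monthly Named vector of monthly apparent survival per sex-age
#'   class at zero density.
#' @param phi_density_slope Named vector (adult, juvenile): logit-scale
#'   change of monthly survival per unit density.
#' @param recruit_frac Fraction of the initial session population entering
#'   as new (mostly juvenile) animals at each later primary period.
#' @param n_occasions Secondary occasions per primary period (up to 10).
#' @param repro_p0,repro_density_slope,repro_indiv_sd Reproduction model for
#'   adult females (recorded from `repro_start_year` onward): baseline
#'   probability, logit-scale density slope, and sd of the per-individual
#'   random intercept.
#' @param repro_start_year First year reproductive condition is recorded.
#' @param mass_coef Daily body-mass-change model (g/day):
#'   `m0 + m_mass * mass + (m_late + m_mass_late * mass) * late +
#'   m_density * D` plus Gaussian noise `mass_noise_sd`.
#' @return Object of class `sim_truth` (a list of the above).
#' @export
sim_truth <- function(years = 2004:2019,
                      grids = default_grids(years),
                      cycle_period = 4,
                      density_peak = 9, density_trough = 0.05,
                      year_noise_sd = 0.2,
                      female_prop_intercept = stats::qlogis(0.2),
                      female_prop_slope = 0.05,
                      class_split_rest = c(M.adult = 0.5, F.juvenile = 0.25,
                                           M.juvenile = 0.25),
                      g0 = 0.3, sigma_m = 15,
                      movement_density_slope = -0.08,
                      phi_monthly = c(F.adult = 0.46, M.adult = 0.29,
                                      F.juvenile = 0.50, M.juvenile = 0.22),
                      phi_density_slope = c(adult = 0.05, juvenile = 0),
                      recruit_frac = 0.2,
                      n_occasions = 6L,
                      repro_p0 = 0.8, repro_density_slope = -0.09,
                      repro_indiv_sd = 0.5,
                      repro_start_year = 2009L,
                      mass_coef = c(m0 = 0.3, m_mass = -0.008,
                                    m_late = -0.35, m_mass_late = 0.006,
                                    m_density = 0),
                      mass_noise_sd = 0.06) {
  stopifnot(density_peak > 0, density_trough > 0,
            density_peak >= density_trough,
            all(phi_monthly >= 0 & phi_monthly <= 1),
            g0 >= 0, g0 <= 1, sigma_m > 0, cycle_period >= 2)
  structure(as.list(environment()), class = "sim_truth")
}

#' Cyclic density trajectory with class composition
#'
#' Total density follows a deterministic log-scale cyclic template (trough,
#' increase, peak, decline) scaled between `density_trough` and
#' `density_peak`, with lognormal year noise shared across grids plus a
#' smaller independent per-grid deviation. The adult-female share of total
#' density is logit-linear in total density; the remainder is split among
#' the other classes in fixed ratios.
#'
#' @param truth A `sim_truth`.
#' @param seed Integer seed for the year/grid noise.
#' @return Data frame, one row per year x grid: `year`, `grid_id`,
#'   `density_total` and one density column per class.
#' @export
simulate_trajectory <- function(truth, seed = 1L) {
  set.seed(seed)
  P <- truth$cycle_period
  template <- if (P >= 4) c(0, 0.55, 1, 0.45, rep(0.15, P - 4)) else c(0, 1, 0.45)
  lt <- log(truth$density_trough); lp <- log(truth$density_peak)
  phase <- (truth$years - truth$years[1]) %% P
  ld_year <- lt + template[phase + 1] * (lp - lt) +
    stats::rnorm(length(truth$years), 0, truth$year_noise_sd)
  out <- expand.grid(year = truth$years, grid_id = names(truth$grids),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ld <- ld_year[match(out$year, truth$years)] +
    stats::rnorm(nrow(out), 0, truth$year_noise_sd / 2)
  D <- pmin(pmax(exp(ld), truth$density_trough), truth$density_peak)
  p_fad <- stats::plogis(truth$female_prop_intercept +
                           truth$female_prop_slope * D)
  rest <- truth$class_split_rest / sum(truth$class_split_rest)
  out$density_total <- D
  out$F.adult <- p_fad * D
  out$M.adult <- (1 - p_fad) * rest[["M.adult"]] * D
  out$F.juvenile <- (1 - p_fad) * rest[["F.juvenile"]] * D
  out$M.juvenile <- (1 - p_fad) * rest[["M.juvenile"]] * D
  out
}

# Draw initial body masses consistent with the class's age threshold.
draw_mass <- function(sex, age, n) {
  thr <- ifelse(sex == "F", 28, 30)
  if (age == "adult") pmax(thr, stats::rnorm(n, thr + 12, 6))
  else pmin(thr - 0.5, pmax(12, stats::rnorm(n, 21, 4)))
}

# Population of true individuals for one grid-year: activity centres
# uniform on the grid + buffer, class structure from the trajectory row.
make_population <- function(traj_row, grid, truth, buffer_m = 100,
                            id_prefix = "ind") {
  xy <- station_xy(grid)
  xr <- range(xy[, 1]) + c(-buffer_m, buffer_m)
  yr <- range(xy[, 2]) + c(-buffer_m, buffer_m)
  area_ha <- diff(xr) * diff(yr) / 1e4
  classes <- c("F.adult", "M.adult", "F.juvenile", "M.juvenile")
  n_cl <- sapply(classes, function(cl) {
    stats::rpois(1, as.numeric(traj_row[[cl]]) * area_ha)
  })
  n <- sum(n_cl)
  if (n == 0L) return(NULL)
  cl <- rep(classes, n_cl)
  sex <- sub("\\..*", "", cl); age <- sub(".*\\.", "", cl)
  mass <- numeric(n)
  for (a in c("adult", "juvenile")) for (s in c("F", "M")) {
    i <- sex == s & age == a
    if (any(i)) mass[i] <- draw_mass(s, a, sum(i))
  }
  data.frame(
    id = sprintf("%s_%03d", id_prefix, seq_len(n)),
    sex = sex, age = age, class = cl,
    x = stats::runif(n, xr[1], xr[2]), y = stats::runif(n, yr[1], yr[2]),
    mass = mass,
    repro_re = stats::rnorm(n, 0, truth$repro_indiv_sd),
    stringsAsFactors = FALSE)
}

#' Simulate multi-catch detections of a set of animals in one session
#'
#' Competing-hazard (multi-catch) trap semantics: on each occasion an
#' animal's per-trap hazard is `-log(1 - g0 exp(-d^2/(2 sigma^2)))`; it is
#' caught with probability `1 - exp(-H)` where `H` sums the hazards, and
#' the trap is then drawn proportionally to the per-trap hazards, so each
#' animal is caught in at most one trap per occasion.
#'
#' @param pop Data frame of animals with columns `id`, `x`, `y` (plus any
#'   biology columns, carried through).
#' @param grid A `trap_grid`.
#' @param n_occasions Number of occasions.
#' @param g0,sigma_m Detection parameters for the session.
#' @return Data frame of detections: `id`, `occasion`, `station` (index into
#'   `grid$stations`), or zero rows if nothing is caught.
#' @export
simulate_detections <- function(pop, grid, n_occasions, g0, sigma_m) {
  if (is.null(pop) || nrow(pop) == 0L || g0 <= 0)
    return(data.frame(id = character(), occasion = integer(),
                      station = integer()))
  xy <- station_xy(grid)
  d2 <- outer(pop$x, xy[, 1], "-")^2 + outer(pop$y, xy[, 2], "-")^2
  g <- pmin(g0 * exp(-d2 / (2 * sigma_m^2)), 1 - 1e-12)
  h <- -log1p(-g)
  H <- rowSums(h)
  p_caught <- -expm1(-H)
  out <- vector("list", n_occasions)
  for (occ in seq_len(n_occasions)) {
    caught <- stats::runif(nrow(pop)) < p_caught
    if (!any(caught)) next
    idx <- which(caught)
    st <- vapply(idx, function(i) {
      sample.int(ncol(h), 1L, prob = h[i, ])
    }, 0L)
    out[[occ]] <- data.frame(id = pop$id[idx], occasion = occ, station = st,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(id = character(), occasion = integer(),
                               station = integer())
  else res
}

# Monthly survival of one animal class at a given density.
phi_at_density <- function(truth, class, density) {
  age <- sub(".*\\.", "", class)
  stats::plogis(stats::qlogis(truth$phi_monthly[[class]]) +
                  truth$phi_density_slope[[age]] * density)
}

#' Simulate a complete multi-year live-trapping study
#'
#' Runs the generative model end to end: cyclic densities per grid-year,
#' populations with uniform activity centres on grid + buffer, survival
#' between primary periods (interval survival is monthly survival to the
#' power interval/30), within-summer recruitment, density-dependent
#' movement (sigma), multi-catch detection, and per-capture body mass,
#' reproductive condition and pregnancy.
#'
#' @param truth A `sim_truth`.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return List with `captures` (data frame in the standard capture dialect,
#'   see [captures]), `trajectory` (the realised density table), and `truth`.
#' @export
simulate_study <- function(truth, seed = 1L) {
  traj <- simulate_trajectory(truth, seed = seed)
  set.seed(seed + 1L)
  all_events <- list()
  k <- 0L
  for (r in seq_len(nrow(traj))) {
    yr <- traj$year[r]; gid <- traj$grid_id[r]
    grid <- truth$grids[[gid]]
    D <- traj$density_total[r]
    np <- n_primaries(yr); dt <- interval_days(yr)
    pop <- make_population(traj[r, ], grid, truth,
                           id_prefix = paste(gid, yr, sep = "_"))
    if (is.null(pop)) next
    n0 <- nrow(pop)
    alive <- rep(TRUE, n0)
    sigma_ses <- truth$sigma_m * exp(truth$movement_density_slope * D)
    for (pr in seq_len(np)) {
      if (pr > 1L) {
        # survival over the interval, then recruitment of new animals
        phi_int <- vapply(pop$class, function(cl) {
          phi_at_density(truth, cl, D)^(dt / 30)
        }, 0)
        alive <- alive & (stats::runif(nrow(pop)) < phi_int)
        n_new <- stats::rpois(1, truth$recruit_frac * n0)
        if (n_new > 0L) {
          sx <- sample(c("F", "M"), n_new, replace = TRUE)
          ag <- sample(c("juvenile", "adult"), n_new, replace = TRUE,
                       prob = c(0.8, 0.2))
          xr <- range(station_xy(grid)[, 1]) + c(-100, 100)
          yr2 <- range(station_xy(grid)[, 2]) + c(-100, 100)
          ms <- numeric(n_new)
          for (a in c("adult", "juvenile")) for (s in c("F", "M")) {
            i <- sx == s & ag == a
            if (any(i)) ms[i] <- draw_mass(s, a, sum(i))
          }
          newpop <- data.frame(
            id = sprintf("%s_%d_r%d_%03d", gid, yr, pr, seq_len(n_new)),
            sex = sx, age = ag, class = paste(sx, ag, sep = "."),
            x = stats::runif(n_new, xr[1], xr[2]),
            y = stats::runif(n_new, yr2[1], yr2[2]),
            mass = ms,
            repro_re = stats::rnorm(n_new, 0, truth$repro_indiv_sd),
            stringsAsFactors = FALSE)
          pop <- rbind(pop, newpop)
          alive <- c(alive, rep(TRUE, n_new))
        }
        # body-mass change over the interval
        mc <- truth$mass_coef
        late <- as.numeric(pr >= np)  # last transition = late summer
        rate <- mc[["m0"]] + mc[["m_mass"]] * pop$mass +
          (mc[["m_late"]] + mc[["m_mass_late"]] * pop$mass) * late +
          mc[["m_density"]] * D +
          stats::rnorm(nrow(pop), 0, truth$mass_noise_sd)
        pop$mass <- pmax(10, pop$mass + rate * dt)
      }
      det <- simulate_detections(pop[alive, , drop = FALSE], grid,
                                 truth$n_occasions, truth$g0, sigma_ses)
      if (nrow(det) == 0L) next
      i <- match(det$id, pop$id)
      repro <- rep(NA_character_, nrow(det))
      pregnant <- rep(FALSE, nrow(det))
      fad <- pop$sex[i] == "F" & pop$age[i] == "adult" &
        yr >= truth$repro_start_year
      if (any(fad)) {
        p_rep <- stats::plogis(stats::qlogis(truth$repro_p0) +
                                 truth$repro_density_slope * D +
                                 pop$repro_re[i][fad])
        is_rep <- stats::runif(sum(fad)) < p_rep
        repro[fad] <- ifelse(is_rep, "reproductive", "nonreproductive")
        pregnant[fad][is_rep] <- stats::runif(sum(is_rep)) < 0.25
      }
      k <- k + 1L
      all_events[[k]] <- data.frame(
        individual_id = det$id, year = yr, primary = pr,
        occasion = det$occasion, grid_id = gid,
        col = grid$stations$col[det$station],
        row = grid$stations$row[det$station],
        sex = pop$sex[i],
        mass_g = round(pop$mass[i] + stats::rnorm(nrow(det), 0, 0.3), 1),
        repro = repro, pregnant = pregnant,
        stringsAsFactors = FALSE)
    }
  }
  captures <- if (k > 0L) do.call(rbind, all_events) else
    stats::setNames(data.frame(matrix(ncol = length(capture_cols), nrow = 0)),
                    capture_cols)
  captures <- captures[order(captures$year, captures$grid_id,
                             captures$primary, captures$occasion,
                             captures$individual_id), ]
  rownames(captures) <- NULL
  list(captures = captures, trajectory = traj, truth = truth)
}

#' Simulate plain open-population (CJS) histories
#'
#' A direct generator of annual presence histories for survival-model
#' validation: each individual enters at the first primary period, survives
#' each interval with probability `phi_monthly^(interval/30)` and, when
#' alive, is detected with probability `p`.
#'
#' @param n Number of individuals per class.
#' @param phi_monthly Named vector of monthly survival per class.
#' @param p Named vector (or scalar) detection probability per class.
#' @param n_primary Number of primary periods.
#' @param interval_days Days between consecutive primaries.
#' @param year Nominal year to stamp on the histories.
#' @return Data frame in the [build_annual_histories] layout.
#' @export
simulate_cjs <- function(n, phi_monthly, p, n_primary = 3L,
                         interval_days = 30, year = 2010L) {
  classes <- names(phi_monthly)
  if (length(p) == 1L) p <- stats::setNames(rep(p, length(classes)), classes)
  rows <- list()
  for (cl in classes) {
    phi_int <- phi_monthly[[cl]]^(interval_days / 30)
    h <- matrix(0L, n, n_primary)
    h[, 1] <- 1L
    alive <- rep(TRUE, n)
    for (t in 2:n_primary) {
      alive <- alive & (stats::runif(n) < phi_int)
      h[, t] <- as.integer(alive & (stats::runif(n) < p[[cl]]))
    }
    hm <- matrix(NA_integer_, n, 4L)
    hm[, seq_len(n_primary)] <- h
    colnames(hm) <- paste0("h", 1:4)
    rows[[cl]] <- cbind(
      data.frame(individual_id = paste0(cl, "_", seq_len(n)), year = year,
                 grid_id = "wet", sex = sub("\\..*", "", cl),
                 age = sub(".*\\.", "", cl), class = cl,
                 stringsAsFactors = FALSE),
      as.data.frame(hm))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
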