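make_events <- function(stations, spacing = 10, ids = "a", year = 2010L,
                        primary = 1L, sex = "M", mass = 35) {
  g <- make_grid("wet", "wet", 12, 12, spacing_m = spacing)
  ev <- data.frame(individual_id = ids, year = year, primary = primary,
                   occasion = seq_len(nrow(stations)), grid_id = "wet",
                   col = stations[, 1], row = stations[, 2], sex = sex,
                   mass_g = mass, repro = NA_character_, pregnant = FALSE,
                   stringsAsFactors = FALSE)
  list(events = ev, grids = list(wet = g))
}

test_that("distances are first-capture-to-recapture, pooled over the year", {
  # stations at (0,0), (30,0), (0,40) m: distances 30 and 40, mean 35
  f <- make_events(cbind(c(1, 4, 1), c(1, 1, 5)))
  d <- compute_distances(f$events, f$grids)
  expect_equal(d$max_dist_m, 40)
  expect_equal(d$mean_dist_m, 35)
  expect_equal(d$n_captures, 3)
  # single capture and same-trap captures both get the zero assignment
  f1 <- make_events(cbind(2, 2))
  expect_equal(compute_distances(f1$events, f1$grids)$max_dist_m, 0)
  f2 <- make_events(cbind(c(2, 2, 2), c(2, 2, 2)))
  d2 <- compute_distances(f2$events, f2$grids)
  expect_equal(d2$max_dist_m, 0)
  expect_equal(d2$mean_dist_m, 0)
})

test_that("mean distance never exceeds max distance on simulated studies", {
  truth <- small_truth()
  sim <- simulate_study(truth, seed = 31)
  d <- compute_distances(sim$captures, truth$grids)
  expect_true(all(d$mean_dist_m <= d$max_dist_m + 1e-12))
  expect_true(all(d$max_dist_m[d$n_captures == 1] == 0))
})

test_that("negative-binomial fit honours the offset contract", {
  set.seed(32)
  n <- 300
  rec <- data.frame(
    density = runif(n, 0.1, 8), sex = sample(c("F", "M"), n, TRUE),
    age = sample(c("adult", "juvenile"), n, TRUE),
    n_captures = sample(2:6, n, TRUE))
  mu <- exp(2.5 - 0.08 * rec$density + 0.4 * (rec$sex == "M") +
              log(rec$n_captures))
  rec$max_dist_m <- rnbinom(n, size = 1.2, mu = mu)
  f1 <- negbin_fit(rec, max_dist_m ~ density + sex)
  rec2 <- rec
  rec2$n_captures <- rec2$n_captures * 2L
  f2 <- negbin_fit(rec2, max_dist_m ~ density + sex)
  # slopes untouched; the intercept absorbs exactly -log(2); with
  # coefficients held fixed a doubled offset doubles every fitted mean
  expect_equal(unname(f1$coef[-1]), unname(f2$coef[-1]), tolerance = 1e-6)
  expect_equal(f2$coef[["(Intercept)"]],
               f1$coef[["(Intercept)"]] - log(2), tolerance = 1e-6)
  expect_equal(unname(fitted(f2$fit)), unname(fitted(f1$fit)),
               tolerance = 1e-6)
  # density slope recovered within its interval
  expect_gt(-0.08, f1$ci95["density", 1])
  expect_lt(-0.08, f1$ci95["density", 2])
  expect_error(negbin_fit(transform(rec, max_dist_m = 0),
                          max_dist_m ~ density), "zero")
})

test_that("negative binomial approaches Poisson when dispersion vanishes", {
  set.seed(33)
  n <- 400
  rec <- data.frame(density = runif(n, 0.1, 8),
                    sex = "M", age = "adult", n_captures = 3L)
  mu <- exp(2 - 0.1 * rec$density + log(rec$n_captures))
  rec$max_dist_m <- rpois(n, mu)
  nb <- negbin_fit(rec, max_dist_m ~ density)
  po <- glm(max_dist_m ~ density + offset(log(n_captures)),
            data = rec, family = poisson())
  expect_equal(unname(nb$coef), unname(coef(po)), tolerance = 1e-3)
})

test_that("binomial GLMM reduces to plain GLM at zero grouping variance", {
  # find a dataset whose random-intercept variance lands on the boundary
  found <- FALSE
  for (s in 1:20) {
    set.seed(2000 + s)
    n <- 240
    obs <- data.frame(individual_id = rep(sprintf("f%03d", 1:(n / 2)), 2),
                      density = runif(n, 0.1, 8))
    obs$reproductive <- rbinom(n, 1, plogis(1.3 - 0.09 * obs$density))
    fit <- glmm_binomial_fit(obs, reproductive ~ density)
    if (fit$ranef_sd < 1e-8) {
      found <- TRUE
      ref <- glm(reproductive ~ density, data = obs, family = binomial())
      expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
      expect_false(fit$separation_flag)
      break
    }
  }
  expect_true(found)
})

test_that("binomial GLMM recovers a density effect on reproduction", {
  set.seed(34)
  n_id <- 300
  obs <- data.frame(individual_id = rep(sprintf("f%03d", 1:n_id), each = 2),
                    density = rep(runif(n_id, 0.1, 8), each = 2))
  re <- rep(rnorm(n_id, 0, 0.5), each = 2)
  obs$reproductive <- rbinom(nrow(obs), 1,
                             plogis(1.3 - 0.09 * obs$density + re))
  fit <- glmm_binomial_fit(obs, reproductive ~ density)
  expect_gt(-0.09, fit$ci95["density", "lo95"])
  expect_lt(-0.09, fit$ci95["density", "hi95"])
  expect_false(fit$separation_flag)
})

test_that("repro observations are adult females from 2009 with condition", {
  truth <- small_truth()
  sim <- simulate_study(truth, seed = 35)
  obs <- repro_observations(sim$captures, truth$grids)
  expect_true(all(obs$year >= 2009))
  expect_true(all(obs$reproductive %in% 0:1))
  cls <- individual_classes(sim$captures)
  m <- match(paste(obs$individual_id, obs$year),
             paste(cls$individual_id, cls$year))
  expect_true(all(cls$class[m] == "F.adult"))
})

test_that("mass-change records follow the exclusion and averaging rules", {
  g <- list(wet = make_grid("wet", "wet", 12, 12))
  base <- data.frame(grid_id = "wet", col = 3L, row = 3L, sex = "F",
                     repro = NA_character_, pregnant = FALSE,
                     stringsAsFactors = FALSE)
  ev <- cbind(data.frame(individual_id = c("a", "a", "b", "b", "b", "c", "c"),
                         year = 2010L,
                         primary = c(1L, 2L, 1L, 1L, 2L, 1L, 3L),
                         occasion = c(1L, 1L, 1L, 2L, 1L, 1L, 1L),
                         mass_g = c(30, 36, 30, 32, 37, 30, 36)), base)
  mc <- compute_mass_change(ev)
  # 30 g -> 36 g over a 30-day interval: +0.2 g/day
  expect_equal(mc$delta_g_per_day[mc$individual_id == "a"], 0.2)
  # two first-period masses averaged: initial 31, delta (37-31)/30 = 0.2
  b <- mc[mc$individual_id == "b", ]
  expect_equal(b$initial_mass_g, 31)
  expect_equal(b$delta_g_per_day, 0.2)
  # June & August only (non-consecutive) contributes nothing
  expect_false("c" %in% mc$individual_id)
  # pregnant females are excluded
  ev2 <- ev
  ev2$pregnant[1] <- TRUE
  expect_false("a" %in% compute_mass_change(ev2)$individual_id)
})

test_that("mass LMM recovers the mass-by-season interaction", {
  set.seed(36)
  n_id <- 260
  rec <- data.frame(
    individual_id = rep(sprintf("m%03d", 1:n_id), each = 2),
    period_pair = rep(c("June-July", "July-August"), n_id),
    initial_mass_g = rep(runif(n_id, 15, 55), each = 2),
    density = rep(runif(n_id, 0.1, 8), each = 2))
  re <- rep(rnorm(n_id, 0, 0.03), each = 2)
  late <- rec$period_pair == "July-August"
  rec$delta_g_per_day <- 0.3 - 0.008 * rec$initial_mass_g - 0.35 * late +
    0.006 * rec$initial_mass_g * late + re + rnorm(nrow(rec), 0, 0.05)
  fit <- lmm_mass_fit(rec)
  ix <- grep(":", names(fit$coef))
  expect_lt(abs(fit$coef[[ix]] - 0.006), 0.002)
  expect_gt(0.006, fit$ci95[ix, "lo95"])
  expect_lt(0.006, fit$ci95[ix, "hi95"])
  # model selection keeps the interaction and drops the null density term
  sel <- mass_model_set(rec)
  expect_true(grepl("initial_mass_g \\* period_pair",
                    sel$table$model[sel$table$selected]))
  expect_false(grepl("density", sel$table$model[sel$table$selected]))
})

test_that("mass LMM reduces to least squares at zero grouping variance", {
  # scan a fixed seed sequence for a dataset whose ML variance estimate
  # lands on the zero boundary (no true grouping -> ~half of datasets do),
  # then the mixed fit must equal OLS to numerical precision
  found <- FALSE
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- 100
    rec <- data.frame(individual_id = rep(sprintf("m%03d", 1:(n / 2)), 2),
                      period_pair = "June-July",
                      initial_mass_g = runif(n, 15, 55))
    rec$delta_g_per_day <- 0.3 - 0.008 * rec$initial_mass_g +
      rnorm(n, 0, 0.05)
    fit <- lmm_mass_fit(rec, delta_g_per_day ~ initial_mass_g)
    if (fit$ranef_sd < 1e-8) {
      found <- TRUE
      ols <- lm(delta_g_per_day ~ initial_mass_g, data = rec)
      expect_equal(unname(fit$coef), unname(coef(ols)), tolerance = 1e-6)
      break
    }
  }
  expect_true(found)
})
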