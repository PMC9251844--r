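test_that("half-normal detection has its closed-form values", {
  expect_equal(halfnormal(0, 0.3, 15), 0.3)
  expect_equal(halfnormal(15, 0.3, 15), 0.3 * exp(-0.5))
  expect_lt(halfnormal(1e6, 0.3, 15), 1e-12)
  expect_error(halfnormal(10, 0.3, -1), "sigma")
})

test_that("habitat mask covers the buffered bounding box", {
  g <- make_grid("wet", "wet", 12, 12)
  m <- build_mask(g, buffer_m = 100, spacing_m = 10)
  # 330-m station extent + 2 x 100-m buffer = 530 m in both directions
  expect_equal(diff(range(m$points[, 1])), 530)
  expect_equal(diff(range(m$points[, 2])), 530)
  expect_equal(nrow(m$points), 54^2)  # seq(-100, 430, 10) per axis
  m0 <- build_mask(g, buffer_m = 0, spacing_m = 10)
  expect_equal(range(m0$points[, 1]), c(0, 330))
  m2 <- build_mask(g, buffer_m = 100, spacing_m = 20)
  expect_lt(abs(nrow(m2$points) / nrow(m$points) - 0.25), 0.05)
  expect_error(build_mask(g, spacing_m = 0), "spacing")
})

test_that("optimiser matches a 25x25 brute-force likelihood grid search", {
  grid <- make_grid("wet", "wet", 12, 12)
  mask <- build_mask(grid, spacing_m = 20)
  ses <- sim_session(D = 3, seed = 11, grid = grid, mask = mask)
  fit <- fit_secr(ses$history, grid, mask, hessian = FALSE)
  caps <- lemcycle:::secr_caps(ses$history, grid, mask)
  g0s <- seq(0.1, 0.6, length.out = 25)
  sigmas <- seq(8, 30, length.out = 25)
  nll <- outer(g0s, sigmas, Vectorize(function(a, b) {
    lemcycle:::secr_negloglik(c(qlogis(a), log(b)), caps)
  }))
  best <- which(nll == min(nll), arr.ind = TRUE)
  # optimiser at least as good as the lattice, and within one lattice cell
  expect_lte(-fit$loglik, min(nll) + 1e-6)
  expect_lt(abs(fit$g0 - g0s[best[1]]), diff(g0s[1:2]) + 1e-9)
  expect_lt(abs(fit$sigma_m - sigmas[best[2]]), diff(sigmas[1:2]) + 1e-9)
})

test_that("fitted likelihood is a local maximum", {
  grid <- make_grid("wet", "wet", 12, 12)
  mask <- build_mask(grid, spacing_m = 20)
  ses <- sim_session(D = 3, seed = 5, grid = grid, mask = mask)
  fit <- fit_secr(ses$history, grid, mask, hessian = FALSE)
  caps <- lemcycle:::secr_caps(ses$history, grid, mask)
  v0 <- lemcycle:::secr_negloglik(fit$par, caps)
  for (d in list(c(0.05, 0), c(-0.05, 0), c(0, 0.05), c(0, -0.05))) {
    expect_gt(lemcycle:::secr_negloglik(fit$par + d, caps), v0)
  }
})

test_that("detection simulation matches its analytic expectation", {
  # independent oracle: E[detected] = sum_i 1 - (1 - p_i)^S with
  # p_i = 1 - exp(-sum_k -log(1 - g(d_ik))), computed directly
  grid <- make_grid("wet", "wet", 12, 12)
  set.seed(99)
  xy <- station_xy(grid)
  xr <- range(xy[, 1]) + c(-100, 100)
  N <- round(5 * diff(xr)^2 / 1e4)
  pop <- data.frame(id = sprintf("i%03d", 1:N),
                    x = runif(N, xr[1], xr[2]), y = runif(N, xr[1], xr[2]))
  d2 <- outer(pop$x, xy[, 1], "-")^2 + outer(pop$y, xy[, 2], "-")^2
  p_occ <- -expm1(-rowSums(-log1p(-0.3 * exp(-d2 / (2 * 15^2)))))
  expected_n <- sum(1 - (1 - p_occ)^6)
  reps <- replicate(200, {
    length(unique(simulate_detections(pop, grid, 6L, 0.3, 15)$id))
  })
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected_n), 2 * se + 1e-9)
  # limits: no detection without contact hazard; saturation at g0 = 1
  expect_equal(nrow(simulate_detections(pop, grid, 6L, 0, 15)), 0)
  sat <- simulate_detections(pop, grid, 3L, 1, 1e6)
  expect_equal(nrow(sat), nrow(pop) * 3L)
})

test_that("density approaches n/area when detection saturates the mask", {
  grid <- make_grid("wet", "wet", 12, 12)
  mask <- build_mask(grid, spacing_m = 20)
  ses <- sim_session(D = 2, g0 = 0.999, sigma = 500, n_occ = 5L, seed = 3,
                     grid = grid, mask = mask)
  fit <- fit_secr(ses$history, grid, mask, hessian = FALSE)
  d <- derive_density(fit)
  expect_lt(abs(fit$esa_ha / mask$area_ha - 1), 0.02)
  expect_lt(abs(d$density_ha - fit$n / mask$area_ha) / d$density_ha, 0.03)
})

test_that("zero detections yield a flagged zero density", {
  grid <- make_grid("wet", "wet", 12, 12)
  ses <- sim_session(D = 4, seed = 2, grid = grid)
  fit <- fit_secr(ses$history, grid, ses$mask)
  d0 <- derive_density(fit, n_detected = 0L)
  expect_equal(d0$density_ha, 0)
  expect_false(d0$converged_flag)
  expect_error(fit_secr(build_session_histories(
    tiny_captures()[0, ], grid, n_occasions = 5L), grid), "no detections")
})

test_that("density estimate is stable under mask refinement and buffer growth", {
  grid <- make_grid("wet", "wet", 12, 12)
  ses <- sim_session(D = 4, seed = 8, grid = grid)
  ref <- derive_density(fit_secr(ses$history, grid,
                                 build_mask(grid, spacing_m = 10),
                                 hessian = FALSE))
  fine <- derive_density(fit_secr(ses$history, grid,
                                  build_mask(grid, spacing_m = 5),
                                  hessian = FALSE))
  expect_lt(abs(fine$density_ha - ref$density_ha) / ref$density_ha, 0.01)
  wide <- derive_density(fit_secr(ses$history, grid,
                                  build_mask(grid, buffer_m = 150,
                                             spacing_m = 10),
                                  hessian = FALSE))
  expect_lt(abs(wide$density_ha - ref$density_ha) / ref$density_ha, 0.02)
})

test_that("single-capture-only sessions are flagged non-identifiable", {
  grid <- make_grid("wet", "wet", 12, 12)
  ev <- data.frame(individual_id = "solo", year = 2010L, primary = 1L,
                   occasion = 1L, grid_id = "wet", col = 6L, row = 6L,
                   sex = "F", mass_g = 30, repro = NA_character_,
                   pregnant = FALSE, stringsAsFactors = FALSE)
  h <- build_session_histories(ev, grid, n_occasions = 6L)
  fit <- suppressWarnings(fit_secr(h, grid, build_mask(grid, spacing_m = 20)))
  expect_false(fit$identifiable)
  expect_false(fit$converged)
})

test_that("session batching routes by abundance and never aborts", {
  grid <- make_grid("wet", "wet", 12, 12)
  ses <- sim_session(D = 4, seed = 13, grid = grid)
  ev <- ses$events
  # high-abundance session: own detection model for the (single) class
  # low-abundance session: 4 individuals, pooled detection
  ids4 <- unique(ev$individual_id)[1:4]
  low <- ev[ev$individual_id %in% ids4, ]
  low$year <- 2011L
  caps <- rbind(ev, low)
  res <- estimate_all_sessions(caps, list(wet = grid), mask_spacing_m = 20)
  expect_equal(nrow(res), 8)  # 2 sessions x 4 classes
  hi <- res[res$year == 2010 & res$class == "F.adult", ]
  lo <- res[res$year == 2011 & res$class == "F.adult", ]
  expect_false(hi$pooled_flag)
  expect_true(lo$pooled_flag)
  expect_gt(hi$density_ha, 0)
  expect_gt(lo$density_ha, 0)
  expect_true(all(res$density_ha[res$class != "F.adult"] == 0))
  # class densities from a pooled fit partition the total: D_c = n_c / a
  expect_equal(lo$n, 4)
})
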