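# Build a minimal annual-history frame from 0/1 pattern strings.
hist_from_patterns <- function(patterns, year = 2010L, class = "F.adult") {
  n <- length(patterns)
  hm <- t(vapply(patterns, function(p) {
    v <- as.integer(strsplit(p, "")[[1]])
    c(v, rep(NA_integer_, 4 - length(v)))
  }, integer(4)))
  colnames(hm) <- paste0("h", 1:4)
  cbind(data.frame(individual_id = sprintf("i%03d", seq_len(n)),
                   year = year, grid_id = "wet",
                   sex = sub("\\..*", "", class),
                   age = sub(".*\\.", "", class), class = class,
                   stringsAsFactors = FALSE),
        as.data.frame(hm))
}

test_that("with perfect detection the survival MLE is the return rate", {
  # 2 occasions, 30-day interval: 14 of 20 released animals re-seen
  h <- hist_from_patterns(c(rep("11", 14), rep("10", 6)))
  fit0 <- fit_cjs(h, ~ 1, ~ 1)
  dat <- fit0$data
  # profile the likelihood over survival with detection pinned at ~1
  nll <- vapply(seq(-3, 3, by = 0.001), function(b) {
    cjs_negloglik(c(b, 20), dat)
  }, 0)
  phi_hat <- plogis(seq(-3, 3, by = 0.001)[which.min(nll)])
  expect_equal(phi_hat, 14 / 20, tolerance = 1e-3)
})

test_that("20-day intervals are standardised through the 2/3 exponent", {
  # same re-sighting data in a 20-day year: phi_monthly^(2/3) = return rate
  h <- hist_from_patterns(c(rep("1100", 14), rep("1000", 6)), year = 2005L)
  h$h3 <- 0L; h$h4 <- 0L  # released at 1, never seen after occasion 2
  fit0 <- fit_cjs(h, ~ 1, ~ 1)
  dat <- fit0$data
  expect_equal(unique(dat$exponent), 2 / 3)
  expect_equal(0.5^(20 / 30), 0.63, tolerance = 0.003)
})

test_that("monthly survival agrees between 20- and 30-day trapping designs", {
  set.seed(21)
  h20 <- simulate_cjs(2000, c(F.adult = 0.5), p = 0.95, n_primary = 4L,
                      interval_days = 20, year = 2005L)
  h30 <- simulate_cjs(2000, c(F.adult = 0.5), p = 0.95, n_primary = 3L,
                      interval_days = 30, year = 2010L)
  f20 <- fit_cjs(h20, ~ 1, ~ 1)
  f30 <- fit_cjs(h30, ~ 1, ~ 1)
  phi20 <- plogis(f20$phi_coef[[1]])
  phi30 <- plogis(f30$phi_coef[[1]])
  expect_lt(abs(phi20 - phi30), 0.04)
  expect_lt(abs(phi20 - 0.5), 0.03)
})

test_that("optimiser matches a 101x101 brute-force likelihood grid", {
  set.seed(22)
  h <- simulate_cjs(30, c(F.adult = 0.45), p = 0.8, n_primary = 3L)
  fit <- fit_cjs(h, ~ 1, ~ 1)
  dat <- fit$data
  phis <- seq(0.01, 0.99, length.out = 101)
  ps <- seq(0.01, 0.99, length.out = 101)
  nll <- outer(phis, ps, Vectorize(function(a, b) {
    cjs_negloglik(c(qlogis(a), qlogis(b)), dat)
  }))
  best <- which(nll == min(nll), arr.ind = TRUE)
  expect_lte(-fit$loglik, min(nll) + 1e-6)
  # the continuum optimum can sit at a lattice cell edge, hence 1.5 cells
  expect_lt(abs(plogis(fit$phi_coef[[1]]) - phis[best[1]]),
            1.5 * diff(phis[1:2]))
  expect_lt(abs(plogis(fit$p_coef[[1]]) - ps[best[2]]),
            1.5 * diff(ps[1:2]))
})

test_that("history probabilities sum to one over all post-release outcomes", {
  par <- c(0.3, -0.2)  # arbitrary logit survival / detection
  lik <- vapply(c("100", "110", "101", "111"), function(p) {
    fit_dat <- lemcycle:::prepare_cjs(hist_from_patterns(p), ~ 1, ~ 1)
    exp(-cjs_negloglik(par, fit_dat))
  }, 0)
  expect_equal(sum(lik), 1, tolerance = 1e-10)
})

test_that("sex-specific monthly survival is recovered at realistic scale", {
  set.seed(23)
  h <- simulate_cjs(400, c(F.adult = 0.46, M.adult = 0.29),
                    p = c(F.adult = 0.88, M.adult = 1.0), n_primary = 3L)
  fit <- fit_cjs(h, ~ class, ~ sex)
  tab <- monthly_survival_table(fit)
  phi_f <- tab$phi_monthly[tab$class == "F.adult"][1]
  phi_m <- tab$phi_monthly[tab$class == "M.adult"][1]
  expect_lt(abs(phi_f - 0.46), 0.05)
  expect_lt(abs(phi_m - 0.29), 0.05)
  expect_true(all(tab$lo95 <= tab$phi_monthly & tab$phi_monthly <= tab$hi95))
  expect_false(any(tab$boundary_flag))
})

test_that("nesting and the simplest-model rule behave as specified", {
  set.seed(24)
  h <- simulate_cjs(150, c(F.adult = 0.45, M.adult = 0.45), p = 0.9)
  f_small <- fit_cjs(h, ~ 1, ~ 1)
  f_big <- fit_cjs(h, ~ class, ~ sex)
  expect_gte(f_big$loglik, f_small$loglik - 1e-6)
  # constructed tie: dAICc = 1.5 in favour of the larger model, but the
  # 5-parameter model is selected over the 8-parameter one
  expect_equal(select_model(c(100, 101.5), c(8L, 5L)), 2L)
  expect_equal(select_model(c(100, 103), c(8L, 5L)), 1L)
  expect_error(select_model(c(Inf, Inf), c(2L, 3L)), "converged")
})

test_that("a year without between-primary recaptures hits the zero boundary", {
  set.seed(25)
  good <- simulate_cjs(120, c(F.adult = 0.5), p = 0.9, year = 2011L)
  bad <- hist_from_patterns(rep("100", 17), year = 2012L)
  fit <- fit_cjs(rbind(good, bad), ~ yearf, ~ 1)
  tab <- monthly_survival_table(fit)
  expect_true(tab$boundary_flag[tab$year == 2012])
  expect_lt(tab$phi_monthly[tab$year == 2012], 1e-4)
  expect_false(tab$boundary_flag[tab$year == 2011])
  # survival entirely without recaptures is not identifiable at all
  expect_error(fit_cjs(bad, ~ 1, ~ 1), "not identifiable")
})

test_that("survival-density regression flags boundaries and degenerate input", {
  set.seed(26)
  pairs <- data.frame(phi = rep(0.4, 12), se_phi = 0.03,
                      density = exp(runif(12, -2, 2)), se_density = 0.1)
  fit <- survival_density_regression(pairs, B = 200, seed = 2)
  expect_true(fit$ci95[1, "x"] <= 0 & 0 <= fit$ci95[2, "x"])
  expect_error(survival_density_regression(pairs[0, ]), "no survival")
  pairs$phi[1:10] <- 0  # boundary cells are dropped with a message
  expect_message(
    expect_error(survival_density_regression(pairs, B = 50), "too few"),
    "boundary")
})
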