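test_that("Huber fit interpolates zero-residual data exactly", {
  x <- 1:10
  y <- 2 + 0.5 * x
  f <- huber_fit(x, y)
  expect_equal(unname(f$coefficients), c(2, 0.5), tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("Huber fit matches least squares on clean Gaussian data", {
  # no systematic difference: the mean standardised gap to OLS over
  # replicates stays well under a tenth of a standard error
  set.seed(1)
  gap <- replicate(60, {
    n <- 200
    x <- runif(n, 0, 10)
    y <- 1 + 0.3 * x + rnorm(n, 0, 0.5)
    hf <- huber_fit(x, y)$coefficients
    ols <- lm(y ~ x)
    (hf - coef(ols)) / summary(ols)$coefficients[, "Std. Error"]
  })
  expect_lt(abs(mean(gap[2, ])), 0.1)
  expect_lt(abs(mean(gap[1, ])), 0.1)
  # infinite tuning constant recovers least squares exactly
  n <- 200
  x <- runif(n, 0, 10)
  y <- 1 + 0.3 * x + rnorm(n, 0, 0.5)
  hf_inf <- huber_fit(x, y, tuning_c = Inf)
  expect_equal(unname(hf_inf$coefficients), unname(coef(lm(y ~ x))),
               tolerance = 1e-7)
})

test_that("Huber fit resists a gross outlier at the leverage centre", {
  set.seed(2)
  n <- 40
  x <- seq(0, 10, length.out = n)
  y <- 1 + 0.3 * x + rnorm(n, 0, 0.3)
  y_cont <- y
  y_cont[which.min(abs(x - 5))] <- 50  # gross y-outlier mid-design
  slope_clean <- coef(lm(y ~ x))[2]
  slope_cont_ols <- coef(lm(y_cont ~ x))[2]
  slope_huber <- huber_fit(x, y_cont)$coefficients[2]
  expect_lt(abs(slope_huber - slope_clean), abs(slope_cont_ols - slope_clean))
})

test_that("Huber IRLS agrees with an independent M-estimator implementation", {
  set.seed(3)
  n <- 120
  x <- runif(n, 0, 5)
  y <- 2 - 0.4 * x + rt(n, df = 3) * 0.5
  hf <- huber_fit(x, y)
  rl <- MASS::rlm(y ~ x, k2 = 1.345, maxit = 100)
  expect_equal(unname(hf$coefficients), unname(coef(rl)), tolerance = 0.02)
  expect_error(huber_fit(cbind(1, x, x), y), "rank deficient")
})

test_that("perturbation preserves links, fixed points and link-scale means", {
  pts <- data.frame(x = c(2, 0.5), se_x = 0, y = c(0.3, 0.8), se_y = 0)
  expect_equal(perturb_dataset(pts), pts)
  set.seed(4)
  pts2 <- data.frame(x = rep(1.5, 1e4), se_x = 1.2,
                     y = rep(0.9, 1e4), se_y = 0.08)
  pert <- perturb_dataset(pts2)
  expect_true(all(pert$y > 0 & pert$y < 1))
  expect_true(all(pert$x > 0))
  # oracle: E[invlink(N(link(v), s))] by numerical integration
  s_y <- 0.08 / (0.9 * 0.1)
  ey <- integrate(function(z) plogis(z) * dnorm(z, qlogis(0.9), s_y),
                  -Inf, Inf)$value
  expect_lt(abs(mean(pert$y) - ey), 4 * sd(pert$y) / sqrt(1e4))
  s_x <- 1.2 / 1.5
  ex <- exp(log(1.5) + s_x^2 / 2)  # lognormal mean, closed form
  expect_lt(abs(mean(pert$x) - ex), 4 * sd(pert$x) / sqrt(1e4))
})

test_that("bootstrap regression collapses to the plain fit when SEs vanish", {
  set.seed(5)
  n <- 80
  x <- runif(n, 0.2, 8)
  y <- plogis(-1 + 0.2 * x + rnorm(n, 0, 0.15))
  pts <- data.frame(x = x, se_x = 0, y = y, se_y = 0)
  fit <- bootstrap_regression(pts, ~ x, B = 2000, seed = 6)
  point <- huber_fit(x, qlogis(y))$coefficients
  expect_lt(abs(fit$beta[["x"]] - point[[2]]), 0.01)
})

test_that("bootstrap CIs are reproducible and widen with input error", {
  set.seed(7)
  n <- 30
  x <- runif(n, 0.2, 8)
  y <- plogis(-1 + 0.15 * x + rnorm(n, 0, 0.2))
  width <- sapply(c(0, 1, 2), function(mult) {
    pts <- data.frame(x = x, se_x = 0.2 * mult * x,
                      y = y, se_y = 0.05 * mult)
    f <- bootstrap_regression(pts, ~ x, B = 300, seed = 11)
    f$ci95[2, "x"] - f$ci95[1, "x"]
  })
  expect_true(all(diff(width) > 0))
  pts <- data.frame(x = x, se_x = 0.1, y = y, se_y = 0.03)
  f1 <- bootstrap_regression(pts, ~ x, B = 200, seed = 42)
  f2 <- bootstrap_regression(pts, ~ x, B = 200, seed = 42)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$ci95, f2$ci95)
})

test_that("regression handles a grid covariate resampled with its point", {
  set.seed(8)
  n <- 60
  grid <- sample(c("wet", "mesic1"), n, replace = TRUE)
  x <- runif(n, 0.2, 8)
  y <- plogis(-1 + 0.2 * x + 0.5 * (grid == "wet") + rnorm(n, 0, 0.2))
  pts <- data.frame(x = x, se_x = 0.1 * x, y = y, se_y = 0.04,
                    grid = grid)
  f <- bootstrap_regression(pts, ~ x + grid, B = 300, seed = 9)
  expect_named(f$beta, c("(Intercept)", "x", "gridwet"))
  expect_gt(f$beta[["x"]], 0)
  expect_true(f$significant[["x"]])
})
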