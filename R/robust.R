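#' Huber M-estimator linear regression
#'
#' Iteratively reweighted least squares with the Huber psi function:
#' observations with standardised residual beyond the tuning constant are
#' downweighted proportionally. Scale is re-estimated each iteration by the
#' median absolute deviation of the residuals; iteration stops when the
#' largest coefficient change drops below `tol`.
#'
#' @param x Design matrix (including the intercept column) or a numeric
#'   vector for a simple straight-line fit.
#' @param y Response vector.
#' @param tuning_c Huber tuning constant; the default 1.345 gives 95%
#'   efficiency under Gaussian errors. `Inf` recovers ordinary least
#'   squares.
#' @param max_iter,tol Iteration control.
#' @return List with `coefficients`, `residuals`, `weights`, `scale`,
#'   `iterations`, `converged`.
#' @export
huber_fit <- function(x, y, tuning_c = 1.345, max_iter = 200, tol = 1e-8) {
  X <- if (is.null(dim(x))) cbind(`(Intercept)` = 1, x = x) else as.matrix(x)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) <= ncol(X))
    stop("need more observations than coefficients")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  # weighted least squares via normal equations: k is tiny, n moderate
  wls <- function(w) {
    Xw <- X * w
    solve(crossprod(Xw, X), crossprod(Xw, y))[, 1]
  }
  beta <- wls(rep(1, length(y)))
  w <- rep(1, length(y))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    s <- stats::mad(r, center = 0)
    if (s < 1e-12) { converged <- TRUE; break }  # interpolating fit
    u <- abs(r) / s
    w <- ifelse(u <= tuning_c, 1, tuning_c / u)
    beta_new <- wls(w)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  r <- y - drop(X %*% beta)
  list(coefficients = beta, residuals = r, weights = w,
       scale = stats::mad(r, center = 0), iterations = it,
       converged = converged)
}

# Link helpers with the boundary conventions used throughout: proportions
# are clamped away from 0/1 before the logit and densities floored before
# the log (a local extirpation yields observed density 0).
clamp_unit <- function(y, eps) pmin(pmax(y, eps), 1 - eps)

#' Perturb an errors-in-both-axes dataset
#'
#' Error propagation step of the two-axis bootstrap: each response is
#' replaced by a draw from a normal distribution on the logit scale centred
#' at the observed value with the delta-method sd `se_y / (y (1 - y))`, and
#' each density by a log-scale draw with sd `se_x / x`, both back-
#' transformed. Points with zero standard error are returned unchanged.
#'
#' @param points Data frame with columns `x`, `se_x`, `y`, `se_y` (other
#'   columns are carried through).
#' @param y_eps Clamp applied to `y` before the logit (default
#'   `0.5 / 201`, half a count out of the 200-replicate composition
#'   bootstrap).
#' @param x_floor Floor applied to `x` before the log, animals/ha.
#' @param y_link `"logit"` (proportions, survival) or `"identity"`.
#' @return `points` with `x` and `y` replaced by their perturbed values.
#' @export
perturb_dataset <- function(points, y_eps = 0.5 / 201, x_floor = 0.01,
                            y_link = "logit") {
  se_x <- ifelse(is.finite(points$se_x), points$se_x, 0)
  se_y <- ifelse(is.finite(points$se_y), points$se_y, 0)
  x <- pmax(points$x, x_floor)
  lx <- log(x)
  se_lx <- se_x / x
  x_new <- ifelse(se_x > 0, exp(stats::rnorm(length(lx), lx, se_lx)), x)
  if (y_link == "logit") {
    y <- clamp_unit(points$y, y_eps)
    ly <- stats::qlogis(y)
    se_ly <- se_y / (y * (1 - y))
    y_new <- ifelse(se_y > 0,
                    stats::plogis(stats::rnorm(length(ly), ly, se_ly)), y)
  } else {
    y_new <- ifelse(se_y > 0,
                    stats::rnorm(length(points$y), points$y, se_y),
                    points$y)
  }
  out <- points
  out$x <- x_new
  out$y <- y_new
  out
}

#' Two-axis error-propagation bootstrap around a robust regression
#'
#' Relates a proportion (or survival probability) to population density
#' when both carry standard errors. Each of `B` replicates (i) resamples
#' the points with replacement, keeping the original sample size and
#' resampling each point — response, density, errors and covariates — as a
#' unit, (ii) perturbs both axes via [perturb_dataset], and (iii) fits a
#' Huber robust regression of the link-scale response on density (plus any
#' covariates in `formula`). Coefficients are reported as the mean over
#' replicates with 2.5%/97.5% quantile confidence limits; a coefficient is
#' called significant when its interval excludes zero.
#'
#' @param points Data frame with `x`, `se_x`, `y`, `se_y` and any covariate
#'   columns named in `formula`.
#' @param formula Right-hand side only, e.g. `~ x` or `~ x + grid`; the
#'   response is always the link-transformed `y`.
#' @param B Number of bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @param y_link `"logit"` (default) or `"identity"` scale for the response.
#' @param x_link `"identity"` (default) or `"log"` scale for the density
#'   axis entering the design matrix (the perturbation is always log-scale).
#' @param tuning_c Huber tuning constant.
#' @param y_eps,x_floor Boundary conventions, see [perturb_dataset].
#' @return Object of class `boot_rlm`: list with `beta` (mean
#'   coefficients), `ci95` (2 x k matrix), `draws` (B x k), `B`,
#'   `n_points`, `n_failed`, `significant`.
#' @export
bootstrap_regression <- function(points, formula = ~ x, B = 2000, seed = 1L,
                                 y_link = "logit", x_link = "identity",
                                 tuning_c = 1.345, y_eps = 0.5 / 201,
                                 x_floor = 0.01) {
  stopifnot(nrow(points) >= 3L, B >= 1)
  set.seed(seed)
  n <- nrow(points)
  fit_one <- function(d) {
    dd <- d
    dd$x <- if (x_link == "log") log(pmax(d$x, x_floor)) else d$x
    X <- stats::model.matrix(formula, dd)
    yy <- if (y_link == "logit") stats::qlogis(clamp_unit(d$y, y_eps)) else d$y
    huber_fit(X, yy, tuning_c = tuning_c)$coefficients
  }
  template <- fit_one(points)
  draws <- matrix(NA_real_, B, length(template),
                  dimnames = list(NULL, names(template)))
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    pert <- perturb_dataset(points[idx, , drop = FALSE],
                            y_eps = y_eps, x_floor = x_floor, y_link = y_link)
    cf <- try(fit_one(pert), silent = TRUE)
    if (inherits(cf, "try-error")) { n_failed <- n_failed + 1L; next }
    draws[b, ] <- cf
  }
  ok <- stats::complete.cases(draws)
  if (!any(ok)) stop("every bootstrap replicate failed")
  beta <- colMeans(draws[ok, , drop = FALSE])
  ci <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975))
  structure(list(beta = beta, ci95 = ci, draws = draws[ok, , drop = FALSE],
                 B = B, n_points = n, n_failed = n_failed,
                 point_fit = template,
                 significant = ci[1, ] > 0 | ci[2, ] < 0),
            class = "boot_rlm")
}

#' @export
print.boot_rlm <- function(x, ...) {
  cat(sprintf("Two-axis bootstrap robust regression (B = %d, n = %d)\n",
              x$B, x$n_points))
  tab <- data.frame(estimate = x$beta, lo95 = x$ci95[1, ], hi95 = x$ci95[2, ],
                    significant = x$significant)
  print(round(tab[1:3], 4))
  invisible(x)
}

#' Tidy a `boot_rlm` into the report layout
#' @param fit A `boot_rlm`.
#' @param response Label for the response column.
#' @return Data frame: `response`, `term`, `estimate`, `lo95`, `hi95`, `B`,
#'   `n`.
#' @export
regression_table <- function(fit, response = "y") {
  data.frame(response = response, term = names(fit$beta),
             estimate = unname(fit$beta),
             lo95 = unname(fit$ci95[1, ]), hi95 = unname(fit$ci95[2, ]),
             B = fit$B, n = fit$n_points, stringsAsFactors = FALSE)
}
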