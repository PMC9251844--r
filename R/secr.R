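#' Half-normal detection function
#'
#' Per-occasion probability of capture in a trap at distance `d` from an
#' animal's activity centre: `g0 * exp(-d^2 / (2 * sigma_m^2))`.
#'
#' @param d Distance in metres (vectorised), `d >= 0`.
#' @param g0 Capture probability at distance 0.
#' @param sigma_m Spatial scale of detection, metres.
#' @return Capture probability.
#' @export
halfnormal <- function(d, g0, sigma_m) {
  if (sigma_m <= 0) stop("sigma_m must be > 0")
  g0 * exp(-d^2 / (2 * sigma_m^2))
}

#' Build a habitat mask around a trapping grid
#'
#' A regular lattice of potential activity-centre locations covering the
#' bounding box of the trap stations expanded by `buffer_m` on all sides.
#' The default 100-m buffer corresponds to three to four times the daily
#' movement of the animals, beyond which detection is negligible.
#'
#' @param grid A `trap_grid`.
#' @param buffer_m Buffer width in metres.
#' @param spacing_m Mask point spacing in metres (default 10).
#' @return Object of class `habitat_mask`: list with `points` (matrix of x,
#'   y), `spacing_m`, `buffer_m`, `cell_ha` (cell area in hectares) and
#'   `area_ha`.
#' @export
build_mask <- function(grid, buffer_m = 100, spacing_m = 10) {
  stopifnot(inherits(grid, "trap_grid"))
  if (spacing_m <= 0) stop("spacing_m must be > 0")
  xy <- station_xy(grid)
  xs <- seq(min(xy[, 1]) - buffer_m, max(xy[, 1]) + buffer_m, by = spacing_m)
  ys <- seq(min(xy[, 2]) - buffer_m, max(xy[, 2]) + buffer_m, by = spacing_m)
  pts <- as.matrix(expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE))
  m <- structure(list(points = pts, spacing_m = spacing_m,
                      buffer_m = buffer_m,
                      cell_ha = spacing_m^2 / 1e4,
                      area_ha = nrow(pts) * spacing_m^2 / 1e4),
                 class = "habitat_mask")
  # cache the mask-to-trap squared distances for the likelihood kernel
  m$d2 <- mask_trap_d2(m, grid)
  m
}

# Squared distances mask points x trap stations.
mask_trap_d2 <- function(mask, grid) {
  xy <- station_xy(grid)
  outer(mask$points[, 1], xy[, 1], "-")^2 +
    outer(mask$points[, 2], xy[, 2], "-")^2
}

# Multi-catch detection quantities at (g0, sigma) for every mask point:
# per-trap hazard h_k(x) = -log(1 - g(d_k)), total hazard H(x), and the
# per-occasion probability of capture anywhere p(x) = 1 - exp(-H).
# logh is only evaluated at trap columns some animal was caught in
# (used_cols); the others never enter the likelihood.
detect_fields <- function(d2, g0, sigma_m, used_cols = NULL) {
  g0 <- min(g0, 1 - 1e-9)
  z <- d2 / (2 * sigma_m^2)
  # beyond z = 34, g < g0 * 2e-15: numerically zero hazard; computing the
  # exponential only inside detection range cuts most of the work
  near <- z < 34
  g <- z
  g[] <- 0
  g[near] <- g0 * exp(-z[near])
  # h = -log(1-g): series g(1 + g/2) is exact to ~1e-9 for g <= 1e-3
  h <- g * (1 + 0.5 * g)
  big <- g > 1e-3
  h[big] <- -log1p(-g[big])
  H <- rowSums(h)
  logh <- if (is.null(used_cols)) log(h + 1e-300)
          else log(h[, used_cols, drop = FALSE] + 1e-300)
  list(logh = logh, H = H, p_occ = -expm1(-H))
}

# Conditional-on-capture multi-catch SECR negative log-likelihood.
# Thin wrapper over the compiled kernel; secr_negloglik_ref below is the
# plain-R reference implementation the kernel is tested against.
secr_negloglik <- function(par, caps) {
  secr_nll_cpp(par, caps$d2, caps$e_i, caps$e_k, caps$e_n, caps$ci,
               caps$w, caps$n, caps$S)
}

# caps: list with Nik (unique histories x K capture counts), ci (captures
# per history), w (multiplicities), S (occasions), d2 (M x K); the mask
# cell area cancels from the conditional likelihood.
secr_negloglik_ref <- function(par, caps) {
  g0 <- stats::plogis(par[1]); sigma <- exp(par[2])
  f <- detect_fields(caps$d2, g0, sigma, caps$used_cols)
  # log Pr(history_i | x) over mask points: M x n
  lp <- f$logh %*% caps$tNik_used
  # + c_i * (log p(x) - log H(x))  - (S - c_i) * H(x), per mask point x
  # and individual i
  lp <- lp + outer(log(f$p_occ + 1e-300) - log(f$H + 1e-300), caps$ci) -
    outer(f$H, caps$S - caps$ci)
  # integrate over the mask (log-sum-exp per unique history)
  nu <- length(caps$ci)
  mx <- lp[cbind(max.col(t(lp)), seq_len(nu))]
  li <- mx + log(colSums(exp(lp - rep(mx, each = nrow(lp)))))
  pdot <- -expm1(caps$S * log1p(-f$p_occ))  # 1 - (1 - p)^S
  sum_pdot <- sum(pdot)
  if (!is.finite(sum_pdot) || sum_pdot <= 0) return(1e10)
  val <- -(sum(caps$w * li) - caps$n * log(sum_pdot))
  if (!is.finite(val)) 1e10 else val
}

# Build the likelihood inputs from a session_history. Identical capture
# histories (common after bootstrap resampling) are collapsed into unique
# rows with multiplicity weights -- an exact reformulation.
secr_caps <- function(history, grid, mask) {
  K <- nrow(grid$stations)
  key <- apply(history$trap, 1, paste, collapse = ",")
  uk <- which(!duplicated(key))
  w <- tabulate(match(key, key[uk]), nbins = length(uk))
  Nik <- matrix(0, length(uk), K)
  for (j in seq_along(uk)) {
    tr <- history$trap[uk[j], ]
    tr <- tr[tr > 0L]
    Nik[j, ] <- tabulate(tr, nbins = K)
  }
  used <- which(colSums(Nik) > 0)
  nz <- which(Nik > 0, arr.ind = TRUE)
  list(Nik = Nik, ci = rowSums(Nik), w = w, n = length(key),
       S = history$n_occasions,
       d2 = if (is.null(mask$d2)) mask_trap_d2(mask, grid) else mask$d2,
       used_cols = used, tNik_used = t(Nik[, used, drop = FALSE]),
       e_i = nz[, 1] - 1L, e_k = nz[, 2] - 1L, e_n = Nik[nz])
}

#' Fit the conditional SECR likelihood for one session
#'
#' Maximises the conditional-on-capture multi-catch SECR likelihood with
#' half-normal detection over (logit g0, log sigma), starting from three
#' deterministic sigma values; the best likelihood wins and ties go to the
#' smallest sigma. The variance matrix comes from the numerical Hessian.
#'
#' When detection is shared across sex-age groups (the low-abundance rule) a
#' single (g0, sigma) describes all animals on the grid and class densities
#' are derived from class counts and the common effective sampling area.
#'
#' @param history A `session_history` (see [build_session_histories]).
#' @param grid The `trap_grid`.
#' @param mask A `habitat_mask`; built with defaults if omitted.
#' @param starts_sigma Deterministic sigma starting values, metres.
#' @param g0_start Starting capture probability at distance 0.
#' @param start Optional explicit starting vector (logit g0, log sigma),
#'   e.g. to warm-start bootstrap refits from the point estimate.
#' @param hessian Compute the numerical Hessian for the variance matrix
#'   (skip in bootstrap replicates where only the point estimate is used).
#' @param reltol Optimiser convergence tolerance; bootstrap refits may run
#'   looser since only replicate variability is consumed.
#' @return Object of class `secr_fit`: `g0`, `sigma_m`, `loglik`, `esa_ha`
#'   (effective sampling area per individual, hectares), `vcov` (on the
#'   logit-g0 / log-sigma scale), `n`, `converged`, `identifiable`.
#' @export
fit_secr <- function(history, grid, mask = build_mask(grid),
                     starts_sigma = c(15, 30, 60), g0_start = 0.2,
                     start = NULL, hessian = TRUE, reltol = 1e-8) {
  n <- length(history$ids)
  if (n == 0L) stop("no detections: cannot fit the conditional likelihood")
  caps <- secr_caps(history, grid, mask)
  # spatial information requires recaptures; flag single-capture-only data
  identifiable <- any(caps$ci > 1L)
  # the three deterministic starts are screened by likelihood value and the
  # optimiser launched from the best; remaining starts are used only if the
  # first optimisation fails to converge (ties go to the smallest sigma)
  starts <- if (!is.null(start)) list(start) else
    lapply(starts_sigma, function(s0) c(stats::qlogis(g0_start), log(s0)))
  if (is.null(start) && identifiable) {
    # data-driven extra start: pooled RMS deviation of capture locations
    # from each individual's centroid estimates sigma directly
    s_hat <- rpsv_sigma(history, grid)
    if (is.finite(s_hat))
      starts <- c(list(c(stats::qlogis(g0_start),
                         log(min(max(s_hat, 4), 150)))), starts)
  }
  if (length(starts) > 1L) {
    v0 <- vapply(starts, secr_negloglik, 0, caps = caps)
    starts <- starts[order(v0, vapply(starts, `[`, 0, 2))]
  }
  best <- NULL
  for (s0 in starts) {
    fit <- try(stats::optim(s0, secr_negloglik, caps = caps,
                            method = "BFGS", hessian = FALSE,
                            control = list(maxit = 200, reltol = reltol)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value - 1e-8) best <- fit
    if (best$convergence == 0) break
  }
  if (is.null(best))
    stop("SECR optimisation failed from every starting point")
  vcov <- matrix(NA_real_, 2, 2)
  if (hessian) {
    H <- try(stats::optimHess(best$par, secr_negloglik, caps = caps),
             silent = TRUE)
    if (!inherits(H, "try-error")) {
      vc <- try(solve(H), silent = TRUE)
      if (!inherits(vc, "try-error") && all(is.finite(vc)) &&
          all(diag(vc) > 0)) vcov <- vc
    }
  }
  g0 <- stats::plogis(best$par[1]); sigma <- exp(best$par[2])
  structure(list(
    g0 = g0, sigma_m = sigma, par = best$par,
    loglik = -best$value,
    esa_ha = secr_esa(best$par, caps, mask),
    vcov = vcov, n = n, n_occasions = history$n_occasions,
    grid_id = history$grid_id, year = history$year, primary = history$primary,
    converged = best$convergence == 0 && identifiable,
    identifiable = identifiable,
    caps = caps, mask = mask), class = "secr_fit")
}

# Effective sampling area a(theta) in hectares: mask integral of the
# probability of being detected at least once during the session.
secr_esa <- function(par, caps, mask) {
  secr_pdot_sum_cpp(par, caps$d2, caps$S) * mask$cell_ha
}

#' @export
print.secr_fit <- function(x, ...) {
  cat(sprintf(
    "SECR conditional fit: n = %d, g0 = %.3f, sigma = %.1f m, esa = %.2f ha\n",
    x$n, x$g0, x$sigma_m, x$esa_ha))
  if (!x$identifiable) cat("  WARNING: no recaptures; not identifiable\n")
  invisible(x)
}

#' Horvitz-Thompson density from a conditional SECR fit
#'
#' Density is the number of detected animals divided by the effective
#' sampling area, `D = n / a(theta)`. The variance combines
#' detection-parameter uncertainty (delta method on the logit-g0/log-sigma
#' scale) with Poisson count variation; the 95% interval is lognormal-based
#' so the lower bound stays positive.
#'
#' @param fit A `secr_fit`.
#' @param n_detected Number of detected individuals to convert (defaults to
#'   the fit's own n; pass a class count to get a class density from a
#'   pooled fit).
#' @return Data frame row: `density_ha`, `se`, `lo95`, `hi95`, `n`,
#'   `converged_flag`.
#' @export
derive_density <- function(fit, n_detected = fit$n) {
  if (n_detected == 0L)
    return(data.frame(density_ha = 0, se = NA_real_, lo95 = NA_real_,
                      hi95 = NA_real_, n = 0L, converged_flag = FALSE))
  a <- fit$esa_ha
  if (!is.finite(a) || a <= 0) stop("effective sampling area is zero")
  D <- n_detected / a
  # delta-method CV of a(theta) + Poisson CV of the count
  cv_a2 <- 0
  if (all(is.finite(fit$vcov))) {
    eps <- 1e-4
    grad <- vapply(1:2, function(j) {
      pp <- fit$par; pp[j] <- pp[j] + eps
      pm <- fit$par; pm[j] <- pm[j] - eps
      (secr_esa(pp, fit$caps, fit$mask) - secr_esa(pm, fit$caps, fit$mask)) /
        (2 * eps)
    }, 0)
    cv_a2 <- max(0, drop(t(grad) %*% fit$vcov %*% grad)) / a^2
  }
  cv2 <- 1 / n_detected + cv_a2
  se <- D * sqrt(cv2)
  cfac <- exp(1.96 * sqrt(log1p(cv2)))
  data.frame(density_ha = D, se = se, lo95 = D / cfac, hi95 = D * cfac,
             n = n_detected, converged_flag = fit$converged)
}

# Pooled RMS deviation of capture locations from individual centroids: a
# moment estimator of the half-normal sigma used as an optimiser start.
rpsv_sigma <- function(history, grid) {
  xy <- station_xy(grid)
  ss <- 0; m <- 0L
  for (i in seq_len(nrow(history$trap))) {
    tr <- history$trap[i, ]
    tr <- tr[tr > 0L]
    if (length(tr) < 2L) next
    px <- xy[tr, 1]; py <- xy[tr, 2]
    ss <- ss + sum((px - mean(px))^2 + (py - mean(py))^2)
    m <- m + length(tr) - 1L
  }
  if (m == 0L) return(NA_real_)
  sqrt(ss / (2 * m))
}

# Subset a session history to a set of individuals.
subset_history <- function(history, keep) {
  h <- history
  h$ids <- history$ids[keep]
  h$trap <- history$trap[keep, , drop = FALSE]
  h
}

#' Estimate SECR densities for every session of a study
#'
#' Applies the abundance routing rule: in sessions with more than
#' `pool_threshold` distinct individuals each sex-age class on the grid is
#' fitted with its own detection model; at or below the threshold (the
#' low-abundance case) all classes are pooled into one fit per grid —
#' capture probability and sigma constant among animals — and class
#' densities come from class counts over the common effective sampling
#' area. Per-session failures are returned as flagged rows; the batch never
#' aborts.
#'
#' @param captures Capture data frame (see [captures]).
#' @param grids Named list of `trap_grid` objects.
#' @param buffer_m,mask_spacing_m Mask geometry (defaults 100 m and 10 m).
#' @param pool_threshold Pooling rule: pooled fit when distinct individuals
#'   in the session <= this value (default 5).
#' @param classes Sex-age classes to report.
#' @return Data frame, one row per year x primary x grid x class:
#'   `year`, `primary`, `grid_id`, `grid_level`, `class`, `n`,
#'   `n_occasions`, `g0`, `sigma_m`, `density_ha`, `se`, `lo95`, `hi95`,
#'   `pooled_flag`, `converged_flag`, `borrowed_flag`. Sessions whose own
#'   detection model is non-identifiable (e.g. every animal caught exactly
#'   once) receive a density computed with detection parameters borrowed
#'   from the grid's identifiable fits and are flagged `borrowed_flag`.
#' @export
estimate_all_sessions <- function(captures, grids, buffer_m = 100,
                                  mask_spacing_m = 10, pool_threshold = 5L,
                                  classes = c("F.adult", "M.adult",
                                              "F.juvenile", "M.juvenile")) {
  cls <- individual_classes(captures)
  clskey <- paste(cls$individual_id, cls$year, sep = "\r")
  masks <- lapply(grids, build_mask, buffer_m = buffer_m,
                  spacing_m = mask_spacing_m)
  sessions <- unique(captures[, c("year", "grid_id", "primary")])
  sessions <- sessions[order(sessions$year, sessions$grid_id, sessions$primary), ]
  out <- vector("list", nrow(sessions))
  for (si in seq_len(nrow(sessions))) {
    yr <- sessions$year[si]; gid <- sessions$grid_id[si]
    pr <- sessions$primary[si]
    grid <- grids[[gid]]; mask <- masks[[gid]]
    ses <- captures[captures$year == yr & captures$grid_id == gid &
                      captures$primary == pr, ]
    hist <- build_session_histories(ses, grid)
    icls <- cls$class[match(paste(hist$ids, yr, sep = "\r"), clskey)]
    n_tot <- length(hist$ids)
    pooled <- n_tot <= pool_threshold
    rows <- lapply(classes, function(cl) {
      n_cl <- sum(!is.na(icls) & icls == cl)
      base <- data.frame(year = yr, primary = pr, grid_id = gid,
                         grid_level = grid_level(grid, yr), class = cl,
                         n = n_cl, n_occasions = hist$n_occasions,
                         g0 = NA_real_, sigma_m = NA_real_,
                         density_ha = 0, se = NA_real_, lo95 = NA_real_,
                         hi95 = NA_real_, pooled_flag = pooled,
                         converged_flag = FALSE, borrowed_flag = FALSE,
                         stringsAsFactors = FALSE)
      base
    })
    names(rows) <- classes
    pooled_fit <- NULL
    get_pooled_fit <- function() {
      if (is.null(pooled_fit) && n_tot > 0L)
        pooled_fit <<- try(fit_secr(hist, grid, mask), silent = TRUE)
      pooled_fit
    }
    for (cl in classes) {
      n_cl <- rows[[cl]]$n
      if (n_cl == 0L) next
      if (pooled) {
        pf <- get_pooled_fit()
        if (inherits(pf, "secr_fit")) {
          d <- derive_density(pf, n_cl)
          rows[[cl]][, c("g0", "sigma_m")] <- c(pf$g0, pf$sigma_m)
          rows[[cl]][, c("density_ha", "se", "lo95", "hi95",
                         "converged_flag")] <-
            d[, c("density_ha", "se", "lo95", "hi95", "converged_flag")]
        }
      } else {
        keep <- !is.na(icls) & icls == cl
        cf <- try(fit_secr(subset_history(hist, keep), grid, mask),
                  silent = TRUE)
        if (!inherits(cf, "secr_fit") || !cf$identifiable) {
          # class data too thin for its own detection model: fall back to
          # detection shared across classes
          pf <- get_pooled_fit()
          if (inherits(pf, "secr_fit")) {
            d <- derive_density(pf, n_cl)
            rows[[cl]][, c("g0", "sigma_m")] <- c(pf$g0, pf$sigma_m)
            rows[[cl]][, c("density_ha", "se", "lo95", "hi95",
                           "converged_flag")] <-
              d[, c("density_ha", "se", "lo95", "hi95", "converged_flag")]
            rows[[cl]]$pooled_flag <- TRUE
          }
        } else {
          d <- derive_density(cf)
          rows[[cl]][, c("g0", "sigma_m")] <- c(cf$g0, cf$sigma_m)
          rows[[cl]][, c("density_ha", "se", "lo95", "hi95",
                         "converged_flag")] <-
            d[, c("density_ha", "se", "lo95", "hi95", "converged_flag")]
        }
      }
    }
    out[[si]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  borrow_detection(res, masks)
}

# Sessions whose own detection model is non-identifiable (typically a
# handful of animals each caught once, common at the cycle trough) or
# failed get a density from the same Horvitz-Thompson formula with
# detection parameters borrowed from the grid's identifiable fits (median
# g0 and sigma; study-wide medians if a grid never had one). Uncertainty
# then carries the count term only. Rows are flagged `borrowed_flag`.
borrow_detection <- function(res, masks) {
  ok <- res$converged_flag & is.finite(res$g0) & is.finite(res$sigma_m)
  fix <- !res$converged_flag & res$n > 0
  if (!any(fix) || !any(ok)) return(res)
  for (gid in unique(res$grid_id[fix])) {
    src <- ok & res$grid_id == gid
    if (!any(src)) src <- ok
    g0_b <- stats::median(res$g0[src])
    sg_b <- stats::median(res$sigma_m[src])
    par_b <- c(stats::qlogis(g0_b), log(sg_b))
    mask <- masks[[gid]]
    for (i in which(fix & res$grid_id == gid)) {
      a <- secr_pdot_sum_cpp(par_b, mask$d2, res$n_occasions[i]) *
        mask$cell_ha
      if (!is.finite(a) || a <= 0) next
      D <- res$n[i] / a
      cv2 <- 1 / res$n[i]
      cfac <- exp(1.96 * sqrt(log1p(cv2)))
      res$g0[i] <- g0_b; res$sigma_m[i] <- sg_b
      res$density_ha[i] <- D
      res$se[i] <- D * sqrt(cv2)
      res$lo95[i] <- D / cfac; res$hi95[i] <- D * cfac
      res$borrowed_flag[i] <- TRUE
    }
  }
  res
}
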