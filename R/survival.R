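#' @title Cormack-Jolly-Seber survival with unequal intervals
#' @description
#' Apparent survival among the primary periods of a summer, conditioned on
#' first capture. Interval survival is parameterised through monthly
#' survival, `phi_interval = phi_monthly^(interval_days/30)`, so estimates
#' are comparable between the 20-day (2004-2007) and 30-day schedules.
#' Summers are modelled independently (between-summer recaptures are
#' negligible in this system).
#' @name survival_cjs
NULL

# Compress annual histories into unique (year, class, grid, pattern) groups
# and build model matrices for phi (one row per group x transition) and p
# (one row per group x occasion >= 2).
prepare_cjs <- function(histories, phi_formula = ~ class,
                        p_formula = ~ sex) {
  h <- histories[!is.na(histories$class), , drop = FALSE]
  hm <- as.matrix(h[, paste0("h", 1:4)])
  # occasions actually available per history (NA marks beyond-schedule)
  TT <- rowSums(!is.na(hm))
  pat <- apply(hm, 1, function(r) paste(r[!is.na(r)], collapse = ""))
  # only histories observed at least twice -- singletons after the last
  # possible release still contribute through chi, keep all with >= 2
  # occasions remaining after first capture
  first <- apply(hm, 1, function(r) which(r == 1L)[1])
  keep <- first < TT
  h <- h[keep, , drop = FALSE]; hm <- hm[keep, , drop = FALSE]
  TT <- TT[keep]; pat <- pat[keep]; first <- first[keep]
  if (nrow(h) == 0L) stop("no usable histories (all first caught at the last occasion)")
  grp_key <- paste(h$year, h$class, h$grid_id, pat, sep = "\r")
  ug <- !duplicated(grp_key)
  w <- as.vector(table(factor(grp_key, levels = grp_key[ug])))
  g <- h[ug, , drop = FALSE]
  ghm <- hm[ug, , drop = FALSE]
  gTT <- TT[ug]; gfirst <- first[ug]
  G <- nrow(g)
  # covariate frame per group x transition
  tr <- do.call(rbind, lapply(seq_len(G), function(i) {
    data.frame(grp = i, t = seq_len(gTT[i] - 1L))
  }))
  covs <- g[tr$grp, c("year", "class", "grid_id", "sex", "age"), drop = FALSE]
  covs$primary <- factor(tr$t)
  covs$yearf <- factor(covs$year)
  covs$class <- factor(covs$class)
  covs$sex <- factor(covs$sex)
  covs$grid <- factor(covs$grid_id)
  Xphi <- stats::model.matrix(phi_formula, covs)
  Xp <- stats::model.matrix(p_formula, covs)  # occasion t+1 detection
  n_released <- sum(w)
  # per-transition bookkeeping for the vectorised likelihood
  last <- vapply(seq_len(G), function(i) {
    max(which(ghm[i, seq_len(gTT[i])] == 1L))
  }, 0L)
  active <- tr$t >= gfirst[tr$grp] & tr$t <= last[tr$grp] - 1L
  seen_next <- ghm[cbind(tr$grp, tr$t + 1L)]
  maxT <- max(gTT)
  trrow <- matrix(NA_integer_, G, maxT - 1L)
  trrow[cbind(tr$grp, tr$t)] <- seq_along(tr$grp)
  list(G = G, w = w, hm = ghm, TT = gTT, first = gfirst, last = last,
       exponent = interval_days(g$year) / 30,
       tr_grp = tr$grp, tr_t = tr$t, active = active,
       seen_next = seen_next, trrow = trrow, maxT = maxT,
       Xphi = Xphi, Xp = Xp, n_released = n_released,
       kphi = ncol(Xphi), kp = ncol(Xp), covs = covs)
}

#' CJS negative log-likelihood
#'
#' Standard open-population likelihood conditioned on first capture, with
#' monthly-standardised interval survival. Exposed so that the optimum can
#' be verified against direct grid searches.
#'
#' @param par Parameter vector on the logit scale: survival coefficients
#'   followed by detection coefficients (lengths `dat$kphi`, `dat$kp`).
#' @param dat Prepared data from the internal compressor (as stored in a
#'   [fit_cjs] result's `$data`).
#' @return Negative log-likelihood.
#' @export
cjs_negloglik <- function(par, dat) {
  bphi <- par[seq_len(dat$kphi)]
  bp <- par[dat$kphi + seq_len(dat$kp)]
  phi_m <- stats::plogis(drop(dat$Xphi %*% bphi))
  phi_int <- phi_m^(dat$exponent[dat$tr_grp])
  p <- stats::plogis(drop(dat$Xp %*% bp))
  wrow <- dat$w[dat$tr_grp]
  # detection-conditional part between first and last capture
  ll <- sum(wrow * dat$active *
              (log(phi_int) +
                 ifelse(dat$seen_next == 1L, log(p), log1p(-p))))
  # chi: probability of never being seen after the last capture,
  # recursed jointly over all groups from the final transition backwards
  chi <- rep(1, dat$G)
  for (t in (dat$maxT - 1L):1L) {
    idx <- which(!is.na(dat$trrow[, t]) & dat$last <= t)
    if (!length(idx)) next
    r <- dat$trrow[idx, t]
    chi[idx] <- (1 - phi_int[r]) + phi_int[r] * (1 - p[r]) * chi[idx]
  }
  ll <- ll + sum(dat$w * log(chi))
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit a CJS model to annual histories
#'
#' @param histories Data frame from [build_annual_histories] or
#'   [simulate_cjs]; rows with unknown class are dropped.
#' @param phi_formula Model for logit monthly survival; covariates
#'   available: `class` (sex-age group), `sex`, `age`, `primary`
#'   (transition index, factor), `yearf` (year factor), `grid`.
#' @param p_formula Model for logit detection at occasions after the first
#'   (default `~ sex`, detection structured by sex).
#' @param label Optional model label.
#' @return Object of class `cjs_fit`: coefficients, `vcov`, `loglik`,
#'   `n_params`, `AICc` (effective sample size = released individuals),
#'   `data` (prepared structure), `converged`.
#' @export
fit_cjs <- function(histories, phi_formula = ~ class, p_formula = ~ sex,
                    label = NULL) {
  dat <- prepare_cjs(histories, phi_formula, p_formula)
  if (sum(dat$w[rowSums(dat$hm, na.rm = TRUE) > 1L]) == 0L)
    stop("no recaptures: survival is not identifiable")
  k <- dat$kphi + dat$kp
  start <- rep(0, k)
  fit <- stats::optim(start, cjs_negloglik, dat = dat, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  H <- try(stats::optimHess(fit$par, cjs_negloglik, dat = dat), silent = TRUE)
  vcov <- matrix(NA_real_, k, k)
  if (!inherits(H, "try-error")) {
    vc <- try(solve(H), silent = TRUE)
    if (inherits(vc, "try-error") || !all(is.finite(diag(vc))))
      # boundary cells (e.g. a year without recaptures) make the Hessian
      # singular; the pseudo-inverse still gives usable variances for the
      # identified cells while the boundary ones are flagged downstream
      vc <- try(MASS::ginv(H), silent = TRUE)
    if (!inherits(vc, "try-error") && all(is.finite(diag(vc))))
      vcov <- vc
  }
  ll <- -fit$value
  structure(list(
    par = fit$par,
    phi_coef = stats::setNames(fit$par[seq_len(dat$kphi)],
                               colnames(dat$Xphi)),
    p_coef = stats::setNames(fit$par[dat$kphi + seq_len(dat$kp)],
                             colnames(dat$Xp)),
    vcov = vcov, loglik = ll, n_params = k,
    AICc = aicc(ll, k, dat$n_released),
    phi_formula = phi_formula, p_formula = p_formula,
    label = if (is.null(label))
      paste0("phi(", deparse(phi_formula[[2]]), ") p(",
             deparse(p_formula[[2]]), ")") else label,
    data = dat, converged = fit$convergence == 0), class = "cjs_fit")
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat(sprintf("CJS fit %s: logLik = %.2f, k = %d, AICc = %.2f\n",
              x$label, x$loglik, x$n_params, x$AICc))
  invisible(x)
}

#' Fit a candidate set of CJS designs and apply the simplest-model rule
#'
#' Each design is a pair of formulas for survival and detection. Models are
#' ranked by AICc (effective sample size = number of released individuals)
#' and the selected model is the one with the fewest parameters among those
#' within 2 AICc units of the best. Non-convergent designs are flagged and
#' excluded from selection.
#'
#' @param histories Annual histories.
#' @param candidates List of lists with elements `phi` (formula), `p`
#'   (formula, optional, default `~ sex`) and `label` (optional).
#' @return List with `fits` (all `cjs_fit` objects or `try-error`s),
#'   `table` (selection table), `selected` (the chosen `cjs_fit`).
#' @export
fit_model_set <- function(histories, candidates) {
  stopifnot(length(candidates) >= 1L)
  fits <- lapply(candidates, function(cand) {
    p_form <- if (is.null(cand$p)) ~ sex else cand$p
    try(fit_cjs(histories, cand$phi, p_form, label = cand$label),
        silent = TRUE)
  })
  ok <- vapply(fits, function(f) inherits(f, "cjs_fit") && f$converged, TRUE)
  if (!any(ok)) stop("no candidate survival model converged")
  lab <- vapply(seq_along(fits), function(i) {
    if (inherits(fits[[i]], "cjs_fit")) fits[[i]]$label
    else paste0("candidate_", i, " (failed)")
  }, "")
  ll <- vapply(fits, function(f) if (inherits(f, "cjs_fit")) f$loglik else NA_real_, 0)
  k <- vapply(fits, function(f) if (inherits(f, "cjs_fit")) f$n_params else NA_integer_, 0L)
  av <- vapply(seq_along(fits), function(i) {
    if (ok[i]) fits[[i]]$AICc else Inf
  }, 0)
  tab <- selection_table(lab, ll, k, av)
  list(fits = fits, table = tab, selected = fits[[which(tab$selected)]])
}

#' Back-transformed monthly survival per design cell
#'
#' Evaluates the fitted model at every distinct covariate cell present in
#' the data, with Wald 95% intervals on the logit scale. Boundary estimates
#' (monthly survival numerically 0 or 1, as happens in years without any
#' between-primary recapture) are flagged.
#'
#' @param fit A `cjs_fit`.
#' @return Data frame: one row per distinct cell with `class`, `year`,
#'   `primary`, `grid`, `phi_monthly`, `lo95`, `hi95`, `p_capture`,
#'   `boundary_flag`.
#' @export
monthly_survival_table <- function(fit) {
  dat <- fit$data
  cells <- !duplicated(dat$Xphi)
  covs <- dat$covs[cells, , drop = FALSE]
  X <- dat$Xphi[cells, , drop = FALSE]
  eta <- drop(X %*% fit$phi_coef)
  Vphi <- fit$vcov[seq_len(dat$kphi), seq_len(dat$kphi), drop = FALSE]
  se <- sqrt(pmax(0, rowSums((X %*% Vphi) * X)))
  Xp <- dat$Xp[cells, , drop = FALSE]
  etap <- drop(Xp %*% fit$p_coef)
  phi <- stats::plogis(eta)
  out <- data.frame(
    class = as.character(covs$class), year = covs$year,
    primary = as.integer(as.character(covs$primary)),
    grid = as.character(covs$grid),
    phi_monthly = phi,
    lo95 = stats::plogis(eta - 1.96 * se),
    hi95 = stats::plogis(eta + 1.96 * se),
    p_capture = stats::plogis(etap),
    boundary_flag = phi < 1e-4 | phi > 1 - 1e-4,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Robust regression of survival on density
#'
#' The a-posteriori analysis: monthly survival estimates (between primary
#' periods t and t+1, per year and sex-age group) are regressed on the
#' density at t with the two-axis error-propagation bootstrap — survival on
#' the logit axis, density on the log axis. Boundary survival cells (0 or
#' 1) cannot be placed on the logit axis and are excluded, with a message.
#'
#' @param pairs Data frame with columns `phi` (monthly survival), `se_phi`,
#'   `density`, `se_density` and optionally covariates.
#' @param B,seed Passed to [bootstrap_regression].
#' @param ... Further arguments to [bootstrap_regression].
#' @return A `boot_rlm`.
#' @export
survival_density_regression <- function(pairs, B = 2000, seed = 1L, ...) {
  if (nrow(pairs) == 0L) stop("no survival-density pairs supplied")
  drop_i <- pairs$phi <= 0 | pairs$phi >= 1 | !is.finite(pairs$phi)
  if (any(drop_i))
    message(sum(drop_i), " boundary survival estimates excluded from the ",
            "logit-scale regression")
  pairs <- pairs[!drop_i, , drop = FALSE]
  if (nrow(pairs) < 3L) stop("too few usable survival-density pairs")
  pts <- data.frame(x = pairs$density, se_x = pairs$se_density,
                    y = pairs$phi, se_y = pairs$se_phi)
  extra <- setdiff(names(pairs), c("phi", "se_phi", "density", "se_density"))
  for (cc in extra) pts[[cc]] <- pairs[[cc]]
  bootstrap_regression(pts, formula = ~ x, B = B, seed = seed,
                       y_link = "logit", x_link = "log", ...)
}

#' Standard candidate designs for the survival analysis
#'
#' The named effects explored: sex-age group, primary period, year, grid,
#' and the group-by-primary interaction, from the constant model up to full
#' time effects with the interaction and an additive grid effect.
#'
#' @return List of candidates for [fit_model_set].
#' @export
standard_survival_candidates <- function() {
  list(
    list(phi = ~ 1, label = "phi(.) p(sex)"),
    list(phi = ~ class, label = "phi(group) p(sex)"),
    list(phi = ~ class + primary, label = "phi(group+primary) p(sex)"),
    list(phi = ~ class * primary, label = "phi(group x primary) p(sex)"),
    list(phi = ~ class + yearf, label = "phi(group+year) p(sex)"),
    list(phi = ~ class * primary + grid,
         label = "phi(group x primary + grid) p(sex)"),
    list(phi = ~ class * primary + grid + yearf,
         label = "phi(group x primary + grid + year) p(sex)")
  )
}
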