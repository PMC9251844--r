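#' Movement distances per individual and year
#'
#' For each individual, the maximum and average Euclidean distance between
#' the station of first capture and every subsequent capture, pooling all
#' primary periods of the year (distances are intra-grid; animals are never
#' caught on more than one grid). Individuals whose captures are all at one
#' trap — including single captures — get distance 0.
#'
#' @param captures Capture data frame.
#' @param grids Named list of `trap_grid` objects (for station
#'   coordinates).
#' @return Data frame, one row per individual x year: `individual_id`,
#'   `year`, `grid_id`, `sex`, `age`, `max_dist_m`, `mean_dist_m`,
#'   `n_captures`.
#' @export
compute_distances <- function(captures, grids) {
  cls <- individual_classes(captures)
  ord <- order(captures$year, captures$primary, captures$occasion)
  x <- captures[ord, ]
  sp <- split(seq_len(nrow(x)), paste(x$individual_id, x$year, sep = "\r"))
  rows <- lapply(sp, function(i) {
    g <- grids[[x$grid_id[i[1]]]]
    xy <- cbind((x$col[i] - 1L) * g$spacing_m, (x$row[i] - 1L) * g$spacing_m)
    if (length(i) == 1L) {
      d <- numeric(0)
    } else {
      d <- sqrt((xy[-1, 1] - xy[1, 1])^2 + (xy[-1, 2] - xy[1, 2])^2)
    }
    data.frame(individual_id = x$individual_id[i[1]], year = x$year[i[1]],
               grid_id = x$grid_id[i[1]],
               max_dist_m = if (length(d)) max(d) else 0,
               mean_dist_m = if (length(d)) mean(d) else 0,
               n_captures = length(i), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  m <- match(paste(out$individual_id, out$year, sep = "\r"),
             paste(cls$individual_id, cls$year, sep = "\r"))
  out$sex <- cls$sex[m]; out$age <- cls$age[m]
  out[order(out$year, out$grid_id, out$individual_id), ]
}

#' Annual population density per grid
#'
#' The density covariate of the movement analysis: the average of the July
#' and August session densities — the last two primary periods of each
#' year — summed over all sex-age classes.
#'
#' @param density_table Output of [estimate_all_sessions].
#' @return Data frame: `year`, `grid_id`, `annual_density`.
#' @export
annual_density <- function(density_table) {
  tot <- stats::aggregate(density_ha ~ year + grid_id + primary,
                          data = density_table, FUN = sum)
  sp <- split(tot, paste(tot$year, tot$grid_id, sep = "\r"))
  out <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$primary), ]
    late <- utils::tail(d$density_ha, 2L)
    data.frame(year = d$year[1], grid_id = d$grid_id[1],
               annual_density = mean(late), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Negative-binomial model of distance moved
#'
#' Distances (rounded to integer metres: many zeros, overdispersed) are
#' modelled with a negative-binomial log-link regression with the
#' log-transformed total number of captures as an offset to control for
#' unequal recapture effort among individuals.
#'
#' @param records Movement records (see [compute_distances]) with a
#'   `density` column attached.
#' @param formula Model formula for the distance response, e.g.
#'   `max_dist_m ~ density + sex * age`; the offset is added internally.
#' @return List with `fit` (the `glm.nb` object), `loglik`, `n_params`,
#'   `AICc`, `label`.
#' @export
negbin_fit <- function(records, formula = max_dist_m ~ density + sex * age) {
  records <- records[!is.na(records$age) & records$age != "unknown", ]
  resp <- all.vars(formula)[1]
  records[[resp]] <- round(records[[resp]])
  if (all(records[[resp]] == 0)) stop("all distances are zero")
  notes <- character()
  fit <- withCallingHandlers(
    MASS::glm.nb(stats::update(formula, . ~ . + offset(log(n_captures))),
                 data = records),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  k <- length(stats::coef(fit)) + 1L  # + dispersion
  ll <- as.numeric(stats::logLik(fit))
  list(fit = fit, loglik = ll, n_params = k,
       AICc = aicc(ll, k, nrow(records)),
       label = deparse(formula), coef = stats::coef(fit),
       notes = notes,
       ci95 = suppressMessages(stats::confint.default(fit)))
}

#' Fit and select among candidate movement models
#'
#' Additive and interactive combinations of sex, age, grid and annual
#' density; selection by the shared simplest-model AICc rule.
#'
#' @param records Movement records with `density` attached.
#' @param response `"max_dist_m"` or `"mean_dist_m"`.
#' @return List with `fits`, `table`, `selected`.
#' @export
movement_model_set <- function(records, response = "max_dist_m") {
  fml <- function(rhs) stats::reformulate(rhs, response = response)
  candidates <- list(
    fml("1"), fml("density"), fml(c("sex", "age")),
    fml("sex * age"), fml(c("density", "sex * age")),
    fml(c("density", "sex * age", "grid_level"))
  )
  fits <- lapply(candidates, function(f) {
    try(negbin_fit(records, f), silent = TRUE)
  })
  ok <- !vapply(fits, inherits, TRUE, "try-error")
  if (!any(ok)) stop("no movement model converged")
  av <- ifelse(ok, vapply(fits, function(f) if (is.list(f)) f$AICc else Inf, 0), Inf)
  ll <- vapply(fits, function(f) if (is.list(f)) f$loglik else NA_real_, 0)
  k <- vapply(fits, function(f) if (is.list(f)) f$n_params else NA_integer_, 0L)
  lab <- vapply(candidates, deparse, "")
  tab <- selection_table(lab, ll, k, av)
  list(fits = fits, table = tab, selected = fits[[which(tab$selected)]])
}

#' Reproduction of adult females: binomial mixed model
#'
#' Reproductive condition (1 = reproductive) of adult females with an
#' individual random intercept for the repeated measures, fitted by
#' Laplace-approximated maximum likelihood (`nAGQ` quadrature points
#' optional). Complete separation is flagged via inflated coefficients.
#'
#' @param observations Data frame with columns `reproductive` (0/1),
#'   `individual_id`, and the fixed-effect covariates.
#' @param formula Fixed-effects part, e.g.
#'   `reproductive ~ density + primary + grid_level`; the random intercept
#'   `(1 | individual_id)` is appended internally.
#' @param nAGQ Quadrature points (1 = Laplace).
#' @return List with `fit` (a `glmerMod`), `loglik`, `n_params`, `AICc`,
#'   `coef`, `ci95`, `ranef_sd`, `separation_flag`.
#' @export
glmm_binomial_fit <- function(observations,
                              formula = reproductive ~ density,
                              nAGQ = 1L) {
  stopifnot(length(unique(observations$individual_id)) >= 2L)
  f <- stats::update(formula, . ~ . + (1 | individual_id))
  notes <- character()
  fit <- withCallingHandlers(
    suppressMessages(
      lme4::glmer(f, data = observations, family = stats::binomial(),
                  nAGQ = nAGQ)),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  list(fit = fit, loglik = ll, n_params = k,
       AICc = aicc(ll, k, nrow(observations)),
       coef = cf,
       ci95 = cbind(lo95 = cf - 1.96 * se, hi95 = cf + 1.96 * se),
       ranef_sd = sqrt(unlist(lme4::VarCorr(fit))[[1]]),
       separation_flag = any(abs(cf) > 10),
       notes = notes,
       label = deparse(formula))
}

#' Candidate set and selection for the reproduction analysis
#' @param observations As in [glmm_binomial_fit].
#' @return List with `fits`, `table`, `selected`.
#' @export
repro_model_set <- function(observations) {
  candidates <- list(
    reproductive ~ 1, reproductive ~ density,
    reproductive ~ density + primary,
    reproductive ~ density + primary + grid_level
  )
  fits <- lapply(candidates, function(f) {
    try(glmm_binomial_fit(observations, f), silent = TRUE)
  })
  ok <- !vapply(fits, inherits, TRUE, "try-error")
  if (!any(ok)) stop("no reproduction model converged")
  av <- ifelse(ok, vapply(fits, function(f) if (is.list(f)) f$AICc else Inf, 0), Inf)
  ll <- vapply(fits, function(f) if (is.list(f)) f$loglik else NA_real_, 0)
  k <- vapply(fits, function(f) if (is.list(f)) f$n_params else NA_integer_, 0L)
  tab <- selection_table(vapply(candidates, deparse, ""), ll, k, av)
  list(fits = fits, table = tab, selected = fits[[which(tab$selected)]])
}

#' Daily body-mass change between consecutive primary periods
#'
#' One record per individual per consecutive period pair: the difference
#' between the (within-period averaged) body mass at period t+1 and at
#' period t, divided by the 20- or 30-day interval. Captures in
#' non-consecutive periods yield no record; females pregnant at either
#' period are excluded.
#'
#' @param captures Capture data frame.
#' @return Data frame: `individual_id`, `year`, `grid_id`, `sex`, `age`,
#'   `period_pair` ("June-July" or "July-August"), `initial_mass_g`,
#'   `delta_g_per_day`.
#' @export
compute_mass_change <- function(captures) {
  cls <- individual_classes(captures)
  x <- captures[!is.na(captures$mass_g), ]
  ag <- stats::aggregate(
    cbind(mass_g = x$mass_g, pregnant = as.numeric(x$pregnant)),
    by = list(individual_id = x$individual_id, year = x$year,
              grid_id = x$grid_id, primary = x$primary), FUN = mean)
  sp <- split(ag, paste(ag$individual_id, ag$year, sep = "\r"))
  rows <- lapply(sp, function(d) {
    d <- d[order(d$primary), ]
    if (nrow(d) < 2L) return(NULL)
    np <- n_primaries(d$year[1]); dt <- interval_days(d$year[1])
    consec <- which(diff(d$primary) == 1L)
    if (!length(consec)) return(NULL)
    out <- lapply(consec, function(i) {
      if (d$pregnant[i] > 0 || d$pregnant[i + 1L] > 0) return(NULL)
      data.frame(individual_id = d$individual_id[1], year = d$year[1],
                 grid_id = d$grid_id[1],
                 period_pair = if (d$primary[i + 1L] == np)
                   "July-August" else "June-July",
                 initial_mass_g = d$mass_g[i],
                 delta_g_per_day = (d$mass_g[i + 1L] - d$mass_g[i]) / dt,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(individual_id = character(), year = integer(),
                      grid_id = character(), period_pair = character(),
                      initial_mass_g = numeric(),
                      delta_g_per_day = numeric(), sex = character(),
                      age = character()))
  rownames(out) <- NULL
  out$period_pair <- factor(out$period_pair,
                            levels = c("June-July", "July-August"))
  m <- match(paste(out$individual_id, out$year, sep = "\r"),
             paste(cls$individual_id, cls$year, sep = "\r"))
  out$sex <- cls$sex[m]; out$age <- cls$age[m]
  out
}

#' Linear mixed model of daily body-mass change
#'
#' Individual random intercept; all candidate models keep initial body
#' mass as a fixed effect (young animals grow faster). Fits use maximum
#' likelihood (not REML) so AICc comparisons across fixed structures are
#' valid. A singular random-effect variance is flagged.
#'
#' @param records Output of [compute_mass_change], with a `density` column
#'   attached when density enters the formula.
#' @param formula Fixed-effects formula for `delta_g_per_day`.
#' @return List with `fit` (an `lmerMod`), `loglik`, `n_params`, `AICc`,
#'   `coef`, `ci95`, `ranef_sd`, `singular_flag`.
#' @export
lmm_mass_fit <- function(records,
                         formula = delta_g_per_day ~
                           initial_mass_g * period_pair) {
  stopifnot(nrow(records) >= 2L)
  if (!is.factor(records$period_pair))
    records$period_pair <- factor(records$period_pair,
                                  levels = c("June-July", "July-August"))
  f <- stats::update(formula, . ~ . + (1 | individual_id))
  notes <- character()
  fit <- withCallingHandlers(
    suppressMessages(
      lme4::lmer(f, data = records, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  list(fit = fit, loglik = ll, n_params = k,
       AICc = aicc(ll, k, nrow(records)),
       coef = cf,
       ci95 = cbind(lo95 = cf - 1.96 * se, hi95 = cf + 1.96 * se),
       ranef_sd = sqrt(unlist(lme4::VarCorr(fit))[[1]]),
       singular_flag = lme4::isSingular(fit),
       notes = notes,
       label = deparse(formula))
}

#' Candidate set and selection for the body-mass analysis
#' @param records As in [lmm_mass_fit].
#' @return List with `fits`, `table`, `selected`.
#' @export
mass_model_set <- function(records) {
  candidates <- list(
    delta_g_per_day ~ initial_mass_g,
    delta_g_per_day ~ initial_mass_g + period_pair,
    delta_g_per_day ~ initial_mass_g * period_pair,
    delta_g_per_day ~ initial_mass_g + density,
    delta_g_per_day ~ initial_mass_g * period_pair + density,
    delta_g_per_day ~ initial_mass_g * period_pair + sex + grid_level
  )
  fits <- lapply(candidates, function(f) {
    try(lmm_mass_fit(records, f), silent = TRUE)
  })
  ok <- !vapply(fits, inherits, TRUE, "try-error")
  if (!any(ok)) stop("no body-mass model converged")
  av <- ifelse(ok, vapply(fits, function(f) if (is.list(f)) f$AICc else Inf, 0), Inf)
  ll <- vapply(fits, function(f) if (is.list(f)) f$loglik else NA_real_, 0)
  k <- vapply(fits, function(f) if (is.list(f)) f$n_params else NA_integer_, 0L)
  tab <- selection_table(vapply(candidates, deparse, ""), ll, k, av)
  list(fits = fits, table = tab, selected = fits[[which(tab$selected)]])
}

#' Extract reproduction observations from captures
#'
#' Adult females with recorded reproductive condition (from 2009 onward):
#' one observation per capture event collapsed to one per individual per
#' primary period.
#'
#' @param captures Capture data frame.
#' @param grids Named list of grids (for the grid covariate level).
#' @return Data frame: `individual_id`, `year`, `primary`, `grid_id`,
#'   `grid_level`, `reproductive` (0/1).
#' @export
repro_observations <- function(captures, grids) {
  cls <- individual_classes(captures)
  m <- match(paste(captures$individual_id, captures$year, sep = "\r"),
             paste(cls$individual_id, cls$year, sep = "\r"))
  x <- captures[cls$class[m] %in% "F.adult" & !is.na(captures$repro), ]
  if (nrow(x) == 0L)
    return(data.frame(individual_id = character(), year = integer(),
                      primary = integer(), grid_id = character(),
                      grid_level = character(), reproductive = integer()))
  ag <- stats::aggregate(
    list(reproductive = as.integer(x$repro == "reproductive")),
    by = list(individual_id = x$individual_id, year = x$year,
              primary = x$primary, grid_id = x$grid_id), FUN = max)
  ag$grid_level <- mapply(function(g, y) grid_level(grids[[g]], y),
                          ag$grid_id, ag$year)
  ag$primary <- factor(ag$primary)
  ag
}
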