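#' Sex/age class proportions from SECR densities
#'
#' The proportion of each class in a session is its SECR density divided by
#' the total density (the sum over all four classes). Sessions with zero
#' total density are flagged with undefined proportions.
#'
#' @param density_table Output of [estimate_all_sessions].
#' @return Data frame, one row per session x class: `year`, `primary`,
#'   `grid_id`, `grid_level`, `class`, `proportion`, `density_total`,
#'   `flag`.
#' @export
proportions_from_densities <- function(density_table) {
  sp <- split(density_table,
              paste(density_table$year, density_table$grid_id,
                    density_table$primary, sep = "\r"))
  out <- do.call(rbind, lapply(sp, function(d) {
    tot <- sum(d$density_ha)
    data.frame(year = d$year, primary = d$primary, grid_id = d$grid_id,
               grid_level = d$grid_level, class = d$class,
               proportion = if (tot > 0) d$density_ha / tot else NA_real_,
               density_total = tot,
               flag = if (tot > 0) "" else "all_zero",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Resample whole individual capture histories with replacement (same n);
# duplicated individuals become distinct synthetic ids. Histories are never
# altered, only resampled as units.
resample_history <- function(history, classes) {
  n <- length(history$ids)
  idx <- sample.int(n, n, replace = TRUE)
  h <- history
  h$ids <- sprintf("bs%03d_%s", seq_len(n), history$ids[idx])
  h$trap <- history$trap[idx, , drop = FALSE]
  rownames(h$trap) <- h$ids
  list(history = h, classes = classes[idx])
}

#' Capture-history bootstrap of class proportions
#'
#' For each session, the individual capture histories are resampled with
#' replacement (keeping the sample size; histories themselves are never
#' changed), the SECR analysis is repeated on each resampled dataset under
#' the same pooling routing as the point estimate, and class proportions
#' are computed from the refitted densities. The bootstrap mean and the
#' standard deviation across replicates give the proportion's standard
#' error. Non-convergent replicates are dropped and counted.
#'
#' @param captures Capture data frame.
#' @param grids Named list of `trap_grid` objects.
#' @param B Number of bootstrap replicates (default 200).
#' @param seed Integer base seed (per-replicate offsets keep replicates
#'   reproducible).
#' @param buffer_m,mask_spacing_m,pool_threshold As in
#'   [estimate_all_sessions].
#' @param classes Class labels.
#' @param point_table Optional precomputed output of
#'   [estimate_all_sessions] under the same settings (avoids refitting the
#'   point estimates).
#' @return Data frame per session x class: `year`, `primary`, `grid_id`,
#'   `class`, `proportion` (point estimate), `boot_mean`, `se`, `n_boot`,
#'   `n_converged`.
#' @export
bootstrap_proportions <- function(captures, grids, B = 200L, seed = 1L,
                                  buffer_m = 100, mask_spacing_m = 10,
                                  pool_threshold = 5L,
                                  classes = c("F.adult", "M.adult",
                                              "F.juvenile", "M.juvenile"),
                                  point_table = NULL) {
  stopifnot(B >= 1L)
  point <- if (is.null(point_table)) {
    estimate_all_sessions(captures, grids, buffer_m = buffer_m,
                          mask_spacing_m = mask_spacing_m,
                          pool_threshold = pool_threshold,
                          classes = classes)
  } else point_table
  props <- proportions_from_densities(point)
  cls <- individual_classes(captures)
  clskey <- paste(cls$individual_id, cls$year, sep = "\r")
  masks <- lapply(grids, build_mask, buffer_m = buffer_m,
                  spacing_m = mask_spacing_m)
  sessions <- unique(captures[, c("year", "grid_id", "primary")])
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
    pmat <- matrix(NA_real_, B, length(classes),
                   dimnames = list(NULL, classes))
    # warm starts for the class-separate refits: the session's own point
    # estimates per class (and pooled fallback)
    warm <- NULL
    if (!pooled && n_tot > 0L) {
      warm <- list()
      pr_rows <- point[point$year == yr & point$grid_id == gid &
                         point$primary == pr, ]
      for (cl in classes) {
        r <- pr_rows[pr_rows$class == cl, ]
        if (nrow(r) == 1L && is.finite(r$g0) && r$g0 > 0 && r$g0 < 1 &&
            is.finite(r$sigma_m) && r$sigma_m > 0)
          warm[[cl]] <- c(stats::qlogis(r$g0), log(r$sigma_m))
      }
      # pooled fallback (thin resampled classes) warm-started too
      pf <- try(fit_secr(hist, grid, mask, hessian = FALSE), silent = TRUE)
      if (inherits(pf, "secr_fit")) warm$pooled <- pf$par
    }
    if (n_tot > 0L) {
      for (b in seq_len(B)) {
        set.seed(seed + 1000L * si + b)
        rs <- resample_history(hist, icls)
        dens <- try(boot_session_densities(rs$history, rs$classes, grid,
                                           mask, pooled, classes,
                                           warm = warm),
                    silent = TRUE)
        if (inherits(dens, "try-error")) next
        tot <- sum(dens)
        if (tot > 0) pmat[b, ] <- dens / tot
      }
    }
    ok <- stats::complete.cases(pmat)
    pe <- props[props$year == yr & props$grid_id == gid &
                  props$primary == pr, ]
    out[[si]] <- data.frame(
      year = yr, primary = pr, grid_id = gid, class = classes,
      proportion = pe$proportion[match(classes, pe$class)],
      boot_mean = if (any(ok)) colMeans(pmat[ok, , drop = FALSE]) else NA_real_,
      se = if (sum(ok) >= 2L) apply(pmat[ok, , drop = FALSE], 2, stats::sd)
           else NA_real_,
      n_boot = B, n_converged = sum(ok),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Class densities for one (resampled) session under the routing rule.
# In the pooled route every class shares one effective sampling area, so
# the refitted proportions n_c/a over sum(n_c/a) reduce exactly to the
# class count shares n_c/n; the SECR refit cancels algebraically and is
# skipped. In the class-separate route each class is refitted, warm-started
# from the point-estimate parameters.
boot_session_densities <- function(history, icls, grid, mask, pooled,
                                   classes, warm = NULL) {
  n_cl <- vapply(classes, function(cl) sum(!is.na(icls) & icls == cl), 0L)
  dens <- stats::setNames(rep(0, length(classes)), classes)
  if (pooled) {
    dens[] <- n_cl  # proportional to n_c / a with common a
  } else {
    pooled_fit <- NULL
    for (cl in classes) {
      if (n_cl[[cl]] == 0L) next
      keep <- !is.na(icls) & icls == cl
      cf <- try(fit_secr(subset_history(history, keep), grid, mask,
                         start = warm[[cl]], hessian = FALSE,
                         reltol = 1e-7),
                silent = TRUE)
      if (inherits(cf, "secr_fit") && cf$identifiable) {
        dens[[cl]] <- n_cl[[cl]] / cf$esa_ha
      } else {
        if (is.null(pooled_fit))
          pooled_fit <- fit_secr(history, grid, mask,
                                 start = warm$pooled, hessian = FALSE,
                                 reltol = 1e-7)
        dens[[cl]] <- n_cl[[cl]] / pooled_fit$esa_ha
      }
    }
  }
  dens
}
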