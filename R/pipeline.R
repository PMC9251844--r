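#' Configuration of a full analysis run
#'
#' Bundles the constants of the standard analysis: 200-replicate
#' capture-history bootstrap for composition, 2000-replicate two-axis
#' regression bootstrap, 100-m mask buffer, pooling at 5 or fewer
#' individuals per session.
#'
#' @param captures_path,grids_path Input files (CSV and YAML/JSON), or
#'   `NULL` when simulating.
#' @param truth A `sim_truth` to simulate from instead of reading inputs.
#' @param out_dir Output directory for the run artifacts.
#' @param B_secr_boot Composition bootstrap replicates (default 200).
#' @param B_regression Regression bootstrap replicates (default 2000).
#' @param buffer_m,mask_spacing_m,pool_threshold SECR settings.
#' @param seed Integer seed governing every stochastic stage.
#' @return Object of class `run_config`.
#' @export
run_config <- function(captures_path = NULL, grids_path = NULL,
                       truth = NULL, out_dir = tempfile("lemcycle_run_"),
                       B_secr_boot = 200L, B_regression = 2000L,
                       buffer_m = 100, mask_spacing_m = 10,
                       pool_threshold = 5L, seed = 1L) {
  stopifnot(B_secr_boot >= 1L, B_regression >= 1L, buffer_m >= 0,
            mask_spacing_m > 0, pool_threshold >= 1L)
  if (is.null(truth) && (is.null(captures_path) || is.null(grids_path)))
    stop("either input paths or a simulation truth must be given")
  structure(list(captures_path = captures_path, grids_path = grids_path,
                 truth = truth, out_dir = out_dir,
                 B_secr_boot = as.integer(B_secr_boot),
                 B_regression = as.integer(B_regression),
                 buffer_m = buffer_m, mask_spacing_m = mask_spacing_m,
                 pool_threshold = as.integer(pool_threshold),
                 seed = as.integer(seed)),
            class = "run_config")
}

stage_path <- function(config, name) file.path(config$out_dir, name)

stage_done <- function(config, name) file.exists(stage_path(config, name))

#' Run the full demographic analysis pipeline
#'
#' Stages, in dependency order: data (read or simulate), SECR densities,
#' composition bootstrap, proportion-vs-density robust regressions,
#' survival model set plus survival-vs-density regressions, movement,
#' reproduction, and body-mass analyses. Each stage writes a CSV artifact
#' and is skipped on rerun if its artifact already exists, so deleting a
#' downstream table and rerunning regenerates only what is missing.
#' Failures in one analysis stage are recorded and do not abort the rest.
#'
#' @param config A `run_config`.
#' @return The output directory, invisibly. A `manifest.json` records the
#'   configuration, seed and package version; `errors.txt` collects any
#'   per-stage failures.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  errors <- character()
  note_error <- function(stage, e) {
    errors <<- c(errors, paste0(stage, ": ", conditionMessage(e)))
  }

  # -- data stage
  if (!is.null(config$truth)) {
    grids <- config$truth$grids
    if (!stage_done(config, "captures.csv")) {
      sim <- simulate_study(config$truth, seed = config$seed)
      write_captures(sim$captures, stage_path(config, "captures.csv"))
      write_grids(grids, stage_path(config, "grids.yaml"))
      utils::write.csv(sim$trajectory, stage_path(config, "truth_trajectory.csv"),
                       row.names = FALSE)
      truth_rec <- config$truth
      truth_rec$grids <- lapply(truth_rec$grids, function(g)
        g[c("grid_id", "habitat", "n_cols", "n_rows", "spacing_m",
            "exclosure_years")])
      jsonlite::write_json(truth_rec, stage_path(config, "truth.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    captures <- read_captures(stage_path(config, "captures.csv"), grids)
  } else {
    grids <- read_grids(config$grids_path)
    captures <- read_captures(config$captures_path, grids)
  }

  # -- densities
  if (!stage_done(config, "densities.csv")) {
    dens <- estimate_all_sessions(captures, grids,
                                  buffer_m = config$buffer_m,
                                  mask_spacing_m = config$mask_spacing_m,
                                  pool_threshold = config$pool_threshold)
    utils::write.csv(dens, stage_path(config, "densities.csv"),
                     row.names = FALSE)
  }
  dens <- utils::read.csv(stage_path(config, "densities.csv"),
                          stringsAsFactors = FALSE)

  # -- composition bootstrap
  if (!stage_done(config, "proportions.csv")) {
    props <- bootstrap_proportions(captures, grids, B = config$B_secr_boot,
                                   seed = config$seed,
                                   buffer_m = config$buffer_m,
                                   mask_spacing_m = config$mask_spacing_m,
                                   pool_threshold = config$pool_threshold,
                                   point_table = dens)
    utils::write.csv(props, stage_path(config, "proportions.csv"),
                     row.names = FALSE)
  }
  props <- utils::read.csv(stage_path(config, "proportions.csv"),
                           stringsAsFactors = FALSE)

  # -- proportion-vs-density regressions, one per class
  if (!stage_done(config, "regressions.csv")) {
    tot <- session_totals(dens)
    reg_rows <- list()
    for (cl in unique(props$class)) {
      res <- try({
        pts <- regression_points(props, tot, cl)
        fit <- bootstrap_regression(pts, formula = ~ x,
                                    B = config$B_regression,
                                    seed = config$seed + 17L)
        regression_table(fit, response = paste0("prop_", cl))
      }, silent = TRUE)
      if (inherits(res, "try-error"))
        note_error(paste0("regression_", cl),
                   simpleError(as.character(res)))
      else reg_rows[[cl]] <- res
    }
    if (length(reg_rows))
      utils::write.csv(do.call(rbind, reg_rows),
                       stage_path(config, "regressions.csv"),
                       row.names = FALSE)
  }

  # -- survival
  if (!stage_done(config, "survival.csv")) {
    res <- try({
      hist <- build_annual_histories(captures)
      ms <- fit_model_set(hist, standard_survival_candidates())
      surv <- monthly_survival_table(ms$selected)
      utils::write.csv(ms$table, stage_path(config, "survival_selection.csv"),
                       row.names = FALSE)
      utils::write.csv(surv, stage_path(config, "survival.csv"),
                       row.names = FALSE)
      # year- and grid-structured fit for the a-posteriori density
      # regression, so that each year x grid contributes a survival
      # estimate per group; detection carries year effects too, otherwise
      # p variation across years (e.g. from density-dependent movement)
      # is confounded into survival
      reg_fit <- fit_cjs(hist, ~ class + yearf + grid, ~ sex + yearf)
      pairs <- survival_density_pairs(monthly_survival_table(reg_fit), dens)
      unlink(stage_path(config, "survival_regressions.csv"))
      for (cl in unique(pairs$class)) {
        pcl <- pairs[pairs$class == cl, ]
        fit <- try(survival_density_regression(
          pcl[, c("phi", "se_phi", "density", "se_density")],
          B = config$B_regression, seed = config$seed + 29L), silent = TRUE)
        if (inherits(fit, "boot_rlm")) {
          tab <- regression_table(fit, response = paste0("phi_", cl))
          f <- stage_path(config, "survival_regressions.csv")
          utils::write.table(tab, f, sep = ",", row.names = FALSE,
                             col.names = !file.exists(f), append = file.exists(f))
        }
      }
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      note_error("survival", simpleError(as.character(res)))
  }

  # -- movement
  if (!stage_done(config, "movement_selection.csv")) {
    res <- try({
      mov <- compute_distances(captures, grids)
      ad <- annual_density(dens)
      m <- match(paste(mov$year, mov$grid_id),
                 paste(ad$year, ad$grid_id))
      mov$density <- ad$annual_density[m]
      mov$grid_level <- mapply(function(g, y) grid_level(grids[[g]], y),
                               mov$grid_id, mov$year)
      mov <- mov[!is.na(mov$density), ]
      utils::write.csv(mov, stage_path(config, "movement_records.csv"),
                       row.names = FALSE)
      ms <- movement_model_set(mov)
      utils::write.csv(ms$table, stage_path(config, "movement_selection.csv"),
                       row.names = FALSE)
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      note_error("movement", simpleError(as.character(res)))
  }

  # -- reproduction
  if (!stage_done(config, "repro_selection.csv")) {
    res <- try({
      obs <- repro_observations(captures, grids)
      tot <- session_totals(dens)
      m <- match(paste(obs$year, obs$grid_id, obs$primary),
                 paste(tot$year, tot$grid_id, tot$primary))
      obs$density <- tot$density_total[m]
      obs <- obs[!is.na(obs$density), ]
      utils::write.csv(obs, stage_path(config, "repro_observations.csv"),
                       row.names = FALSE)
      ms <- repro_model_set(obs)
      utils::write.csv(ms$table, stage_path(config, "repro_selection.csv"),
                       row.names = FALSE)
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      note_error("reproduction", simpleError(as.character(res)))
  }

  # -- body mass
  if (!stage_done(config, "mass_selection.csv")) {
    res <- try({
      mass <- compute_mass_change(captures)
      ad <- annual_density(dens)
      m <- match(paste(mass$year, mass$grid_id),
                 paste(ad$year, ad$grid_id))
      mass$density <- ad$annual_density[m]
      mass$grid_level <- mapply(function(g, y) grid_level(grids[[g]], y),
                                mass$grid_id, mass$year)
      mass <- mass[!is.na(mass$density), ]
      utils::write.csv(mass, stage_path(config, "mass_records.csv"),
                       row.names = FALSE)
      ms <- mass_model_set(mass)
      utils::write.csv(ms$table, stage_path(config, "mass_selection.csv"),
                       row.names = FALSE)
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      note_error("mass", simpleError(as.character(res)))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lemcycle")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = config[c("B_secr_boot", "B_regression", "buffer_m",
                      "mask_spacing_m", "pool_threshold")],
    simulated = !is.null(config$truth),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, stage_path(config, "manifest.json"),
                       auto_unbox = TRUE)
  if (length(errors))
    writeLines(errors, stage_path(config, "errors.txt"))
  invisible(config$out_dir)
}

#' Session total densities with combined standard errors
#'
#' Total density per session is the sum of the class densities; its
#' standard error combines the class-level SEs in quadrature.
#'
#' @param density_table Output of [estimate_all_sessions].
#' @return Data frame: `year`, `primary`, `grid_id`, `density_total`,
#'   `se_total`.
#' @export
session_totals <- function(density_table) {
  sp <- split(density_table,
              paste(density_table$year, density_table$grid_id,
                    density_table$primary, sep = "\r"))
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(year = d$year[1], primary = d$primary[1],
               grid_id = d$grid_id[1],
               density_total = sum(d$density_ha),
               se_total = sqrt(sum(d$se^2, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Assemble the errored points for a proportion-vs-density regression
#'
#' Joins one class's bootstrap proportions (y with SE) with session total
#' densities (x with SE); sessions with missing SEs on the proportion are
#' dropped.
#'
#' @param props Output of [bootstrap_proportions].
#' @param totals Output of [session_totals].
#' @param class Class label, e.g. `"F.adult"`.
#' @return Data frame with `x`, `se_x`, `y`, `se_y`, `grid_id`.
#' @export
regression_points <- function(props, totals, class) {
  p <- props[props$class == class & !is.na(props$proportion) &
               !is.na(props$se), ]
  m <- match(paste(p$year, p$grid_id, p$primary),
             paste(totals$year, totals$grid_id, totals$primary))
  data.frame(x = totals$density_total[m], se_x = totals$se_total[m],
             y = p$proportion, se_y = p$se, grid_id = p$grid_id,
             stringsAsFactors = FALSE)
}

#' Pair survival estimates with the density where they were estimated
#'
#' Each survival cell (class x year x grid) is matched with that grid's
#' summer density (session totals averaged over the year's primary
#' periods); cells whose table lacks grid structure fall back to the
#' across-grid average.
#'
#' @param survival_table Output of [monthly_survival_table] (cells per
#'   class x year x grid).
#' @param density_table Output of [estimate_all_sessions].
#' @return Data frame: `class`, `year`, `primary`, `grid`, `phi`,
#'   `se_phi`, `density`, `se_density`.
#' @export
survival_density_pairs <- function(survival_table, density_table) {
  tot <- session_totals(density_table)
  byyg <- stats::aggregate(cbind(density_total, se_total) ~ year + grid_id,
                           data = tot, FUN = mean)
  byy <- stats::aggregate(cbind(density_total, se_total) ~ year,
                          data = tot, FUN = mean)
  s <- survival_table
  m <- match(paste(s$year, s$grid), paste(byyg$year, byyg$grid_id))
  dens <- byyg$density_total[m]
  se_d <- byyg$se_total[m]
  miss <- is.na(dens)
  if (any(miss)) {
    my <- match(s$year[miss], byy$year)
    dens[miss] <- byy$density_total[my]
    se_d[miss] <- byy$se_total[my]
  }
  out <- data.frame(class = s$class, year = s$year, primary = s$primary,
                    grid = s$grid,
                    phi = s$phi_monthly,
                    se_phi = (s$hi95 - s$lo95) / (2 * 1.96),
                    density = dens, se_density = se_d,
                    stringsAsFactors = FALSE)
  out[!is.na(out$density) & is.finite(out$se_phi), ]
}

#' Summarise a pipeline run as a markdown report
#'
#' Tabulates the density trajectory, the composition and survival
#' regression coefficients with their intervals, and the selected model of
#' each analysis; when the run was simulated, a recovery section compares
#' the regression slopes against the generator's parameters. Partial runs
#' give partial reports with warnings.
#'
#' @param run_dir Directory written by [run_pipeline].
#' @param path Output file (default `report.md` inside `run_dir`).
#' @return The report path, invisibly.
#' @export
make_report <- function(run_dir, path = file.path(run_dir, "report.md")) {
  if (!dir.exists(run_dir) || !length(list.files(run_dir)))
    stop("not a pipeline run directory: ", run_dir)
  lines <- c("# Demographic analysis report", "")
  rd <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  fmt_tab <- function(df) {
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, function(r) paste(r, collapse = " | ")))
  }
  dens <- rd("densities.csv")
  if (!is.null(dens)) {
    tot <- session_totals(dens)
    lines <- c(lines, "## Density trajectory (animals/ha, session totals)",
               "", fmt_tab(within(tot, {
                 density_total <- round(density_total, 3)
                 se_total <- round(se_total, 3)
               })), "")
  } else {
    lines <- c(lines, "WARNING: densities missing", "")
  }
  for (f in c(regressions = "regressions.csv",
              survival_regressions = "survival_regressions.csv")) {
    x <- rd(f)
    if (!is.null(x)) {
      x[c("estimate", "lo95", "hi95")] <-
        lapply(x[c("estimate", "lo95", "hi95")], round, 4)
      lines <- c(lines, paste0("## ", sub(".csv", "", f)), "",
                 fmt_tab(x), "")
    } else {
      lines <- c(lines, paste0("WARNING: ", f, " missing"), "")
    }
  }
  for (f in c("survival_selection.csv", "movement_selection.csv",
              "repro_selection.csv", "mass_selection.csv")) {
    x <- rd(f)
    if (!is.null(x)) {
      sel <- x[x$selected == TRUE | x$selected == "TRUE", "model"]
      lines <- c(lines, paste0("* Selected ", sub("_selection.csv", "", f),
                               " model: `", sel, "`"))
    } else {
      lines <- c(lines, paste0("* WARNING: ", f, " missing"))
    }
  }
  lines <- c(lines, "")
  truth_p <- file.path(run_dir, "truth.json")
  if (file.exists(truth_p)) {
    truth <- jsonlite::read_json(truth_p)
    lines <- c(lines, "## Recovery against simulation truth", "",
               sprintf("* generator adult-female logit slope: %s",
                       truth$female_prop_slope),
               sprintf("* generator movement log-scale density slope: %s",
                       truth$movement_density_slope),
               sprintf("* generator reproduction logit density slope: %s",
                       truth$repro_density_slope))
    reg <- rd("regressions.csv")
    if (!is.null(reg)) {
      fa <- reg[reg$response == "prop_F.adult" & reg$term == "x", ]
      if (nrow(fa))
        lines <- c(lines, sprintf(
          "* estimated adult-female proportion slope: %.4f [%.4f, %.4f]",
          fa$estimate, fa$lo95, fa$hi95))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}
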