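#' Default end-to-end analysis configuration
#'
#' Bundles the default formulation profiles, the five-trial program, the
#' generative hazard specification, the trough-occupancy sensitivity grid
#' (75/80/85 percent) and the case-base settings into one configuration
#' object consumed by [run_trajectories()], [run_full_analysis()] and
#' [run_sensitivity()].
#'
#' @param seed Master seed used for simulation and case-base sampling.
#' @return An \code{"analysis_config"} list.
#' @export
default_analysis_config <- function(seed = 20260101) {
  structure(list(formulations = default_formulations(),
                 trials = default_trial_designs(),
                 hazard = hazard_spec(),
                 seed = as.integer(seed),
                 trough_occupancy_grid = c(75, 80, 85),
                 base_ratio = 100,
                 occ_scale = 10),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' The file holds \code{formulations} blocks keyed by name with keys
#' \code{ed50_mg_per_day}, \code{half_life_days}, \code{time_to_peak_days},
#' \code{dosing_interval_days}, \code{trough_occupancy_pct},
#' \code{max_occupancy_pct}; a \code{trials} list with
#' \code{trial_id}, \code{formulation}, \code{n_active}, \code{n_placebo},
#' \code{max_followup_days}, \code{dropout_hazard_per_day}; a
#' \code{hazard} block with the [hazard_spec()] fields; and scalars
#' \code{seed}, \code{trough_occupancy_grid}, \code{base_ratio},
#' \code{occ_scale}. A bundled default lives at
#' \code{system.file("extdata", "default_config.yaml", package = "occrelapse")}.
#'
#' @param path Path to a YAML (or JSON) configuration file.
#' @return An \code{"analysis_config"} list.
#' @export
read_analysis_config <- function(path) {
  raw <- if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  need <- c("formulations", "trials", "hazard", "seed")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("configuration is missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  formulations <- mapply(as_formulation_params, raw$formulations,
                         names(raw$formulations), SIMPLIFY = FALSE)
  trials <- lapply(raw$trials, function(tr) {
    need_t <- c("trial_id", "formulation", "n_active", "n_placebo",
                "max_followup_days")
    miss_t <- setdiff(need_t, names(tr))
    if (length(miss_t))
      stop("trial block is missing keys: ", paste(miss_t, collapse = ", "),
           call. = FALSE)
    trial_design(tr$trial_id, tr$formulation, tr$n_active, tr$n_placebo,
                 tr$max_followup_days,
                 if (is.null(tr$dropout_hazard_per_day)) 5e-4
                 else tr$dropout_hazard_per_day)
  })
  hz <- raw$hazard
  spec <- hazard_spec(
    baseline_hazard_per_day = if (is.null(hz$baseline_hazard_per_day)) 0.002
                              else hz$baseline_hazard_per_day,
    beta_group = if (is.null(hz$beta_group)) 0 else hz$beta_group,
    beta_occ_per_10pct = if (is.null(hz$beta_occ_per_10pct)) -0.34
                         else hz$beta_occ_per_10pct,
    beta_rate = if (is.null(hz$beta_rate)) 0 else hz$beta_rate,
    beta_time_interaction_per_day =
      if (is.null(hz$beta_time_interaction_per_day)) 0
      else hz$beta_time_interaction_per_day)
  grid <- if (is.null(raw$trough_occupancy_grid)) c(75, 80, 85)
          else as.numeric(raw$trough_occupancy_grid)
  maxo <- min(vapply(formulations, `[[`, numeric(1), "max_occupancy_pct"))
  if (any(grid <= 0 | grid >= maxo))
    stop("trough_occupancy_grid values must lie in (0, max_occupancy_pct)",
         call. = FALSE)
  structure(list(formulations = formulations,
                 trials = trials,
                 hazard = spec,
                 seed = as.integer(raw$seed),
                 trough_occupancy_grid = grid,
                 base_ratio = if (is.null(raw$base_ratio)) 100 else raw$base_ratio,
                 occ_scale = if (is.null(raw$occ_scale)) 10 else raw$occ_scale),
            class = "analysis_config")
}

program_horizon <- function(config)
  max(vapply(config$trials, `[[`, numeric(1), "max_followup_days"))

trial_trajectories <- function(params, horizon)
  list(active = active_trajectory(params, horizon),
       placebo = placebo_trajectory(params, horizon))

#' Compute and export all formulation trajectories
#'
#' Builds the six occupancy trajectories (three formulations by two arms)
#' over the longest trial horizon; optionally writes a tidy CSV and a
#' figure of occupancy against time.
#'
#' @param config An \code{"analysis_config"}.
#' @param out_dir Optional directory for \code{trajectories.csv} and
#'   \code{trajectories.png}.
#' @return List with \code{trajectories} (named list of six) and
#'   \code{table} (the tidy data frame).
#' @export
run_trajectories <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  horizon <- program_horizon(config)
  trajs <- list()
  for (f in names(config$formulations)) {
    p <- config$formulations[[f]]
    trajs[[paste0(f, "_active")]] <- active_trajectory(p, horizon)
    trajs[[paste0(f, "_placebo")]] <- placebo_trajectory(p, horizon)
  }
  tab <- do.call(rbind, lapply(trajs, function(tr)
    data.frame(formulation = attr(tr, "formulation"), arm = attr(tr, "arm"),
               day = tr$day, plasma_equiv = tr$plasma_equiv,
               occupancy_pct = tr$occupancy_pct,
               rate_pct_per_day = tr$rate_pct_per_day)))
  rownames(tab) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE, quote = FALSE)
    grDevices::png(file.path(out_dir, "trajectories.png"),
                   width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_trajectory_set(trajs)
  }
  list(trajectories = trajs, table = tab)
}

plot_trajectory_set <- function(trajs) {
  cols <- c(oral = "grey40", lai_1m = "steelblue", lai_3m = "firebrick")
  first <- trajs[[1L]]
  graphics::plot(NULL, xlim = range(first$day), ylim = c(0, 100),
                 xlab = "Days since randomization",
                 ylab = "D2 receptor occupancy (%)",
                 main = "Receptor occupancy by formulation and arm")
  for (tr in trajs) {
    f <- attr(tr, "formulation")
    graphics::lines(tr$day, tr$occupancy_pct, col = cols[[f]],
                    lty = if (attr(tr, "arm") == "active") 1 else 2)
  }
  graphics::legend("topright", bty = "n",
                   legend = c(names(cols), "active", "placebo"),
                   col = c(cols, "black", "black"),
                   lty = c(1, 1, 1, 1, 2))
  invisible(trajs)
}

cb_summary <- function(fit) {
  list(group = unname(fit$coefficients[["group"]]),
       group_se = unname(fit$se[["group"]]),
       time = unname(fit$coefficients[["time"]]),
       time_se = unname(fit$se[["time"]]),
       interaction = unname(fit$coefficients[["group_time"]]),
       interaction_se = unname(fit$se[["group_time"]]),
       n_cases = fit$n_cases)
}

cox_summary <- function(fit, term) {
  hr <- hazard_ratio(fit, term)
  list(estimate = unname(hr$estimate), se = unname(hr$se),
       hr = unname(hr$hr), ci_lower = unname(hr$lower),
       ci_upper = unname(hr$upper))
}

pool_summary <- function(pool) {
  list(estimate = pool$pooled_estimate, se = pool$pooled_se,
       ci_lower = pool$ci_lower, ci_upper = pool$ci_upper,
       tau_squared = pool$tau_squared, p_value = pool$p_value, k = pool$k)
}

skipped <- function(reason) list(skipped = TRUE, reason = reason)

#' Run the four relapse analyses on trial data
#'
#' Executes, per trial and with meta-analytic pooling: (i) a group-only Cox
#' model per trial with a Wald-type formulation moderator test across
#' trials; (ii) the case-base smooth-in-time model per trial, random-effects
#' pooling of the group-by-time interaction across all trials, and an
#' oral-versus-injectable moderator contrast on the interaction; (iii) Cox
#' models with randomization group and the daily rate of occupancy change,
#' injectable trials only, pooled within formulation and across all
#' injectable trials; and (iv) Cox models with group and absolute daily
#' occupancy (per \code{occ_scale} percentage points), injectable trials
#' only, pooled likewise. Oral trials are excluded from (iii) and (iv)
#' because oral occupancy collapses too quickly for time-varying analyses.
#' Every analysis key is always present, either populated or flagged
#' skipped with a reason.
#'
#' @param config An \code{"analysis_config"}.
#' @param data Patient-level records (data frame or path to a CSV written
#'   by [write_subjects_csv()]), or \code{NULL} to simulate the program
#'   from the configuration.
#' @return A \code{"relapse_report"} nested list (serializable with
#'   [write_report_json()]) with elements \code{meta}, \code{group_effect},
#'   \code{time_interaction}, \code{occupancy_rate_effect},
#'   \code{occupancy_effect}.
#' @export
run_full_analysis <- function(config, data = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  simulated <- is.null(data)
  if (simulated) {
    data <- simulate_program(config$trials, config$hazard, seed = config$seed,
                             formulations = config$formulations)
  } else if (is.character(data)) {
    data <- read_subjects_csv(data)
  }
  designs <- config$trials
  ids <- vapply(designs, `[[`, character(1), "trial_id")
  forms <- vapply(designs, `[[`, character(1), "formulation")
  is_lai <- forms != "oral"
  by_trial <- split(data, factor(data$trial_id, levels = ids))

  fit_trial <- function(id, covs) {
    d <- designs[[match(id, ids)]]
    recs <- by_trial[[id]]
    if (is.null(recs) || nrow(recs) == 0L) return(skipped("no records"))
    if (length(unique(recs$arm)) < 2L) return(skipped("single-arm trial"))
    if (sum(recs$event) < 1L) return(skipped("no events"))
    trajs <- trial_trajectories(config$formulations[[d$formulation]],
                                d$max_followup_days)
    tab <- build_counting_process(recs, trajs, covariates = covs)
    tryCatch(fit_cox_tv(tab, covariates = covs, occ_scale = config$occ_scale),
             error = function(e) skipped(conditionMessage(e)))
  }
  ok <- function(x) !is.list(x) || is.null(x$skipped)
  trial_head <- function(id) {
    recs <- by_trial[[id]]
    list(trial_id = id, formulation = forms[[match(id, ids)]],
         n = if (is.null(recs)) 0L else nrow(recs),
         n_events = if (is.null(recs)) 0L else sum(recs$event))
  }

  ## (i) formulation effect: group-only Cox per trial + moderator test
  fits_i <- lapply(ids, fit_trial, covs = "group")
  names(fits_i) <- ids
  good_i <- vapply(fits_i, ok, logical(1))
  per_trial_i <- lapply(ids, function(id) {
    f <- fits_i[[id]]
    c(trial_head(id), if (ok(f)) cox_summary(f, "group") else f)
  })
  names(per_trial_i) <- ids
  mod_i <- if (sum(good_i) >= 2L && length(unique(forms[good_i])) >= 2L) {
    mt <- wald_moderator_test(fits_i[good_i], forms[good_i])
    list(Q = mt$Q, df = mt$df, p_value = mt$p_value, pairwise = mt$pairwise)
  } else skipped("need >= 2 trials spanning >= 2 formulations")
  analysis_i <- list(per_trial = per_trial_i, moderator_test = mod_i)

  ## (ii) time-varying hazard ratio via case-base
  cb_seeds <- (config$seed + 7919L * seq_along(ids)) %% .Machine$integer.max
  fits_ii <- lapply(seq_along(ids), function(i) {
    recs <- by_trial[[ids[i]]]
    if (is.null(recs) || sum(recs$event) < 1L) return(skipped("no events"))
    tryCatch({
      sm <- sample_base_series(recs, base_ratio = config$base_ratio,
                               seed = cb_seeds[i])
      fit_casebase(sm, include_interaction = TRUE)
    }, error = function(e) skipped(conditionMessage(e)))
  })
  names(fits_ii) <- ids
  good_ii <- vapply(fits_ii, ok, logical(1))
  per_trial_ii <- lapply(ids, function(id) {
    f <- fits_ii[[id]]
    c(trial_head(id), if (ok(f)) cb_summary(f) else f)
  })
  names(per_trial_ii) <- ids
  analysis_ii <- if (sum(good_ii) >= 2L) {
    pooled <- pool_interactions(fits_ii[good_ii],
                                moderator = ifelse(is_lai[good_ii], "lai", "oral"))
    list(per_trial = per_trial_ii,
         pooled_interaction = pool_summary(pooled),
         oral_vs_lai =
           if (!is.null(pooled$moderator_test))
             list(Q = pooled$moderator_test$Q, df = pooled$moderator_test$df,
                  p_value = pooled$moderator_test$p_value)
           else skipped("both oral and injectable fits required"))
  } else {
    list(per_trial = per_trial_ii,
         pooled_interaction = skipped("fewer than two usable trials"),
         oral_vs_lai = skipped("fewer than two usable trials"))
  }

  ## (iii)/(iv): occupancy-based analyses on injectable trials only
  occ_analysis <- function(covs, term) {
    lai_ids <- ids[is_lai]
    fits <- lapply(lai_ids, fit_trial, covs = covs)
    names(fits) <- lai_ids
    good <- vapply(fits, ok, logical(1))
    per_trial <- lapply(lai_ids, function(id) {
      f <- fits[[id]]
      c(trial_head(id), if (ok(f)) cox_summary(f, term) else f)
    })
    names(per_trial) <- lai_ids
    pools <- list()
    lai_forms <- forms[is_lai]
    for (f in unique(lai_forms)) {
      sel <- good & lai_forms == f
      pools[[f]] <- if (sum(sel) >= 1L) {
        est <- vapply(fits[sel], function(x) stats::coef(x)[[term]], numeric(1))
        ses <- vapply(fits[sel], function(x) x$se[[term]], numeric(1))
        pool_summary(pool_random_effects(est, ses))
      } else skipped("no usable trials for this formulation")
    }
    pools$lai_combined <- if (sum(good) >= 1L) {
      est <- vapply(fits[good], function(x) stats::coef(x)[[term]], numeric(1))
      ses <- vapply(fits[good], function(x) x$se[[term]], numeric(1))
      pool_summary(pool_random_effects(est, ses))
    } else skipped("no usable injectable trials")
    list(per_trial = per_trial, pooled = pools,
         excluded_trials = as.list(ids[!is_lai]))
  }
  analysis_iii <- if (any(is_lai)) occ_analysis(c("group", "rate"), "rate")
                  else skipped("no injectable trials")
  analysis_iv <- if (any(is_lai)) occ_analysis(c("group", "occupancy"), "occupancy")
                 else skipped("no injectable trials")

  structure(list(
    meta = list(schema_version = "1.0",
                seed = config$seed,
                simulated = simulated,
                n_subjects = nrow(data),
                n_events = sum(data$event),
                occ_scale = config$occ_scale,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    group_effect = analysis_i,
    time_interaction = analysis_ii,
    occupancy_rate_effect = analysis_iii,
    occupancy_effect = analysis_iv),
    class = "relapse_report")
}

#' @export
print.relapse_report <- function(x, ...) {
  cat(sprintf("Relapse analysis report (%d subjects, %d events%s)\n",
              x$meta$n_subjects, x$meta$n_events,
              if (isTRUE(x$meta$simulated)) ", simulated" else ""))
  show_pool <- function(label, p) {
    if (!is.null(p$skipped)) cat(sprintf("  %s: skipped (%s)\n", label, p$reason))
    else cat(sprintf("  %s: %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
                     label, p$estimate, p$se, p$ci_lower, p$ci_upper, p$p_value))
  }
  cat("Per-trial treatment effect (log HR):\n")
  for (tr in x$group_effect$per_trial) {
    if (!is.null(tr$skipped))
      cat(sprintf("  %s: skipped (%s)\n", tr$trial_id, tr$reason))
    else
      cat(sprintf("  %-9s (%s): %.3f (SE %.3f), HR %.3f\n", tr$trial_id,
                  tr$formulation, tr$estimate, tr$se, tr$hr))
  }
  mt <- x$group_effect$moderator_test
  if (is.null(mt$skipped))
    cat(sprintf("Formulation moderator test: Q = %.3f (df %d), p = %.3g\n",
                mt$Q, mt$df, mt$p_value))
  show_pool("Pooled group x time interaction", x$time_interaction$pooled_interaction)
  if (is.null(x$occupancy_rate_effect$skipped))
    show_pool("Pooled occupancy-rate coefficient (LAI combined)",
              x$occupancy_rate_effect$pooled$lai_combined)
  if (is.null(x$occupancy_effect$skipped))
    show_pool(sprintf("Pooled occupancy coefficient per %g pts (LAI combined)",
                      x$meta$occ_scale),
              x$occupancy_effect$pooled$lai_combined)
  invisible(x)
}

#' Serialize a report (or sensitivity set) to JSON
#'
#' @param report A \code{"relapse_report"} or the result of
#'   [run_sensitivity()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "relapse_report")) x <- unclass(x)
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Sensitivity analysis over trough occupancy assumptions
#'
#' Repeats the full analysis for each trough occupancy in the grid,
#' regenerating every formulation trajectory at that trough. When
#' \code{data} is \code{NULL} the program is simulated once under the
#' configured (baseline) formulations and the same records are re-analysed
#' at each trough, so the trough assumption affects only the analysis
#' covariates, never the event times.
#'
#' @param config An \code{"analysis_config"} whose
#'   \code{trough_occupancy_grid} has at least two values.
#' @param data Optional patient records (data frame or CSV path).
#' @return List with \code{reports} (one \code{"relapse_report"} per trough)
#'   and \code{comparison}, a data frame of the pooled injectable-trial
#'   occupancy, rate and interaction coefficients per trough.
#' @export
run_sensitivity <- function(config, data = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  grid <- config$trough_occupancy_grid
  if (length(grid) < 2L)
    stop("'trough_occupancy_grid' needs at least two values", call. = FALSE)
  if (is.null(data)) {
    data <- simulate_program(config$trials, config$hazard, seed = config$seed,
                             formulations = config$formulations)
  } else if (is.character(data)) {
    data <- read_subjects_csv(data)
  }
  reports <- list()
  rows <- list()
  for (trough in grid) {
    cfg <- config
    cfg$formulations <- lapply(config$formulations, function(p) {
      p$trough_occupancy_pct <- trough
      stopifnot(trough > 0, trough < p$max_occupancy_pct)
      p
    })
    rep <- run_full_analysis(cfg, data = data)
    key <- sprintf("trough_%g", trough)
    reports[[key]] <- rep
    get_est <- function(p) if (is.null(p$skipped)) p$estimate else NA_real_
    rows[[key]] <- data.frame(
      trough_occupancy_pct = trough,
      occupancy_coef = get_est(rep$occupancy_effect$pooled$lai_combined),
      rate_coef = get_est(rep$occupancy_rate_effect$pooled$lai_combined),
      interaction_coef = get_est(rep$time_interaction$pooled_interaction))
  }
  comparison <- do.call(rbind, rows)
  rownames(comparison) <- NULL
  list(reports = reports, comparison = comparison)
}
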