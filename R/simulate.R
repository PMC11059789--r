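#' Trial design for the synthetic discontinuation program
#'
#' One parallel-group, placebo-controlled discontinuation trial: stabilized
#' patients are randomized at day 0 to continue active treatment or switch
#' to placebo, and followed to relapse, dropout, or the administrative
#' horizon.
#'
#' @param trial_id Label for the trial.
#' @param formulation One of \code{"oral"}, \code{"lai_1m"}, \code{"lai_3m"}.
#' @param n_active,n_placebo Arm sizes (their sum must be at least 2).
#' @param max_followup_days Administrative censoring horizon in days.
#' @param dropout_hazard_per_day Rate of the independent exponential
#'   dropout (non-relapse censoring) process; 0 disables dropout.
#' @return A \code{"trial_design"} object.
#' @export
trial_design <- function(trial_id, formulation, n_active, n_placebo,
                         max_followup_days,
                         dropout_hazard_per_day = 5e-4) {
  formulation <- match.arg(formulation, c("oral", "lai_1m", "lai_3m"))
  stopifnot(n_active >= 0, n_placebo >= 0, n_active + n_placebo >= 2,
            max_followup_days >= 1, dropout_hazard_per_day >= 0)
  structure(list(trial_id = as.character(trial_id), formulation = formulation,
                 n_active = as.integer(n_active),
                 n_placebo = as.integer(n_placebo),
                 max_followup_days = as.integer(max_followup_days),
                 dropout_hazard_per_day = dropout_hazard_per_day),
            class = "trial_design")
}

#' The default five-trial discontinuation program
#'
#' Arm sizes and follow-up horizons of the five paliperidone
#' discontinuation trials being emulated: one 3-monthly injectable trial
#' (159 active / 144 placebo), two 1-monthly injectable trials (164/170 and
#' 205/203) and two oral trials (105/102 and 65/71), 1388 participants in
#' all. Month horizons are converted at 30.4375 days/month and rounded:
#' 487 days for 16-month, 426 for 14-month and 365 for 12-month follow-up.
#'
#' @param dropout_hazard_per_day Shared dropout rate; the default yields
#'   roughly 15-20 percent non-relapse dropout over follow-up.
#' @return List of five [trial_design()] objects.
#' @export
default_trial_designs <- function(dropout_hazard_per_day = 5e-4) {
  list(
    trial_design("PSY-3012", "lai_3m", 159, 144, 487, dropout_hazard_per_day),
    trial_design("SCA-3004", "lai_1m", 164, 170, 487, dropout_hazard_per_day),
    trial_design("PSY-3001", "lai_1m", 205, 203, 487, dropout_hazard_per_day),
    trial_design("SCH-301",  "oral",   105, 102, 365, dropout_hazard_per_day),
    trial_design("SCH-3041", "oral",    65,  71, 426, dropout_hazard_per_day))
}

#' Generative hazard specification
#'
#' Ground truth for the simulator: a piecewise-constant daily relapse
#' hazard whose log-linear predictor mirrors the covariates of the
#' analyses —
#' \deqn{h(t) = h_0 \exp(\beta_g I_{active} + \beta_{occ} occ(t)/10 +
#'   \beta_{rate} rate(t) + \beta_{t \times g} I_{active} t).}
#'
#' @param baseline_hazard_per_day Baseline daily hazard \eqn{h_0 > 0}
#'   (applies at zero occupancy).
#' @param beta_group Log-hazard effect of active assignment.
#' @param beta_occ_per_10pct Log-hazard effect per 10 percentage points of
#'   receptor occupancy; the default -0.34 is a plausible protective scale
#'   used for parameter-recovery experiments.
#' @param beta_rate Log-hazard effect per percent/day of occupancy change.
#' @param beta_time_interaction_per_day Group-by-time log-hazard
#'   interaction, per day.
#' @return A \code{"hazard_spec"} object.
#' @export
hazard_spec <- function(baseline_hazard_per_day = 0.002,
                        beta_group = 0,
                        beta_occ_per_10pct = -0.34,
                        beta_rate = 0,
                        beta_time_interaction_per_day = 0) {
  stopifnot(baseline_hazard_per_day > 0,
            all(is.finite(c(beta_group, beta_occ_per_10pct, beta_rate,
                            beta_time_interaction_per_day))))
  structure(list(baseline_hazard_per_day = baseline_hazard_per_day,
                 beta_group = beta_group,
                 beta_occ_per_10pct = beta_occ_per_10pct,
                 beta_rate = beta_rate,
                 beta_time_interaction_per_day = beta_time_interaction_per_day),
            class = "hazard_spec")
}

#' Daily relapse hazard implied by a trajectory and hazard specification
#'
#' @param arm \code{"active"} or \code{"placebo"}.
#' @param day Integer day(s) within the trajectory grid; the returned
#'   hazard applies over the interval \code{(day, day + 1]}.
#' @param traj The arm's [active_trajectory()] or [placebo_trajectory()].
#' @param spec A [hazard_spec()].
#' @return Nonnegative per-day hazard, vectorised over \code{day}.
#' @export
daily_hazard <- function(arm, day, traj, spec) {
  arm <- match.arg(arm, c("active", "placebo"))
  stopifnot(inherits(traj, "occupancy_trajectory"), inherits(spec, "hazard_spec"))
  idx <- match(day, traj$day)
  if (anyNA(idx)) stop("'day' outside the trajectory grid", call. = FALSE)
  active <- as.numeric(arm == "active")
  lp <- spec$beta_group * active +
    spec$beta_occ_per_10pct * traj$occupancy_pct[idx] / 10 +
    spec$beta_rate * traj$rate_pct_per_day[idx] +
    spec$beta_time_interaction_per_day * active * day
  spec$baseline_hazard_per_day * exp(lp)
}

# Vectorised inverse-transform sampling for n subjects sharing a daily
# hazard sequence h[1..m] (h[d] applies over (d-1, d]). Relapse occurs in
# the first interval where the cumulative hazard exceeds -log U; dropout is
# an independent exponential rounded up to the end of its day; ties within
# a day resolve to relapse.
sim_arm_times <- function(n, hazard, dropout_rate, max_followup) {
  H <- cumsum(hazard)
  u <- stats::runif(n)
  relapse <- findInterval(-log(u), H) + 1L  # m+1 => no relapse in horizon
  dropout <- if (dropout_rate > 0) ceiling(stats::rexp(n, dropout_rate)) else
    rep(Inf, n)
  t_obs <- pmin(relapse, dropout, max_followup)
  event <- as.integer(relapse <= pmin(dropout, max_followup))
  data.frame(time_days = as.integer(t_obs), event = event)
}

#' Simulate a single participant
#'
#' Samples a relapse time by inverse-transform on the accumulated daily
#' hazard, an independent exponential dropout time, and applies
#' administrative censoring at the trial horizon; the observed time is the
#' minimum and the event flag records whether relapse came first. Uses the
#' current RNG state.
#'
#' @inheritParams daily_hazard
#' @param design A [trial_design()].
#' @return One-row data frame with \code{arm}, \code{time_days},
#'   \code{event}.
#' @export
#' @examples
#' set.seed(1)
#' tr <- placebo_trajectory(default_formulations()$lai_1m, 487)
#' simulate_subject("placebo", default_trial_designs()[[2]], tr, hazard_spec())
simulate_subject <- function(arm, design, traj, spec) {
  arm <- match.arg(arm, c("active", "placebo"))
  stopifnot(inherits(design, "trial_design"))
  m <- design$max_followup_days
  if (max(traj$day) < m)
    stop("trajectory horizon shorter than the trial follow-up", call. = FALSE)
  h <- daily_hazard(arm, 0:(m - 1L), traj, spec)
  out <- sim_arm_times(1L, h, design$dropout_hazard_per_day, m)
  cbind(data.frame(arm = arm), out)
}

#' Simulate one discontinuation trial
#'
#' Generates \code{n_active + n_placebo} participant records whose relapse
#' hazards are driven by the formulation's active and placebo occupancy
#' trajectories.
#'
#' @param design A [trial_design()].
#' @param params The [formulation_params()] for the trial's formulation.
#' @param spec A [hazard_spec()].
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with columns \code{subject_id}, \code{trial_id},
#'   \code{formulation}, \code{arm}, \code{time_days}, \code{event}.
#' @export
simulate_trial <- function(design, params, spec = hazard_spec(), seed = NULL) {
  stopifnot(inherits(design, "trial_design"),
            inherits(params, "formulation_params"),
            inherits(spec, "hazard_spec"))
  if (params$name != design$formulation)
    stop("formulation parameters do not match the trial design", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- design$max_followup_days
  days <- 0:(m - 1L)
  rows <- list()
  for (arm in c("active", "placebo")) {
    n <- if (arm == "active") design$n_active else design$n_placebo
    if (n == 0L) next
    traj <- if (arm == "active") active_trajectory(params, m) else
      placebo_trajectory(params, m)
    h <- daily_hazard(arm, days, traj, spec)
    out <- sim_arm_times(n, h, design$dropout_hazard_per_day, m)
    rows[[arm]] <- cbind(data.frame(arm = arm), out)
  }
  res <- do.call(rbind, rows)
  data.frame(subject_id = paste0(design$trial_id, "-",
                                 sprintf("%04d", seq_len(nrow(res)))),
             trial_id = design$trial_id,
             formulation = design$formulation,
             arm = res$arm, time_days = res$time_days, event = res$event,
             row.names = NULL)
}

#' Simulate the full multi-trial program
#'
#' Runs [simulate_trial()] for each design, with per-trial seeds derived
#' deterministically from the master seed, and concatenates the records.
#'
#' @param designs List of [trial_design()] objects with distinct
#'   \code{trial_id}s.
#' @param spec A [hazard_spec()] shared across trials.
#' @param seed Master integer seed.
#' @param formulations Named list of [formulation_params()]; defaults to
#'   [default_formulations()].
#' @return Data frame of participant records across all trials.
#' @export
#' @examples
#' dat <- simulate_program(default_trial_designs(), hazard_spec(), seed = 1)
#' nrow(dat)  # 1388
simulate_program <- function(designs, spec = hazard_spec(), seed = NULL,
                             formulations = default_formulations()) {
  stopifnot(length(designs) >= 1L)
  ids <- vapply(designs, function(d) d$trial_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate trial_id in 'designs'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max, length(designs))
  out <- vector("list", length(designs))
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    out[[i]] <- simulate_trial(d, formulations[[d$formulation]], spec,
                               seed = trial_seeds[i])
  }
  do.call(rbind, out)
}

#' Write participant records to CSV
#'
#' @param subjects Data frame from [simulate_trial()] or
#'   [simulate_program()].
#' @param path Output file path.
#' @return \code{path}, invisibly. Header:
#'   subject_id, trial_id, formulation, arm, time_days, event.
#' @export
write_subjects_csv <- function(subjects, path) {
  cols <- c("subject_id", "trial_id", "formulation", "arm", "time_days", "event")
  stopifnot(all(cols %in% names(subjects)))
  utils::write.csv(subjects[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read participant records from CSV
#'
#' @param path CSV written by [write_subjects_csv()].
#' @return Data frame of participant records.
#' @export
read_subjects_csv <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("subject_id", "trial_id", "formulation", "arm", "time_days", "event")
  miss <- setdiff(cols, names(dat))
  if (length(miss))
    stop("patient CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  dat[cols]
}
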