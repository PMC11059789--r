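#' Receptor occupancy from a plasma dose-equivalent
#'
#' Saturating Emax dose-response:
#' \code{occupancy = max_occupancy * dose / (dose + ED50)}. Strictly
#' increasing and concave in dose, bounded above by the maximal occupancy.
#'
#' @param dose Plasma dose-equivalent in mg/day (vectorised, nonnegative).
#' @param params A [formulation_params()] object.
#' @return Occupancy in percent.
#' @export
#' @examples
#' p <- default_formulations()$lai_1m
#' occupancy_from_dose(2.38, p)  # 50: dose equals ED50
occupancy_from_dose <- function(dose, params) {
  stopifnot(inherits(params, "formulation_params"), is.numeric(dose))
  if (any(dose < 0)) stop("'dose' must be nonnegative", call. = FALSE)
  params$max_occupancy_pct * dose / (dose + params$ed50)
}

#' Plasma dose-equivalent producing a given occupancy
#'
#' Algebraic inversion of the Emax relation:
#' \code{dose = ED50 * occ / (max_occupancy - occ)}. Used to convert the
#' assumed trough occupancy at randomization into a trough plasma level.
#'
#' @param occ_pct Occupancy in percent (vectorised), each value in
#'   \code{[0, max_occupancy_pct)}.
#' @inheritParams occupancy_from_dose
#' @return Dose-equivalent in mg/day.
#' @export
#' @examples
#' dose_from_occupancy(80, default_formulations()$lai_1m)  # 9.52
dose_from_occupancy <- function(occ_pct, params) {
  stopifnot(inherits(params, "formulation_params"), is.numeric(occ_pct))
  if (any(occ_pct < 0)) stop("'occ_pct' must be nonnegative", call. = FALSE)
  if (any(occ_pct >= params$max_occupancy_pct))
    stop("occupancy at or above the maximal occupancy is unreachable at finite dose",
         call. = FALSE)
  params$ed50 * occ_pct / (params$max_occupancy_pct - occ_pct)
}

#' Steady-state peak plasma level of an injectable formulation
#'
#' At steady state the plasma level decays first-order from the
#' post-injection peak back to the trough over the remainder of the dosing
#' interval, so
#' \code{peak = trough_plasma * 2^((interval - t_peak) / half_life)}.
#'
#' @inheritParams occupancy_from_dose
#' @return Peak plasma dose-equivalent in mg/day.
#' @export
#' @examples
#' fp <- default_formulations()
#' # peak occupancies print as 86% (1-monthly) and 85% (3-monthly)
#' round(occupancy_from_dose(steady_state_peak(fp$lai_1m), fp$lai_1m))
#' round(occupancy_from_dose(steady_state_peak(fp$lai_3m), fp$lai_3m))
steady_state_peak <- function(params) {
  stopifnot(inherits(params, "formulation_params"))
  if (!is_injectable(params))
    stop("steady-state peak is defined for injectable formulations only",
         call. = FALSE)
  trough <- dose_from_occupancy(params$trough_occupancy_pct, params)
  decay_days <- params$dosing_interval_days - params$time_to_peak_days
  trough * 2^(decay_days / params$half_life_days)
}

new_trajectory <- function(params, arm, day, plasma) {
  occ <- occupancy_from_dose(plasma, params)
  structure(
    data.frame(day = day,
               plasma_equiv = plasma,
               occupancy_pct = occ,
               rate_pct_per_day = forward_rate(occ)),
    class = c("occupancy_trajectory", "data.frame"),
    formulation = params$name,
    arm = arm,
    params = params)
}

forward_rate <- function(occ) {
  n <- length(occ)
  if (n < 2L) stop("a trajectory needs at least 2 grid points", call. = FALSE)
  d <- diff(occ)
  c(d, d[n - 1L])  # last grid point carries the last defined difference
}

#' Active-arm plasma and occupancy trajectory
#'
#' For injectables, plasma follows a periodic sawtooth at steady state: an
#' injection is administered at randomization (day 0) with plasma at the
#' trough, plasma rises linearly to the peak over \code{time_to_peak_days},
#' then decays first-order back to the trough at the next injection.
#' Occupancy is the pointwise Emax transform of plasma. Oral active
#' treatment is modelled as a constant daily plasma-equivalent at the
#' trough-derived level.
#'
#' @inheritParams occupancy_from_dose
#' @param horizon_days Length of the daily grid; the trajectory covers
#'   integer days \code{0:horizon_days} with day 0 = randomization.
#' @return An \code{"occupancy_trajectory"} data frame with columns
#'   \code{day}, \code{plasma_equiv}, \code{occupancy_pct},
#'   \code{rate_pct_per_day} (forward first difference of occupancy,
#'   assigned to the start day of each one-day interval).
#' @export
#' @examples
#' tr <- active_trajectory(default_formulations()$lai_1m, 60)
#' range(round(tr$occupancy_pct))  # 80 to 86
active_trajectory <- function(params, horizon_days) {
  stopifnot(inherits(params, "formulation_params"),
            length(horizon_days) == 1L, horizon_days >= 1)
  day <- 0:horizon_days
  trough <- dose_from_occupancy(params$trough_occupancy_pct, params)
  if (!is_injectable(params)) {
    plasma <- rep(trough, length(day))
  } else {
    peak <- steady_state_peak(params)
    tau <- day %% params$dosing_interval_days
    tp <- params$time_to_peak_days
    plasma <- ifelse(tau <= tp,
                     trough + (peak - trough) * tau / tp,
                     peak * 2^(-(tau - tp) / params$half_life_days))
  }
  new_trajectory(params, "active", day, plasma)
}

#' Placebo-arm plasma and occupancy trajectory
#'
#' After randomization to placebo, plasma decays first-order from the
#' trough level: \code{plasma(t) = trough_plasma * 2^(-t / half_life)}.
#' Occupancy (the Emax transform) is strictly decreasing but decays more
#' slowly than plasma because the Emax curve is concave.
#'
#' @inheritParams active_trajectory
#' @return An \code{"occupancy_trajectory"} data frame; see
#'   [active_trajectory()].
#' @export
#' @examples
#' tr <- placebo_trajectory(default_formulations()$lai_1m, 365)
#' tr$occupancy_pct[tr$day == 0]   # 80, the trough assumption
#' round(tr$occupancy_pct[tr$day == 37], 1)  # one half-life later
placebo_trajectory <- function(params, horizon_days) {
  stopifnot(inherits(params, "formulation_params"),
            length(horizon_days) == 1L, horizon_days >= 1)
  day <- 0:horizon_days
  trough <- dose_from_occupancy(params$trough_occupancy_pct, params)
  plasma <- trough * 2^(-day / params$half_life_days)
  new_trajectory(params, "placebo", day, plasma)
}

#' Daily rate of change of receptor occupancy
#'
#' The first derivative of the occupancy series, taken as the forward
#' first difference assigned to the start day of each one-day interval;
#' the final grid point carries the last defined difference.
#'
#' @param traj An \code{"occupancy_trajectory"}.
#' @return Numeric vector, percent per day, aligned with \code{traj$day}.
#' @export
occupancy_rate <- function(traj) {
  stopifnot(inherits(traj, "occupancy_trajectory"))
  forward_rate(traj$occupancy_pct)
}

#' @export
print.occupancy_trajectory <- function(x, ...) {
  cat(sprintf("Occupancy trajectory: %s, %s arm, days 0-%d\n",
              attr(x, "formulation"), attr(x, "arm"), max(x$day)))
  cat(sprintf("  occupancy %.1f%% to %.1f%%\n",
              min(x$occupancy_pct), max(x$occupancy_pct)))
  NextMethod()
}

#' @export
plot.occupancy_trajectory <- function(x, ...,
                                      ylab = "D2 receptor occupancy (%)",
                                      xlab = "Days since randomization") {
  graphics::plot(x$day, x$occupancy_pct, type = "l",
                 ylim = c(0, attr(x, "params")$max_occupancy_pct),
                 xlab = xlab, ylab = ylab,
                 main = sprintf("%s (%s arm)", attr(x, "formulation"),
                                attr(x, "arm")), ...)
  invisible(x)
}

#' Export trajectories to a tidy CSV
#'
#' @param trajectories A list of \code{"occupancy_trajectory"} objects.
#' @param path Output file path.
#' @return \code{path}, invisibly. Columns: formulation, arm, day,
#'   plasma_equiv, occupancy_pct, rate_pct_per_day.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  if (inherits(trajectories, "occupancy_trajectory"))
    trajectories <- list(trajectories)
  tidy <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(formulation = attr(tr, "formulation"), arm = attr(tr, "arm"),
               day = tr$day, plasma_equiv = tr$plasma_equiv,
               occupancy_pct = tr$occupancy_pct,
               rate_pct_per_day = tr$rate_pct_per_day)
  }))
  utils::write.csv(tidy, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
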