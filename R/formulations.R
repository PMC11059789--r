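#' Formulation pharmacokinetic/pharmacodynamic parameters
#'
#' Bundles the constants that determine a paliperidone formulation's plasma
#' and D2 receptor-occupancy trajectory: the Emax median effective dose
#' (ED50), the apparent elimination half-life, and for long-acting
#' injectables the time from injection to peak plasma level and the dosing
#' interval. Occupancy follows the saturating Emax relation
#' \code{occupancy = max_occupancy * dose / (dose + ED50)}, so the trough
#' occupancy (the level at a dosing trough, assumed to hold at
#' randomization) fixes the trough plasma-equivalent level.
#'
#' @param name One of \code{"oral"}, \code{"lai_1m"}, \code{"lai_3m"}.
#' @param ed50 Median effective dose in mg/day plasma-dose-equivalents
#'   (the dose giving half-maximal occupancy).
#' @param half_life_days Elimination half-life in days. For the oral
#'   formulation this is the post-discontinuation washout half-life used by
#'   the placebo arm (oral active treatment is modelled as a constant daily
#'   level).
#' @param time_to_peak_days Days from injection to peak plasma level;
#'   \code{NA} for oral.
#' @param dosing_interval_days Days between injections; \code{NA} for oral.
#' @param trough_occupancy_pct Receptor occupancy (percent) at the dosing
#'   trough, in (0, \code{max_occupancy_pct}).
#' @param max_occupancy_pct Asymptotic maximal occupancy, percent.
#'
#' @return An object of class \code{"formulation_params"}.
#' @seealso [default_formulations()], [active_trajectory()],
#'   [placebo_trajectory()]
#' @export
#' @examples
#' p <- formulation_params("lai_1m", ed50 = 2.38, half_life_days = 37,
#'                         time_to_peak_days = 5, dosing_interval_days = 30,
#'                         trough_occupancy_pct = 80)
#' dose_from_occupancy(80, p)  # trough plasma-equivalent, 9.52 mg/day
formulation_params <- function(name,
                               ed50,
                               half_life_days,
                               time_to_peak_days = NA_real_,
                               dosing_interval_days = NA_real_,
                               trough_occupancy_pct = 80,
                               max_occupancy_pct = 100) {
  name <- match.arg(name, c("oral", "lai_1m", "lai_3m"))
  stopifnot(is.numeric(ed50), length(ed50) == 1L, is.finite(ed50),
            is.numeric(half_life_days), length(half_life_days) == 1L,
            is.finite(half_life_days))
  if (ed50 <= 0) stop("'ed50' must be positive", call. = FALSE)
  if (half_life_days <= 0) stop("'half_life_days' must be positive", call. = FALSE)
  if (!(max_occupancy_pct > 0 && max_occupancy_pct <= 100))
    stop("'max_occupancy_pct' must lie in (0, 100]", call. = FALSE)
  if (!(trough_occupancy_pct > 0 && trough_occupancy_pct < max_occupancy_pct))
    stop("'trough_occupancy_pct' must lie strictly between 0 and 'max_occupancy_pct'",
         call. = FALSE)
  injectable <- name != "oral"
  if (injectable) {
    if (!is.finite(time_to_peak_days) || !is.finite(dosing_interval_days))
      stop("injectable formulations need 'time_to_peak_days' and 'dosing_interval_days'",
           call. = FALSE)
    if (!(time_to_peak_days > 0 && time_to_peak_days < dosing_interval_days))
      stop("need 0 < time_to_peak_days < dosing_interval_days", call. = FALSE)
  }
  structure(
    list(name = name,
         ed50 = ed50,
         half_life_days = half_life_days,
         time_to_peak_days = if (injectable) time_to_peak_days else NA_real_,
         dosing_interval_days = if (injectable) dosing_interval_days else NA_real_,
         trough_occupancy_pct = trough_occupancy_pct,
         max_occupancy_pct = max_occupancy_pct),
    class = "formulation_params")
}

#' Default formulation profiles
#'
#' The three study formulations with their published pharmacokinetic
#' constants: ED50 2.38 mg/day for all; half-lives of 37 days (1-monthly
#' injectable), 111.5 days (3-monthly injectable) and a 1-day washout for
#' oral; times to peak of 5 and 28 days and dosing intervals of 30 and 90
#' days for the injectables. Trough occupancy defaults to 80 percent, the
#' level assumed at randomization after stabilization; pass 75 or 85 for the
#' sensitivity profiles.
#'
#' @param trough_occupancy_pct Trough occupancy (percent) shared by all
#'   three profiles.
#' @param oral_washout_half_life_days Washout half-life (days) used for the
#'   placebo arm of oral trials.
#' @return Named list of [formulation_params()] objects
#'   (\code{oral}, \code{lai_1m}, \code{lai_3m}).
#' @export
#' @examples
#' fp <- default_formulations()
#' round(steady_state_peak(fp$lai_1m), 2)
default_formulations <- function(trough_occupancy_pct = 80,
                                 oral_washout_half_life_days = 1) {
  list(
    oral = formulation_params("oral", ed50 = 2.38,
                              half_life_days = oral_washout_half_life_days,
                              trough_occupancy_pct = trough_occupancy_pct),
    lai_1m = formulation_params("lai_1m", ed50 = 2.38, half_life_days = 37,
                                time_to_peak_days = 5,
                                dosing_interval_days = 30,
                                trough_occupancy_pct = trough_occupancy_pct),
    lai_3m = formulation_params("lai_3m", ed50 = 2.38, half_life_days = 111.5,
                                time_to_peak_days = 28,
                                dosing_interval_days = 90,
                                trough_occupancy_pct = trough_occupancy_pct))
}

#' @export
print.formulation_params <- function(x, ...) {
  cat("Formulation parameters:", x$name, "\n")
  cat(sprintf("  ED50 %.3g mg/day; half-life %.4g d; trough occupancy %.3g%% (max %.3g%%)\n",
              x$ed50, x$half_life_days, x$trough_occupancy_pct, x$max_occupancy_pct))
  if (x$name != "oral")
    cat(sprintf("  time to peak %.3g d; dosing interval %.3g d\n",
                x$time_to_peak_days, x$dosing_interval_days))
  invisible(x)
}

is_injectable <- function(params) params$name != "oral"

as_formulation_params <- function(x, name) {
  if (inherits(x, "formulation_params")) return(x)
  # config block with the documented keys
  need <- c("ed50_mg_per_day", "half_life_days", "trough_occupancy_pct")
  if (!all(need %in% names(x)))
    stop("formulation block '", name, "' is missing keys: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  formulation_params(
    name = name,
    ed50 = x$ed50_mg_per_day,
    half_life_days = x$half_life_days,
    time_to_peak_days = if (is.null(x$time_to_peak_days)) NA_real_ else x$time_to_peak_days,
    dosing_interval_days = if (is.null(x$dosing_interval_days)) NA_real_ else x$dosing_interval_days,
    trough_occupancy_pct = x$trough_occupancy_pct,
    max_occupancy_pct = if (is.null(x$max_occupancy_pct)) 100 else x$max_occupancy_pct)
}
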