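#' Build a counting-process table with time-varying occupancy covariates
#'
#' Expands participant records into half-open daily risk intervals
#' \code{(d, d+1]} carrying that day's covariate values from the arm's
#' occupancy trajectory (left-aligned: the value on \code{(d, d+1]} is the
#' trajectory value at day \code{d}), then losslessly merges consecutive
#' days on which all covariate values are equal. Total exposure time per
#' subject is preserved exactly and the event indicator sits on the final
#' interval only.
#'
#' @param subjects Data frame with columns \code{subject_id}, \code{arm},
#'   \code{time_days}, \code{event} (as produced by [simulate_trial()]).
#' @param trajectories Named list with elements \code{active} and
#'   \code{placebo}, each an \code{"occupancy_trajectory"} covering the
#'   longest follow-up.
#' @param covariates Character subset of
#'   \code{c("group", "occupancy", "rate")} to carry.
#' @return A \code{"counting_process"} data frame with columns
#'   \code{subject_id}, \code{start_day}, \code{stop_day}, \code{event},
#'   \code{group} (0 placebo, 1 active) and, when requested,
#'   \code{occupancy_pct} and \code{rate_pct_per_day}.
#' @export
build_counting_process <- function(subjects, trajectories,
                                   covariates = c("group", "occupancy", "rate")) {
  covariates <- match.arg(covariates, several.ok = TRUE)
  stopifnot(all(c("subject_id", "arm", "time_days", "event") %in% names(subjects)))
  need_traj <- any(c("occupancy", "rate") %in% covariates)
  if (need_traj) {
    stopifnot(is.list(trajectories),
              all(c("active", "placebo") %in% names(trajectories)))
    horizon <- vapply(trajectories, function(tr) max(tr$day), numeric(1))
    if (max(subjects$time_days) > min(horizon[c("active", "placebo")]))
      stop("subject follow-up exceeds the trajectory horizon", call. = FALSE)
  }
  t_i <- as.integer(subjects$time_days)
  stopifnot(all(t_i >= 1L))
  idx <- rep.int(seq_len(nrow(subjects)), t_i)
  day <- sequence(t_i) - 1L              # covariate day d for interval (d, d+1]
  arm <- subjects$arm[idx]
  group <- as.numeric(arm == "active")
  cov <- list(group = group)
  if (need_traj) {
    occ_by_arm <- lapply(trajectories, `[[`, "occupancy_pct")
    rate_by_arm <- lapply(trajectories, `[[`, "rate_pct_per_day")
    pos <- day + 1L
    if ("occupancy" %in% covariates)
      cov$occupancy_pct <- ifelse(group == 1, occ_by_arm$active[pos],
                                  occ_by_arm$placebo[pos])
    if ("rate" %in% covariates)
      cov$rate_pct_per_day <- ifelse(group == 1, rate_by_arm$active[pos],
                                     rate_by_arm$placebo[pos])
  }
  # merge consecutive days with identical covariate values
  new_subject <- day == 0L
  changed <- new_subject
  for (v in cov) changed <- changed | c(TRUE, v[-1L] != v[-length(v)])
  grp <- cumsum(changed)
  first <- which(changed)
  last <- c(first[-1L] - 1L, length(day))
  out <- data.frame(subject_id = subjects$subject_id[idx][first],
                    start_day = day[first],
                    stop_day = day[last] + 1L,
                    event = 0L)
  is_last_row <- c(diff(idx[first]) != 0L, TRUE)
  out$event[is_last_row] <- as.integer(subjects$event)
  out$group <- cov$group[first]
  if (!is.null(cov$occupancy_pct)) out$occupancy_pct <- cov$occupancy_pct[first]
  if (!is.null(cov$rate_pct_per_day))
    out$rate_pct_per_day <- cov$rate_pct_per_day[first]
  class(out) <- c("counting_process", "data.frame")
  out
}

#' Fit a Cox proportional hazards model on counting-process data
#'
#' Maximizes the start-stop partial likelihood (Efron approximation for
#' tied event times) via [survival::coxph()], with strict convergence
#' control and explicit diagnostics: absence of events, non-convergence and
#' apparent infinite coefficients (perfect separation) raise errors rather
#' than returning a silent result. The occupancy covariate is entered per
#' \code{occ_scale} percentage points (default 10), so its coefficient is a
#' log hazard ratio per 10 points of occupancy.
#'
#' @param table A \code{"counting_process"} data frame from
#'   [build_counting_process()].
#' @param covariates Character subset of
#'   \code{c("group", "occupancy", "rate")} naming the model terms.
#' @param occ_scale Percentage points of occupancy per coefficient unit.
#' @return A \code{"cox_tv_fit"} with elements \code{coefficients},
#'   \code{se}, \code{vcov}, \code{loglik}, \code{n_events}, \code{n},
#'   \code{converged}, \code{n_iter}.
#' @export
fit_cox_tv <- function(table, covariates = c("group"), occ_scale = 10) {
  stopifnot(is.data.frame(table),
            all(c("start_day", "stop_day", "event") %in% names(table)))
  covariates <- match.arg(covariates, c("group", "occupancy", "rate"),
                          several.ok = TRUE)
  if (sum(table$event) < 1L) stop("no events in the data", call. = FALSE)
  dat <- data.frame(start = table$start_day, stop = table$stop_day,
                    event = table$event)
  terms <- character(0)
  if ("group" %in% covariates) {
    dat$group <- table$group
    terms <- c(terms, "group")
  }
  if ("occupancy" %in% covariates) {
    if (is.null(table$occupancy_pct))
      stop("table lacks an 'occupancy_pct' column", call. = FALSE)
    dat$occ <- table$occupancy_pct / occ_scale
    terms <- c(terms, "occ")
  }
  if ("rate" %in% covariates) {
    if (is.null(table$rate_pct_per_day))
      stop("table lacks a 'rate_pct_per_day' column", call. = FALSE)
    dat$rate <- table$rate_pct_per_day
    terms <- c(terms, "rate")
  }
  fml <- stats::as.formula(paste("survival::Surv(start, stop, event) ~",
                                 paste(terms, collapse = " + ")))
  warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron",
                    control = survival::coxph.control(eps = 1e-11,
                                                      iter.max = 50)),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("collinear covariates: coefficient(s) inestimable", call. = FALSE)
  if (any(abs(beta) > 10) || any(grepl("infinite", warn)))
    stop("apparent perfect separation: a coefficient diverges", call. = FALSE)
  if (any(grepl("did not converge", warn)))
    stop("partial-likelihood maximization did not converge", call. = FALSE)
  nice <- c(group = "group", occ = "occupancy", rate = "rate")
  names(beta) <- nice[names(beta)]
  V <- stats::vcov(fit)
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(coefficients = beta,
                 se = sqrt(diag(V)),
                 vcov = V,
                 loglik = fit$loglik[2],
                 n_events = fit$nevent,
                 n = length(unique(table$subject_id)),
                 converged = TRUE,
                 n_iter = fit$iter,
                 occ_scale = occ_scale),
            class = "cox_tv_fit")
}

#' @export
print.cox_tv_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards fit (%d events, %d subjects)\n",
              x$n_events, x$n))
  tab <- data.frame(coef = x$coefficients, se = x$se,
                    z = x$coefficients / x$se,
                    `exp(coef)` = exp(x$coefficients), check.names = FALSE)
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.cox_tv_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_tv_fit <- function(object, ...) object$vcov

#' @export
summary.cox_tv_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  data.frame(term = names(object$coefficients),
             estimate = unname(object$coefficients),
             se = unname(object$se), z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))),
             hr = unname(exp(object$coefficients)), row.names = NULL)
}

#' Hazard ratio with Wald confidence interval
#'
#' @param fit A \code{"cox_tv_fit"} (or \code{"casebase_fit"}).
#' @param coefficient Name of the coefficient to exponentiate.
#' @param level Confidence level (default 0.95).
#' @return List with \code{hr}, \code{lower}, \code{upper},
#'   \code{estimate} (log scale) and \code{se}.
#' @export
hazard_ratio <- function(fit, coefficient, level = 0.95) {
  beta <- stats::coef(fit)
  if (!coefficient %in% names(beta))
    stop("unknown coefficient '", coefficient, "'", call. = FALSE)
  est <- beta[[coefficient]]
  se <- fit$se[[coefficient]]
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(hr = exp(est), lower = exp(est - zq * se), upper = exp(est + zq * se),
       estimate = est, se = se)
}

#' Wald-type moderator test of formulation across trials
#'
#' Tests whether the per-trial treatment log hazard ratios differ by
#' formulation: a fixed-effect (inverse-variance) meta-regression of the
#' group coefficients on formulation indicators, with a Wald chi-square on
#' the moderator block and all pairwise formulation contrasts as z-tests.
#'
#' @param fits List of \code{"cox_tv_fit"} objects, one per trial, each
#'   containing a \code{group} coefficient; alternatively a numeric vector
#'   of log hazard ratios (then \code{ses} must be given).
#' @param moderator Character/factor of formulation labels, one per trial,
#'   spanning at least two levels.
#' @param ses Standard errors when \code{fits} is numeric.
#' @return See [meta_moderator()].
#' @export
wald_moderator_test <- function(fits, moderator, ses = NULL) {
  if (is.list(fits)) {
    est <- vapply(fits, function(f) stats::coef(f)[["group"]], numeric(1))
    ses <- vapply(fits, function(f) f$se[["group"]], numeric(1))
  } else {
    est <- fits
    if (is.null(ses)) stop("'ses' required with numeric estimates", call. = FALSE)
  }
  meta_moderator(est, ses, moderator)
}

#' Export a counting-process table to CSV
#'
#' @param table A \code{"counting_process"} data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_counting_process_csv <- function(table, path) {
  out <- table
  for (v in c("occupancy_pct", "rate_pct_per_day"))
    if (is.null(out[[v]])) out[[v]] <- NA_real_
  cols <- c("subject_id", "start_day", "stop_day", "event", "group",
            "occupancy_pct", "rate_pct_per_day")
  utils::write.csv(as.data.frame(out)[cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
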