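#' Sample a case-base person-moment series
#'
#' Case-base sampling for smooth-in-time hazard estimation: the case series
#' contains one person-moment per relapse event (at its observed day); the
#' base series contains \code{base_ratio} moments per event, drawn
#' uniformly over the observed person-time (a subject is chosen with
#' probability proportional to its follow-up, with replacement, and a
#' moment drawn uniformly within that follow-up). The sampling offset
#' \code{log(B/b)} — total person-time over base-series size — converts
#' logistic-regression intercepts back to the log hazard scale.
#'
#' @param subjects Participant records with columns \code{subject_id},
#'   \code{arm}, \code{time_days}, \code{event}.
#' @param base_ratio Base moments per case (default 100).
#' @param seed Optional integer seed.
#' @return A \code{"person_moment_sample"} data frame with columns
#'   \code{subject_id}, \code{day}, \code{is_case}, \code{group}, and
#'   attributes \code{base_size}, \code{total_person_time}, \code{offset}.
#' @export
sample_base_series <- function(subjects, base_ratio = 100, seed = NULL) {
  stopifnot(all(c("subject_id", "arm", "time_days", "event") %in% names(subjects)),
            base_ratio >= 1)
  n_events <- sum(subjects$event)
  if (n_events < 1L) stop("no events: cannot form a case series", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  B <- sum(subjects$time_days)
  b <- as.integer(round(base_ratio * n_events))
  pick <- sample.int(nrow(subjects), b, replace = TRUE,
                     prob = subjects$time_days)
  base <- data.frame(subject_id = subjects$subject_id[pick],
                     day = stats::runif(b, 0, subjects$time_days[pick]),
                     is_case = 0L,
                     group = as.numeric(subjects$arm[pick] == "active"))
  ev <- subjects[subjects$event == 1L, ]
  cases <- data.frame(subject_id = ev$subject_id,
                      day = as.numeric(ev$time_days),
                      is_case = 1L,
                      group = as.numeric(ev$arm == "active"))
  out <- rbind(cases, base)
  structure(out,
            class = c("person_moment_sample", "data.frame"),
            base_size = b,
            total_person_time = B,
            offset = log(B / b))
}

#' Fit the smooth-in-time hazard model to a person-moment sample
#'
#' Logistic regression of case status on randomization group, time since
#' randomization, and (optionally) their interaction, fit by iteratively
#' reweighted least squares via [stats::glm()]. Under case-base sampling
#' the log odds of being a case equal the log hazard plus the sampling
#' offset \code{log(B/b)}, so the slope coefficients estimate log
#' hazard-ratio parameters directly and the log baseline hazard is the
#' fitted intercept minus the offset.
#'
#' @param sample A \code{"person_moment_sample"} from
#'   [sample_base_series()].
#' @param include_interaction Include the group-by-time term (the
#'   time-varying hazard ratio); default \code{TRUE}.
#' @return A \code{"casebase_fit"}: \code{coefficients} (named
#'   \code{group}, \code{time}, and \code{group_time} when requested),
#'   \code{se}, \code{vcov}, \code{log_baseline_hazard}, \code{offset},
#'   \code{converged}.
#' @export
fit_casebase <- function(sample, include_interaction = TRUE) {
  stopifnot(inherits(sample, "person_moment_sample"))
  if (!all(c(0L, 1L) %in% sample$is_case) ||
      any(tapply(sample$is_case, sample$group, function(x) length(unique(x))) < 2L))
    stop("need both case and base moments in each group", call. = FALSE)
  fml <- if (include_interaction) is_case ~ group * day else is_case ~ group + day
  fit <- stats::glm(fml, family = stats::binomial(), data = sample,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  if (!fit$converged)
    stop("logistic fit did not converge (possible separation)", call. = FALSE)
  beta <- stats::coef(fit)
  if (anyNA(beta)) stop("inestimable coefficients (separation?)", call. = FALSE)
  if (any(abs(beta[-1L]) > 20))
    stop("apparent separation: a coefficient diverges", call. = FALSE)
  nm <- c("(Intercept)" = "intercept", group = "group", day = "time",
          "group:day" = "group_time")
  names(beta) <- nm[names(beta)]
  V <- stats::vcov(fit)
  dimnames(V) <- list(names(beta), names(beta))
  off <- attr(sample, "offset")
  slopes <- beta[setdiff(names(beta), "intercept")]
  structure(list(coefficients = slopes,
                 intercept = beta[["intercept"]],
                 log_baseline_hazard = beta[["intercept"]] - off,
                 se = sqrt(diag(V))[names(slopes)],
                 vcov = V,
                 offset = off,
                 n_cases = sum(sample$is_case),
                 converged = TRUE),
            class = "casebase_fit")
}

#' @export
coef.casebase_fit <- function(object, ...) object$coefficients

#' @export
vcov.casebase_fit <- function(object, ...) object$vcov

#' @export
print.casebase_fit <- function(x, ...) {
  cat(sprintf("Case-base smooth-in-time hazard fit (%d cases)\n", x$n_cases))
  tab <- data.frame(coef = x$coefficients, se = x$se,
                    z = x$coefficients / x$se)
  print(round(tab, 5))
  cat(sprintf("  log baseline hazard %.4f (offset %.4f)\n",
              x$log_baseline_hazard, x$offset))
  invisible(x)
}

#' Time-varying hazard ratio from a case-base fit
#'
#' \code{HR(t) = exp(beta_group + beta_group_time * t)} with a delta-method
#' Wald confidence interval from the coefficient covariance.
#'
#' @param fit A converged \code{"casebase_fit"}.
#' @param day Nonnegative day(s) since randomization.
#' @param level Confidence level.
#' @return Data frame with \code{day}, \code{hr}, \code{lower},
#'   \code{upper}.
#' @export
time_varying_hr <- function(fit, day, level = 0.95) {
  stopifnot(inherits(fit, "casebase_fit"), fit$converged)
  if (any(day < 0)) stop("'day' must be nonnegative", call. = FALSE)
  bg <- fit$coefficients[["group"]]
  bi <- if ("group_time" %in% names(fit$coefficients))
    fit$coefficients[["group_time"]] else 0
  est <- bg + bi * day
  if ("group_time" %in% names(fit$coefficients)) {
    V <- fit$vcov[c("group", "group_time"), c("group", "group_time")]
    v <- V["group", "group"] + day^2 * V["group_time", "group_time"] +
      2 * day * V["group", "group_time"]
  } else {
    v <- rep(fit$vcov["group", "group"], length(day))
  }
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(day = day, hr = exp(est),
             lower = exp(est - zq * sqrt(v)),
             upper = exp(est + zq * sqrt(v)))
}

#' Pool group-by-time interaction coefficients across trials
#'
#' Random-effects pooling (via [pool_random_effects()]) of the per-trial
#' case-base interaction coefficients; optionally also a moderator contrast
#' (e.g. oral vs long-acting injectable) via [meta_moderator()].
#'
#' @param fits List of at least two \code{"casebase_fit"} objects fitted
#'   with the interaction term.
#' @param moderator Optional labels for a moderator contrast.
#' @param method Pooling method passed to [pool_random_effects()].
#' @return A \code{"meta_pool"}; when \code{moderator} is given, with an
#'   extra element \code{moderator_test}.
#' @export
pool_interactions <- function(fits, moderator = NULL, method = "DL") {
  stopifnot(is.list(fits))
  if (length(fits) < 2L) stop("need at least two fits to pool", call. = FALSE)
  est <- vapply(fits, function(f) f$coefficients[["group_time"]], numeric(1))
  ses <- vapply(fits, function(f) f$se[["group_time"]], numeric(1))
  out <- pool_random_effects(est, ses, method = method)
  if (!is.null(moderator)) out$moderator_test <- meta_moderator(est, ses, moderator)
  out
}
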