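#' Random-effects pooling of per-trial coefficients
#'
#' DerSimonian-Laird moment-based random-effects meta-analysis (the
#' default), with REML available for sensitivity: fixed-effect weights
#' \eqn{w_i = 1/se_i^2}, heterogeneity
#' \eqn{Q = \sum w_i (\beta_i - \hat\beta_{FE})^2},
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w))},
#' and random-effects weights \eqn{1/(se_i^2 + \tau^2)}. Computation is
#' delegated to [metafor::rma()]. With a single trial the pooled estimate
#' and standard error pass through unchanged and \eqn{\tau^2 = 0}.
#'
#' @param estimates Numeric vector of per-trial coefficients (log
#'   hazard-ratio scale).
#' @param ses Positive standard errors, same length.
#' @param method \code{"DL"} (DerSimonian-Laird, default) or \code{"REML"}.
#' @return A \code{"meta_pool"} list: \code{pooled_estimate},
#'   \code{pooled_se}, \code{tau_squared}, \code{z_value}, \code{p_value},
#'   \code{ci_lower}, \code{ci_upper}, \code{k}, \code{weights}
#'   (normalized to sum to 1).
#' @export
#' @examples
#' pool_random_effects(c(0.4, 0.6), c(0.2, 0.2))  # pooled 0.5, SE 0.1414
pool_random_effects <- function(estimates, ses, method = c("DL", "REML")) {
  method <- match.arg(method)
  stopifnot(length(estimates) == length(ses), length(estimates) >= 1L)
  if (any(!is.finite(ses)) || any(ses <= 0))
    stop("all standard errors must be positive and finite", call. = FALSE)
  fit <- metafor::rma(yi = estimates, sei = ses, method = method)
  w <- stats::weights(fit)
  structure(list(pooled_estimate = as.numeric(fit$beta),
                 pooled_se = fit$se,
                 tau_squared = fit$tau2,
                 z_value = fit$zval,
                 p_value = fit$pval,
                 ci_lower = fit$ci.lb,
                 ci_upper = fit$ci.ub,
                 k = fit$k,
                 weights = as.numeric(w) / sum(w),
                 method = method),
            class = "meta_pool")
}

#' @export
print.meta_pool <- function(x, ...) {
  cat(sprintf("Random-effects pooled estimate (%s, k = %d)\n", x$method, x$k))
  cat(sprintf("  %.4f (SE %.4f), 95%% CI [%.4f, %.4f], tau^2 = %.4g, p = %.4g\n",
              x$pooled_estimate, x$pooled_se, x$ci_lower, x$ci_upper,
              x$tau_squared, x$p_value))
  invisible(x)
}

#' Moderator (meta-regression) Wald test across trials
#'
#' Fixed-effect inverse-variance meta-regression of per-trial coefficients
#' on moderator-level indicators, with a Wald chi-square on the moderator
#' block (\code{levels - 1} degrees of freedom) and all pairwise level
#' contrasts as z-tests on the per-level fixed-effect means.
#'
#' @param estimates,ses Per-trial coefficients and their (positive)
#'   standard errors.
#' @param moderator Labels (e.g. formulation) of the same length, spanning
#'   at least two levels, each level with at least one trial.
#' @return A \code{"meta_moderator"} list: \code{Q} (Wald chi-square),
#'   \code{df}, \code{p_value}, \code{level_means} (per-level fixed-effect
#'   estimate and se) and \code{pairwise} (data frame of contrasts with z
#'   and p).
#' @export
meta_moderator <- function(estimates, ses, moderator) {
  stopifnot(length(estimates) == length(ses),
            length(estimates) == length(moderator))
  if (any(!is.finite(ses)) || any(ses <= 0))
    stop("all standard errors must be positive and finite", call. = FALSE)
  moderator <- factor(moderator)
  if (any(table(moderator) == 0L) || nlevels(moderator) < 2L)
    stop("moderator must span >= 2 levels, each with >= 1 trial", call. = FALSE)
  fit <- metafor::rma(yi = estimates, sei = ses,
                      mods = ~ factor(moderator), method = "FE")
  # per-level fixed-effect means for pairwise contrasts
  lv <- levels(moderator)
  means <- vapply(lv, function(l) {
    w <- 1 / ses[moderator == l]^2
    c(est = sum(w * estimates[moderator == l]) / sum(w),
      se = sqrt(1 / sum(w)))
  }, numeric(2))
  pairs <- utils::combn(lv, 2L)
  diff <- means["est", pairs[1L, ]] - means["est", pairs[2L, ]]
  sed <- sqrt(means["se", pairs[1L, ]]^2 + means["se", pairs[2L, ]]^2)
  z <- diff / sed
  pairwise <- data.frame(level1 = pairs[1L, ], level2 = pairs[2L, ],
                         difference = unname(diff), se = unname(sed),
                         z = unname(z),
                         p = unname(2 * stats::pnorm(-abs(z))),
                         row.names = NULL)
  structure(list(Q = unname(fit$QM), df = fit$QMdf[1L],
                 p_value = unname(fit$QMp),
                 level_means = data.frame(level = lv,
                                          estimate = unname(means["est", ]),
                                          se = unname(means["se", ]),
                                          row.names = NULL),
                 pairwise = pairwise),
            class = "meta_moderator")
}

#' @export
print.meta_moderator <- function(x, ...) {
  cat(sprintf("Moderator Wald test: Q = %.4f on %d df, p = %.4g\n",
              x$Q, x$df, x$p_value))
  cat("Pairwise contrasts:\n")
  print(x$pairwise, digits = 4)
  invisible(x)
}
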