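fp <- default_formulations()
trajs120 <- list(active = active_trajectory(fp$lai_1m, 120),
                 placebo = placebo_trajectory(fp$lai_1m, 120))

test_that("counting-process intervals are half-open, contiguous and lossless", {
  # group only: maximal merge, one row per subject
  subj <- make_subjects(c(10, 25, 7), c(1, 0, 1),
                        c("active", "placebo", "active"))
  tab <- build_counting_process(subj, trajs120, covariates = "group")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$start_day, c(0, 0, 0))
  expect_equal(tab$stop_day, c(10, 25, 7))
  expect_equal(tab$event, c(1, 0, 1))
  expect_equal(tab$group, c(1, 0, 1))
  # daily-varying occupancy: one row per day, event on the last
  one <- make_subjects(3, 1, "placebo")
  tab1 <- build_counting_process(one, trajs120,
                                 covariates = c("group", "occupancy"))
  expect_equal(nrow(tab1), 3)
  expect_equal(tab1$start_day, 0:2)
  expect_equal(tab1$stop_day, 1:3)
  expect_equal(tab1$event, c(0, 0, 1))
  # left-aligned covariates: value on (d, d+1] is the day-d value
  expect_equal(tab1$occupancy_pct,
               trajs120$placebo$occupancy_pct[1:3])
  expect_error(build_counting_process(make_subjects(121, 1, "placebo"),
                                      trajs120, c("group", "occupancy")),
               "horizon")
})

test_that("exposure time is conserved for every subject in a large simulation", {
  d <- trial_design("T1", "lai_1m", 500, 500, 120)
  dat <- simulate_trial(d, fp$lai_1m, hazard_spec(0.004), seed = 17)
  tab <- build_counting_process(dat, trajs120,
                                covariates = c("group", "occupancy", "rate"))
  exposure <- tapply(tab$stop_day - tab$start_day, tab$subject_id, sum)
  expect_equal(as.numeric(exposure[dat$subject_id]), as.numeric(dat$time_days))
  # intervals non-overlapping and contiguous within subject
  by_subj <- split(tab, tab$subject_id)
  ok <- vapply(by_subj, function(s) {
    s <- s[order(s$start_day), ]
    all(s$start_day < s$stop_day) &&
      all(s$start_day[-1] == s$stop_day[-nrow(s)]) &&
      sum(s$event) == max(0, s$event[nrow(s)])
  }, logical(1))
  expect_true(all(ok))
  # exactly one terminal row per subject carries the event flag
  expect_equal(sum(tab$event), sum(dat$event))
})

test_that("interval compression does not change the fitted model", {
  d <- trial_design("T1", "lai_1m", 150, 150, 120)
  dat <- simulate_trial(d, fp$lai_1m, hazard_spec(0.004), seed = 23)
  tab <- build_counting_process(dat, trajs120,
                                covariates = c("group", "occupancy"))
  # re-expand every interval to strictly daily rows
  n_days <- tab$stop_day - tab$start_day
  idx <- rep(seq_len(nrow(tab)), n_days)
  daily <- tab[idx, ]
  daily$start_day <- tab$start_day[idx] + sequence(n_days) - 1L
  daily$stop_day <- daily$start_day + 1L
  daily$event <- 0L
  daily$event[cumsum(n_days)] <- tab$event
  class(daily) <- class(tab)
  f1 <- fit_cox_tv(tab, c("group", "occupancy"))
  f2 <- fit_cox_tv(daily, c("group", "occupancy"))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("the Newton solution matches a dense grid search of the partial likelihood", {
  # 6 subjects, staggered entry-free start-stop data, distinct event times
  tab <- data.frame(subject_id = sprintf("s%d", 1:6),
                    start_day = rep(0L, 6),
                    stop_day = c(3L, 5L, 7L, 9L, 11L, 12L),
                    event = c(1L, 0L, 1L, 1L, 0L, 1L),
                    group = c(1, 1, 0, 1, 0, 0))
  class(tab) <- c("counting_process", "data.frame")
  fit <- fit_cox_tv(tab, "group")
  oracle <- grid_mle(tab$start_day, tab$stop_day, tab$event, tab$group)
  expect_equal(unname(coef(fit)[["group"]]), oracle, tolerance = 1e-3)
  # tied event times exercise the Efron correction
  tab2 <- tab
  tab2$stop_day <- c(3L, 5L, 3L, 9L, 9L, 12L)
  tab2$event <- c(1L, 0L, 1L, 1L, 1L, 0L)
  fit2 <- fit_cox_tv(tab2, "group")
  oracle2 <- grid_mle(tab2$start_day, tab2$stop_day, tab2$event, tab2$group)
  expect_equal(unname(coef(fit2)[["group"]]), oracle2, tolerance = 1e-3)
})

test_that("degenerate fits raise diagnostics instead of silent results", {
  none <- make_subjects(c(5, 8), c(0, 0), c("active", "placebo"))
  tabn <- build_counting_process(none, trajs120, "group")
  expect_error(fit_cox_tv(tabn, "group"), "no events")
  # two subjects, event only in one group: monotone partial likelihood
  sep <- data.frame(subject_id = c("a", "b"), start_day = c(0L, 0L),
                    stop_day = c(1L, 2L), event = c(1L, 0L), group = c(1, 0))
  class(sep) <- c("counting_process", "data.frame")
  expect_error(fit_cox_tv(sep, "group"), "separation|diverg|converge")
})

test_that("group effect is recovered and covariate shifts leave it unchanged", {
  d <- trial_design("T1", "lai_1m", 1000, 1000, 120)
  dat <- simulate_trial(d, fp$lai_1m, hazard_spec(0.006, beta_group = -1, beta_occ_per_10pct = 0),
                        seed = 41)
  tab <- build_counting_process(dat, trajs120, "group")
  fit <- fit_cox_tv(tab, "group")
  expect_equal(unname(coef(fit)[["group"]]), -1, tolerance = 0.15)
  hr <- hazard_ratio(fit, "group")
  expect_equal(hr$hr, exp(coef(fit)[["group"]]))
  # partial likelihood depends only on covariate differences
  tab2 <- build_counting_process(dat, trajs120, c("group", "occupancy"))
  f1 <- fit_cox_tv(tab2, c("group", "occupancy"))
  tab2$occupancy_pct <- tab2$occupancy_pct + 250
  f2 <- fit_cox_tv(tab2, c("group", "occupancy"))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
})

test_that("Cox z-statistics hold the nominal type-I error under the null", {
  reject <- logical(400)
  d <- trial_design("T1", "lai_1m", 60, 60, 120)
  tr <- list(active = trajs120$active, placebo = trajs120$placebo)
  for (r in seq_along(reject)) {
    dat <- simulate_trial(d, fp$lai_1m, hazard_spec(0.008, 0, 0, 0, 0),
                          seed = 10000 + r)
    tab <- build_counting_process(dat, tr, "group")
    fit <- fit_cox_tv(tab, "group")
    reject[r] <- abs(coef(fit)[["group"]] / fit$se[["group"]]) >= 1.96
  }
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.09)
})

test_that("hazard ratios carry Wald intervals in the documented form", {
  fit <- structure(list(coefficients = c(group = 0), se = c(group = 0.1)),
                   class = "cox_tv_fit")
  hr <- hazard_ratio(fit, "group")
  expect_equal(round(c(hr$hr, hr$lower, hr$upper), 2), c(1, 0.82, 1.22))
  fit0 <- structure(list(coefficients = c(group = -0.5), se = c(group = 0)),
                    class = "cox_tv_fit")
  hr0 <- hazard_ratio(fit0, "group")
  expect_equal(c(hr0$lower, hr0$hr, hr0$upper), rep(exp(-0.5), 3))
  expect_error(hazard_ratio(fit, "occupancy"), "unknown coefficient")
})

test_that("the formulation moderator test reduces to the two-trial z contrast", {
  # identical trials: zero statistic
  m0 <- wald_moderator_test(c(-1, -1, -1), c("oral", "lai_1m", "lai_3m"),
                            ses = c(0.2, 0.3, 0.25))
  expect_equal(m0$Q, 0, tolerance = 1e-10)
  expect_equal(m0$p_value, 1, tolerance = 1e-10)
  # one trial per formulation: z = (b1 - b2) / sqrt(s1^2 + s2^2)
  m <- wald_moderator_test(c(-0.8, -1.4), c("oral", "lai_1m"),
                           ses = c(0.25, 0.4))
  z_hand <- (-1.4 - (-0.8)) / sqrt(0.25^2 + 0.4^2)
  expect_equal(abs(m$pairwise$z), abs(z_hand), tolerance = 1e-10)
  expect_equal(m$Q, z_hand^2, tolerance = 1e-10)
  expect_error(wald_moderator_test(c(-1, -1), c("oral", "oral"),
                                   ses = c(0.2, 0.2)), "levels")
})

test_that("counting-process CSV export writes the documented columns", {
  subj <- make_subjects(c(4, 6), c(1, 0), c("active", "placebo"))
  tab <- build_counting_process(subj, trajs120, c("group", "occupancy", "rate"))
  path <- tempfile(fileext = ".csv")
  write_counting_process_csv(tab, path)
  back <- read.csv(path)
  expect_equal(names(back), c("subject_id", "start_day", "stop_day", "event",
                              "group", "occupancy_pct", "rate_pct_per_day"))
  expect_equal(sum(back$stop_day - back$start_day), 10)
})
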