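fp <- default_formulations()

test_that("Emax dose-occupancy conversions match hand algebra and round-trip", {
  p <- fp$lai_1m
  expect_equal(occupancy_from_dose(2.38, p), 50)     # dose equals ED50
  expect_equal(occupancy_from_dose(0, p), 0)
  expect_equal(dose_from_occupancy(0, p), 0)
  expect_equal(dose_from_occupancy(50, p), 2.38)
  expect_equal(dose_from_occupancy(80, p), 9.52)     # 2.38 * 80/20
  expect_equal(occupancy_from_dose(9.52, p), 80)
  occ <- seq(0.5, 99.5, by = 0.5)
  expect_equal(occupancy_from_dose(dose_from_occupancy(occ, p), p), occ,
               tolerance = 1e-9)
  # strictly increasing and concave in dose, bounded by the maximum
  d <- seq(0, 200, by = 0.5)
  o <- occupancy_from_dose(d, p)
  expect_true(all(diff(o) > 0))
  expect_true(all(diff(diff(o)) < 0))
  expect_true(all(o < p$max_occupancy_pct))
  expect_error(dose_from_occupancy(100, p), "unreachable")
  expect_error(occupancy_from_dose(-1, p), "nonnegative")
})

test_that("steady-state peak agrees with root-finding and prints 86%/85%", {
  trough <- dose_from_occupancy(80, fp$lai_1m)
  # independent route: the peak is the level whose first-order decay over
  # (interval - t_peak) days lands on the trough
  for (p in list(fp$lai_1m, fp$lai_3m)) {
    decay_days <- p$dosing_interval_days - p$time_to_peak_days
    root <- uniroot(function(peak) peak * 2^(-decay_days / p$half_life_days) - trough,
                    c(trough, 100), tol = 1e-12)$root
    expect_equal(steady_state_peak(p), root, tolerance = 1e-9)
  }
  expect_equal(round(occupancy_from_dose(steady_state_peak(fp$lai_1m), fp$lai_1m)), 86)
  expect_equal(round(occupancy_from_dose(steady_state_peak(fp$lai_3m), fp$lai_3m)), 85)
  # zero decay time: peak collapses to the trough
  p0 <- formulation_params("lai_1m", 2.38, 37, time_to_peak_days = 30 - 1e-9,
                           dosing_interval_days = 30)
  expect_equal(steady_state_peak(p0), trough, tolerance = 1e-6)
  expect_error(steady_state_peak(fp$oral), "injectable")
})

test_that("active injectable trajectory is a periodic sawtooth anchored at the trough", {
  tr <- active_trajectory(fp$lai_1m, 487)
  expect_s3_class(tr, "occupancy_trajectory")
  expect_equal(tr$day, 0:487)
  expect_equal(tr$occupancy_pct[tr$day == 0], 80)
  peak_occ <- occupancy_from_dose(steady_state_peak(fp$lai_1m), fp$lai_1m)
  expect_equal(tr$occupancy_pct[tr$day == 5], peak_occ, tolerance = 1e-9)
  # trough recurrence at every dosing time, within 0.01 percentage points
  dosing_days <- seq(0, 487, by = 30)
  expect_true(all(abs(tr$occupancy_pct[tr$day %in% dosing_days] - 80) < 0.01))
  expect_true(all(tr$occupancy_pct >= 0 & tr$occupancy_pct < 100))
  expect_equal(range(round(tr$occupancy_pct)), c(80, 86))
  tr3 <- active_trajectory(fp$lai_3m, 487)
  expect_true(all(abs(tr3$occupancy_pct[tr3$day %in% seq(0, 487, by = 90)] - 80) < 0.01))
  expect_equal(range(round(tr3$occupancy_pct)), c(80, 85))
  # oral active treatment is a constant daily level
  tro <- active_trajectory(fp$oral, 100)
  expect_true(all(tro$plasma_equiv == tro$plasma_equiv[1]))
  expect_equal(tro$occupancy_pct, rep(80, 101))
})

test_that("placebo trajectory decays first-order from the trough", {
  tr <- placebo_trajectory(fp$lai_1m, 365)
  expect_equal(tr$occupancy_pct[tr$day == 0], 80)
  # one half-life: plasma 4.76, occupancy 4.76/(4.76+2.38) by hand
  expect_equal(tr$plasma_equiv[tr$day == 37], 4.76, tolerance = 1e-12)
  expect_equal(tr$occupancy_pct[tr$day == 37], 100 * 4.76 / 7.14,
               tolerance = 1e-12)
  expect_true(all(diff(tr$occupancy_pct) < 0))
  expect_true(all(tr$rate_pct_per_day <= 0))
  # washout limit
  far <- placebo_trajectory(fp$lai_1m, 5000)
  expect_lt(far$occupancy_pct[far$day == 5000], 0.01)
  # occupancy decays slower than plasma (Emax concavity)
  rel_occ <- tr$occupancy_pct / tr$occupancy_pct[1]
  rel_pla <- tr$plasma_equiv / tr$plasma_equiv[1]
  expect_true(all(rel_occ[-1] > rel_pla[-1]))
})

test_that("occupancy rate is the forward difference with an analytic-derivative check", {
  expect_true(all(occupancy_rate(active_trajectory(fp$oral, 50)) == 0))
  tr <- placebo_trajectory(fp$lai_1m, 200)
  r <- occupancy_rate(tr)
  expect_length(r, 201)
  expect_true(all(r < 0))
  expect_equal(r[1:200], diff(tr$occupancy_pct))
  expect_equal(r[201], r[200])  # final point carries the last difference
  # day 0 -> 1 forward difference vs the chain-rule derivative of the
  # Emax-of-exponential composition at t = 0, within 1%
  p <- fp$lai_1m
  trough <- dose_from_occupancy(80, p)
  dplasma <- -log(2) / p$half_life_days * trough
  docc <- 100 * p$ed50 / (trough + p$ed50)^2 * dplasma
  expect_equal(r[1], docc, tolerance = 0.01)
  expect_error(occupancy_rate(tr[1, ]), "at least 2")
})

test_that("raising the trough assumption raises the whole placebo trajectory", {
  trs <- lapply(c(75, 80, 85), function(tr)
    placebo_trajectory(default_formulations(tr)$lai_1m, 365)$occupancy_pct)
  expect_true(all(trs[[2]] > trs[[1]]))
  expect_true(all(trs[[3]] > trs[[2]]))
})

test_that("formulation parameter validation enforces the documented invariants", {
  expect_error(formulation_params("lai_1m", ed50 = -1, half_life_days = 37,
                                  time_to_peak_days = 5, dosing_interval_days = 30),
               "ed50")
  expect_error(formulation_params("oral", 2.38, 1, trough_occupancy_pct = 0),
               "trough")
  expect_error(formulation_params("oral", 2.38, 1, trough_occupancy_pct = 100),
               "trough")
  expect_error(formulation_params("lai_1m", 2.38, 37, time_to_peak_days = 31,
                                  dosing_interval_days = 30),
               "time_to_peak")
  expect_error(formulation_params("lai_1m", 2.38, 37),
               "injectable")
})

test_that("trajectory CSV export is tidy and lossless", {
  path <- tempfile(fileext = ".csv")
  tr <- active_trajectory(fp$lai_1m, 60)
  write_trajectories_csv(list(tr), path)
  back <- read.csv(path)
  expect_equal(names(back), c("formulation", "arm", "day", "plasma_equiv",
                              "occupancy_pct", "rate_pct_per_day"))
  expect_equal(back$occupancy_pct, tr$occupancy_pct, tolerance = 1e-9)
  expect_equal(unique(back$arm), "active")
})
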