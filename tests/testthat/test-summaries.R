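# Brute-force oracles, kept deliberately naive and separate from the
# implementations they check.
oracle_moving_mean <- function(x, window, truncate = TRUE) {
  n <- length(x)
  l <- (window - 1) %/% 2
  r <- window - 1 - l
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- i - l; hi <- i + r
    if (lo < 1 || hi > n) {
      if (truncate) out[i] <- mean(x[max(1, lo):min(n, hi)])
    } else {
      out[i] <- mean(x[lo:hi])
    }
  }
  out
}

oracle_extreme <- function(x, n_weeks = 3, window = 7, direction = "high") {
  n <- length(x)
  starts <- 1:(n - window + 1)
  vals <- vapply(starts, function(s) mean(x[s:(s + window - 1)]), numeric(1))
  taken <- rep(FALSE, n)
  picks <- integer(0)
  for (k in seq_len(n_weeks)) {
    best <- NA; best_v <- if (direction == "high") -Inf else Inf
    for (s in starts) {
      if (any(taken[s:(s + window - 1)])) next
      better <- if (direction == "high") vals[s - starts[1] + 1] > best_v else
        vals[s - starts[1] + 1] < best_v
      if (better) { best <- s; best_v <- vals[s - starts[1] + 1] }
    }
    if (is.na(best)) break
    taken[best:(best + window - 1)] <- TRUE
    picks <- c(picks, best + (window - 1) %/% 2)
  }
  picks
}

test_that("moving means match a brute-force oracle at both edge policies", {
  # constants are fixed points; window 1 is the identity
  expect_equal(moving_mean(rep(5, 30), 7), rep(5, 30))
  x <- rnorm(50)
  expect_equal(moving_mean(x, 1), x)

  # a +70 spike spread over a 7-day window adds +10 to the 7 covering windows
  y <- rep(100, 40); y[20] <- 170
  mm <- moving_mean(y, 7)
  expect_equal(mm[17:23], rep(110, 7))
  expect_equal(mm[c(16, 24)], c(100, 100))

  set.seed(99)
  for (i in 1:50) {
    x <- rnorm(60, 700, 80)
    for (w in c(2, 7, 14, 30)) {
      expect_equal(moving_mean(x, w), oracle_moving_mean(x, w))
      expect_equal(moving_mean(x, w, ends = "na"),
                   oracle_moving_mean(x, w, truncate = FALSE))
    }
  }
  # agrees with zoo's rolling mean where windows are full
  x <- rnorm(100)
  z <- zoo::rollmean(x, 7, fill = NA, align = "center")
  expect_equal(moving_mean(x, 7, ends = "na"), as.numeric(z))
  expect_error(moving_mean(x, 200), "exceeds")
})

test_that("sum of deviance contracts under longer windows", {
  expect_equal(sum_of_deviance(rep(700, 100), 1), 0)
  expect_equal(sum_of_deviance(rep(700, 100), 7), 0)
  expect_equal(sum_of_deviance(rep(700, 100), 30), 0)

  # alternating +/- 100 around the mean: window 1 sums 100 per day
  alt <- 700 + rep(c(100, -100), 50)
  expect_equal(sum_of_deviance(alt, 1), 100 * 100)

  set.seed(7)
  for (i in 1:100) {
    x <- rnorm(90, 700, 90)
    d1 <- sum_of_deviance(x, 1)
    d7 <- sum_of_deviance(x, 7)
    d30 <- sum_of_deviance(x, 30)
    expect_lte(d7, d1)
    expect_lte(d30, d7 + 1e-9)
    # oracle recomputation
    aee <- mean(x)
    mm <- oracle_moving_mean(x, 7, truncate = FALSE)
    expect_equal(d7, sum(abs(mm - aee), na.rm = TRUE))
  }
  # invariance under rotation of a periodic series
  x <- 700 + 100 * sin(2 * pi * (1:60) / 10)
  rot <- c(x[31:60], x[1:30])
  expect_equal(sum_of_deviance(x, 1), sum_of_deviance(rot, 1))
})

test_that("extreme weeks are greedy, non-overlapping and tie-stable", {
  # three isolated spikes are found in height order
  x <- rep(500, 60)
  x[c(10, 30, 50)] <- c(900, 1200, 1050)
  ew <- extreme_weeks(x)
  hi <- ew[ew$set == "high", ]
  # ties among windows containing a spike break to the earliest, so the
  # selected window is the first one covering each spike, in height order
  expect_equal(hi$center_index, c(27, 47, 7))
  expect_equal(hi$rank, 1:3)
  expect_true(all(abs(hi$center_index - c(30, 50, 10)) <= 3))
  expect_true(all(diff(sort(hi$center_index)) >= 7))

  # ties break to the earliest center date
  flat <- extreme_weeks(rep(5, 30))
  expect_equal(flat$center_index[flat$set == "high"], c(4, 11, 18))
  expect_equal(flat$center_index[flat$set == "low"], c(4, 11, 18))

  # stages of the central day are reported
  st <- rep(c("breeding", "wintering"), each = 30)
  ew2 <- extreme_weeks(c(rnorm(30, 900, 10), rnorm(30, 500, 10)),
                       stages = st)
  expect_true(all(ew2$stage[ew2$set == "high"] == "breeding"))
  expect_true(all(ew2$stage[ew2$set == "low"] == "wintering"))

  expect_error(extreme_weeks(rnorm(20)), "at least 21")
  # when fewer than three disjoint windows fit, as many as fit are returned:
  # the central spike makes greedy picks consume the middle of the series
  x3 <- rep(0, 21); x3[11] <- 100
  w <- capture_warnings(short <- extreme_weeks(x3))
  expect_true(any(grepl("only 2 non-overlapping high", w)))
  expect_equal(sum(short$set == "high"), 2)

  # sequential-greedy equals the brute-force oracle on random series
  set.seed(31)
  for (i in 1:200) {
    x <- rnorm(60, 700, 120)
    ew <- extreme_weeks(x)
    expect_equal(ew$center_index[ew$set == "high"], oracle_extreme(x, 3, 7, "high"))
    expect_equal(ew$center_index[ew$set == "low"], oracle_extreme(x, 3, 7, "low"))
  }
})

test_that("annual summaries average DEE and budgets over the filled year", {
  daily <- data.frame(date = as.Date("2020-06-01") + 0:364, dee = 700,
                      hours_flap = 2, hours_soar = 1, hours_walk = 2,
                      hours_stationary = 19,
                      energy_flap = 0.3, energy_soar = 0.1,
                      energy_walk = 0.2, energy_stationary = 0.4)
  a <- annual_summary(daily)
  expect_equal(a$aee, 700)
  expect_equal(a$hours_flap, 2)
  expect_equal(a$n_days, 365)
  expect_error(annual_summary(daily[1:100, ]), "complete")
  expect_error(annual_summary(daily[-10, ]), "complete")
  # identical inputs give identical summaries
  expect_identical(annual_summary(daily), annual_summary(daily))
})

test_that("the migration table matches the generator's configuration", {
  coh <- test_cohort()
  tab <- migration_table(coh$results)
  expect_true(all(c("strategy", "season", "n_mig_days_mean") %in% names(tab)))
  waf_s <- tab[tab$strategy == "WestAfrica" & tab$season == "spring", ]
  expect_equal(waf_s$n_mig_days_mean, 14, tolerance = 0.05)
  expect_equal(waf_s$period_days_mean, 21, tolerance = 0.05)
  # spring migratory periods are shorter than autumn for every strategy
  for (s in unique(tab$strategy)) {
    expect_lt(tab$period_days_mean[tab$strategy == s & tab$season == "spring"],
              tab$period_days_mean[tab$strategy == s & tab$season == "autumn"])
  }
  # migration-day DEE sits at the published scale (around 1000-1200 kJ/day)
  expect_true(all(tab$mean_dee_mean > 800 & tab$mean_dee_mean < 1500))
  # mean daily flight hours on migration days are ordered with the templates
  expect_gt(min(tab$mean_flight_h_mean), 5)
  expect_lt(max(tab$mean_flight_h_mean), 13)
})

test_that("model export tables are tidy and round-trip exactly", {
  coh <- test_cohort()
  sub <- coh$results[1:3]
  tabs <- export_model_tables(sub)
  expect_equal(nrow(tabs$annual), 3)
  expect_true(all(c("aee", "dev_7", "strategy", "hours_flap") %in%
                    names(tabs$annual)))
  expect_equal(nrow(tabs$daily), sum(vapply(sub, function(r) nrow(r$daily),
                                            numeric(1))))
  expect_true(all(c("dee", "stage", "simulated_fraction", "t_air") %in%
                    names(tabs$daily)))
  dir <- file.path(tempdir(), "tables")
  write_model_tables(tabs, dir)
  back <- utils::read.csv(file.path(dir, "model_annual.csv"))
  expect_identical(back$aee, tabs$annual$aee)
  expect_identical(back$dev_7, tabs$annual$dev_7)
  unlink(dir, recursive = TRUE)
})
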