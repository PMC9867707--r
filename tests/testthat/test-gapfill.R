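make_day <- function(step_min, hours = NULL) {
  y0 <- as.POSIXct("2020-06-01 00:00:00", tz = "UTC")
  ts <- if (is.null(hours)) y0 + seq(0, 86400 - 1, by = step_min * 60) else
    y0 + hours * 3600
  data.frame(timestamp = ts, lat = 40, lon = -4)
}

test_that("days are thinned to the day's lowest sampling frequency", {
  # uniform 10-min day: target 20 min, 72 fixes kept
  out <- subsample_day(make_day(10))
  expect_equal(nrow(out), 72)
  expect_true(all(diff(as.numeric(out$timestamp)) == 1200))

  # mixed 10- and 30-min spacing: the largest gap (30 min) drives the target
  d <- make_day(10)
  keep <- c(TRUE, rep(c(FALSE, FALSE, TRUE, TRUE, TRUE), length.out = 143))
  mixed <- d[keep, ]
  out2 <- subsample_day(mixed)
  expect_equal(max(diff(as.numeric(mixed$timestamp))) / 60, 30)
  expect_lte(nrow(out2), 48)  # one per 30-min bin

  # day already at 60 min: unchanged
  d60 <- make_day(60)
  expect_identical(subsample_day(d60), d60)

  # 2.5-min data forced to a 20-min grid keeps the first fix per bin
  out3 <- subsample_day(make_day(2.5), target = 20)
  expect_equal(nrow(out3), 72)
  expect_equal(as.numeric(out3$timestamp[1:3] - out3$timestamp[1],
                          units = "mins"), c(0, 20, 40))
})

test_that("coverage counts observed days against the bird-year length", {
  y0 <- as.Date("2020-06-01")
  mk <- function(days) data.frame(
    timestamp = as.POSIXct(paste(y0 + days, "12:00:00"), tz = "UTC"))
  full <- coverage(mk(0:364), year_start = y0, ndays = 365)
  expect_equal(full$fraction, 1)
  expect_true(full$pass)
  c100 <- coverage(mk(0:264), year_start = y0, ndays = 365)
  expect_equal(c100$fraction, (365 - 100) / 365, tolerance = 1e-12)
  expect_false(c100$pass)
  c80 <- coverage(mk(0:284), year_start = y0, ndays = 365)
  expect_equal(c80$fraction, (365 - 80) / 365, tolerance = 1e-12)
  expect_true(c80$pass)
})

test_that("stationary periods are runs of consecutive non-relocation days", {
  days <- data.frame(
    date = as.Date("2020-06-01") + 0:6,
    day_type = c("stationary", "stationary", "relocation", "stationary",
                 NA, "stationary", "relocation"))
  sp <- stationary_periods(days)
  expect_equal(sp$period_id, c(1L, 1L, NA, 2L, 2L, 2L, NA))
})

test_that("gaps inside a stationary period are filled and flagged", {
  coh_by <- generate_bird_year(strategy_template("Iberia"), 60, seed = 21)
  gapped <- inject_gaps(coh_by, list(c("2021-01-10", "2021-01-12")))
  seg <- segment_stages(gapped)
  filled <- fill_gaps(gapped, seg, seed = 5)
  expect_false(is.null(filled))
  d <- as.Date(filled$fixes$timestamp, tz = "UTC")
  gd <- d >= as.Date("2021-01-10") & d <= as.Date("2021-01-12")
  expect_equal(sum(gd), 3 * 24)
  expect_true(all(filled$fixes$simulated[gd]))
  expect_true(all(!filled$fixes$simulated[!gd]))
  expect_equal(filled$gap_report$filled_fraction,
               sum(gd) / nrow(filled$fixes))

  # donors come from the same (wintering) stationary period
  expect_true(all(filled$fixes$lat[gd] > 35 & filled$fixes$lat[gd] < 45))

  # filled days remain stationary: day types are unchanged by filling
  seg2 <- segment_stages(filled)
  expect_equal(seg2$days$day_type[seg2$days$date %in%
                                    (as.Date("2021-01-10") + 0:2)],
               rep("stationary", 3))

  # deterministic under the seed
  filled2 <- fill_gaps(gapped, seg, seed = 5)
  expect_identical(filled$fixes, filled2$fixes)
  filled3 <- fill_gaps(gapped, seg, seed = 6)
  expect_false(identical(filled$fixes, filled3$fixes))

  # no gaps: identity on the fix table
  no_gap <- fill_gaps(coh_by, segment_stages(coh_by), seed = 1)
  expect_equal(nrow(no_gap$fixes), nrow(coh_by$fixes))
  expect_equal(no_gap$gap_report$filled_fraction, 0)
})

test_that("a relocation during a gap discards the bird-year", {
  by <- generate_bird_year(strategy_template("WestAfrica"), 60, seed = 22)
  tr <- by$truth
  # cover the first week of spring migration (relocation inside the gap)
  w0 <- tr$winter_end + 1
  gapped <- inject_gaps(by, list(c(w0, w0 + 6)))
  seg <- segment_stages(gapped)
  expect_warning(out <- fill_gaps(gapped, seg, seed = 1),
                 "relocated during a data gap")
  expect_null(out)
  # and the pipeline reports it as discarded
  expect_warning(res <- process_bird_year(gapped), "relocated")
  expect_equal(res$discarded, "relocation_gap")
})

test_that("donor windows widen stepwise and fail beyond +/- 3 h", {
  # donors exist at every hour except 11-13: the 12:00 slot needs +/- 2 h
  mm <- mini_bird_year(hours = setdiff(0:23, 11:13), interval_min = 120)
  expect_warning(out <- fill_gaps(mm$bird_year, mm$seg, seed = 1),
                 "widened to \\+/- 2 h")
  expect_false(is.null(out))
  expect_equal(sum(out$fixes$simulated), 12)

  # donors only around midday: small-hour slots find nothing within 3 h
  mm2 <- mini_bird_year(hours = 10:14, interval_min = 120)
  expect_error(suppressWarnings(fill_gaps(mm2$bird_year, mm2$seg, seed = 1)),
               "no donor within")
})

test_that("gap filling does not bias the stationary period's mean DEE", {
  by <- generate_bird_year(strategy_template("Iberia"), 60, seed = 23)
  seg0 <- segment_stages(by)
  wdays <- seq(seg0$winter_start, seg0$winter_end, by = "day")
  fx0 <- annotate_energy(by$fixes)
  d0 <- daily_energy_table(fx0)
  truth_mean <- mean(d0$dee[d0$date %in% wdays])

  # mask ~20% of the winter period in scattered 3-day runs
  n <- length(wdays)
  starts <- wdays[seq(6, n - 6, by = 15)]
  windows <- lapply(starts, function(s) c(s, s + 2))
  gapped <- inject_gaps(by, windows)
  seg <- segment_stages(gapped)

  means <- vapply(1:30, function(s) {
    f <- fill_gaps(gapped, seg, seed = s)
    fx <- annotate_energy(f$fixes)
    dt <- daily_energy_table(fx)
    mean(dt$dee[dt$date %in% wdays])
  }, numeric(1))
  mc_se <- stats::sd(means)
  expect_lt(abs(mean(means) - truth_mean), 2 * mc_se)
})
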