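# Interval harmonization, coverage filtering and gap filling by resampling
# fixes within stationary periods.

#' Subsample one day's fixes to a harmonized interval
#'
#' Data are thinned to an interval between `min_interval` and `max_interval`
#' minutes, driven by the lowest sampling frequency of the day: the target
#' interval is the day's largest observed gap between fixes, floored at
#' `min_interval` and capped at `max_interval`. The day is cut into
#' target-interval bins from midnight and the earliest fix per bin is kept.
#'
#' @param day_fixes Data frame of one day's fixes with `timestamp`.
#' @param target Optional forced target interval (minutes); default the rule
#'   above.
#' @param min_interval,max_interval Bounds in minutes (defaults 20 and 60).
#' @return The subsampled day.
#' @export
subsample_day <- function(day_fixes, target = NULL, min_interval = 20,
                          max_interval = 60) {
  stopifnot(is.data.frame(day_fixes), nrow(day_fixes) >= 1L)
  day_fixes <- day_fixes[order(day_fixes$timestamp), , drop = FALSE]
  if (is.null(target)) {
    if (nrow(day_fixes) < 2L) return(day_fixes)
    biggest <- max(diff(as.numeric(day_fixes$timestamp))) / 60
    target <- min(max(biggest, min_interval), max_interval)
  }
  mins <- (as.numeric(day_fixes$timestamp) %% 86400) / 60
  bin <- floor(mins / target)
  keep <- !duplicated(bin)
  day_fixes[keep, , drop = FALSE]
}

#' Subsample a fix table day by day
#'
#' @param fixes Fix table with `timestamp`.
#' @param ... Passed to [subsample_day()].
#' @return Subsampled fix table.
#' @export
subsample_fixes <- function(fixes, ...) {
  parts <- split(fixes, date_of(fixes$timestamp))
  out <- do.call(rbind, lapply(parts, subsample_day, ...))
  rownames(out) <- NULL
  out[order(out$timestamp), , drop = FALSE]
}

#' Annual data coverage of a bird-year
#'
#' Fraction of the bird-year's days with at least one fix. Bird-years need at
#' least `min_fraction` (default 75%) coverage to enter the analysis.
#'
#' @param x A `bird_year` or a fix table with `timestamp`.
#' @param year_start,ndays Year bounds (taken from the object for a
#'   `bird_year`; otherwise default to the observed span).
#' @param min_fraction Pass threshold (default 0.75).
#' @return List: `fraction`, `pass`, `days_observed`, `days_total`.
#' @export
coverage <- function(x, year_start = NULL, ndays = NULL, min_fraction = 0.75) {
  if (inherits(x, "bird_year")) {
    year_start <- x$year_start; ndays <- x$ndays; x <- x$fixes
  }
  stopifnot(is.data.frame(x))
  d <- date_of(x$timestamp)
  if (is.null(year_start)) year_start <- min(d)
  if (is.null(ndays)) ndays <- as.numeric(max(d) - year_start) + 1
  obs <- length(unique(d[d >= year_start & d < year_start + ndays]))
  fraction <- obs / ndays
  list(fraction = fraction, pass = fraction >= min_fraction,
       days_observed = obs, days_total = ndays)
}

#' Stationary periods of a segmented bird-year
#'
#' A stationary period is a maximal run of consecutive non-relocation days;
#' days with missing day type (data gaps) extend the surrounding run. These
#' runs are the donor pools for gap filling.
#'
#' @param days Day table with `date` and `day_type` (e.g. `seg$days` from
#'   [segment_stages()]).
#' @return The day table with an integer `period_id` column (`NA` on
#'   relocation days).
#' @export
stationary_periods <- function(days) {
  stopifnot(is.data.frame(days), all(c("date", "day_type") %in% names(days)))
  days <- days[order(days$date), , drop = FALSE]
  rel <- !is.na(days$day_type) & days$day_type == "relocation"
  pid <- cumsum(rel) + 1L
  pid[rel] <- NA_integer_
  days$period_id <- pid
  days
}

#' Fill data gaps by resampling within stationary periods
#'
#' Each missing measurement slot inside a gap receives a donor fix drawn
#' uniformly from the same stationary period whose time of day lies within
#' +/- 1 h of the slot (the window widens stepwise to +/- 2 h then +/- 3 h,
#' with a warning, when empty). The filled fix carries the donor's behavior,
#' DBA and location but the slot's date-time, so thermoregulatory costs can be
#' computed with the weather of the missing moment (`weather_fun`); without a
#' weather function the donor's weather is reused. Donors are drawn without
#' replacement while possible. Filled fixes are flagged `simulated`.
#'
#' A bird-year that relocated during a gap (net displacement across the gap
#' exceeding the relocation threshold) is discarded: the function returns
#' `NULL` with a warning.
#'
#' @param bird_year A `bird_year`.
#' @param seg Its [segment_stages()] result.
#' @param seed Seed for donor sampling (deterministic fill).
#' @param interval_min Slot interval in minutes (default: the bird-year's).
#' @param weather_fun Optional `function(lat, lon, timestamp)` returning a
#'   list/data.frame with `t_air`, `wind`, `solar` for the slot.
#' @param threshold_km Relocation threshold across gaps (default 70).
#' @return The bird-year with simulated fixes appended (sorted), plus a
#'   `gap_report` element (per-gap days, slots, window widening, and the
#'   overall `filled_fraction` of fixes); or `NULL` if discarded.
#' @export
fill_gaps <- function(bird_year, seg, seed = 1L, interval_min = NULL,
                      weather_fun = NULL, threshold_km = 70) {
  stopifnot(inherits(bird_year, "bird_year"), inherits(seg, "stage_seg"))
  fixes <- bird_year$fixes[order(bird_year$fixes$timestamp), , drop = FALSE]
  if (is.null(interval_min)) interval_min <- bird_year$interval_min
  y0 <- bird_year$year_start
  all_days <- seq(y0, y0 + bird_year$ndays - 1, by = "day")
  have <- unique(date_of(fixes$timestamp))
  missing_days <- as.Date(setdiff(all_days, have), origin = "1970-01-01")
  if (length(missing_days) == 0L) {
    bird_year$gap_report <- list(gaps = list(), filled_fraction = 0)
    return(bird_year)
  }

  per <- stationary_periods(seg$days)
  fix_date <- date_of(fixes$timestamp)
  fix_pid <- per$period_id[match(fix_date, per$date)]
  fix_tod <- (as.numeric(fixes$timestamp) %% 86400) / 3600

  # group missing days into runs
  runs <- split(missing_days,
                cumsum(c(1, diff(as.numeric(missing_days)) != 1)))

  with_seed(seed,
            fill_gaps_impl(bird_year, fixes, fix_pid, fix_tod, runs,
                           interval_min, weather_fun, threshold_km))
}

fill_gaps_impl <- function(bird_year, fixes, fix_pid, fix_tod, runs,
                           interval_min, weather_fun, threshold_km) {
  fix_date <- date_of(fixes$timestamp)
  filled <- list(); report <- list()
  {
    for (run in runs) {
      before <- fixes$timestamp[fix_date < run[1]]
      after <- fixes$timestamp[fix_date > run[length(run)]]
      if (length(before) == 0L || length(after) == 0L) next  # edge gap
      ib <- which(fixes$timestamp == max(before))[1]
      ia <- which(fixes$timestamp == min(after))[1]
      dgap <- great_circle_km(fixes$lat[ib], fixes$lon[ib],
                              fixes$lat[ia], fixes$lon[ia])
      if (dgap > threshold_km) {
        warning(sprintf(
          "bird-year %s relocated during a data gap (%s..%s, %.0f km); discarded",
          bird_year$id, run[1], run[length(run)], dgap))
        return(NULL)
      }
      pid <- fix_pid[ib]
      if (is.na(pid) || !identical(pid, fix_pid[ia])) {
        warning(sprintf(
          "gap %s..%s not inside one stationary period; bird-year %s discarded",
          run[1], run[length(run)], bird_year$id))
        return(NULL)
      }
      pool <- which(!is.na(fix_pid) & fix_pid == pid & !fixes$simulated)
      used <- integer(0)
      widened <- 1
      slots_tod <- seq(0, 24 - 1e-9, by = interval_min / 60)
      gap_fills <- list()
      for (day in as.list(run)) {
        for (s in slots_tod) {
          dt <- abs(fix_tod[pool] - s)
          dt <- pmin(dt, 24 - dt)  # circular time-of-day distance
          win <- 1
          cand <- pool[dt <= win]
          while (length(cand) == 0L && win < 3) {
            win <- win + 1
            cand <- pool[dt <= win]
          }
          if (length(cand) == 0L) {
            stop(sprintf("no donor within +/- 3 h of %02.1f h in period %d",
                         s, pid), call. = FALSE)
          }
          if (win > widened) widened <- win
          fresh <- setdiff(cand, used)
          donor <- if (length(fresh) > 0L) {
            fresh[sample.int(length(fresh), 1L)]
          } else {
            cand[sample.int(length(cand), 1L)]  # reuse: donors < slots
          }
          used <- c(used, donor)
          f <- fixes[donor, , drop = FALSE]
          f$timestamp <- as.POSIXct(paste(day, "00:00:00"), tz = "UTC") +
            s * 3600
          if (!is.null(weather_fun)) {
            wx <- weather_fun(f$lat, f$lon, f$timestamp)
            f$t_air <- wx$t_air; f$wind <- wx$wind; f$solar <- wx$solar
          }
          f$simulated <- TRUE
          gap_fills[[length(gap_fills) + 1L]] <- f
        }
      }
      if (widened > 1) {
        warning(sprintf("gap %s..%s: donor window widened to +/- %d h",
                        run[1], run[length(run)], widened))
      }
      filled <- c(filled, gap_fills)
      report[[length(report) + 1L]] <- list(
        start = run[1], end = run[length(run)], n_days = length(run),
        n_slots = length(run) * length(slots_tod), widened_to = widened)
    }
    new_fixes <- if (length(filled) > 0L) {
      rbind(fixes, do.call(rbind, filled))
    } else fixes
    new_fixes <- new_fixes[order(new_fixes$timestamp), , drop = FALSE]
    rownames(new_fixes) <- NULL
    bird_year$fixes <- new_fixes
    bird_year$gap_report <- list(
      gaps = report,
      filled_fraction = sum(new_fixes$simulated) / nrow(new_fixes))
    bird_year
  }
}
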