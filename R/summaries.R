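# Annual and stage-level statistics: AEE, moving means, sum of deviance,
# extreme weeks, migration-day tables, and tidy exports for external model
# fitting.

#' Annual summary of a bird-year's daily energy table
#'
#' Annual energy expenditure (AEE) is the arithmetic mean of DEE over the
#' filled year. Mean daily hours per mode average the per-day time budgets
#' (which exclude simulated fixes); mean energy fractions include them.
#'
#' @param daily Daily energy table (see [daily_energy_table()]), one row per
#'   day of a filled bird-year.
#' @param require_complete Error unless the table covers a full contiguous
#'   year (default `TRUE`).
#' @return One-row data.frame: `aee` (kJ day^-1), `rmr_multiple`, mean
#'   `hours_*` and `energy_*` per mode, `n_days`.
#' @export
annual_summary <- function(daily, require_complete = TRUE) {
  stopifnot(is.data.frame(daily), "dee" %in% names(daily))
  if (require_complete) {
    if (nrow(daily) < 365 ||
        any(diff(as.numeric(daily$date)) != 1)) {
      stop("annual summary needs a complete contiguous year of daily values",
           call. = FALSE)
    }
  }
  aee <- mean(daily$dee)
  out <- data.frame(aee = aee, rmr_multiple = rmr_multiple(aee))
  for (m in BEHAVIOR_MODES) {
    out[[paste0("hours_", m)]] <- mean(daily[[paste0("hours_", m)]], na.rm = TRUE)
    out[[paste0("energy_", m)]] <- mean(daily[[paste0("energy_", m)]])
  }
  out$n_days <- nrow(daily)
  out
}

#' Centered moving mean
#'
#' Centered moving average with window `window` days. For even windows the
#' extra day goes to the trailing side. Series ends use truncated (partial)
#' windows by default, or `NA` when `ends = "na"`.
#'
#' @param x Numeric series.
#' @param window Window length in days (>= 1; must not exceed the series).
#' @param ends `"truncate"` (partial windows at the edges) or `"na"` (full
#'   windows only).
#' @return Numeric vector the length of `x`.
#' @export
moving_mean <- function(x, window, ends = c("truncate", "na")) {
  ends <- match.arg(ends)
  n <- length(x)
  window <- as.integer(window)
  if (window < 1L) stop("`window` must be >= 1", call. = FALSE)
  if (window > n) stop("`window` exceeds the series length", call. = FALSE)
  l <- (window - 1L) %/% 2L
  r <- window - 1L - l
  i <- seq_len(n)
  lo <- pmax(1L, i - l); hi <- pmin(n, i + r)
  cs <- c(0, cumsum(x))
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  if (ends == "na") out[i - l < 1L | i + r > n] <- NA_real_
  out
}

#' Sum of deviance between (smoothed) DEE and AEE
#'
#' Quantifies how concentrated energy expenditure is in time: the deviances
#' `|moving_mean(dee, window) - AEE|` summed over the year. Window 1 is the
#' raw daily deviance; windows 7 and 30 ask whether weekly or monthly energy
#' expenditure deviates from the annual mean (above-average days inside a
#' window can be balanced by below-average ones). For windows > 1 only full
#' windows enter the sum, avoiding edge inflation from truncated means.
#'
#' @param dee Numeric series of daily energy expenditure (complete year).
#' @param window 1, 7 or 30 (any positive window is accepted).
#' @param aee Annual mean; default `mean(dee)`.
#' @param edges `"full"` (default; windows > 1 use full windows only) or
#'   `"truncate"`.
#' @return Sum of deviance, kJ.
#' @export
sum_of_deviance <- function(dee, window = 7, aee = NULL,
                            edges = c("full", "truncate")) {
  edges <- match.arg(edges)
  if (any(!is.finite(dee))) stop("`dee` must be finite", call. = FALSE)
  if (is.null(aee)) aee <- mean(dee)
  if (window == 1) return(sum(abs(dee - aee)))
  mm <- moving_mean(dee, window,
                    ends = if (edges == "full") "na" else "truncate")
  sum(abs(mm - aee), na.rm = TRUE)
}

#' Extreme weeks of a DEE series
#'
#' Finds the `n_weeks` highest and lowest 7-day windows of mean DEE. Windows
#' are selected greedily from most to least extreme, and selected windows
#' exclude their days from later picks, so no day contributes to more than one
#' high (or one low) week. Ties break to the earliest center date. The stage
#' of each window's central day is reported.
#'
#' @param dee Numeric series of daily energy expenditure (>= 21 days).
#' @param dates Optional Date vector aligned with `dee`.
#' @param stages Optional character vector of annual-cycle stages per day.
#' @param n_weeks Number of windows per set (default 3).
#' @param window Window length (default 7).
#' @return Data frame: `set` ("high"/"low"), `rank`, `center_index`,
#'   `center_date`, `mean_dee`, `stage`.
#' @export
extreme_weeks <- function(dee, dates = NULL, stages = NULL, n_weeks = 3,
                          window = 7) {
  n <- length(dee)
  if (n < n_weeks * window) {
    stop(sprintf("need at least %d days", n_weeks * window), call. = FALSE)
  }
  if (is.null(dates)) dates <- as.Date(NA) + seq_len(n) * 0
  half <- (window - 1L) %/% 2L
  starts <- seq_len(n - window + 1L)
  wmean <- moving_mean(dee, window, ends = "na")[starts + half]

  pick <- function(direction) {
    taken <- rep(FALSE, n)
    sel <- list()
    for (rank in seq_len(n_weeks)) {
      free <- vapply(starts, function(s) !any(taken[s:(s + window - 1L)]),
                     logical(1))
      if (!any(free)) break
      val <- ifelse(free, wmean, NA)
      j <- if (direction == "high") which.max(val) else which.min(val)
      s <- starts[j]
      taken[s:(s + window - 1L)] <- TRUE
      ctr <- s + half
      sel[[rank]] <- data.frame(
        set = direction, rank = rank, center_index = ctr,
        center_date = dates[ctr], mean_dee = wmean[j],
        stage = if (is.null(stages)) NA_character_ else stages[ctr],
        stringsAsFactors = FALSE)
    }
    if (length(sel) < n_weeks) {
      warning(sprintf("only %d non-overlapping %s weeks available",
                      length(sel), direction))
    }
    do.call(rbind, sel)
  }
  out <- rbind(pick("high"), pick("low"))
  rownames(out) <- NULL
  out
}

#' Migration-day table by strategy and season
#'
#' For each bird-year and migratory season: length of the migratory period in
#' days (departure to arrival, including stopover days), number of migration
#' days (net displacement above the relocation threshold), and mean and
#' maximum DEE and daily flight hours over migration days; aggregated to mean
#' and standard deviation across bird-years per strategy and season.
#'
#' @param results List of [process_bird_year()] results (discarded entries are
#'   skipped).
#' @return Data frame with one row per strategy x season.
#' @export
migration_table <- function(results) {
  rows <- list()
  for (res in results) {
    if (!is.null(res$discarded)) next
    seg <- res$seg; daily <- res$daily
    for (season in c("autumn", "spring")) {
      stg <- paste0(season, "_migration")
      period <- if (season == "autumn") {
        as.numeric(seg$winter_start - seg$departure_date) - 1
      } else {
        as.numeric(seg$arrival_date - seg$winter_end) - 1
      }
      dd <- daily[daily$stage == stg & !is.na(daily$day_subtype) &
                    daily$day_subtype == "migration_day", , drop = FALSE]
      fh <- dd$hours_flap + dd$hours_soar
      rows[[length(rows) + 1L]] <- data.frame(
        id = res$id, strategy = res$strategy, season = season,
        period_days = period, n_mig_days = nrow(dd),
        mean_dee = if (nrow(dd)) mean(dd$dee) else NA_real_,
        max_dee = if (nrow(dd)) max(dd$dee) else NA_real_,
        mean_flight_h = if (nrow(dd)) mean(fh, na.rm = TRUE) else NA_real_,
        max_flight_h = if (nrow(dd)) max(fh, na.rm = TRUE) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no usable bird-years", call. = FALSE)
  per <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v, na.rm = TRUE))
  groups <- unique(per[, c("strategy", "season")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- per[per$strategy == groups$strategy[i] & per$season == groups$season[i], ]
    row <- data.frame(strategy = groups$strategy[i], season = groups$season[i],
                      n_bird_years = nrow(g), stringsAsFactors = FALSE)
    for (v in c("period_days", "n_mig_days", "mean_dee", "max_dee",
                "mean_flight_h", "max_flight_h")) {
      a <- agg(g[[v]])
      row[[paste0(v, "_mean")]] <- a[["mean"]]
      row[[paste0(v, "_sd")]] <- a[["sd"]]
    }
    row
  })
  out <- do.call(rbind, out)
  attr(out, "per_bird_year") <- per
  out
}

#' Tidy tables for external mixed-model fitting
#'
#' One row per bird-year for annual models (AEE, sums of deviance, annual
#' time/energy budgets, strategy) and one row per bird-day for time-series
#' models (DEE, per-mode hours, flight/stationary metabolic rates, weather,
#' stage, simulated fraction). Simulated fixes are excluded from the per-mode
#' hour columns by construction of the daily time budgets. The tables are
#' ready for LMM/GAMM fitting in external statistics packages; the package
#' itself fits no models.
#'
#' @param results List of [process_bird_year()] results.
#' @return List with data.frames `annual` and `daily`.
#' @export
export_model_tables <- function(results) {
  annual <- list(); daily <- list()
  for (res in results) {
    if (!is.null(res$discarded)) next
    a <- cbind(data.frame(id = res$id, strategy = res$strategy,
                          stringsAsFactors = FALSE),
               res$annual)
    a$dev_1 <- res$dev[["1"]]; a$dev_7 <- res$dev[["7"]]
    a$dev_30 <- res$dev[["30"]]
    annual[[length(annual) + 1L]] <- a
    d <- res$daily
    d$id <- res$id; d$strategy <- res$strategy
    d$simulated_fraction <- d$n_simulated / d$n_fixes
    daily[[length(daily) + 1L]] <- d
  }
  if (length(annual) == 0L) stop("no usable bird-years", call. = FALSE)
  list(annual = do.call(rbind, annual), daily = do.call(rbind, daily))
}

#' Write model tables as full-precision CSV
#'
#' Numeric columns are written with 17 significant digits so a read-back
#' reproduces the doubles bit-exactly.
#'
#' @param tables List from [export_model_tables()].
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_model_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    df <- tables[[nm]]
    for (j in seq_along(df)) {
      if (is.numeric(df[[j]])) {
        df[[j]] <- formatC(df[[j]], digits = 17, format = "g")
      }
    }
    p <- file.path(dir, paste0("model_", nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
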