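# Shared fixtures, built once per test run and memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# The reference synthetic cohort: 20 bird-years per strategy at the 60-min
# interval, processed end to end.
test_cohort <- function() {
  memo("cohort", function() simulate_cohort(20, seed = 1))
}

# One processed bird-year per strategy (cheap, reuses the cohort).
test_result <- function(strategy = "Iberia") {
  coh <- test_cohort()
  i <- which(vapply(coh$results, function(r) r$strategy_true, character(1)) ==
               strategy)[1]
  list(bird_year = coh$bird_years[[i]], result = coh$results[[i]])
}

# High-resolution (2.5-min) annotated fix tables, two bird-years per
# strategy, for interval-sensitivity checks.
test_hires_fixes <- function() {
  memo("hires", function() {
    out <- list()
    k <- 0
    for (s in c("FRUK", "Iberia", "NorthAfrica", "WestAfrica")) {
      for (j in 1:2) {
        k <- k + 1
        out[[k]] <- annotate_energy(
          generate_bird_year(strategy_template(s), 2.5, seed = 500 + k)$fixes)
      }
    }
    out
  })
}

# A tiny hand-built bird-year + segmentation for gap-filling edge cases:
# `hours` gives the fix hours present on each observed day; `missing`
# marks days (1-based) removed entirely.
mini_bird_year <- function(ndays = 9, hours = 0:23, missing = 5,
                           interval_min = 120, lat = 40, lon = -4) {
  y0 <- as.Date("2020-06-01")
  rows <- list()
  for (d in seq_len(ndays)) {
    if (d %in% missing) next
    for (h in hours) {
      rows[[length(rows) + 1L]] <- data.frame(
        timestamp = as.POSIXct(paste(y0 + d - 1, "00:00:00"), tz = "UTC") +
          h * 3600,
        lat = lat, lon = lon, behavior = "sit", dba = 0.02,
        t_air = 15, wind = 3, solar = 100, simulated = FALSE)
    }
  }
  by <- structure(list(
    id = "mini", strategy = "test", colony = c(52.46, 4.58),
    interval_min = interval_min, year_start = y0, ndays = ndays,
    fixes = do.call(rbind, rows), truth = NULL, gaps = list()
  ), class = "bird_year")
  seg <- structure(list(
    days = data.frame(date = seq(y0, by = "day", length.out = ndays),
                      day_type = "stationary")
  ), class = "stage_seg")
  list(bird_year = by, seg = seg)
}
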