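# Synthetic bird-years: GPS + acceleration-derived fixes with the statistical
# structure the downstream analysis assumes (stage schedules, migration legs,
# stopovers, behavior budgets, weather), so the whole pipeline is testable
# without field data.

#' Strategy template for the synthetic generator
#'
#' Templates encode the four migration strategies of Dutch-breeding lesser
#' black-backed gulls: wintering in France/UK (short distance), Iberia, North
#' Africa, or West Africa (long distance, > 4500 km). Stage schedules,
#' migration-day counts and daily flight hours follow the published
#' per-strategy means; per-stage behavior budgets are calibrated to the annual
#' time-budget means (about 2.2 h flapping and 1.4 h soaring per day, winter
#' stationary time peaking near 20 h per day, extra walking in the France/UK
#' strategy, soaring making up 39% of flight time).
#'
#' The bird-year runs June 1 to May 31. The bird leaves the colony with a
#' short (~16 km) evening staging hop on its last breeding day, so the
#' colony-radius segmentation convention recovers the scheduled boundary dates
#' exactly; migration legs are split over the scheduled number of migration
#' days, interleaved with stopovers at the configured latitudes.
#'
#' @param name One of `"FRUK"`, `"Iberia"`, `"NorthAfrica"`, `"WestAfrica"`.
#' @return An object of class `strategy_template`. Key fields: `colony`,
#'   `winter_centroid` (lat/lon), `n_migration_days_autumn/_spring`,
#'   `stopover_autumn/_spring` (lists of `list(lat, lon, days)`),
#'   `departure_day`, `autumn_len`, `arrival_day`, `spring_len` (day offsets
#'   from June 1), `flight_h_autumn/_spring` (mean daily flight hours on
#'   migration days), and `stage_budgets` (per-stage expected fix fractions
#'   over flap/soar/walk/stationary/float).
#' @examples
#' tpl <- strategy_template("WestAfrica")
#' rowSums(tpl$stage_budgets)  # each stage budget sums to 1
#' @export
strategy_template <- function(name = c("FRUK", "Iberia", "NorthAfrica",
                                       "WestAfrica")) {
  name <- match.arg(name)
  budgets <- rbind(
    breeding = c(flap = 0.130, soar = 0.085, walk = 0.120, stationary = 0.580, float = 0.085),
    autumn   = c(flap = 0.065, soar = 0.033, walk = 0.120, stationary = 0.630, float = 0.152),
    winter   = c(flap = 0.046, soar = 0.042, walk = 0.075, stationary = 0.700, float = 0.137),
    spring   = c(flap = 0.070, soar = 0.040, walk = 0.090, stationary = 0.650, float = 0.150)
  )
  par <- switch(name,
    FRUK = list(
      winter_centroid = c(48.5, 1.5), n_a = 5L, n_s = 5L,
      departure_day = 75L, autumn_len = 33L, arrival_day = 300L, spring_len = 16L,
      stopover_autumn = list(list(lat = 50.8, lon = 2.5, days = 28L)),
      stopover_spring = list(list(lat = 50.5, lon = 2.0, days = 11L)),
      flight_h_autumn = 7.8, flight_h_spring = 6.6,
      walk_boost = 0.040),
    Iberia = list(
      winter_centroid = c(40.0, -4.0), n_a = 7L, n_s = 9L,
      departure_day = 68L, autumn_len = 106L, arrival_day = 308L, spring_len = 23L,
      stopover_autumn = list(list(lat = 50.8, lon = 2.0, days = 99L)),
      stopover_spring = list(list(lat = 45.0, lon = -1.0, days = 14L)),
      flight_h_autumn = 9.3, flight_h_spring = 8.7,
      walk_boost = 0),
    NorthAfrica = list(
      winter_centroid = c(31.5, -8.0), n_a = 9L, n_s = 10L,
      departure_day = 70L, autumn_len = 96L, arrival_day = 312L, spring_len = 19L,
      stopover_autumn = list(list(lat = 50.5, lon = 1.0, days = 87L)),
      stopover_spring = list(list(lat = 41.0, lon = -5.0, days = 9L)),
      flight_h_autumn = 9.9, flight_h_spring = 9.3,
      walk_boost = 0),
    WestAfrica = list(
      winter_centroid = c(14.7, -17.0), n_a = 18L, n_s = 14L,
      departure_day = 60L, autumn_len = 123L, arrival_day = 320L, spring_len = 21L,
      stopover_autumn = list(list(lat = 50.5, lon = 0.0, days = 105L)),
      stopover_spring = list(list(lat = 32.0, lon = -9.0, days = 7L)),
      flight_h_autumn = 7.7, flight_h_spring = 10.6,
      walk_boost = 0)
  )
  # extra walking in autumn/winter for the short-distance strategy,
  # compensated out of stationary time
  if (par$walk_boost > 0) {
    for (st in c("autumn", "winter")) {
      budgets[st, "walk"] <- budgets[st, "walk"] + par$walk_boost
      budgets[st, "stationary"] <- budgets[st, "stationary"] - par$walk_boost
    }
  }
  tpl <- structure(c(list(
    name = name, colony = c(52.46, 4.58),
    stage_budgets = budgets,
    n_migration_days_autumn = par$n_a, n_migration_days_spring = par$n_s,
    flight_h_sd = 1.5, soar_share_flight = 0.39,
    jitter_site = 0.25, jitter_day = 0.03, jitter_fix = 0.01,
    budget_sigma = 0.15, budget_sigma_day = 0.30
  ), par[setdiff(names(par), c("n_a", "n_s", "walk_boost"))]),
  class = "strategy_template")
  tpl$n_a <- NULL
  validate_template(tpl)
  tpl
}

validate_template <- function(tpl) {
  if (!inherits(tpl, "strategy_template")) {
    stop("`template` must be a strategy_template", call. = FALSE)
  }
  if (max(abs(rowSums(tpl$stage_budgets) - 1)) > 1e-8) {
    stop("stage budget fractions must sum to 1", call. = FALSE)
  }
  if (any(tpl$stage_budgets < 0)) stop("budget fractions must be non-negative",
                                       call. = FALSE)
  sa <- sum(vapply(tpl$stopover_autumn, function(s) s$days, numeric(1)))
  ss <- sum(vapply(tpl$stopover_spring, function(s) s$days, numeric(1)))
  if (tpl$n_migration_days_autumn + sa != tpl$autumn_len) {
    stop("autumn migration days + stopover days must equal autumn_len",
         call. = FALSE)
  }
  if (tpl$n_migration_days_spring + ss != tpl$spring_len) {
    stop("spring migration days + stopover days must equal spring_len",
         call. = FALSE)
  }
  invisible(tpl)
}

#' @export
print.strategy_template <- function(x, ...) {
  cat(sprintf("<strategy_template %s: winter %.1f, %.1f; mig days %d + %d>\n",
              x$name, x$winter_centroid[1], x$winter_centroid[2],
              x$n_migration_days_autumn, x$n_migration_days_spring))
  invisible(x)
}

#' Synthetic weather sample
#'
#' Closed-form seasonal + diurnal sinusoids with Gaussian noise: air
#' temperature at 2 m, wind speed at 10 m (Weibull) and surface solar
#' radiation from solar elevation with a random cloudiness factor. The field
#' is monotone in latitude and season in the way the thermoregulation model
#' needs: tropical (15 degrees N) winters stay above the 10 degree C lower
#' critical temperature, temperate (52 degrees N) winters drop below it, and
#' solar radiation is exactly zero at local night.
#'
#' @param lat Latitude, degrees.
#' @param day_of_year Day of year, 1-366.
#' @param hour Local solar hour, decimal, in [0, 24).
#' @param seed Optional seed; if supplied the draw is deterministic and the
#'   caller's RNG state is untouched.
#' @param noise If `FALSE`, return the deterministic field (no temperature
#'   noise, mean wind, fixed 0.8 cloud factor).
#' @return Data frame `t_air` (deg C), `wind` (m s^-1, >= 0), `solar`
#'   (W m^-2, >= 0). Vectorized; recycled to the longest argument.
#' @examples
#' synth_weather(15, 15, 12, seed = 1)$t_air  # tropical winter noon, > 10
#' synth_weather(52, 15, 0, seed = 1)$solar   # local midnight, 0
#' @export
synth_weather <- function(lat, day_of_year, hour, seed = NULL, noise = TRUE) {
  if (any(!is.finite(lat)) || any(lat < -90) || any(lat > 90)) {
    stop("`lat` out of range", call. = FALSE)
  }
  if (any(!is.finite(day_of_year)) || any(day_of_year < 1) || any(day_of_year > 366)) {
    stop("`day_of_year` out of range", call. = FALSE)
  }
  if (any(!is.finite(hour)) || any(hour < 0) || any(hour >= 24)) {
    stop("`hour` out of range", call. = FALSE)
  }
  n <- max(length(lat), length(day_of_year), length(hour))
  lat <- rep_len(lat, n); doy <- rep_len(day_of_year, n); hour <- rep_len(hour, n)
  gen <- function() synth_weather_core(lat, doy, hour, noise)
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

synth_weather_core <- function(lat, doy, hour, noise) {
  n <- length(lat)
  # seasonal phase: warmest mid-July in the northern hemisphere
  phase <- ifelse(lat >= 0, doy - 200, doy - 200 + 182.6)
  seas <- cos(2 * pi * phase / 365.25)
  m <- 28 - 0.35 * abs(lat)
  amp <- 1 + 0.2 * abs(lat)
  t_air <- m + amp * seas + 1.5 * cos(2 * pi * (hour - 14) / 24)
  if (noise) t_air <- t_air + stats::rnorm(n, 0, 1.0)

  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365.25)
  rad <- pi / 180
  sinel <- sin(lat * rad) * sin(decl * rad) +
    cos(lat * rad) * cos(decl * rad) * cos(pi * (hour - 12) / 12)
  cloud <- if (noise) stats::runif(n, 0.55, 1) else rep(0.8, n)
  solar <- pmax(0, sinel) * 720 * cloud

  wind <- if (noise) stats::rweibull(n, shape = 2, scale = 5) else
    rep(5 * gamma(1.5), n)
  data.frame(t_air = t_air, wind = wind, solar = solar)
}

#' Synthetic 1-s tri-axial acceleration burst
#'
#' Generates a 20-sample burst (1 s at 20 Hz) in g around a 1-g gravity
#' baseline on the heave axis. Dynamic amplitude is ranked
#' flap > walk > soar > stationary; sitting/standing bursts are near-constant
#' (post-baseline-removal DBA well below 0.05 g).
#'
#' @param mode One of `"flap"`, `"soar"`, `"walk"`, `"sit"`, `"stand"`,
#'   `"sit/stand"`, `"float"`.
#' @param seed Optional seed for a deterministic burst.
#' @param n_samples,sample_rate Burst shape (defaults 20 samples at 20 Hz).
#' @return An [acc_burst()].
#' @export
generate_acc_burst <- function(mode, seed = NULL, n_samples = 20,
                               sample_rate = 20) {
  known <- c("flap", "soar", "walk", "sit", "stand", "sit/stand", "float")
  if (!is.character(mode) || length(mode) != 1L || !(mode %in% known)) {
    stop("unknown behavior mode: ", paste(mode, collapse = ", "), call. = FALSE)
  }
  gen <- function() {
    t <- (seq_len(n_samples) - 1) / sample_rate
    wave <- function(freq, amp) amp * sin(2 * pi * freq * t + stats::runif(1, 0, 2 * pi))
    nz <- function(sd) stats::rnorm(n_samples, 0, sd)
    dyn <- switch(mode,
      flap = cbind(wave(3.5, 0.35) + nz(0.10), wave(3.5, 0.30) + nz(0.10),
                   wave(3.5, 1.20) + nz(0.15)),
      walk = cbind(wave(2.0, 0.30) + nz(0.08), nz(0.08),
                   wave(2.0, 0.45) + nz(0.08)),
      soar = cbind(nz(0.12), nz(0.12), nz(0.12)),
      float = cbind(wave(0.4, 0.03) + nz(0.01), nz(0.01),
                    wave(0.4, 0.04) + nz(0.01)),
      cbind(nz(0.012), nz(0.012), nz(0.012))  # sit / stand / sit-stand
    )
    g0 <- c(0, 0, 1) + stats::rnorm(3, 0, 0.05)  # posture offset
    acc_burst(sweep(dyn, 2L, g0, "+"), sample_rate = sample_rate)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# ---- bird-year generation --------------------------------------------------

# Allocate n items over legs proportional to leg length (largest remainder,
# each leg gets at least one).
allocate_days <- function(dist, n) {
  k <- length(dist)
  if (n < k) stop("fewer migration days than route legs", call. = FALSE)
  raw <- dist / sum(dist) * (n - k) + 1
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

build_schedule <- function(tpl, year_start, ndays) {
  jig <- function(p, sd) c(p[1] + stats::rnorm(1, 0, sd), p[2] + stats::rnorm(1, 0, sd))
  colony <- tpl$colony
  staging <- c(colony[1] - 0.15, colony[2])
  winter_ctr <- jig(tpl$winter_centroid, tpl$jitter_site)
  stops_a <- lapply(tpl$stopover_autumn, function(s)
    list(pos = jig(c(s$lat, s$lon), tpl$jitter_site), days = s$days))
  stops_s <- lapply(tpl$stopover_spring, function(s)
    list(pos = jig(c(s$lat, s$lon), tpl$jitter_site), days = s$days))

  dep <- tpl$departure_day
  winter_start <- dep + tpl$autumn_len + 1L
  arr <- tpl$arrival_day
  spring_start <- arr - tpl$spring_len
  if (spring_start <= winter_start) stop("winter period has non-positive length",
                                         call. = FALSE)

  day <- 0:(ndays - 1L)
  stage <- rep("breeding", ndays)
  stage[day > dep & day < winter_start] <- "autumn_migration"
  stage[day >= winter_start & day < spring_start] <- "wintering"
  stage[day >= spring_start & day < arr] <- "spring_migration"

  sched <- data.frame(
    day = day, date = year_start + day, stage = stage,
    kind = "resident", site_lat = colony[1], site_lon = colony[2],
    lat0 = NA_real_, lon0 = NA_real_, lat1 = NA_real_, lon1 = NA_real_,
    move_start = NA_real_, move_end = NA_real_, flight_h = NA_real_,
    season = NA_character_, stringsAsFactors = FALSE
  )

  set_site <- function(sched, idx, pos) {
    sched$site_lat[idx] <- pos[1]; sched$site_lon[idx] <- pos[2]; sched
  }

  # one migratory season: fill days [first_day, first_day + len - 1]
  lay_season <- function(sched, first_day, waypoints, stops, n_mig, fh_mean,
                         season) {
    k <- length(waypoints) - 1L
    dist <- vapply(seq_len(k), function(j)
      great_circle_km(waypoints[[j]][1], waypoints[[j]][2],
                      waypoints[[j + 1L]][1], waypoints[[j + 1L]][2]),
      numeric(1))
    per_leg <- allocate_days(dist, n_mig)
    d <- first_day
    for (j in seq_len(k)) {
      p0 <- waypoints[[j]]; p1 <- waypoints[[j + 1L]]
      nj <- per_leg[j]
      for (i in seq_len(nj)) {
        row <- which(sched$day == d)
        f0 <- (i - 1) / nj; f1 <- i / nj
        fh <- min(17, max(6, stats::rnorm(1, fh_mean, tpl$flight_h_sd)))
        h0 <- stats::runif(1, 5, 23.4 - fh)
        sched$kind[row] <- "migration"
        sched$season[row] <- season
        sched$lat0[row] <- p0[1] + f0 * (p1[1] - p0[1])
        sched$lon0[row] <- p0[2] + f0 * (p1[2] - p0[2])
        sched$lat1[row] <- p0[1] + f1 * (p1[1] - p0[1])
        sched$lon1[row] <- p0[2] + f1 * (p1[2] - p0[2])
        sched$move_start[row] <- h0; sched$move_end[row] <- h0 + fh
        sched$flight_h[row] <- fh
        d <- d + 1L
      }
      if (j <= length(stops)) {
        idx <- which(sched$day %in% (d:(d + stops[[j]]$days - 1L)))
        sched <- set_site(sched, idx, stops[[j]]$pos)
        d <- d + stops[[j]]$days
      }
    }
    list(sched = sched, next_day = d)
  }

  # autumn: staging -> stopovers -> winter centre
  res <- lay_season(sched, dep + 1L, c(list(staging), lapply(stops_a, `[[`, "pos"),
                                       list(winter_ctr)),
                    stops_a, tpl$n_migration_days_autumn, tpl$flight_h_autumn,
                    "autumn")
  sched <- res$sched
  stopifnot(res$next_day == winter_start)
  sched <- set_site(sched, which(stage == "wintering"), winter_ctr)
  # spring: winter centre -> stopovers -> staging
  res <- lay_season(sched, spring_start, c(list(winter_ctr),
                                           lapply(stops_s, `[[`, "pos"),
                                           list(staging)),
                    stops_s, tpl$n_migration_days_spring, tpl$flight_h_spring,
                    "spring")
  sched <- res$sched
  stopifnot(res$next_day == arr)

  # staging hops on the departure and arrival days
  drow <- which(sched$day == dep)
  sched$kind[drow] <- "staging"
  sched$lat0[drow] <- colony[1]; sched$lon0[drow] <- colony[2]
  sched$lat1[drow] <- staging[1]; sched$lon1[drow] <- staging[2]
  sched$move_start[drow] <- 18; sched$move_end[drow] <- 18.5
  arow <- which(sched$day == arr)
  sched$kind[arow] <- "staging"
  sched$lat0[arow] <- staging[1]; sched$lon0[arow] <- staging[2]
  sched$lat1[arow] <- colony[1]; sched$lon1[arow] <- colony[2]
  sched$move_start[arow] <- 9.5; sched$move_end[arow] <- 10

  # daily site jitter for resident days (breeding sits tight on the colony)
  resd <- sched$kind == "resident"
  sd_day <- ifelse(sched$stage[resd] == "breeding", 0.02, tpl$jitter_day)
  sched$lat0[resd] <- sched$site_lat[resd] + stats::rnorm(sum(resd), 0, sd_day)
  sched$lon0[resd] <- sched$site_lon[resd] + stats::rnorm(sum(resd), 0, sd_day)
  sched$lat1[resd] <- sched$lat0[resd]; sched$lon1[resd] <- sched$lon0[resd]

  list(sched = sched, winter_ctr = winter_ctr,
       boundaries = list(departure_date = year_start + dep,
                         winter_start = year_start + winter_start,
                         winter_end = year_start + spring_start - 1L,
                         arrival_date = year_start + arr))
}

stage_key <- c(breeding = "breeding", autumn_migration = "autumn",
               wintering = "winter", spring_migration = "spring")

#' Generate a synthetic bird-year
#'
#' Simulates one individual's fixes from June 1 to May 31 at a fixed sampling
#' interval: colony residence, an autumn migration with stopovers, winter
#' quiescence at the strategy's wintering area, and a spring migration home.
#' Migration days contain a single 6-17 h flight bout (flapping-dominated,
#' with the configured soaring share); all other days draw each fix's behavior
#' from the active stage's budget. Per-fix weather comes from
#' [synth_weather()]; per-fix DBA is drawn from mode-specific distributions.
#' Mean-one lognormal multipliers on the flight and walking fractions, at the
#' bird-year level (individual effect) and at the day level (day-to-day
#' foraging decisions), create realistic variation without biasing expected
#' budgets away from the template. Deterministic for a fixed seed.
#'
#' @param template A [strategy_template()].
#' @param sampling_interval Fix interval in minutes, in [2.5, 60] (default 20,
#'   the most common annual sampling interval).
#' @param seed Integer seed (all randomness of the bird-year flows through it).
#' @param year_start First day of the bird-year (a June 1; default 2020-06-01).
#' @param id Identifier stored on the object.
#' @return An object of class `bird_year`: `fixes` (timestamp, lat, lon,
#'   behavior, dba, t_air, wind, solar, simulated), `colony`, `interval_min`,
#'   `year_start`, `ndays`, and `truth` (scheduled stage boundaries,
#'   per-season migration-day counts, realized per-stage budgets, and the
#'   day-by-day schedule) for parameter-recovery checks.
#' @export
generate_bird_year <- function(template, sampling_interval = 20, seed = 1L,
                               year_start = as.Date("2020-06-01"),
                               id = NULL) {
  validate_template(template)
  if (!is.numeric(sampling_interval) || length(sampling_interval) != 1L ||
      sampling_interval < 2.5 || sampling_interval > 60) {
    stop("`sampling_interval` must be a single value in [2.5, 60] minutes",
         call. = FALSE)
  }
  year_start <- as.Date(year_start)
  if (format(year_start, "%m-%d") != "06-01") {
    stop("`year_start` must be a June 1", call. = FALSE)
  }
  ndays <- as.integer(seq(year_start, by = "1 year", length.out = 2)[2] - year_start)

  with_seed(seed, {
    bs <- build_schedule(template, year_start, ndays)
    sched <- bs$sched

    # Activity-level heterogeneity: mean-one lognormal multipliers on the
    # flight (flap + soar) and walk fractions, at the bird-year level
    # (individual effect) and the day level (day-to-day foraging decisions,
    # which dominate variation in the field). The displaced fraction is
    # absorbed into stationary time, keeping expected budgets equal to the
    # template's.
    clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
    ln1 <- function(n, sigma) exp(stats::rnorm(n, -sigma^2 / 2, sigma))
    s_b <- template$budget_sigma; s_d <- template$budget_sigma_day
    mf_bird <- clamp(ln1(1, s_b), 0.5, 2)
    mw_bird <- clamp(ln1(1, s_b), 0.5, 2)
    mf_day <- clamp(mf_bird * ln1(ndays, s_d), 0.2, 2.5)
    mw_day <- clamp(mw_bird * ln1(ndays, s_d), 0.2, 2.5)

    shift_budget <- function(base, mf, mw) {
      c(flap = unname(base["flap"] * mf), soar = unname(base["soar"] * mf),
        walk = unname(base["walk"] * mw),
        stationary = unname(base["stationary"] +
                              (base["flap"] + base["soar"]) * (1 - mf) +
                              base["walk"] * (1 - mw)),
        float = unname(base["float"]))
    }
    # bird-level expected budgets (expectation over day effects)
    budgets <- t(vapply(rownames(template$stage_budgets), function(s)
      shift_budget(template$stage_budgets[s, ], mf_bird, mw_bird),
      numeric(5)))
    # realized per-day budgets
    day_budgets <- t(vapply(seq_len(ndays), function(d)
      shift_budget(template$stage_budgets[stage_key[[sched$stage[d]]], ],
                   mf_day[d], mw_day[d]),
      numeric(5)))

    t0 <- as.POSIXct(paste(year_start, "00:00:00"), tz = "UTC")
    step <- sampling_interval * 60
    times <- t0 + seq(0, ndays * 86400 - 1, by = step)
    day_idx <- floor(as.numeric(times - t0, units = "secs") / 86400)
    tod <- (as.numeric(times - t0, units = "secs") %% 86400) / 3600
    n <- length(times)

    behavior <- character(n)
    lat <- numeric(n); lon <- numeric(n)
    ground_budget <- c(flap = 0.01, soar = 0.01, walk = 0.08,
                       stationary = 0.75, float = 0.15)
    labs <- c("flap", "soar", "walk", "sit", "float")

    draw_modes <- function(k, budget) {
      lab <- sample(labs, k, replace = TRUE, prob = budget)
      st <- lab == "sit"
      lab[st] <- sample(c("sit", "stand"), sum(st), replace = TRUE)
      lab
    }

    idx_by_day <- split(seq_len(n), day_idx)
    for (d in seq_len(ndays)) {
      row <- sched[d, ]
      ii <- idx_by_day[[as.character(d - 1L)]]
      h <- tod[ii]
      if (row$kind == "migration") {
        inflight <- h >= row$move_start & h < row$move_end
        behavior[ii[inflight]] <- sample(
          c("flap", "soar"), sum(inflight), replace = TRUE,
          prob = c(1 - template$soar_share_flight, template$soar_share_flight))
        behavior[ii[!inflight]] <- draw_modes(sum(!inflight), ground_budget)
      } else {
        behavior[ii] <- draw_modes(length(ii), day_budgets[d, ])
      }
      if (is.na(row$move_start)) {
        frac <- rep(0, length(ii))
      } else {
        frac <- pmin(1, pmax(0, (h - row$move_start) /
                               (row$move_end - row$move_start)))
      }
      lat[ii] <- row$lat0 + frac * (row$lat1 - row$lat0)
      lon[ii] <- row$lon0 + frac * (row$lon1 - row$lon0)
    }
    lat <- lat + stats::rnorm(n, 0, template$jitter_fix)
    lon <- lon + stats::rnorm(n, 0, template$jitter_fix)

    dba_mean <- c(flap = 1.4, soar = 0.25, walk = 0.5, sit = 0.02,
                  stand = 0.02, float = 0.035)
    dba_sd <- c(flap = 0.15, soar = 0.05, walk = 0.08, sit = 0.008,
                stand = 0.008, float = 0.01)
    dba <- pmax(0.001, stats::rnorm(n, dba_mean[behavior], dba_sd[behavior]))

    wx <- synth_weather_core(lat, doy_of(times),
                             (tod + lon / 15) %% 24, noise = TRUE)

    fixes <- data.frame(
      timestamp = times, lat = lat, lon = lon, behavior = behavior,
      dba = dba, t_air = wx$t_air, wind = wx$wind, solar = wx$solar,
      simulated = FALSE
    )

    structure(list(
      id = if (is.null(id)) sprintf("%s_seed%d", template$name, seed) else id,
      strategy = template$name,
      colony = template$colony,
      winter_centroid = bs$winter_ctr,
      interval_min = sampling_interval,
      year_start = year_start, ndays = ndays,
      fixes = fixes,
      truth = list(
        departure_date = bs$boundaries$departure_date,
        winter_start = bs$boundaries$winter_start,
        winter_end = bs$boundaries$winter_end,
        arrival_date = bs$boundaries$arrival_date,
        n_migration_days = c(autumn = template$n_migration_days_autumn,
                             spring = template$n_migration_days_spring),
        budgets = budgets,
        day_budgets = day_budgets,
        schedule = sched
      ),
      gaps = list()
    ), class = "bird_year")
  })
}

#' @export
print.bird_year <- function(x, ...) {
  cat(sprintf("<bird_year %s: %s strategy, %d fixes @ %g min, %s..%s>\n",
              x$id, x$strategy, nrow(x$fixes), x$interval_min,
              x$year_start, x$year_start + x$ndays - 1))
  invisible(x)
}

#' Remove fixes inside gap windows
#'
#' Emulates tracker data gaps (e.g. solar-powered loggers at high latitude in
#' winter) by deleting all fixes whose date falls inside the given windows.
#' Overlapping windows are merged. Gap metadata and the fraction of days
#' removed are recorded on the object.
#'
#' @param bird_year A [generate_bird_year()] object.
#' @param gap_windows List of date ranges `c(start, end)` (Date or coercible),
#'   inclusive; or a data.frame with columns `start`, `end`.
#' @return The bird-year with fixes removed and `gaps` metadata (`windows`,
#'   `fraction_days_removed`).
#' @export
inject_gaps <- function(bird_year, gap_windows) {
  stopifnot(inherits(bird_year, "bird_year"))
  if (is.data.frame(gap_windows)) {
    gap_windows <- lapply(seq_len(nrow(gap_windows)), function(i)
      c(gap_windows$start[i], gap_windows$end[i]))
  }
  if (length(gap_windows) == 0L) return(bird_year)
  w <- lapply(gap_windows, function(g) as.Date(g))
  y0 <- bird_year$year_start; y1 <- y0 + bird_year$ndays - 1
  for (g in w) {
    if (length(g) != 2L || g[1] > g[2] || g[1] < y0 || g[2] > y1) {
      stop("gap windows must be start <= end and lie within the bird-year",
           call. = FALSE)
    }
  }
  w <- w[order(vapply(w, function(g) as.numeric(g[1]), numeric(1)))]
  merged <- list(w[[1]])
  for (g in w[-1]) {
    last <- merged[[length(merged)]]
    if (g[1] <= last[2] + 1) {
      merged[[length(merged)]][2] <- max(last[2], g[2])
    } else {
      merged <- c(merged, list(g))
    }
  }
  d <- date_of(bird_year$fixes$timestamp)
  drop <- rep(FALSE, length(d))
  ndrop_days <- 0
  for (g in merged) {
    drop <- drop | (d >= g[1] & d <= g[2])
    ndrop_days <- ndrop_days + as.numeric(g[2] - g[1]) + 1
  }
  bird_year$fixes <- bird_year$fixes[!drop, , drop = FALSE]
  bird_year$gaps <- list(windows = merged,
                         fraction_days_removed = ndrop_days / bird_year$ndays)
  bird_year
}

#' Write / read a bird-year as CSV plus YAML sidecar
#'
#' The CSV holds one row per fix (ISO-8601 UTC timestamp, lat, lon, behavior
#' label, DBA, weather, simulated flag); the YAML sidecar records identity and
#' generator parameters. Round-trips preserve fix values.
#'
#' @param bird_year A `bird_year`.
#' @param path CSV path; the sidecar is written next to it as `<path>.yml`.
#' @return `write_bird_year`: the path, invisibly. `read_bird_year`: a
#'   `bird_year` (without generator ground truth).
#' @export
write_bird_year <- function(bird_year, path) {
  stopifnot(inherits(bird_year, "bird_year"))
  f <- bird_year$fixes
  f$timestamp <- format(f$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(f, path, row.names = FALSE)
  meta <- list(id = bird_year$id, strategy = bird_year$strategy,
               colony = as.numeric(bird_year$colony),
               interval_min = bird_year$interval_min,
               year_start = as.character(bird_year$year_start),
               ndays = bird_year$ndays)
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_bird_year
#' @export
read_bird_year <- function(path) {
  f <- utils::read.csv(path, stringsAsFactors = FALSE)
  f$timestamp <- as.POSIXct(f$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  structure(list(
    id = meta$id, strategy = meta$strategy, colony = unlist(meta$colony),
    winter_centroid = NULL, interval_min = meta$interval_min,
    year_start = as.Date(meta$year_start), ndays = meta$ndays,
    fixes = f, truth = NULL, gaps = list()
  ), class = "bird_year")
}
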