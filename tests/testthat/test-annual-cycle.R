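test_that("great-circle distance matches its definition and oracles", {
  expect_equal(great_circle_km(52, 4, 52, 4), 0)
  # one degree of meridian arc
  expect_equal(great_circle_km(52, 4, 53, 4), 6371.0088 * pi / 180,
               tolerance = 1e-9)
  set.seed(7)
  lat1 <- runif(200, -60, 60); lon1 <- runif(200, -180, 180)
  lat2 <- runif(200, -60, 60); lon2 <- runif(200, -180, 180)
  d1 <- great_circle_km(lat1, lon1, lat2, lon2)
  d2 <- great_circle_km(lat2, lon2, lat1, lon1)
  expect_equal(d1, d2)
  # spherical law of cosines oracle
  rad <- pi / 180
  slc <- 6371.0088 * acos(pmin(1, pmax(-1,
    sin(lat1 * rad) * sin(lat2 * rad) +
      cos(lat1 * rad) * cos(lat2 * rad) * cos((lon2 - lon1) * rad))))
  expect_lt(max(abs(d1 - slc)), 1e-3)  # < 1 m
  # independent implementation (geosphere), same radius
  gh <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                 r = 6371008.8) / 1000
  expect_lt(max(abs(d1 - gh)), 1e-6)
  expect_error(great_circle_km(95, 0, 0, 0), "out of range")
})

test_that("relocation days need displacement strictly above the threshold", {
  expect_equal(classify_day(c(71, 70, 0, NA)),
               c("relocation", "stationary", "stationary", NA))
  expect_equal(classify_day(120, threshold = 150), "stationary")
  expect_error(classify_day(-3), "non-negative")
})

test_that("daily displacement anchors on fixes closest to midnight", {
  y0 <- as.POSIXct("2020-06-01 00:00:00", tz = "UTC")
  ts <- y0 + seq(0, 4 * 86400 - 1, by = 3600)
  lat <- rep(50, length(ts)); lon <- rep(4, length(ts))
  day <- floor(as.numeric(ts - y0, units = "secs") / 86400)
  # day 2 moves 3 degrees south over the day
  frac <- (as.numeric(ts - y0, units = "secs") %% 86400) / 86400
  lat[day == 1] <- 50 - 3 * frac[day == 1]
  lat[day >= 2] <- 47
  fx <- data.frame(timestamp = ts, lat = lat, lon = lon)
  dd <- daily_displacement(fx)
  expect_lt(dd$displacement_km[1], 5)
  expect_gt(dd$displacement_km[2], 300)
  expect_lt(dd$displacement_km[3], 5)
  # a day deep inside a multi-day data gap has missing displacement:
  # neither of its midnights has a fix within the 6-h tolerance
  ts6 <- y0 + seq(0, 6 * 86400 - 1, by = 3600)
  day6 <- floor(as.numeric(ts6 - y0, units = "secs") / 86400)
  fx2 <- data.frame(timestamp = ts6, lat = 50, lon = 4)[!(day6 %in% 1:3), ]
  dd2 <- daily_displacement(fx2)
  expect_true(is.na(dd2$displacement_km[3]))  # middle gap day
  expect_false(is.na(dd2$displacement_km[1]))
})

test_that("winter core area encloses ~95% mass and picks the south cluster", {
  set.seed(11)
  one <- data.frame(lat = rnorm(500, 40, 0.5), lon = rnorm(500, -4, 0.5))
  a1 <- winter_core_area(one)
  expect_equal(a1$n_components, 1)
  expect_equal(a1$mass_core, 0.95, tolerance = 0.02)
  expect_equal(a1$centroid_lat, 40, tolerance = 0.3)
  expect_true(all(point_in_core(a1, 40, -4)))

  two <- rbind(data.frame(lat = rnorm(300, 45, 0.4), lon = rnorm(300, 2, 0.4)),
               data.frame(lat = rnorm(300, 15, 0.4), lon = rnorm(300, -16, 0.4)))
  a2 <- winter_core_area(two)
  expect_gt(a2$n_components, 1)
  expect_equal(a2$centroid_lat, 15, tolerance = 0.5)
  expect_true(point_in_core(a2, 15, -16))
  expect_false(point_in_core(a2, 45, 2))
  expect_error(winter_core_area(one[1:20, ]), "at least 50")
})

test_that("strategies are assigned from the winter centroid regions", {
  expect_equal(assign_strategy(14.7, -17.0), "WestAfrica")
  expect_equal(assign_strategy(31.0, -8.0), "NorthAfrica")
  expect_equal(assign_strategy(40.0, -4.0), "Iberia")
  expect_equal(assign_strategy(48.5, 1.5), "FRUK")
  expect_warning(out <- assign_strategy(10, 100), "outside")
  expect_equal(out, "unassigned")
})

test_that("land-cover codes reduce to six habitat classes", {
  expect_equal(remap_habitat("cropland"), "agricultural")
  expect_equal(remap_habitat("shrubland"), "terrestrial_open")
  expect_equal(remap_habitat("sea"), "marine")
  expect_equal(remap_habitat("built-up", within_colony = TRUE),
               "terrestrial_open")
  expect_equal(remap_habitat(c("urban", "forest"), c(FALSE, FALSE)),
               c("built_up", "forest"))
  expect_error(remap_habitat("lava_field"), "lava_field")
})

test_that("stage segmentation partitions the year in the canonical order", {
  tr <- test_result("WestAfrica")
  r <- tr$result; truth <- tr$bird_year$truth
  days <- r$seg$days
  expect_true(all(!is.na(days$stage)))
  # contiguous blocks in breeding -> autumn -> winter -> spring -> breeding
  rle_st <- rle(days$stage)$values
  expect_equal(rle_st, c("breeding", "autumn_migration", "wintering",
                         "spring_migration", "breeding"))
  expect_lte(abs(as.integer(r$seg$departure_date - truth$departure_date)), 2)
  expect_lte(abs(as.integer(r$seg$winter_start - truth$winter_start)), 2)
  expect_lte(abs(as.integer(r$seg$winter_end - truth$winter_end)), 2)
  expect_lte(abs(as.integer(r$seg$arrival_date - truth$arrival_date)), 2)
  # migration days are relocation days by definition
  md <- !is.na(days$day_subtype) & days$day_subtype == "migration_day"
  expect_true(all(days$day_type[md] == "relocation"))
})

test_that("degenerate tracks are rejected by segmentation", {
  ts <- as.POSIXct("2020-06-01", tz = "UTC") + seq(0, 364 * 86400, by = 21600)
  stay <- data.frame(timestamp = ts,
                     lat = 52.46 + rnorm(length(ts), 0, 0.01),
                     lon = 4.58 + rnorm(length(ts), 0, 0.01))
  expect_error(segment_stages(stay, colony = c(52.46, 4.58)), "never left")
  away <- transform(stay, lat = lat - 10)
  expect_error(segment_stages(away, colony = c(52.46, 4.58)),
               "no fix ever within")
})
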