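# Annual-cycle segmentation: geodesic displacement, relocation-day
# classification, KDE wintering areas, stage boundaries, strategy assignment
# and habitat reduction.

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Vectorized over
#' coordinate vectors.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84 treated as
#'   spherical).
#' @return Distance(s) in km; symmetric, non-negative, zero iff the points
#'   coincide.
#' @examples
#' great_circle_km(52, 4, 53, 4)  # one degree of meridian, ~111.19 km
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1); check_coords(lat2, lon2)
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90) || any(lat > 90) || any(lon < -180) || any(lon > 360)) {
    stop("coordinates out of range", call. = FALSE)
  }
  invisible(TRUE)
}

#' Net daily displacement from fixes closest to midnight
#'
#' For each UTC calendar day, the great-circle distance between the fix
#' closest to the day's starting midnight and the fix closest to its ending
#' midnight. Days where either midnight has no fix within `tol_hours` get a
#' missing displacement.
#'
#' @param fixes Data frame with `timestamp` (POSIXct UTC), `lat`, `lon`.
#' @param tol_hours Maximum distance (hours) from midnight for a fix to anchor
#'   it (default 6).
#' @return Data frame `date`, `displacement_km` (NA where missing).
#' @export
daily_displacement <- function(fixes, tol_hours = 6) {
  stopifnot(is.data.frame(fixes), nrow(fixes) > 0L)
  ord <- order(fixes$timestamp)
  ts <- as.numeric(fixes$timestamp[ord])
  lat <- fixes$lat[ord]; lon <- fixes$lon[ord]

  d0 <- date_of(min(fixes$timestamp))
  d1 <- date_of(max(fixes$timestamp))
  days <- seq(d0, d1, by = "day")
  mids <- as.numeric(as.POSIXct(paste(c(days, d1 + 1), "00:00:00"), tz = "UTC"))

  # nearest fix to each midnight
  i <- findInterval(mids, ts)
  lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(ts))
  use_hi <- abs(ts[hi] - mids) < abs(ts[lo] - mids) | i == 0L
  near <- ifelse(use_hi, hi, lo)
  ok <- abs(ts[near] - mids) <= tol_hours * 3600

  n <- length(days)
  disp <- rep(NA_real_, n)
  both <- ok[seq_len(n)] & ok[seq_len(n) + 1L]
  if (any(both)) {
    a <- near[seq_len(n)][both]; b <- near[seq_len(n) + 1L][both]
    disp[both] <- great_circle_km(lat[a], lon[a], lat[b], lon[b])
  }
  data.frame(date = days, displacement_km = disp)
}

#' Classify a day as relocation or stationary
#'
#' A relocation day has net displacement strictly greater than the threshold
#' (default 70 km, the drop in the frequency distribution of daily net
#' displacements); boundary and smaller values are stationary. Missing
#' displacements stay missing.
#'
#' @param displacement Numeric vector of daily net displacements, km (NA ok).
#' @param threshold Threshold in km (default 70).
#' @return Character vector `"relocation"`/`"stationary"`/`NA`.
#' @export
classify_day <- function(displacement, threshold = 70) {
  if (any(displacement < 0, na.rm = TRUE)) {
    stop("displacements must be non-negative", call. = FALSE)
  }
  ifelse(is.na(displacement), NA_character_,
         ifelse(displacement > threshold, "relocation", "stationary"))
}

# --- Lambert azimuthal equal-area projection (spherical), for the KDE ------

laea_project <- function(lat, lon, lat0, lon0) {
  rad <- pi / 180
  phi <- lat * rad; lam <- lon * rad
  phi0 <- lat0 * rad; lam0 <- lon0 * rad
  kden <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  k <- sqrt(2 / kden)
  list(x = EARTH_RADIUS_KM * k * cos(phi) * sin(lam - lam0),
       y = EARTH_RADIUS_KM * k * (cos(phi0) * sin(phi) -
                                    sin(phi0) * cos(phi) * cos(lam - lam0)))
}

laea_inverse <- function(x, y, lat0, lon0) {
  rad <- pi / 180
  phi0 <- lat0 * rad; lam0 <- lon0 * rad
  rho <- sqrt(x^2 + y^2)
  out_lat <- rep(lat0, length(x)); out_lon <- rep(lon0, length(x))
  nz <- rho > 1e-9
  if (any(nz)) {
    cc <- 2 * asin(pmin(1, rho[nz] / (2 * EARTH_RADIUS_KM)))
    phi <- asin(cos(cc) * sin(phi0) + y[nz] * sin(cc) * cos(phi0) / rho[nz])
    lam <- lam0 + atan2(x[nz] * sin(cc),
                        rho[nz] * cos(phi0) * cos(cc) - y[nz] * sin(phi0) * sin(cc))
    out_lat[nz] <- phi / rad; out_lon[nz] <- lam / rad
  }
  list(lat = out_lat, lon = out_lon)
}

# Connected components (4-neighbour) of a logical matrix, by iterative
# minimum-label propagation. Grids here are small (<= 200 x 200).
label_components <- function(mask) {
  lab <- matrix(Inf, nrow(mask), ncol(mask))
  lab[mask] <- which(mask)
  repeat {
    new <- lab
    new[-1, ] <- pmin(new[-1, ], lab[-nrow(lab), ])
    new[-nrow(lab), ] <- pmin(new[-nrow(lab), ], lab[-1, ])
    new[, -1] <- pmin(new[, -1], lab[, -ncol(lab)])
    new[, -ncol(lab)] <- pmin(new[, -ncol(lab)], lab[, -1])
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!mask] <- NA
  ids <- sort(unique(lab[is.finite(lab)]))
  matrix(match(lab, ids), nrow(mask), ncol(mask))
}

#' Wintering core area from nonbreeding positions
#'
#' Fits a 2-D kernel density estimate (Gaussian kernels, Scott's bandwidth) to
#' positions on a Lambert azimuthal equal-area projection centred on the data,
#' thresholds it at the level enclosing `level` (default 95%) of the estimated
#' mass, and identifies connected core areas. When several disjoint core areas
#' exist (e.g. a long autumn stopover plus the true winter area), the one with
#' the southernmost centroid is taken as the wintering area.
#'
#' @param positions Data frame with `lat`, `lon` of fixes between colony
#'   departure and arrival; at least 50 rows.
#' @param level Density mass to enclose (default 0.95).
#' @param gridsize Grid resolution per axis for the KDE (default 200).
#' @param bw Optional bandwidth (km, length 2); default Scott's rule capped
#'   at `bw_cap`. Scott's rule over-smooths strongly multimodal nonbreeding
#'   distributions (its scale estimate spans the whole migration corridor),
#'   so the cap keeps core areas at the few-hundred-km scale typical of gull
#'   wintering ranges.
#' @param bw_cap Bandwidth cap in km (default 50).
#' @param bw_floor Bandwidth floor in km (default 10): with highly
#'   site-faithful birds most positions fall within a few km, and the data
#'   scale then underestimates the ranging scale of a wintering area.
#' @return An object of class `core_area` with the selected component, its
#'   centroid (`centroid_lat`, `centroid_lon`), the density grid, the mass
#'   actually enclosed by all core areas (`mass_core`) and by the selected one
#'   (`mass_winter`).
#' @export
winter_core_area <- function(positions, level = 0.95, gridsize = 200,
                             bw = NULL, bw_cap = 50, bw_floor = 10) {
  stopifnot(is.data.frame(positions), all(c("lat", "lon") %in% names(positions)))
  n <- nrow(positions)
  if (n < 50L) stop("need at least 50 positions for a winter core area", call. = FALSE)
  check_coords(positions$lat, positions$lon)

  lat0 <- mean(positions$lat); lon0 <- mean(positions$lon)
  pr <- laea_project(positions$lat, positions$lon, lat0, lon0)

  robust_sd <- function(v) {
    s <- min(stats::sd(v), stats::IQR(v) / 1.349)
    if (!is.finite(s) || s <= 0) s <- max(stats::sd(v), 1)
    s
  }
  if (is.null(bw)) {
    bw <- pmin(c(robust_sd(pr$x), robust_sd(pr$y)) * n^(-1 / 6), bw_cap)
  }
  bw <- pmax(bw, bw_floor)
  lims <- c(range(pr$x) + c(-3, 3) * bw[1], range(pr$y) + c(-3, 3) * bw[2])
  # MASS::kde2d uses kernel sd = h/4
  kd <- MASS::kde2d(pr$x, pr$y, h = 4 * bw, n = gridsize, lims = lims)

  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  zmass <- kd$z / sum(kd$z)
  ord <- order(kd$z, decreasing = TRUE)
  cum <- cumsum(zmass[ord])
  zc <- kd$z[ord][which(cum >= level)[1]]
  mask <- kd$z >= zc
  comp <- label_components(mask)
  ncomp <- max(comp, na.rm = TRUE)

  # centroid of each component from density-weighted cell centres
  cent <- lapply(seq_len(ncomp), function(k) {
    sel <- !is.na(comp) & comp == k
    idx <- which(sel, arr.ind = TRUE)
    w <- kd$z[sel]
    cx <- sum(kd$x[idx[, 1]] * w) / sum(w)
    cy <- sum(kd$y[idx[, 2]] * w) / sum(w)
    laea_inverse(cx, cy, lat0, lon0)
  })
  lats <- vapply(cent, function(c) c$lat, numeric(1))
  winter_id <- which.min(lats)

  structure(list(
    lat0 = lat0, lon0 = lon0, gx = kd$x, gy = kd$y, z = kd$z, level = zc,
    comp = comp, n_components = ncomp, winter_component = winter_id,
    centroid_lat = cent[[winter_id]]$lat, centroid_lon = cent[[winter_id]]$lon,
    component_lats = lats,
    mass_core = sum(zmass[mask]),
    mass_winter = sum(zmass[!is.na(comp) & comp == winter_id]),
    bw = bw, n = n
  ), class = "core_area")
}

#' @export
print.core_area <- function(x, ...) {
  cat(sprintf(
    "<core_area: %d component(s), winter centroid %.2f, %.2f; mass %.3f>\n",
    x$n_components, x$centroid_lat, x$centroid_lon, x$mass_core))
  invisible(x)
}

#' Test whether positions fall inside the selected winter core area
#'
#' @param area A [winter_core_area()] result.
#' @param lat,lon Coordinates in degrees (vectorized).
#' @return Logical vector.
#' @export
point_in_core <- function(area, lat, lon) {
  pr <- laea_project(lat, lon, area$lat0, area$lon0)
  ix <- findInterval(pr$x, area$gx, all.inside = FALSE)
  iy <- findInterval(pr$y, area$gy, all.inside = FALSE)
  # snap to nearest grid node; outside the grid -> FALSE
  nx <- length(area$gx); ny <- length(area$gy)
  inside <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  res <- rep(FALSE, length(lat))
  if (any(inside)) {
    ix2 <- pmin(ix[inside] + 1L, nx); iy2 <- pmin(iy[inside] + 1L, ny)
    ix0 <- ifelse(abs(area$gx[ix2] - pr$x[inside]) <
                    abs(area$gx[ix[inside]] - pr$x[inside]), ix2, ix[inside])
    iy0 <- ifelse(abs(area$gy[iy2] - pr$y[inside]) <
                    abs(area$gy[iy[inside]] - pr$y[inside]), iy2, iy[inside])
    cc <- area$comp[cbind(ix0, iy0)]
    res[inside] <- !is.na(cc) & cc == area$winter_component
  }
  res
}

#' Default migration-strategy regions
#'
#' Latitude/longitude boxes approximating the four wintering regions, checked
#' in order (first hit wins): Iberia (Spain/Portugal), France + UK, North
#' Africa (Africa north of 25 deg), West Africa (Africa south of 25 deg).
#'
#' @return List of regions, each `list(name, lat = c(min, max),
#'   lon = c(min, max))`.
#' @export
default_strategy_regions <- function() {
  list(
    list(name = "Iberia",      lat = c(36, 44),  lon = c(-10, 3)),
    list(name = "FRUK",        lat = c(43, 60),  lon = c(-11, 8)),
    list(name = "NorthAfrica", lat = c(25, 36),  lon = c(-20, 40)),
    list(name = "WestAfrica",  lat = c(-35, 25), lon = c(-20, 40))
  )
}

#' Assign a migration strategy from a winter centroid
#'
#' @param lat,lon Winter-area centroid, degrees.
#' @param regions Region list as in [default_strategy_regions()].
#' @return Strategy name, or `"unassigned"` (with a warning) if the centroid
#'   falls outside all regions.
#' @examples
#' assign_strategy(14.7, -17.0)  # "WestAfrica"
#' @export
assign_strategy <- function(lat, lon, regions = default_strategy_regions()) {
  check_coords(lat, lon)
  for (r in regions) {
    if (lat >= r$lat[1] && lat <= r$lat[2] && lon >= r$lon[1] && lon <= r$lon[2]) {
      return(r$name)
    }
  }
  warning(sprintf("winter centroid (%.2f, %.2f) outside all strategy regions",
                  lat, lon))
  "unassigned"
}

#' Segment a bird-year into annual-cycle stages
#'
#' Partitions the bird-year into breeding, autumn migration, wintering and
#' spring migration. The last detection within `radius_km` of the colony marks
#' the transition from breeding to autumn migration, and the first detection
#' within the radius the following spring marks the return to breeding. The
#' wintering stage spans the first to the last stationary day whose daily
#' position lies inside the wintering area (the southernmost 95% KDE core area
#' of nonbreeding positions). Relocation days within the migratory periods are
#' migration days; stationary days there are stopover days.
#'
#' Days with missing displacement inherit stationary (stopover) status when
#' flanked by stationary days, otherwise their day type stays missing.
#'
#' @param fixes Fix table (`timestamp`, `lat`, `lon`, ...), or a `bird_year`.
#' @param colony Colony coordinates `c(lat, lon)` (taken from the object for a
#'   `bird_year`).
#' @param radius_km Colony association radius, km (default 10).
#' @param threshold_km Relocation threshold, km (default 70).
#' @param min_absence_days Minimum colony absence (days) to accept a
#'   migration; shorter absences mean the bird never left (default 30).
#' @param ... Passed to [winter_core_area()].
#' @return An object of class `stage_seg`: `days` (date, stage, day_type,
#'   displacement_km), boundary dates (`departure_date`, `winter_start`,
#'   `winter_end`, `arrival_date`), `winter_area`, `winter_centroid`,
#'   `strategy`.
#' @export
segment_stages <- function(fixes, colony = NULL, radius_km = 10,
                           threshold_km = 70, min_absence_days = 30, ...) {
  if (inherits(fixes, "bird_year")) {
    if (is.null(colony)) colony <- fixes$colony
    fixes <- fixes$fixes
  }
  stopifnot(is.data.frame(fixes), !is.null(colony))
  fixes <- fixes[order(fixes$timestamp), , drop = FALSE]

  dist_col <- great_circle_km(fixes$lat, fixes$lon, colony[1], colony[2])
  at_col <- which(dist_col <= radius_km)
  if (length(at_col) == 0L) {
    stop("no fix ever within the colony radius; cannot segment", call. = FALSE)
  }
  tcol <- fixes$timestamp[at_col]
  gaps <- diff(as.numeric(tcol))
  if (length(gaps) == 0L || max(gaps) < min_absence_days * 86400) {
    stop("bird never left the colony long enough to migrate", call. = FALSE)
  }
  g <- which.max(gaps)
  departure_date <- date_of(tcol[g])
  arrival_date <- date_of(tcol[g + 1L])

  dd <- daily_displacement(fixes)
  dd$day_type <- classify_day(dd$displacement_km, threshold_km)

  # nonbreeding positions: strictly between departure and arrival fixes
  away <- fixes$timestamp > tcol[g] & fixes$timestamp < tcol[g + 1L]
  area <- winter_core_area(fixes[away, c("lat", "lon")], ...)

  # daily median positions for winter-area membership
  day <- date_of(fixes$timestamp)
  med_lat <- tapply(fixes$lat, day, stats::median)
  med_lon <- tapply(fixes$lon, day, stats::median)
  pos <- data.frame(date = as.Date(names(med_lat)),
                    lat = as.vector(med_lat), lon = as.vector(med_lon))
  dd <- merge(dd, pos, by = "date", all.x = TRUE, sort = TRUE)

  nonb <- dd$date > departure_date & dd$date < arrival_date
  stat <- !is.na(dd$day_type) & dd$day_type == "stationary"
  has_pos <- !is.na(dd$lat)
  in_area <- rep(FALSE, nrow(dd))
  cand <- nonb & stat & has_pos
  if (any(cand)) in_area[cand] <- point_in_core(area, dd$lat[cand], dd$lon[cand])
  if (!any(in_area)) {
    stop("no stationary day inside the wintering area; cannot segment",
         call. = FALSE)
  }
  winter_start <- min(dd$date[in_area])
  winter_end <- max(dd$date[in_area])

  stage <- rep("breeding", nrow(dd))
  stage[dd$date > departure_date & dd$date < winter_start] <- "autumn_migration"
  stage[dd$date >= winter_start & dd$date <= winter_end] <- "wintering"
  stage[dd$date > winter_end & dd$date < arrival_date] <- "spring_migration"
  dd$stage <- stage

  # missing-displacement days flanked by stationary days inherit stationary
  dt <- dd$day_type
  known <- which(!is.na(dt))
  for (i in which(is.na(dt))) {
    prv_idx <- known[known < i]; nxt_idx <- known[known > i]
    prv <- if (length(prv_idx)) dt[max(prv_idx)] else NA_character_
    nxt <- if (length(nxt_idx)) dt[min(nxt_idx)] else NA_character_
    if (identical(prv, "stationary") && identical(nxt, "stationary")) {
      dd$day_type[i] <- "stationary"
    }
  }

  mig <- dd$stage %in% c("autumn_migration", "spring_migration")
  dd$day_subtype <- NA_character_
  dd$day_subtype[mig & dd$day_type == "relocation"] <- "migration_day"
  dd$day_subtype[mig & dd$day_type == "stationary"] <- "stopover_day"

  strategy <- assign_strategy(area$centroid_lat, area$centroid_lon)

  structure(list(
    days = dd[, c("date", "stage", "day_type", "day_subtype",
                  "displacement_km", "lat", "lon")],
    departure_date = departure_date, arrival_date = arrival_date,
    winter_start = winter_start, winter_end = winter_end,
    winter_area = area,
    winter_centroid = c(lat = area$centroid_lat, lon = area$centroid_lon),
    strategy = strategy,
    colony = colony, radius_km = radius_km, threshold_km = threshold_km
  ), class = "stage_seg")
}

#' @export
print.stage_seg <- function(x, ...) {
  cat(sprintf(
    "<stage_seg: %s | departure %s, winter %s..%s, arrival %s>\n",
    x$strategy, x$departure_date, x$winter_start, x$winter_end, x$arrival_date))
  invisible(x)
}

#' Default land-cover to habitat-class map
#'
#' Reduces land-cover codes to six habitat classes: marine, built-up,
#' agricultural (croplands, which include most landfill sites), terrestrial
#' open (herbaceous/bare/sparse vegetation, shrubland), inland wet (permanent
#' inland water, herbaceous wetland) and forest.
#'
#' @return Named character vector code -> class.
#' @export
default_habitat_map <- function() {
  c(sea = "marine", marine = "marine", ocean = "marine",
    `built-up` = "built_up", urban = "built_up",
    cropland = "agricultural", agriculture = "agricultural",
    herbaceous_vegetation = "terrestrial_open", bare = "terrestrial_open",
    sparse_vegetation = "terrestrial_open", shrubland = "terrestrial_open",
    permanent_water = "inland_wet", inland_water = "inland_wet",
    herbaceous_wetland = "inland_wet", wetland = "inland_wet",
    forest = "forest", forest_evergreen = "forest", forest_deciduous = "forest",
    forest_mixed = "forest")
}

#' Reduce a land-cover code to one of six habitat classes
#'
#' Habitat misclassified inside breeding colonies is corrected to terrestrial
#' open habitat via `within_colony`.
#'
#' @param raw_class Character vector of land-cover codes.
#' @param within_colony Logical; fix lies within a breeding colony.
#' @param map Named map as from [default_habitat_map()].
#' @return Character vector of habitat classes.
#' @export
remap_habitat <- function(raw_class, within_colony = FALSE,
                          map = default_habitat_map()) {
  raw_class <- as.character(raw_class)
  unknown <- setdiff(unique(raw_class), names(map))
  if (length(unknown) > 0L) {
    stop("unmapped land-cover code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- unname(map[raw_class])
  n <- max(length(out), length(within_colony))
  out <- rep_len(out, n)
  out[rep_len(as.logical(within_colony), n)] <- "terrestrial_open"
  out
}
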