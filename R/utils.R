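# Internal helpers shared across modules.

W_TO_KJ_DAY <- 86.4          # 1 W sustained for 24 h = 86.4 kJ
EARTH_RADIUS_KM <- 6371.0088 # IUGG mean Earth radius

BEHAVIOR_MODES <- c("flap", "soar", "walk", "stationary")

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the previous RNG
#' state so callers' random streams are unaffected. All stochastic operations
#' in the package route their randomness through this helper.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Day-of-year (1-366) and decimal local solar hour for POSIXct timestamps.
doy_of <- function(time) as.POSIXlt(time, tz = "UTC")$yday + 1L

utc_hour_of <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

local_solar_hour <- function(time, lon) (utc_hour_of(time) + lon / 15) %% 24

date_of <- function(time) as.Date(time, tz = "UTC")

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}
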