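# Accelerometry: tri-axial bursts -> dynamic body acceleration (VeDBA),
# and reduction of upstream classifier labels to four behavior modes.

#' Construct an acceleration burst
#'
#' An `acc_burst` holds one short recording chunk (typically 1 s at 20 Hz) of
#' tri-axial acceleration in g, ordered surge (x), sway (y), heave (z).
#'
#' @param samples Numeric matrix (or coercible) with 3 columns `x`, `y`, `z`
#'   and one row per sample, units g.
#' @param sample_rate Sampling rate in Hz (default 20).
#' @return An object of class `acc_burst`.
#' @examples
#' b <- acc_burst(cbind(x = rnorm(20, 0, 0.1), y = 0, z = 1))
#' compute_dba(remove_baseline(b))
#' @export
acc_burst <- function(samples, sample_rate = 20) {
  m <- as.matrix(samples)
  if (is.null(dim(m)) || ncol(m) != 3L) {
    stop("`samples` must have three columns (x, y, z)", call. = FALSE)
  }
  storage.mode(m) <- "double"
  if (nrow(m) < 2L) stop("an acceleration burst needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(m))) stop("acceleration samples must be finite", call. = FALSE)
  colnames(m) <- c("x", "y", "z")
  stopifnot_scalar_number(sample_rate, "sample_rate")
  structure(list(samples = m, sample_rate = sample_rate), class = "acc_burst")
}

#' @export
print.acc_burst <- function(x, ...) {
  cat(sprintf("<acc_burst: %d samples @ %g Hz>\n", nrow(x$samples), x$sample_rate))
  invisible(x)
}

as_burst <- function(burst) {
  if (!inherits(burst, "acc_burst")) burst <- acc_burst(burst)
  burst
}

#' Remove the static (gravitational) baseline from a burst
#'
#' Subtracts the per-axis mean acceleration across the recording chunk, leaving
#' the dynamic component. After removal each axis has zero mean (to within
#' 1e-9 g).
#'
#' @param burst An [acc_burst()] (or 3-column matrix).
#' @return An `acc_burst` of dynamic accelerations.
#' @export
remove_baseline <- function(burst) {
  burst <- as_burst(burst)
  m <- burst$samples
  burst$samples <- sweep(m, 2L, colMeans(m))
  burst
}

#' Dynamic body acceleration (VeDBA) of a baseline-removed burst
#'
#' The per-sample vector norm `sqrt(x^2 + y^2 + z^2)` of the dynamic
#' acceleration, averaged over the burst. Averaging (rather than summing) makes
#' the value independent of burst length; this is the vectorial DBA convention
#' used by accelerometry calibration studies. The burst is expected to be
#' baseline-removed already (see [remove_baseline()]).
#'
#' @param burst An [acc_burst()] (or 3-column matrix) of dynamic accelerations.
#' @return DBA in g (non-negative scalar).
#' @export
compute_dba <- function(burst) {
  burst <- as_burst(burst)
  m <- burst$samples
  mean(sqrt(rowSums(m * m)))
}

#' DBA of a raw burst (baseline removal + VeDBA)
#'
#' Convenience wrapper: `compute_dba(remove_baseline(burst))`.
#'
#' @inheritParams compute_dba
#' @return DBA in g.
#' @export
dba <- function(burst) compute_dba(remove_baseline(burst))

#' Default classifier-label to behavior-mode map
#'
#' Maps labels emitted by an upstream behavior classifier onto the four modes
#' used by the energetics: flapping, soaring, walking and stationary (sitting,
#' standing or floating on water). Floating is a stationary sub-state tracked
#' separately because it has its own energetic cost.
#'
#' @return Named character vector mapping label -> mode, with attribute
#'   `floating` listing labels that denote floating on water.
#' @export
default_label_map <- function() {
  map <- c(
    flap = "flap", flapping = "flap",
    soar = "soar", soaring = "soar",
    walk = "walk", walking = "walk",
    sit = "stationary", stand = "stationary", `sit/stand` = "stationary",
    rest = "stationary", stationary = "stationary",
    float = "stationary", floating = "stationary"
  )
  attr(map, "floating") <- c("float", "floating")
  map
}

#' Reduce classifier labels to the four behavior modes
#'
#' @param label Character vector of classifier labels.
#' @param map Label map as returned by [default_label_map()].
#' @return A data.frame with columns `mode` (one of flap/soar/walk/stationary)
#'   and `floating` (logical; only `TRUE` for stationary on-water labels).
#' @examples
#' reduce_behavior(c("float", "sit", "flap"))
#' @export
reduce_behavior <- function(label, map = default_label_map()) {
  label <- as.character(label)
  unknown <- setdiff(unique(label), names(map))
  if (length(unknown) > 0L) {
    stop("unknown behavior label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mode <- unname(map[label])
  floating <- label %in% attr(map, "floating")
  data.frame(mode = mode, floating = floating, stringsAsFactors = FALSE)
}
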