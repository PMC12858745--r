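#' Volume-control calibration curve
#'
#' A calibration curve maps an ear-piece volume-control setting (percent of
#' maximum) to the acoustic output level at the ear (dBA). Both coordinates
#' must be strictly increasing so that the curve is invertible; between
#' anchors the curve is interpolated with a monotone shape-preserving
#' piecewise-cubic Hermite spline (Fritsch-Carlson), which reproduces the
#' anchors exactly and preserves monotonicity everywhere, capturing the
#' mildly nonlinear volume-to-level relation of real devices.
#'
#' @param volume_percent Numeric vector of volume-control settings, percent
#'   of maximum, in \[0, 100\], strictly increasing, length >= 2.
#' @param level Numeric vector of output levels (dBA), strictly increasing,
#'   same length as `volume_percent`.
#'
#' @return An object of class `calibration_curve`.
#' @seealso [default_calibration()], [volume_to_level()], [level_to_volume()],
#'   [read_calibration()]
#' @export
#' @examples
#' cal <- calibration_curve(c(0, 50, 100), c(60, 85, 100))
#' volume_to_level(cal, 75)
calibration_curve <- function(volume_percent, level) {
  volume_percent <- as.numeric(volume_percent)
  level <- as.numeric(level)
  if (length(volume_percent) < 2L || length(level) != length(volume_percent))
    stop_domain("calibration curve needs >= 2 (volume, level) pairs of equal length")
  if (anyNA(volume_percent) || anyNA(level))
    stop_domain("calibration curve anchors must not contain missing values")
  if (any(volume_percent < 0) || any(volume_percent > 100))
    stop_domain("volume anchors must lie in [0, 100]")
  if (any(diff(volume_percent) <= 0))
    stop_domain("volume anchors must be strictly increasing")
  if (any(diff(level) <= 0))
    stop_domain("level anchors must be strictly increasing (curve must be invertible)")
  structure(
    list(volume_percent = volume_percent, level = level),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration curve (", length(x$volume_percent), " anchors):\n", sep = "")
  print(data.frame(volume_percent = x$volume_percent, level_dba = x$level),
        row.names = FALSE)
  invisible(x)
}

#' Default volume-to-level calibration fixture
#'
#' A replaceable set of anchor points spanning the full volume range. The top
#' anchor (100% -> 100 dBA) reflects the maximum output level reported for
#' TETRA radio ear-pieces; the remaining anchors are declared fixture values
#' giving a realistic, mildly compressive curve. Replace with measured device
#' output levels (via [read_calibration()]) whenever a measurement table for
#' the device fleet under study is available; all dosimetry code is
#' curve-agnostic.
#'
#' @return A `calibration_curve`.
#' @export
default_calibration <- function() {
  calibration_curve(
    volume_percent = c(0, 25, 50, 75, 100),
    level = c(58, 76, 85, 93, 100)
  )
}

#' Read a calibration curve from CSV
#'
#' Expects a header `volume_percent,level_dba` with rows strictly increasing
#' in both columns.
#'
#' @param path Path to a CSV file.
#' @return A `calibration_curve`.
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("volume_percent", "level_dba")
  if (!all(need %in% names(df)))
    stop_domain("calibration CSV must have columns: ", paste(need, collapse = ", "))
  calibration_curve(df$volume_percent, df$level_dba)
}

# Interpolator: monotone Hermite spline through the anchors.
cal_fun <- function(curve) {
  stats::splinefun(curve$volume_percent, curve$level, method = "monoH.FC")
}

#' Convert volume-control settings to output levels
#'
#' Evaluates the calibration curve at the given settings. Values at anchor
#' points are reproduced exactly; between anchors the monotone interpolant is
#' used. No extrapolation: settings outside the anchored volume range are a
#' domain error (the shipped default curve spans 0-100%).
#'
#' @param curve A [calibration_curve()].
#' @param volume Numeric vector of settings, percent of maximum.
#' @return Numeric vector of levels (dBA).
#' @export
volume_to_level <- function(curve, volume) {
  stopifnot(inherits(curve, "calibration_curve"))
  volume <- as.numeric(volume)
  if (anyNA(volume)) stop_domain("volume must not be missing")
  if (any(volume < 0 | volume > 100))
    stop_domain("volume must lie in [0, 100]")
  rng <- range(curve$volume_percent)
  if (any(volume < rng[1] | volume > rng[2]))
    stop_domain("volume ", paste(volume[volume < rng[1] | volume > rng[2]], collapse = ", "),
                " outside the calibrated range [", rng[1], ", ", rng[2], "]")
  cal_fun(curve)(volume)
}

#' Convert output levels back to volume-control settings
#'
#' Inverts the calibration curve by bracketed root-finding on the forward
#' map (bisection-safeguarded, tolerance 1e-9 in volume), so that
#' `volume_to_level(curve, level_to_volume(curve, L))` returns `L` to within
#' 1e-6 dB. Levels outside the curve's range are a domain error.
#'
#' @param curve A [calibration_curve()].
#' @param level Numeric vector of levels (dBA).
#' @return Numeric vector of settings, percent of maximum.
#' @export
level_to_volume <- function(curve, level) {
  stopifnot(inherits(curve, "calibration_curve"))
  level <- as.numeric(level)
  if (anyNA(level)) stop_domain("level must not be missing")
  lr <- range(curve$level)
  if (any(level < lr[1] | level > lr[2]))
    stop_domain("level outside the calibrated range [", lr[1], ", ", lr[2], "] dBA")
  f <- cal_fun(curve)
  vr <- range(curve$volume_percent)
  # vectorised bracketed Newton: inverse-interpolated start on a dense grid,
  # then Newton steps on the monotone spline, clipped to the volume range
  grid_v <- seq(vr[1], vr[2], length.out = 512L)
  v <- stats::approx(f(grid_v), grid_v, xout = level, ties = "ordered")$y
  converged <- FALSE
  for (it in 1:60) {
    res <- f(v) - level
    if (max(abs(res)) < 1e-10) { converged <- TRUE; break }
    dv <- pmax(f(v, deriv = 1), 1e-8)
    v <- pmin(pmax(v - res / dv, vr[1]), vr[2])
  }
  if (!converged) {        # fall back to bisection for any stragglers
    bad <- which(abs(f(v) - level) >= 1e-10)
    v[bad] <- vapply(level[bad], function(L)
      stats::uniroot(function(x) f(x) - L, interval = vr, tol = 1e-12)$root,
      numeric(1))
  }
  # anchors resolve exactly, avoiding round-off at the range ends
  hit <- match(level, curve$level)
  v[!is.na(hit)] <- curve$volume_percent[hit[!is.na(hit)]]
  v
}
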