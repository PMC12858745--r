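#' Dosimetry constants
#'
#' Single authoritative definitions of the constants used throughout the
#' exposure calculations:
#' \describe{
#'   \item{duty_cycle}{0.2 — assumed fraction of ear-piece wearing time during
#'     which radio speech/chatter is actually transmitted; wearing durations
#'     are multiplied by this to give noise-exposure durations.}
#'   \item{ref_level}{85 dBA — the reference level for the exposure unit and
#'     the UK Upper Exposure Action Value used in reporting.}
#'   \item{work_week_h}{40 h — the notional working week over which weekly
#'     levels are averaged.}
#'   \item{working_year_weeks}{47 — working weeks per year.}
#'   \item{unit_hours}{1880 h (= 47 x 40) — one exposure unit equals 1880 h of
#'     constant exposure at 85 dBA (one working year).}
#' }
#' @return Named list of the five constants.
#' @export
noise_constants <- function() {
  list(duty_cycle = 0.2, ref_level = 85, work_week_h = 40,
       working_year_weeks = 47, unit_hours = 47 * 40)
}

.const <- noise_constants()

#' Validate a table of career segments
#'
#' A career segment describes one period of ear-piece use: its duration in
#' years, hours of wear per week, the proportion of wearing time at the
#' "loud" volume-control setting, and the loud and normal settings themselves
#' (percent of maximum). Respondents occasionally report a "loud" setting
#' below their "normal" setting; such rows are accepted but flagged.
#'
#' @param segments Data frame with columns `duration_years` (> 0),
#'   `hours_per_week` (in (0, 168\]), `prop_loud` (in \[0, 1\]),
#'   `volume_loud`, `volume_normal` (percent, in \[0, 100\]).
#' @return The input, invisibly, with a logical attribute
#'   `volume_order_flag` marking rows where `volume_loud < volume_normal`.
#' @export
validate_segments <- function(segments) {
  need <- c("duration_years", "hours_per_week", "prop_loud",
            "volume_loud", "volume_normal")
  miss <- setdiff(need, names(segments))
  if (length(miss))
    stop_domain("segments table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(segments)) {
    with(segments, {
      if (anyNA(segments[need])) stop_domain("segment fields must not be missing")
      if (any(duration_years <= 0)) stop_domain("duration_years must be > 0")
      if (any(hours_per_week <= 0 | hours_per_week > 168))
        stop_domain("hours_per_week must lie in (0, 168]")
      if (any(prop_loud < 0 | prop_loud > 1)) stop_domain("prop_loud must lie in [0, 1]")
      if (any(volume_loud < 0 | volume_loud > 100 |
              volume_normal < 0 | volume_normal > 100))
        stop_domain("volume settings must lie in [0, 100]")
    })
  }
  flag <- if (nrow(segments)) segments$volume_loud < segments$volume_normal else logical(0)
  if (any(flag))
    warning(sum(flag), " segment(s) report a 'loud' setting below the 'normal' setting",
            call. = FALSE)
  attr(segments, "volume_order_flag") <- flag
  invisible(segments)
}

#' Noise-exposure hours of a career segment
#'
#' Wearing time is converted to noise-exposure time with the transmission
#' duty cycle: `years x 47 x hours_per_week x 0.2`, split between the loud
#' and normal settings by `prop_loud`.
#'
#' @param segments Data frame of career segments (see [validate_segments()]).
#' @return Data frame with columns `hours_loud`, `hours_normal`.
#' @export
#' @examples
#' seg <- data.frame(duration_years = 1, hours_per_week = 40, prop_loud = 0.5,
#'                   volume_loud = 80, volume_normal = 50)
#' segment_exposure_hours(seg)  # 188 h at each setting
segment_exposure_hours <- function(segments) {
  validate_segments(segments)
  base <- segments$duration_years * .const$working_year_weeks *
    segments$hours_per_week * .const$duty_cycle
  data.frame(hours_loud = base * segments$prop_loud,
             hours_normal = base * (1 - segments$prop_loud))
}

# Energy (in exposure units) of h hours at level L dBA.
energy_units <- function(hours, level) {
  hours * 10^((level - .const$ref_level) / 10) / .const$unit_hours
}

#' Career-long ear-piece noise-exposure energy
#'
#' Sums sound energy over every segment's loud and normal sub-exposures,
#' expressed in exposure units: one unit is the energy of one working year
#' (47 weeks x 40 h = 1880 h) of constant exposure at 85 dBA. Each
#' sub-exposure contributes `h * 10^((L - 85)/10) / 1880` units, with `L`
#' the calibrated output level at the reported volume setting.
#'
#' @param segments Data frame of career segments; zero rows give 0 energy.
#' @param curve A [calibration_curve()].
#' @return Exposure energy in units (scalar, >= 0).
#' @export
device_noise <- function(segments, curve = default_calibration()) {
  if (!nrow(segments)) return(0)
  h <- segment_exposure_hours(segments)
  sum(energy_units(h$hours_loud, volume_to_level(curve, segments$volume_loud)),
      energy_units(h$hours_normal, volume_to_level(curve, segments$volume_normal)))
}

#' Weekly-averaged noise-exposure level
#'
#' The constant level that, present for 40 h in each working week of
#' ear-piece use, would carry the same total energy as the career exposure:
#' `85 + 10 log10(noise x 1880 / (40 x weeks_of_use))` dBA. This is the
#' metric compared against the 85 dBA Upper Exposure Action Value.
#'
#' @param noise Exposure energy in units (> 0).
#' @param weeks_of_use Working weeks of ear-piece use over the career (> 0).
#' @return Weekly-averaged level (dBA).
#' @export
device_weekly_level <- function(noise, weeks_of_use) {
  if (any(noise <= 0) || any(weeks_of_use <= 0))
    stop_domain("weekly level is undefined for zero exposure")
  .const$ref_level +
    10 * log10(noise * .const$unit_hours / (.const$work_week_h * weeks_of_use))
}

#' Energy-weighted average volume-control setting
#'
#' Inverts the energy summation: the average level during exposed time is
#' `85 + 10 log10(noise x 1880 / exposure_hours_total)` dBA, which is then
#' mapped back to a volume setting through the inverse calibration curve.
#' Because the average is energy-weighted it is never below the
#' duration-weighted mean setting.
#'
#' @param noise Exposure energy in units (> 0).
#' @param exposure_hours_total Total noise-exposure hours (> 0).
#' @param curve A [calibration_curve()].
#' @return Average volume-control setting (percent of maximum).
#' @export
device_volume_average <- function(noise, exposure_hours_total,
                                  curve = default_calibration()) {
  if (any(noise <= 0) || any(exposure_hours_total <= 0))
    stop_domain("volume average is undefined for zero exposure")
  l_avg <- .const$ref_level + 10 * log10(noise * .const$unit_hours / exposure_hours_total)
  level_to_volume(curve, l_avg)
}

#' Summarise a career's ear-piece exposure
#'
#' Computes all exposure metrics for one participant's career segments.
#' For an empty career the energy and hours are zero and the level/volume
#' metrics are `NA` (they are undefined, never -Inf).
#'
#' @param segments Data frame of the participant's career segments.
#' @param curve A [calibration_curve()].
#' @param weeks_of_use Working weeks of use; defaults to
#'   `sum(duration_years) x 47`, overridable where reported weeks exist.
#' @return One-row data frame: `device_noise` (units), `weekly_level` (dBA),
#'   `volume_average` (%), `exposure_hours_total` (h), `weeks_of_use`,
#'   `avg_level_during_exposure` (dBA).
#' @export
exposure_summary <- function(segments, curve = default_calibration(),
                             weeks_of_use = NULL) {
  if (!nrow(segments)) {
    return(data.frame(device_noise = 0, weekly_level = NA_real_,
                      volume_average = NA_real_, exposure_hours_total = 0,
                      weeks_of_use = 0, avg_level_during_exposure = NA_real_))
  }
  h <- segment_exposure_hours(segments)
  hours_total <- sum(h$hours_loud + h$hours_normal)
  noise <- device_noise(segments, curve)
  weeks <- weeks_of_use %||%
    (sum(segments$duration_years) * .const$working_year_weeks)
  l_avg <- .const$ref_level + 10 * log10(noise * .const$unit_hours / hours_total)
  data.frame(
    device_noise = noise,
    weekly_level = device_weekly_level(noise, weeks),
    volume_average = device_volume_average(noise, hours_total, curve),
    exposure_hours_total = hours_total,
    weeks_of_use = weeks,
    avg_level_during_exposure = l_avg
  )
}

#' Exposure summaries for a cohort
#'
#' Applies [exposure_summary()] per participant over a long segments table.
#' Participants absent from the table (nonusers) are not represented;
#' join on `participant_id` downstream.
#'
#' @param segments_df Long data frame with `participant_id` plus the segment
#'   columns of [validate_segments()].
#' @param curve A [calibration_curve()].
#' @return Data frame keyed by `participant_id` with the summary columns.
#' @export
cohort_exposure <- function(segments_df, curve = default_calibration()) {
  if (!nrow(segments_df)) {
    out <- exposure_summary(segments_df[0, , drop = FALSE], curve)
    return(cbind(participant_id = character(0), out[0, ]))
  }
  validate_segments(segments_df)
  # vectorised over the whole table, then aggregated: much faster than a
  # per-participant split at cohort sizes
  base <- segments_df$duration_years * .const$working_year_weeks *
    segments_df$hours_per_week * .const$duty_cycle
  hl <- base * segments_df$prop_loud
  hn <- base * (1 - segments_df$prop_loud)
  ll <- volume_to_level(curve, segments_df$volume_loud)
  ln <- volume_to_level(curve, segments_df$volume_normal)
  e <- energy_units(hl, ll) + energy_units(hn, ln)
  id <- segments_df$participant_id
  agg <- rowsum(cbind(noise = e, hours = hl + hn,
                      years = segments_df$duration_years), group = id)
  ids <- rownames(agg)
  noise <- agg[, "noise"]; hours <- agg[, "hours"]
  weeks <- agg[, "years"] * .const$working_year_weeks
  l_avg <- .const$ref_level + 10 * log10(noise * .const$unit_hours / hours)
  data.frame(
    participant_id = ids,
    device_noise = noise,
    weekly_level = device_weekly_level(noise, weeks),
    volume_average = device_volume_average(noise, hours, curve),
    exposure_hours_total = hours,
    weeks_of_use = weeks,
    avg_level_during_exposure = l_avg,
    row.names = NULL
  )
}
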