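#' Response options for the TTS-frequency question
#'
#' How often ear-piece use was followed by signs of temporary threshold
#' shift (temporary tinnitus and/or muffled hearing) in the exposed ear,
#' in ascending order of frequency.
#' @return Character vector of the five ordered response options.
#' @export
tts_levels <- function() {
  c("Never", "Sometimes", "About half the time", "Most of the time", "Every time")
}

# Default mapping from response option to the proportion of shifts followed
# by signs of TTS. Interior options use midpoints of their plain-language
# intervals; endpoints are forced by the wording.
default_tts_multipliers <- function() {
  c("Never" = 0, "Sometimes" = 0.25, "About half the time" = 0.5,
    "Most of the time" = 0.75, "Every time" = 1)
}

#' Validate a participants table
#'
#' Checks types, enumerated values and cross-field invariants of a survey
#' participants table: `device_side` is present exactly for unilateral
#' users (before any imputation), a tinnitus location other than "none"
#' is present exactly when prolonged spontaneous tinnitus is reported,
#' and a TTS-frequency response implies ear-piece use.
#'
#' @param participants Data frame; see the package README for the column
#'   schema. Extra columns are tolerated and carried through.
#' @return The input, invisibly.
#' @export
validate_participants <- function(participants) {
  need <- c("participant_id", "age", "sex", "device_use", "device_side",
            "side_reason_contra_pathology", "tts_prop", "tin_long",
            "tin_location", "diagnosed_hl", "din_right", "din_left",
            "din_antiphasic", "excluded_prior_hl")
  miss <- setdiff(need, names(participants))
  if (length(miss))
    stop_domain("participants table missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(participants)) return(invisible(participants))
  if (anyDuplicated(participants$participant_id))
    stop_domain("duplicate participant_id values")
  if (!all(participants$device_use %in% c("nonuser", "unilateral", "nonunilateral")))
    stop_domain("device_use must be nonuser/unilateral/nonunilateral")
  if (!all(participants$sex %in% c("male", "female")))
    stop_domain("sex must be male/female")
  side <- participants$device_side
  if (!all(is.na(side) | side %in% c("right", "left")))
    stop_domain("device_side must be right/left or missing")
  uni <- participants$device_use == "unilateral"
  if (any(uni & is.na(side)) || any(!uni & !is.na(side)))
    stop_domain("device_side must be present exactly for unilateral users")
  tp <- participants$tts_prop
  if (!all(is.na(tp) | tp %in% tts_levels()))
    stop_domain("tts_prop must be one of: ", paste(tts_levels(), collapse = "; "))
  if (any(!is.na(tp) & participants$device_use == "nonuser"))
    stop_domain("tts_prop reported by a nonuser")
  loc <- participants$tin_location
  if (!all(loc %in% c("none", "central", "right_only_or_mainly", "left_only_or_mainly")))
    stop_domain("unknown tin_location value")
  if (any((loc != "none") != participants$tin_long))
    stop_domain("tin_location must be 'none' exactly when tin_long is FALSE")
  invisible(participants)
}

#' Estimate the number of shifts worked while wearing an ear-piece
#'
#' Survey careers report hours of wear per week, not shifts; the shift count
#' is estimated as `years x 47 x min(hours_per_week / shift_hours, max_shifts)`
#' summed over segments and rounded half away from zero. Defaults assume an
#' 8-h shift and at most 5 shifts per week (a full-time policing pattern);
#' both are configurable.
#'
#' @param segments Data frame of career segments (may be empty).
#' @param shift_hours Nominal shift length in hours.
#' @param max_shifts_per_week Cap on shifts per week.
#' @return Integer shift count (>= 0).
#' @export
#' @examples
#' estimate_shifts(data.frame(duration_years = 1, hours_per_week = 40,
#'                            prop_loud = 0, volume_loud = 0, volume_normal = 0))
estimate_shifts <- function(segments, shift_hours = 8, max_shifts_per_week = 5) {
  if (!nrow(segments)) return(0L)
  validate_segments(segments)
  sh <- segments$duration_years * .const$working_year_weeks *
    pmin(segments$hours_per_week / shift_hours, max_shifts_per_week)
  as.integer(round_half_up(sum(sh)))
}

# Vectorised per-participant shift estimate over a long segments table;
# rounding happens once per participant, after summing segments.
estimate_shifts_by_id <- function(segments, shift_hours = 8,
                                  max_shifts_per_week = 5) {
  if (!nrow(segments)) return(stats::setNames(integer(0), character(0)))
  validate_segments(segments)
  sh <- segments$duration_years * .const$working_year_weeks *
    pmin(segments$hours_per_week / shift_hours, max_shifts_per_week)
  tot <- rowsum(sh, segments$participant_id)
  stats::setNames(as.integer(round_half_up(tot[, 1])), rownames(tot))
}

#' Estimated instances of ear-piece-associated TTS
#'
#' Combines the TTS-frequency response with the estimated shift count:
#' `shifts x multiplier`, rounded half away from zero, where the multiplier
#' maps each response option to a proportion of shifts.
#'
#' @param tts_prop Character vector of response options (see [tts_levels()]).
#' @param shifts Integer vector of shift counts.
#' @param multipliers Named numeric vector overriding the default mapping.
#' @return Integer vector of TTS instance counts; `NA` where `tts_prop` is
#'   missing.
#' @export
tts_count <- function(tts_prop, shifts, multipliers = default_tts_multipliers()) {
  if (!all(names(default_tts_multipliers()) %in% names(multipliers)))
    stop_domain("multipliers must name all five response options")
  bad <- !is.na(tts_prop) & !(tts_prop %in% tts_levels())
  if (any(bad)) stop_domain("unknown tts_prop value: ", tts_prop[bad][1])
  out <- round_half_up(multipliers[tts_prop] * shifts)
  as.integer(unname(out))
}

#' Three-level grouping of TTS instance counts
#'
#' @param count Integer vector of TTS instance counts.
#' @return Factor with levels `none` (0), `1-100`, `>100`; `NA` propagates.
#' @export
tts_group <- function(count) {
  g <- ifelse(is.na(count), NA_character_,
              ifelse(count == 0, "none", ifelse(count <= 100, "1-100", ">100")))
  factor(g, levels = c("none", "1-100", ">100"))
}

#' Impute exposed-ear side for nonusers
#'
#' Nonusers have no exposed ear; for the between-ear speech-perception
#' analysis a side is assigned pseudorandomly such that the imputed
#' right/left proportions equal those observed in unilateral users
#' (57/43 by default). The right-side quota is `round(p_right * n)`
#' (half-to-even), assigned to a seeded random permutation of the ids;
#' the remainder are left.
#'
#' @param ids Vector of participant ids to impute (may be empty).
#' @param seed Integer seed; required for reproducibility.
#' @param p_right Target proportion of right-side assignments.
#' @return Named character vector (`right`/`left`) keyed by id.
#' @export
impute_device_side <- function(ids, seed, p_right = 0.57) {
  if (missing(seed)) stop_domain("a seed is required for side imputation")
  n <- length(ids)
  if (!n) return(stats::setNames(character(0), character(0)))
  n_right <- round(p_right * n)
  out <- rep("left", n)
  perm <- withr::with_seed(seed, sample.int(n))
  out[perm[seq_len(n_right)]] <- "right"
  stats::setNames(out, ids)
}

#' Build the analysis table from raw survey tables
#'
#' Joins the exposure summaries onto the participants table and derives all
#' registered analysis variables: exposure energy, weekly level, average
#' volume setting, estimated shifts, TTS instance counts and groups, the
#' exposed-ear side with imputation for nonusers, and the between-ear
#' digits-in-noise difference (`digits_diff` = exposed-ear threshold minus
#' control-ear threshold; positive means poorer performance in the exposed
#' ear).
#'
#' @param participants Participants table (validated).
#' @param segments Long career-segments table with `participant_id`.
#' @param curve A [calibration_curve()].
#' @param seed Integer seed for the side imputation.
#' @return The participants table augmented with derived columns
#'   (`device_noise`, `weekly_level`, `volume_average`,
#'   `exposure_hours_total`, `weeks_of_use`, `avg_level_during_exposure`,
#'   `shifts_estimate`, `tts_count`, `tts_group`, `device_side_full`,
#'   `digits_diff`).
#' @export
derive_variables <- function(participants, segments, curve = default_calibration(),
                             seed = 1L) {
  validate_participants(participants)
  dat <- participants
  exp_sum <- cohort_exposure(segments, curve)
  dat <- merge(dat, exp_sum, by = "participant_id", all.x = TRUE, sort = FALSE)
  nonexp <- is.na(dat$device_noise)
  dat$device_noise[nonexp] <- 0
  dat$exposure_hours_total[nonexp] <- 0
  dat$weeks_of_use[nonexp] <- 0

  shifts <- rep(0L, nrow(dat))
  if (nrow(segments)) {
    sh <- estimate_shifts_by_id(segments)
    idx <- match(names(sh), dat$participant_id)
    shifts[idx[!is.na(idx)]] <- sh[!is.na(idx)]
  }
  dat$shifts_estimate <- shifts
  dat$tts_count <- tts_count(dat$tts_prop, dat$shifts_estimate)
  dat$tts_group <- tts_group(dat$tts_count)

  dat$device_side_full <- dat$device_side
  nonuser <- dat$device_use == "nonuser"
  if (any(nonuser)) {
    imp <- impute_device_side(dat$participant_id[nonuser], seed = seed)
    dat$device_side_full[nonuser] <- unname(imp[dat$participant_id[nonuser]])
  }

  dat$digits_diff <- ifelse(
    is.na(dat$device_side_full) | is.na(dat$din_right) | is.na(dat$din_left),
    NA_real_,
    ifelse(dat$device_side_full == "right",
           dat$din_right - dat$din_left,
           dat$din_left - dat$din_right))
  dat
}

#' Registered analysis sample for each research question
#'
#' Applies the registered inclusion/exclusion rules:
#' * RQ3, RQ5 — ear-piece users only.
#' * RQ4, RQ7 — exclude nonunilateral users and unilateral users who chose
#'   their ear because of hearing loss or other pathology in the opposite
#'   ear (nonusers are retained).
#' * RQ6 — as RQ4, further restricted to users with noncentral (asymmetric)
#'   prolonged spontaneous tinnitus.
#'
#' Filtering is idempotent. Missing outcomes/predictors are handled by
#' listwise deletion at fit time, not here.
#'
#' @param data Derived analysis table (see [derive_variables()]).
#' @param analysis One of `"RQ3"`, `"RQ4"`, `"RQ5"`, `"RQ6"`, `"RQ7"`.
#' @return The filtered table, with attribute `exclusion_log`, a data frame
#'   of per-rule exclusion counts.
#' @export
analysis_sample <- function(data, analysis) {
  analysis <- match.arg(analysis, c("RQ3", "RQ4", "RQ5", "RQ6", "RQ7"))
  log <- data.frame(rule = character(0), n_excluded = integer(0))
  drop_rule <- function(d, keep, rule) {
    log <<- rbind(log, data.frame(rule = rule, n_excluded = sum(!keep)))
    d[keep, , drop = FALSE]
  }
  out <- data
  if (analysis %in% c("RQ3", "RQ5", "RQ6")) {
    out <- drop_rule(out, out$device_use != "nonuser", "nonuser")
  }
  if (analysis %in% c("RQ4", "RQ6", "RQ7")) {
    out <- drop_rule(out, out$device_use != "nonunilateral", "nonunilateral user")
    contra <- out$device_use == "unilateral" &
      !is.na(out$side_reason_contra_pathology) & out$side_reason_contra_pathology
    out <- drop_rule(out, !contra, "side chosen due to contralateral pathology")
  }
  if (analysis == "RQ6") {
    out <- drop_rule(out, out$tin_location %in%
                       c("right_only_or_mainly", "left_only_or_mainly"),
                     "no noncentral tinnitus")
  }
  attr(out, "exclusion_log") <- log
  out
}

#' Reshape to ear-wise records for the tinnitus-laterality analysis
#'
#' Each eligible participant (a unilateral user with asymmetric tinnitus)
#' contributes two rows, one per ear, with indicator columns: `ear`
#' (right/left), `exposed` (is this the ear-piece ear?) and `tin_present`
#' (is this the predominant tinnitus ear?). Exactly one row per participant
#' is exposed and exactly one is tinnitus-present.
#'
#' @param data RQ6-filtered analysis table.
#' @return Data frame of `2 * nrow(data)` ear records.
#' @export
earwise_reshape <- function(data) {
  if (!nrow(data)) {
    return(data.frame(participant_id = character(0), ear = character(0),
                      exposed = logical(0), tin_present = logical(0)))
  }
  if (any(!data$tin_location %in% c("right_only_or_mainly", "left_only_or_mainly")))
    stop_domain("earwise_reshape requires noncentral-tinnitus records (RQ6 filter)")
  if (any(data$device_use != "unilateral") || anyNA(data$device_side))
    stop_domain("earwise_reshape requires unilateral users with a reported side")
  tin_side <- ifelse(data$tin_location == "right_only_or_mainly", "right", "left")
  long <- data.frame(
    participant_id = rep(data$participant_id, each = 2),
    ear = rep(c("right", "left"), times = nrow(data)),
    exposed = as.vector(rbind(data$device_side == "right",
                              data$device_side == "left")),
    tin_present = as.vector(rbind(tin_side == "right", tin_side == "left"))
  )
  long
}

#' Quality-control filter for digits-in-noise thresholds
#'
#' Per-condition (right, left, antiphasic) means and SDs are computed once
#' over all records with complete thresholds; a participant is excluded when
#' any of their three thresholds lies strictly outside mean +/- 3 SD for its
#' condition. The rule is single-pass (statistics are not recomputed after
#' exclusion) and decided per participant: one aberrant ear removes all of
#' that participant's thresholds.
#'
#' @param data Analysis table with `din_right`, `din_left`, `din_antiphasic`.
#' @param n_sd Exclusion bound in SDs (default 3).
#' @return List with elements `kept` and `excluded` (both data frames) and
#'   `stats` (the per-condition means/SDs used).
#' @export
din_outlier_filter <- function(data, n_sd = 3) {
  cond <- c("din_right", "din_left", "din_antiphasic")
  complete <- stats::complete.cases(data[cond])
  if (sum(complete) < 2)
    stop_domain("need >= 2 complete DIN records to compute exclusion bounds")
  mu <- colMeans(data[complete, cond])
  sdv <- vapply(data[complete, cond], stats::sd, numeric(1))
  bad <- rep(FALSE, nrow(data))
  for (j in cond) {
    x <- data[[j]]
    bad <- bad | (!is.na(x) & abs(x - mu[j]) > n_sd * sdv[j])
  }
  list(kept = data[!bad, , drop = FALSE],
       excluded = data[bad, , drop = FALSE],
       stats = data.frame(condition = cond, mean = unname(mu), sd = unname(sdv)))
}
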