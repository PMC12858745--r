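# Shared fixture builders. Everything is generated in code; no stored data.

# A calibration curve whose 0->100% range is exactly linear in dB,
# convenient when a closed-form level is needed.
linear_curve <- function(lo = 60, hi = 100) {
  calibration_curve(c(0, 100), c(lo, hi))
}

# One career segment row.
seg_row <- function(years = 1, hpw = 40, prop_loud = 0.5,
                    v_loud = 75, v_normal = 50, id = NULL, index = 1L) {
  df <- data.frame(duration_years = years, hours_per_week = hpw,
                   prop_loud = prop_loud, volume_loud = v_loud,
                   volume_normal = v_normal)
  if (!is.null(id)) df <- cbind(participant_id = id, segment_index = index, df)
  df
}

# Minimal valid participants table; override columns via ...
participants_row <- function(id = "P1", device_use = "unilateral",
                             device_side = if (device_use == "unilateral") "right" else NA,
                             tts_prop = if (device_use == "nonuser") NA else "Sometimes",
                             tin_long = FALSE,
                             tin_location = if (tin_long) "central" else "none",
                             ...) {
  base <- data.frame(
    participant_id = id, age = 55, sex = "male", device_use = device_use,
    device_side = device_side,
    side_reason_contra_pathology = if (device_use == "unilateral") FALSE else NA,
    tts_prop = tts_prop, tin_long = tin_long, tin_location = tin_location,
    diagnosed_hl = FALSE, diagnosed_hl_laterality = NA_character_,
    din_right = NA_real_, din_left = NA_real_, din_antiphasic = NA_real_,
    excluded_prior_hl = FALSE, stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base
}

# Random careers for dosimetry property tests.
random_career <- function(n_segments = sample(1:4, 1)) {
  do.call(rbind, lapply(seq_len(n_segments), function(i)
    seg_row(years = runif(1, 0.2, 10), hpw = runif(1, 1, 60),
            prop_loud = runif(1), v_loud = runif(1, 0, 100),
            v_normal = runif(1, 0, 100))))
}

# Independent brute-force dosimetry oracle: chop every sub-exposure into
# <= 1 h chunks and sum per-chunk energy directly from the definition.
brute_force_noise <- function(segments, curve) {
  total <- 0
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    for (blk in list(c(s$prop_loud, s$volume_loud),
                     c(1 - s$prop_loud, s$volume_normal))) {
      h <- s$duration_years * 47 * s$hours_per_week * 0.2 * blk[1]
      if (h <= 0) next
      L <- volume_to_level(curve, blk[2])
      n_whole <- floor(h)
      frac <- h - n_whole
      per_hour <- 10^((L - 85) / 10) / 1880
      total <- total + n_whole * per_hour + frac * per_hour
    }
  }
  total
}

# Derived-table fixture for ear-wise model tests: n unilateral users with
# asymmetric tinnitus whose tinnitus side follows `p_concordant` (given the
# exposed side) or a fixed left bias when `p_left` is supplied.
earwise_cohort <- function(n, p_concordant = 0.8, p_left = NULL,
                           p_right_side = 0.57) {
  side <- ifelse(runif(n) < p_right_side, "right", "left")
  if (is.null(p_left)) {
    conc <- runif(n) < p_concordant
    tin_side <- ifelse(conc, side, ifelse(side == "right", "left", "right"))
  } else {
    tin_side <- ifelse(runif(n) < p_left, "left", "right")
  }
  data.frame(
    participant_id = sprintf("E%04d", seq_len(n)),
    age = 55, device_use = "unilateral", device_side = side,
    side_reason_contra_pathology = FALSE,
    tin_long = TRUE,
    tin_location = paste0(tin_side, "_only_or_mainly"),
    stringsAsFactors = FALSE
  )
}

quiet_generate <- function(...) suppressWarnings(generate_cohort(...))
quiet_null <- function(...) suppressWarnings(generate_null_cohort(...))
quiet_derive <- function(...) suppressWarnings(derive_variables(...))
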