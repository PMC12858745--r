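#' Simulated digits-in-noise listener
#'
#' Psychometric abstraction of a listener in the digit-triplet test. A
#' single digit at signal-to-noise ratio `snr` is recognised with
#' probability `lapse/2 + (1 - lapse) * plogis(k * (snr - T))`, where `T`
#' is the ear's digit threshold (the SNR of 50% single-digit recognition —
#' the symmetric lapse keeps the 50% point anchored at `T`) and `k` is set
#' so that the psychometric slope at threshold equals `slope` (probability
#' per dB). In the antiphasic condition the effective threshold is the
#' better (lower) monaural threshold minus `antiphasic_advantage`, a scalar
#' binaural-unmasking benefit.
#'
#' @param digit_threshold_right,digit_threshold_left Monaural digit
#'   thresholds (dB SNR).
#' @param slope Probability change per dB at threshold (> 0).
#' @param antiphasic_advantage Binaural unmasking benefit (dB, >= 0).
#' @param lapse_rate Attention-lapse probability in \[0, 0.1\].
#' @return An object of class `listener_profile`.
#' @export
listener_profile <- function(digit_threshold_right = -10,
                             digit_threshold_left = -10,
                             slope = 0.12,
                             antiphasic_advantage = 6,
                             lapse_rate = 0.01) {
  if (slope <= 0) stop_domain("slope must be > 0")
  if (antiphasic_advantage < 0) stop_domain("antiphasic_advantage must be >= 0")
  if (lapse_rate < 0 || lapse_rate > 0.1) stop_domain("lapse_rate must lie in [0, 0.1]")
  structure(list(digit_threshold_right = digit_threshold_right,
                 digit_threshold_left = digit_threshold_left,
                 slope = slope,
                 antiphasic_advantage = antiphasic_advantage,
                 lapse_rate = lapse_rate),
            class = "listener_profile")
}

#' Adaptive-track configuration
#'
#' Two-down one-up staircase: the SNR drops one step after two consecutive
#' correct trials and rises one step after any incorrect trial, converging
#' on the 70.7%-correct point. The first `turnpoints_initial` reversals use
#' `step_initial`-dB steps; subsequent reversals use `step_final`-dB steps
#' (the new step applies from the next SNR update onward). The run ends at
#' reversal `turnpoints_initial + turnpoints_final`, and threshold is the
#' mean SNR of the final `turnpoints_final` reversals.
#'
#' @param start_snr Starting SNR (dB).
#' @param step_initial,step_final Step sizes (dB, > 0).
#' @param turnpoints_initial,turnpoints_final Reversal counts for the two
#'   phases (`turnpoints_final >= 2`).
#' @param max_trials Trial budget before the run is declared nonconverged
#'   (>= 20).
#' @param snr_floor,snr_ceiling Hard SNR bounds (dB).
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(start_snr = 2, step_initial = 6, step_final = 2,
                             turnpoints_initial = 2, turnpoints_final = 4,
                             max_trials = 100, snr_floor = -30, snr_ceiling = 20) {
  if (step_initial <= 0 || step_final <= 0) stop_domain("step sizes must be > 0")
  if (turnpoints_final < 2) stop_domain("turnpoints_final must be >= 2")
  if (max_trials < 20) stop_domain("max_trials must be >= 20")
  if (snr_floor >= snr_ceiling) stop_domain("snr_floor must be below snr_ceiling")
  structure(list(start_snr = start_snr, step_initial = step_initial,
                 step_final = step_final, turnpoints_initial = turnpoints_initial,
                 turnpoints_final = turnpoints_final, max_trials = max_trials,
                 snr_floor = snr_floor, snr_ceiling = snr_ceiling),
            class = "staircase_config")
}

effective_threshold <- function(listener, condition) {
  switch(condition,
         right = listener$digit_threshold_right,
         left = listener$digit_threshold_left,
         antiphasic = min(listener$digit_threshold_right,
                          listener$digit_threshold_left) -
           listener$antiphasic_advantage,
         stop_domain("condition must be right/left/antiphasic"))
}

#' Probability of a correct digit-triplet trial
#'
#' A trial is scored correct when at least two of the three digits are
#' entered correctly; with independent per-digit recognition probability
#' `p` the trial probability is `p^3 + 3 p^2 (1 - p)`, strictly increasing
#' in SNR.
#'
#' @param listener A [listener_profile()].
#' @param snr Signal-to-noise ratio (dB), vectorised.
#' @param condition `"right"`, `"left"` or `"antiphasic"`.
#' @return Probability vector.
#' @export
trial_correct_prob <- function(listener, snr, condition = "right") {
  stopifnot(inherits(listener, "listener_profile"))
  thr <- effective_threshold(listener, condition)
  k <- 4 * listener$slope / (1 - listener$lapse_rate)
  p <- listener$lapse_rate / 2 +
    (1 - listener$lapse_rate) * stats::plogis(k * (snr - thr))
  p^3 + 3 * p^2 * (1 - p)
}

#' SNR tracked by the two-down one-up rule
#'
#' The asymptotic convergence point of a two-down one-up staircase is the
#' SNR where the trial-level probability of a correct response equals
#' `sqrt(1/2)` (about 70.7%); located by root-finding on
#' [trial_correct_prob()].
#'
#' @inheritParams trial_correct_prob
#' @return The 70.7%-correct SNR (dB).
#' @export
staircase_target_snr <- function(listener, condition = "right") {
  stats::uniroot(function(s) trial_correct_prob(listener, s, condition) - sqrt(0.5),
                 interval = c(-60, 60), tol = 1e-9)$root
}

# Core engine shared by the live run and track replay. `respond(snr, i)`
# returns TRUE/FALSE for trial i.
staircase_core <- function(respond, config) {
  snr <- config$start_snr
  step <- config$step_initial
  n_turn_total <- config$turnpoints_initial + config$turnpoints_final
  consec <- 0L
  last_dir <- 0L
  pinned <- 0L
  turn_snr <- numeric(0)
  rows <- vector("list", config$max_trials)
  status <- "nonconverged"
  for (i in seq_len(config$max_trials)) {
    correct <- respond(snr, i)
    is_turn <- FALSE
    if (correct) {
      consec <- consec + 1L
      if (consec == 2L) {
        dir <- -1L
        consec <- 0L
      } else dir <- 0L
    } else {
      consec <- 0L
      dir <- 1L
    }
    if (dir != 0L) {
      if (last_dir != 0L && dir != last_dir) {
        is_turn <- TRUE
        turn_snr <- c(turn_snr, snr)
      }
      last_dir <- dir
    }
    rows[[i]] <- c(snr = snr, correct = as.numeric(correct),
                   is_turnpoint = as.numeric(is_turn))
    if (length(turn_snr) >= n_turn_total) {
      status <- "converged"
      rows <- rows[seq_len(i)]
      break
    }
    if (is_turn && length(turn_snr) == config$turnpoints_initial) {
      step <- config$step_final  # new step applies from the next update on
    }
    if (dir != 0L) {
      new_snr <- max(config$snr_floor, min(config$snr_ceiling, snr + dir * step))
      pinned <- if (new_snr == snr &&
                    new_snr %in% c(config$snr_floor, config$snr_ceiling))
        pinned + 1L else 0L
      if (pinned > 10L) {
        status <- "degenerate"
        rows <- rows[seq_len(i)]
        break
      }
      snr <- new_snr
    }
  }
  track <- as.data.frame(do.call(rbind, rows))
  track$correct <- track$correct == 1
  track$is_turnpoint <- track$is_turnpoint == 1
  threshold <- if (status == "converged") {
    mean(utils::tail(turn_snr, config$turnpoints_final))
  } else NA_real_
  list(threshold = threshold, track = track, status = status,
       turnpoints = turn_snr)
}

#' Run one adaptive digits-in-noise track
#'
#' Simulates a seeded adaptive run for one condition. Non-convergence
#' within the trial budget, or an SNR pinned at a bound for more than 10
#' consecutive updates (a degenerate listener), yields a missing threshold
#' with the corresponding status.
#'
#' @param listener A [listener_profile()].
#' @param config A [staircase_config()].
#' @param condition `"right"`, `"left"` or `"antiphasic"`.
#' @return List: `threshold` (dB SNR or `NA`), `track` (data frame of
#'   `snr`, `correct`, `is_turnpoint` per trial), `status`
#'   (`converged`/`nonconverged`/`degenerate`), `turnpoints` (reversal SNRs).
#'   Uses the current RNG stream; seed it with [set.seed()] or [withr::with_seed()].
#' @export
run_staircase <- function(listener, config = staircase_config(),
                          condition = "right") {
  stopifnot(inherits(listener, "listener_profile"),
            inherits(config, "staircase_config"))
  staircase_core(function(snr, i) {
    stats::runif(1) < trial_correct_prob(listener, snr, condition)
  }, config)
}

#' Replay a stored track
#'
#' Recomputes every SNR update, turnpoint flag and the threshold from the
#' stored trial-by-trial correctness alone, verifying that the recorded SNR
#' sequence is reproduced exactly. Used to audit stored tracks.
#'
#' @param track Data frame from [run_staircase()].
#' @param config The [staircase_config()] used for the original run.
#' @return As [run_staircase()]; errors if the stored SNR sequence cannot
#'   be reproduced.
#' @export
replay_staircase <- function(track, config = staircase_config()) {
  res <- staircase_core(function(snr, i) {
    if (abs(snr - track$snr[i]) > 1e-12)
      stop_domain("replay diverged from stored track at trial ", i)
    track$correct[i]
  }, config)
  res
}

#' Simulate a full test battery
#'
#' Runs an unscored antiphasic practice track, then the two monaural blocks
#' in randomized order, then the scored antiphasic block, mirroring the
#' block structure of the online test.
#'
#' @param listener A [listener_profile()].
#' @param config A [staircase_config()].
#' @param seed Integer seed making the battery reproducible.
#' @return List: `din_right`, `din_left`, `din_antiphasic` (dB SNR, `NA`
#'   when a block failed to converge), `block_order` (scored blocks in
#'   presentation order), `converged` (named logical), `ear_tested_first`.
#' @export
simulate_battery <- function(listener, config = staircase_config(), seed) {
  if (missing(seed)) stop_domain("a seed is required for a reproducible battery")
  withr::with_seed(seed, {
    invisible(run_staircase(listener, config, "antiphasic"))  # practice, discarded
    mono <- sample(c("right", "left"))
    runs <- lapply(c(mono, "antiphasic"), function(cond)
      run_staircase(listener, config, cond))
    names(runs) <- c(mono, "antiphasic")
    list(
      din_right = runs$right$threshold,
      din_left = runs$left$threshold,
      din_antiphasic = runs$antiphasic$threshold,
      block_order = c(mono, "antiphasic"),
      converged = vapply(runs, function(r) r$status == "converged", logical(1)),
      ear_tested_first = mono[1]
    )
  })
}
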