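test_that("participant validation enforces the cross-field invariants", {
  expect_silent(validate_participants(participants_row()))
  # side present for a nonuser
  expect_error(validate_participants(
    participants_row(device_use = "nonuser", device_side = "right",
                     tts_prop = NA)), "device_side")
  # unilateral user without a side
  expect_error(validate_participants(
    participants_row(device_side = NA)), "device_side")
  # tinnitus location inconsistent with tinnitus presence
  expect_error(validate_participants(
    participants_row(tin_long = TRUE, tin_location = "none")), "tin_location")
  expect_error(validate_participants(
    participants_row(tin_long = FALSE, tin_location = "central")), "tin_location")
  # TTS response from a nonuser
  expect_error(validate_participants(
    participants_row(device_use = "nonuser", device_side = NA,
                     tts_prop = "Sometimes")), "nonuser")
  expect_error(validate_participants(
    participants_row(tts_prop = "Rarely")), "tts_prop")
})

test_that("shift estimation follows the capped-shifts formula", {
  expect_equal(estimate_shifts(seg_row(years = 1, hpw = 40)), 235L)
  expect_equal(estimate_shifts(seg_row(years = 2, hpw = 4)), 47L)
  expect_equal(estimate_shifts(seg_row()[0, ]), 0L)
  # cap at 5 shifts/week: 60 h/wk counts the same as 40 h/wk
  expect_equal(estimate_shifts(seg_row(years = 1, hpw = 60)),
               estimate_shifts(seg_row(years = 1, hpw = 40)))
  # configurable shift pattern
  expect_equal(estimate_shifts(seg_row(years = 1, hpw = 48),
                               shift_hours = 12, max_shifts_per_week = 4),
               188L)
})

test_that("TTS instance counts combine response option with shifts", {
  expect_equal(tts_count("Never", 500L), 0L)
  expect_equal(tts_count("Every time", 235L), 235L)
  expect_equal(tts_count("About half the time", 200L), 100L)
  expect_equal(tts_count("Sometimes", 235L), 59L)   # 58.75 rounds half-up
  expect_equal(tts_count("Most of the time", 2L), 2L)  # 1.5 rounds up
  expect_true(is.na(tts_count(NA_character_, 100L)))
  expect_error(tts_count("Often", 10L), "tts_prop")
})

test_that("TTS grouping respects the registered boundaries", {
  g <- tts_group(c(0L, 1L, 100L, 101L, 5000L, NA))
  expect_equal(as.character(g), c("none", "1-100", "1-100", ">100", ">100", NA))
  expect_equal(levels(g), c("none", "1-100", ">100"))
})

test_that("side imputation hits the quota deterministically", {
  ids <- sprintf("N%03d", 1:100)
  a <- impute_device_side(ids, seed = 5)
  expect_equal(sum(a == "right"), 57)
  expect_equal(sum(a == "left"), 43)
  expect_identical(a, impute_device_side(ids, seed = 5))
  b <- impute_device_side(ids, seed = 6)
  expect_equal(sum(b == "right"), 57)
  expect_false(identical(a, b))
  expect_length(impute_device_side(character(0), seed = 1), 0)
  # round-half-even quota
  expect_equal(sum(impute_device_side(sprintf("x%d", 1:50), seed = 1) == "right"),
               28)  # 0.57*50 = 28.5 -> 28
  expect_error(impute_device_side(ids), "seed")
})

test_that("analysis samples implement the registered exclusion rules", {
  dat <- rbind(
    participants_row("A", device_use = "nonuser", device_side = NA, tts_prop = NA),
    participants_row("B", device_use = "unilateral"),
    participants_row("C", device_use = "nonunilateral", device_side = NA),
    participants_row("D", device_use = "unilateral",
                     side_reason_contra_pathology = TRUE,
                     tin_long = TRUE, tin_location = "right_only_or_mainly"),
    participants_row("E", device_use = "unilateral", tin_long = TRUE,
                     tin_location = "left_only_or_mainly"),
    participants_row("F", device_use = "unilateral", tin_long = TRUE,
                     tin_location = "central")
  )
  ids <- function(x) x$participant_id
  expect_setequal(ids(analysis_sample(dat, "RQ3")), c("B", "C", "D", "E", "F"))
  expect_setequal(ids(analysis_sample(dat, "RQ5")), c("B", "C", "D", "E", "F"))
  expect_setequal(ids(analysis_sample(dat, "RQ4")), c("A", "B", "E", "F"))
  expect_setequal(ids(analysis_sample(dat, "RQ7")), c("A", "B", "E", "F"))
  expect_setequal(ids(analysis_sample(dat, "RQ6")), "E")
  expect_error(analysis_sample(dat, "RQ9"))
  # idempotence
  once <- analysis_sample(dat, "RQ6")
  twice <- analysis_sample(once, "RQ6")
  expect_equal(ids(twice), ids(once))
  # exclusion log accounts for every dropped record
  log <- attr(analysis_sample(dat, "RQ6"), "exclusion_log")
  expect_equal(sum(log$n_excluded), nrow(dat) - 1)
})

test_that("ear-wise reshape maps sides and conserves rows", {
  dat <- rbind(
    participants_row("R1", tin_long = TRUE, tin_location = "left_only_or_mainly"),
    participants_row("R2", tin_long = TRUE, tin_location = "right_only_or_mainly")
  )
  ears <- earwise_reshape(dat)
  expect_equal(nrow(ears), 4)
  expect_equal(sum(ears$tin_present), 2)
  expect_equal(sum(ears$exposed), 2)
  # right-side user with left-mainly tinnitus: exposed ear is tinnitus-free
  r1 <- ears[ears$participant_id == "R1", ]
  expect_true(r1$exposed[r1$ear == "right"])
  expect_true(r1$tin_present[r1$ear == "left"])
  expect_false(r1$tin_present[r1$ear == "right"])
  # right-side user with right-only tinnitus: exposed ear carries it
  r2 <- ears[ears$participant_id == "R2", ]
  expect_true(r2$tin_present[r2$ear == "right"] && r2$exposed[r2$ear == "right"])
  # per-participant invariants: one exposed, one tinnitus ear each
  per <- split(ears, ears$participant_id)
  expect_true(all(vapply(per, function(p)
    sum(p$exposed) == 1 && sum(p$tin_present) == 1, logical(1))))
  # laterality table round-trips through the reshape
  collapsed <- vapply(per, function(p) p$ear[p$tin_present], character(1))
  expect_equal(unname(collapsed[c("R1", "R2")]), c("left", "right"))
  # central tinnitus reaching the reshape is a contract violation
  expect_error(earwise_reshape(
    participants_row("X", tin_long = TRUE, tin_location = "central")),
    "noncentral")
})

test_that("digits difference uses the exposed-minus-control convention", {
  p <- rbind(
    participants_row("D1", din_right = -6, din_left = -8, din_antiphasic = -14),
    participants_row("D2", device_side = "left", din_right = -6, din_left = -8,
                     din_antiphasic = -14),
    participants_row("D3", din_right = -8, din_left = -8, din_antiphasic = -14),
    participants_row("D4")
  )
  d <- derive_variables(p, seg_row(id = "D1")[0, ], seed = 1)
  dd <- setNames(d$digits_diff, d$participant_id)
  expect_equal(unname(dd["D1"]), 2)     # exposed right worse by 2 dB
  expect_equal(unname(dd["D2"]), -2)    # swapped side flips the sign
  expect_equal(unname(dd["D3"]), 0)
  expect_true(is.na(dd["D4"]))          # missing thresholds propagate
})

test_that("derived table imputes sides for nonusers only", {
  set.seed(2)
  n <- 60
  p <- do.call(rbind, lapply(seq_len(n), function(i)
    participants_row(sprintf("P%03d", i),
                     device_use = if (i <= 30) "nonuser" else "unilateral",
                     device_side = if (i <= 30) NA else "left",
                     tts_prop = if (i <= 30) NA else "Never")))
  d <- derive_variables(p, seg_row(id = "x")[0, ], seed = 3)
  expect_true(all(!is.na(d$device_side_full)))
  expect_true(all(d$device_side_full[d$device_use == "unilateral"] == "left"))
  imp <- d$device_side_full[d$device_use == "nonuser"]
  expect_equal(sum(imp == "right"), round(0.57 * 30))
  # users' reported sides are never altered
  expect_identical(d$device_side[d$device_use == "unilateral"],
                   p$device_side[p$device_use == "unilateral"])
})

test_that("3-SD QC rule is single-pass and participant-level", {
  make <- function(n, shift_id = NULL, shift_col = "din_right", shift = 0) {
    p <- do.call(rbind, lapply(seq_len(n), function(i)
      participants_row(sprintf("Q%03d", i),
                       din_right = -9 + (i %% 7) * 0.3,
                       din_left = -9 + (i %% 5) * 0.3,
                       din_antiphasic = -15 + (i %% 6) * 0.3)))
    if (!is.null(shift_id)) p[[shift_col]][shift_id] <- shift
    p
  }
  # identical thresholds: SD 0, nothing excluded
  same <- do.call(rbind, lapply(1:10, function(i)
    participants_row(sprintf("S%02d", i), din_right = -9, din_left = -9,
                     din_antiphasic = -15)))
  res <- din_outlier_filter(same)
  expect_equal(nrow(res$excluded), 0)
  # a planted threshold at mean + 5 SD of the others is excluded
  base <- make(40)
  mu <- mean(base$din_right); s <- sd(base$din_right)
  bad <- make(40, shift_id = 7, shift = mu + 5 * s)
  res2 <- din_outlier_filter(bad)
  expect_equal(res2$excluded$participant_id, "Q007")
  # verification by direct computation against the filter's own bounds
  st <- res2$stats
  lim <- st$mean[st$condition == "din_right"] + 3 * st$sd[st$condition == "din_right"]
  expect_gt(bad$din_right[7], lim)
  # one bad ear removes the whole participant (all three thresholds)
  expect_false("Q007" %in% res2$kept$participant_id)
  # bounds are computed once over all complete records, outlier included
  expect_equal(st$mean[st$condition == "din_right"], mean(bad$din_right))
  expect_error(din_outlier_filter(same[1, ]), "complete")
})
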