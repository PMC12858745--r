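# CSV conventions throughout: UTF-8, comma-separated, mandatory header,
# '.' decimal, empty field = missing.

#' Read a participants table from CSV
#'
#' Parses and validates the survey participants schema. Logical columns
#' accept TRUE/FALSE; empty cells are missing. Extra columns (such as
#' `ear_tested_first`) are carried through.
#'
#' @param path Path to a CSV file.
#' @return Validated participants data frame.
#' @export
read_participants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  for (col in c("side_reason_contra_pathology", "tin_long", "diagnosed_hl",
                "excluded_prior_hl")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df$participant_id <- as.character(df$participant_id)
  validate_participants(df)
  df
}

#' Read a career-segments table from CSV
#'
#' @param path Path to a CSV file with columns `participant_id`,
#'   `segment_index`, `duration_years`, `hours_per_week`, `prop_loud`,
#'   `volume_loud`, `volume_normal`.
#' @return Validated long segments data frame.
#' @export
read_segments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  df$participant_id <- as.character(df$participant_id)
  validate_segments(df)
  df
}

#' Write a generated cohort to CSV files
#'
#' @param cohort A list from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (`participants.csv`,
#'   `segments.csv`, `truth.json`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(participants = file.path(dir, "participants.csv"),
             segments = file.path(dir, "segments.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(cohort$participants, paths["participants"],
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$segments, paths["segments"],
                   row.names = FALSE, na = "")
  truth <- cohort$truth
  truth$config$curve <- list(volume_percent = truth$config$curve$volume_percent,
                             level = truth$config$curve$level)
  truth$config <- truth$config[!vapply(truth$config, is.function, logical(1))]
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Validate survey input files
#'
#' Runs the schema/range validators over the three input tables and applies
#' survey-consistency rules, flagging (not dropping) offending records. The
#' default consistency rule marks a participant inconsistent when their
#' total reported career years exceed `max_career_years` (25 by default).
#'
#' @param participants Participants data frame or CSV path.
#' @param segments Segments data frame or CSV path.
#' @param calibration A [calibration_curve()] or CSV path.
#' @param max_career_years Consistency cap on total career years.
#' @return List: `ok` (logical), `flags` (data frame of participant_id /
#'   rule), `counts` (rows read per table).
#' @export
validate_survey <- function(participants, segments,
                            calibration = default_calibration(),
                            max_career_years = 25) {
  if (is.character(participants)) participants <- read_participants(participants)
  else validate_participants(participants)
  if (is.character(segments)) segments <- read_segments(segments)
  else validate_segments(segments)
  if (is.character(calibration)) calibration <- read_calibration(calibration)
  stopifnot(inherits(calibration, "calibration_curve"))

  orphan <- setdiff(segments$participant_id, participants$participant_id)
  flags <- data.frame(participant_id = character(0), rule = character(0))
  if (length(orphan))
    flags <- rbind(flags, data.frame(participant_id = orphan,
                                     rule = "segments without participant record"))
  seg_users <- participants$device_use[match(segments$participant_id,
                                             participants$participant_id)]
  bad_nonuser <- unique(segments$participant_id[!is.na(seg_users) &
                                                  seg_users == "nonuser"])
  if (length(bad_nonuser))
    flags <- rbind(flags, data.frame(participant_id = bad_nonuser,
                                     rule = "career segments reported by a nonuser"))
  if (nrow(segments)) {
    yrs <- rowsum(segments$duration_years, segments$participant_id)
    over <- rownames(yrs)[yrs[, 1] > max_career_years]
    if (length(over))
      flags <- rbind(flags, data.frame(
        participant_id = over,
        rule = paste0("total career years exceed ", max_career_years)))
  }
  list(ok = nrow(flags) == 0L, flags = flags,
       counts = c(participants = nrow(participants), segments = nrow(segments),
                  calibration_anchors = length(calibration$volume_percent)))
}

#' Build a run manifest
#'
#' Records input-file digests, configuration digest, seeds and per-stage
#' row counts so that every reported sample size is auditable and two runs
#' with identical inputs produce identical manifests.
#'
#' @param input_paths Named character vector of input file paths.
#' @param seed Integer seed(s) used.
#' @param counts Named vector/list of per-stage row counts
#'   (read / excluded / analysed).
#' @param config Optional configuration object to digest.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(input_paths = character(0), seed = NA_integer_,
                         counts = list(), config = NULL) {
  digests <- if (length(input_paths)) {
    vapply(input_paths, function(p) unname(tools::md5sum(p)), character(1))
  } else character(0)
  cfg_digest <- if (!is.null(config)) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(paste(utils::capture.output(utils::str(config)), collapse = "\n"), tf)
    unname(tools::md5sum(tf))
  } else NA_character_
  structure(list(input_digests = digests, config_digest = cfg_digest,
                 seed = seed, counts = counts,
                 package_version = as.character(utils::packageVersion("earnoise"))),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Run manifest (earnoise ", x$package_version, ")\n", sep = "")
  cat("seed:", x$seed, "\n")
  if (length(x$input_digests)) {
    cat("inputs:\n")
    for (nm in names(x$input_digests))
      cat("  ", nm, ": ", x$input_digests[[nm]], "\n", sep = "")
  }
  if (length(x$counts)) {
    cat("counts:\n")
    for (nm in names(x$counts)) cat("  ", nm, ": ", x$counts[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Run the full pipeline from files
#'
#' Reads and validates the input CSVs, runs the requested analyses, and
#' writes per-analysis JSON results, tidy CSV estimate tables, figures and
#' a run manifest to `out_dir`.
#'
#' @param participants_csv,segments_csv Paths to the input tables.
#' @param calibration_csv Optional path to a calibration CSV; defaults to
#'   the built-in curve.
#' @param analyses Analyses to run (`"all"` or a subset of RQ1..RQ7).
#' @param seed Integer seed.
#' @param out_dir Output directory; `NULL` suppresses writing.
#' @param figures Write figure PDFs as well?
#' @return The list of analysis results, with the manifest as an attribute.
#' @export
analyse_files <- function(participants_csv, segments_csv,
                          calibration_csv = NULL, analyses = "all",
                          seed = 1L, out_dir = NULL, figures = TRUE) {
  participants <- read_participants(participants_csv)
  segments <- read_segments(segments_csv)
  curve <- if (is.null(calibration_csv)) default_calibration()
  else read_calibration(calibration_csv)
  val <- validate_survey(participants, segments, curve)
  if (!val$ok)
    warning(nrow(val$flags), " consistency flag(s); see validate_survey()",
            call. = FALSE)
  res <- run_analyses(participants, segments, curve, analyses = analyses,
                      seed = seed)
  paths <- c(participants = unname(participants_csv),
             segments = unname(segments_csv))
  if (!is.null(calibration_csv))
    paths <- c(paths, calibration = unname(calibration_csv))
  manifest <- run_manifest(paths, seed = seed,
                           counts = c(val$counts,
                                      analysed = vapply(res, function(r)
                                        r$n_used %||% r$n %||% NA_integer_,
                                        numeric(1))))
  attr(res, "manifest") <- manifest
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res)) {
      r <- res[[nm]]
      if (inherits(r, "fit_result")) {
        utils::write.csv(r$estimates, file.path(out_dir, paste0(nm, "_estimates.csv")),
                         row.names = FALSE)
        slim <- r[c("analysis_id", "n_used", "estimates", "scale", "flags")]
        jsonlite::write_json(slim, file.path(out_dir, paste0(nm, ".json")),
                             auto_unbox = TRUE, digits = NA, force = TRUE)
      } else {
        jsonlite::write_json(r, file.path(out_dir, paste0(nm, ".json")),
                             auto_unbox = TRUE, digits = NA, force = TRUE)
      }
    }
    jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (figures) write_figures(attr(res, "derived"), out_dir)
  }
  res
}
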