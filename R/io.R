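#' @title Readers and writers for the artifact formats
#' @description
#' Delimited-text formats for session logs, SV profiles, study tables and
#' EMG recordings, plus a JSON session export with a schema version field.
#' Reading validates against the documented schemas and reports offending
#' line numbers; `write` followed by `read` is the identity on valid files.
#' @name io
NULL

SESSION_LOG_COLUMNS <- c("participant_id", "phase", "pair_id",
                         "presentation_index", "left_strategy",
                         "right_strategy", "left_value", "right_value",
                         "chosen")
SESSION_SCHEMA_VERSION <- "1.0"

#' Write a session log to CSV
#'
#' @param session A `session_log` (or its `records` data frame).
#' @param path Output file.
#' @export
write_session_log <- function(session, path) {
  records <- if (inherits(session, "session_log")) session$records else session
  stopifnot(identical(names(records), SESSION_LOG_COLUMNS))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a session log CSV
#'
#' Checks the column schema, strategy labels, phase structure (3 equal +
#' 6 titration presentations per pair, indices 1-9 in order), the monetary
#' ranges (equal rounds at 1.00/1.00; titration anchored at 2.00 with the
#' flexible value in `[0.03, 1.97]`) and that every chosen label is one of
#' the two offered.  Violations are reported with file line numbers.
#'
#' @param path CSV file written by [write_session_log()].
#' @return The validated records data frame.
#' @export
read_session_log <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(records), SESSION_LOG_COLUMNS)) {
    stop("schema violation in ", path, ": expected columns ",
         paste(SESSION_LOG_COLUMNS, collapse = ", "), call. = FALSE)
  }
  line <- seq_len(nrow(records)) + 1L  # header is line 1
  fail <- function(rows, msg) {
    stop("validation error in ", path, " (line ",
         paste(line[rows], collapse = ", "), "): ", msg, call. = FALSE)
  }
  bad <- !(records$left_strategy %in% strategies()) |
    !(records$right_strategy %in% strategies()) |
    !(records$chosen %in% strategies())
  if (any(bad)) fail(which(bad), "unknown strategy label")
  bad <- records$chosen != records$left_strategy &
    records$chosen != records$right_strategy
  if (any(bad)) fail(which(bad), "chosen strategy is not one of the offer")
  eq <- records$phase == "equal"
  bad <- eq & (records$left_value != 1 | records$right_value != 1)
  if (any(bad)) fail(which(bad), "equal-round values must both be 1.00")
  ti <- records$phase == "titration"
  flex_val <- ifelse(records$left_value == 2, records$right_value,
                     records$left_value)
  fixed_val <- ifelse(records$left_value == 2, records$left_value,
                      records$right_value)
  bad <- ti & fixed_val != 2
  if (any(bad)) fail(which(bad), "titration offers must anchor one side at 2.00")
  bad <- ti & (flex_val < 0.03 | flex_val > 1.97)
  if (any(bad)) fail(which(bad),
                     "flexible value outside the titration range [0.03, 1.97]")
  for (pp in split(seq_len(nrow(records)),
                   list(records$participant_id, records$pair_id), drop = TRUE)) {
    idx <- records$presentation_index[pp]
    if (length(pp) != 9L || !identical(as.integer(idx), 1:9)) {
      fail(pp[1], "each pair needs presentations 1-9 in order (3 equal + 6 titration)")
    }
    if (!identical(records$phase[pp], c(rep("equal", 3), rep("titration", 6)))) {
      fail(pp[1], "phase must be equal for presentations 1-3 and titration for 4-9")
    }
  }
  records
}

#' Export a session log as structured JSON
#'
#' Same content as the CSV log plus a `schema_version` field.
#'
#' @param session A `session_log` or records data frame.
#' @param path Output file.
#' @export
write_session_json <- function(session, path) {
  records <- if (inherits(session, "session_log")) session$records else session
  jsonlite::write_json(
    list(schema_version = SESSION_SCHEMA_VERSION, records = records),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a JSON session export
#'
#' @param path File written by [write_session_json()].
#' @return The records data frame.
#' @export
read_session_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version)) {
    stop("schema violation: missing schema_version", call. = FALSE)
  }
  obj$records
}

#' Write / read the SV profile table
#'
#' @param profile_table Data frame from [sv_profile_table()].
#' @param path CSV file.
#' @export
write_sv_profiles <- function(profile_table, path) {
  utils::write.csv(profile_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sv_profiles
#' @export
read_sv_profiles <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the long-format study table
#'
#' @param study_table Trial-level table from [generate_study()].
#' @param path CSV file.
#' @export
write_study_table <- function(study_table, path) {
  utils::write.csv(study_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a raw EMG recording as delimited text
#'
#' The signal file starts with a `# sampling_rate: <Hz>` header line
#' followed by two tab-separated columns (corrugator, levator, in mV);
#' events go to a companion CSV with `onset_sample` and `condition`.
#'
#' @param recording An [emg_recording()].
#' @param signal_path,events_path Output files.
#' @export
write_emg_recording <- function(recording, signal_path, events_path) {
  stopifnot(inherits(recording, "emg_recording"))
  con <- file(signal_path, "w")
  on.exit(close(con))
  writeLines(paste0("# sampling_rate: ", recording$sampling_rate), con)
  utils::write.table(
    data.frame(corrugator = recording$corrugator,
               levator = recording$levator),
    con, sep = "\t", row.names = FALSE, quote = FALSE
  )
  utils::write.csv(recording$events, events_path, row.names = FALSE,
                   quote = FALSE)
  invisible(signal_path)
}

#' @rdname write_emg_recording
#' @export
read_emg_recording <- function(signal_path, events_path) {
  header <- readLines(signal_path, n = 1)
  m <- regmatches(header, regexec("^# sampling_rate: *([0-9.]+)$", header))[[1]]
  if (length(m) != 2) {
    stop("schema violation in ", signal_path,
         " (line 1): expected '# sampling_rate: <Hz>'", call. = FALSE)
  }
  sig <- utils::read.table(signal_path, header = TRUE, sep = "\t", skip = 1)
  events <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  emg_recording(sig$corrugator, sig$levator,
                sampling_rate = as.numeric(m[2]), events = events)
}

#' Seeded run configuration
#'
#' A single top-level seed plus generator and analysis options; serializes
#' losslessly through JSON.
#'
#' @param seed Integer master seed.
#' @param n Cohort size.
#' @param granularity `"trial"` or `"condition"` rows for the study table.
#' @param adjust Post-hoc adjustment method.
#' @param out_dir Output directory for CLI runs.
#' @param generator Optional named list of [study_config()] overrides.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, n = 120, granularity = c("trial", "condition"),
                       adjust = c("tukey", "bonferroni"), out_dir = ".",
                       generator = list()) {
  granularity <- match.arg(granularity)
  adjust <- match.arg(adjust)
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 granularity = granularity, adjust = adjust,
                 out_dir = out_dir, generator = generator),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, obj)
}
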