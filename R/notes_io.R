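#' Construct a developmental song dataset
#'
#' A `song_dev` object holds every detected note of one bird across an
#' intermittently recorded development, as a single note table plus the
#' reference (final) recording day used by the proficiency analyses.
#'
#' @param notes data.frame with columns `recording_id` (integer serial in
#'   recorded order), `day` (integer days post-hatch), `onset` (ms from
#'   recording start), `duration` (ms), and optionally `hour` (clock hour of
#'   the recording, numeric) and `label` (note-type character). Rows are
#'   re-sorted by (day, recording_id, onset).
#' @param bird_id character identifier.
#' @param final_day reference day for proficiency; defaults to the last
#'   recorded day.
#'
#' @return An object of class `song_dev`: a list with elements `bird_id`,
#'   `notes` and `final_day`.
#' @export
song_dev <- function(notes, bird_id = "bird", final_day = NULL) {
  required <- c("recording_id", "day", "onset", "duration")
  missing_cols <- setdiff(required, names(notes))
  if (length(missing_cols)) {
    stop("note table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"hour" %in% names(notes)) notes$hour <- rep(NA_real_, nrow(notes))
  if (!"label" %in% names(notes)) {
    notes$label <- rep(NA_character_, nrow(notes))
  }
  notes <- notes[, c("recording_id", "day", "onset", "duration", "hour", "label")]
  notes$recording_id <- as.integer(notes$recording_id)
  notes$day <- as.integer(notes$day)
  notes$onset <- as.numeric(notes$onset)
  notes$duration <- as.numeric(notes$duration)
  if (nrow(notes)) {
    if (any(notes$onset < 0, na.rm = TRUE)) stop("onsets must be >= 0")
    if (any(notes$duration <= 0, na.rm = TRUE)) stop("durations must be > 0")
    day_per_rec <- tapply(notes$day, notes$recording_id, function(d) length(unique(d)))
    if (any(day_per_rec > 1)) stop("a recording_id spans more than one day")
    notes <- notes[order(notes$day, notes$recording_id, notes$onset), ,
                   drop = FALSE]
    rownames(notes) <- NULL
    dup <- stats::ave(notes$onset, notes$recording_id,
                      FUN = function(o) c(1, diff(o)))
    if (any(dup[duplicated(notes$recording_id)] <= 0)) {
      stop("onsets must be strictly increasing within a recording")
    }
  }
  if (is.null(final_day)) {
    final_day <- if (nrow(notes)) max(notes$day) else NA_integer_
  }
  structure(list(bird_id = as.character(bird_id), notes = notes,
                 final_day = as.integer(final_day)),
            class = "song_dev")
}

#' @export
print.song_dev <- function(x, ...) {
  cat(sprintf("<song_dev> bird %s: %d notes, %d recordings, %d days",
              x$bird_id, nrow(x$notes),
              length(unique(x$notes$recording_id)),
              length(unique(x$notes$day))))
  if (nrow(x$notes)) {
    cat(sprintf(" (%d-%d post-hatch), final day %d",
                min(x$notes$day), max(x$notes$day), x$final_day))
  }
  cat("\n")
  invisible(x)
}

#' @export
recording_days <- function(ds) UseMethod("recording_days")

#' Recording days of a dataset
#' @param ds a `song_dev` object.
#' @return sorted integer vector of days post-hatch with notes.
#' @export
recording_days.song_dev <- function(ds) sort(unique(ds$notes$day))

# canonical column names of the on-disk note table
.note_table_cols <- c(recording_id = "recording_id", day = "day",
                      onset = "onset_ms", duration = "duration_ms",
                      timestamp = "timestamp", label = "label")

#' Read a delimited note-event table
#'
#' Parses one-note-per-row tables as produced by external note-detection
#' software. Mandatory columns: recording id, day post-hatch, onset (ms) and
#' duration (ms); a wall-clock timestamp (ISO-8601, hour resolution is
#' enough) and a note label are optional. Rows whose onset or duration fail
#' to parse are dropped and counted, not fatal: field recordings are messy
#' and dataset-level validity is what matters.
#'
#' @param path file path of a delimited text table with one header row.
#' @param sep field separator; `NULL` (default) picks "," for `.csv` paths
#'   and tab otherwise.
#' @param dialect named character vector mapping the canonical names
#'   (`recording_id`, `day`, `onset`, `duration`, `timestamp`, `label`) to
#'   the file's column names, for feature-table dialects that use different
#'   headers. Unmentioned names keep the defaults
#'   (`recording_id`, `day`, `onset_ms`, `duration_ms`, `timestamp`, `label`).
#' @param bird_id,final_day passed to [song_dev()]; `bird_id` defaults to a
#'   `bird_id` column if present, else the file stem.
#'
#' @return a [song_dev()] dataset with attribute `load_report`, a list with
#'   `rows_read`, `rows_dropped`, `n_recordings`, `n_days` (see
#'   [load_report()]).
#' @export
read_note_table <- function(path, sep = NULL, dialect = NULL,
                            bird_id = NULL, final_day = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  cols <- .note_table_cols
  if (!is.null(dialect)) {
    unknown <- setdiff(names(dialect), names(cols))
    if (length(unknown)) stop("unknown dialect key(s): ",
                              paste(unknown, collapse = ", "))
    cols[names(dialect)] <- dialect
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) stop("empty note table: ", path)
  mandatory <- cols[c("recording_id", "day", "onset", "duration")]
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop("note table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  rows_read <- nrow(raw)
  onset <- suppressWarnings(as.numeric(raw[[cols[["onset"]]]]))
  duration <- suppressWarnings(as.numeric(raw[[cols[["duration"]]]]))
  rec <- suppressWarnings(as.integer(raw[[cols[["recording_id"]]]]))
  day <- suppressWarnings(as.integer(raw[[cols[["day"]]]]))
  ok <- !(is.na(onset) | is.na(duration) | is.na(rec) | is.na(day)) &
    onset >= 0 & duration > 0
  dropped <- sum(!ok)
  notes <- data.frame(recording_id = rec[ok], day = day[ok],
                      onset = onset[ok], duration = duration[ok])
  ts_col <- cols[["timestamp"]]
  notes$hour <- if (ts_col %in% names(raw)) {
    .iso_hour(raw[[ts_col]][ok])
  } else rep(NA_real_, nrow(notes))
  lab_col <- cols[["label"]]
  notes$label <- if (lab_col %in% names(raw)) {
    as.character(raw[[lab_col]][ok])
  } else rep(NA_character_, nrow(notes))
  if (is.null(bird_id)) {
    bird_id <- if ("bird_id" %in% names(raw) && nrow(notes)) {
      raw$bird_id[ok][1]
    } else sub("\\.[^.]*$", "", basename(path))
  }
  ds <- song_dev(notes, bird_id = bird_id, final_day = final_day)
  attr(ds, "load_report") <- list(
    rows_read = rows_read, rows_dropped = dropped,
    n_recordings = length(unique(ds$notes$recording_id)),
    n_days = length(unique(ds$notes$day)))
  ds
}

# hour of day from ISO-8601-ish timestamps; NA where unparsable
.iso_hour <- function(ts) {
  hh <- suppressWarnings(as.numeric(sub("^.*[T ](\\d{1,2}).*$", "\\1", ts)))
  hh[hh < 0 | hh > 23] <- NA_real_
  hh
}

#' Load report of a parsed note table
#'
#' @param ds a dataset returned by [read_note_table()].
#' @return list with `rows_read`, `rows_dropped`, `n_recordings`, `n_days`.
#' @export
load_report <- function(ds) attr(ds, "load_report")

#' Write a dataset back to the note-table format
#'
#' Inverse of [read_note_table()]: `read_note_table(write_note_table(ds, f))`
#' reproduces `ds` exactly. Timestamps are written as ISO-8601 with the day
#' post-hatch encoded as a synthetic date offset so the clock hour survives a
#' round trip.
#'
#' @param ds a [song_dev()] dataset.
#' @param path output file path.
#' @param sep field separator; `NULL` picks by extension as in
#'   [read_note_table()].
#' @return `path`, invisibly.
#' @export
write_note_table <- function(ds, path, sep = NULL) {
  stopifnot(inherits(ds, "song_dev"))
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  n <- ds$notes
  out <- data.frame(bird_id = rep(ds$bird_id, nrow(n)),
                    recording_id = n$recording_id, day = n$day,
                    onset_ms = n$onset, duration_ms = n$duration,
                    timestamp = ifelse(is.na(n$hour), "",
                                       sprintf("2000-01-01T%02d:00:00", as.integer(n$hour))),
                    label = ifelse(is.na(n$label), "", n$label))
  if (nrow(out) == 0) {
    out <- out[0, , drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write note table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Remove noise notes by duration
#'
#' Detected sounds shorter than 15 ms or longer than 350 ms are mostly noise
#' in songbird recordings; removing them before interval computation improves
#' the accuracy of the IOI measurements. Both bounds are inclusive; the
#' recording structure is preserved (a recording whose notes are all removed
#' simply contributes no events).
#'
#' @param ds a [song_dev()] dataset.
#' @param min_dur,max_dur keep notes with `min_dur <= duration <= max_dur`
#'   (ms). Defaults 15 and 350.
#' @return the filtered dataset, with attribute `n_removed`.
#' @export
filter_notes <- function(ds, min_dur = 15, max_dur = 350) {
  stopifnot(inherits(ds, "song_dev"))
  if (!(min_dur >= 0 && min_dur < max_dur)) {
    stop("need 0 <= min_dur < max_dur")
  }
  keep <- ds$notes$duration >= min_dur & ds$notes$duration <= max_dur
  out <- ds
  out$notes <- ds$notes[keep, , drop = FALSE]
  rownames(out$notes) <- NULL
  if (nrow(out$notes) == 0 && nrow(ds$notes) > 0) {
    warning("all notes removed by the duration filter")
  }
  attr(out, "n_removed") <- sum(!keep)
  out
}
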