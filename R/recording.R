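#' Construct a continuous multichannel sEMG recording
#'
#' A `Recording` bundles a channels-by-samples signal matrix (microvolts) with
#' its sampling rate, the cue schedule used to label it, and acquisition
#' metadata.  Sample indices in the schedule are 0-based and intervals are
#' half-open `[start, end)`, which keeps window arithmetic unambiguous.
#'
#' @param signal Numeric matrix `[n_channels x n_samples]`, microvolts.
#' @param fs Sampling rate in Hz (2048 for Nearlab-style acquisitions,
#'   2000 for Ninapro-style).
#' @param schedule Data frame with columns `label`, `phase`
#'   (one of `"rest"`, `"preparation"`, `"movement"`), `start`, `end`
#'   (0-based, half-open), and optionally `repetition` and `orientation`.
#' @param subject_id Subject token.
#' @param orientation Hand orientation of the recording
#'   (`"upward"`, `"sideway"`, `"downward"`) or `NA`.
#' @param taxonomy Taxonomy used to validate movement labels.
#' @param meta Optional named list of free-form metadata (e.g. channel order).
#' @return An object of class `"emg_recording"`.
#' @export
emg_recording <- function(signal, fs, schedule = NULL, subject_id = "S1",
                          orientation = NA_character_,
                          taxonomy = emg_taxonomy(), meta = list()) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stopf("fs must be a positive scalar")
  n <- ncol(signal)
  if (is.null(schedule)) {
    schedule <- data.frame(label = character(), phase = character(),
                           start = integer(), end = integer(),
                           repetition = integer(), orientation = character(),
                           stringsAsFactors = FALSE)
  }
  schedule <- as.data.frame(schedule, stringsAsFactors = FALSE)
  req <- c("label", "phase", "start", "end")
  if (!all(req %in% names(schedule))) {
    stopf("schedule must have columns %s", paste(req, collapse = ", "))
  }
  if (!"repetition" %in% names(schedule)) schedule$repetition <- NA_integer_
  if (!"orientation" %in% names(schedule)) schedule$orientation <- orientation
  if (nrow(schedule) > 0L) {
    if (any(!schedule$phase %in% c("rest", "preparation", "movement"))) {
      stopf("schedule phases must be rest/preparation/movement")
    }
    if (any(schedule$start < 0L) || any(schedule$end > n) ||
        any(schedule$end <= schedule$start)) {
      stopf("schedule intervals must satisfy 0 <= start < end <= n_samples")
    }
    o <- order(schedule$start)
    schedule <- schedule[o, , drop = FALSE]
    if (nrow(schedule) > 1L &&
        any(schedule$start[-1L] < schedule$end[-nrow(schedule)])) {
      bad <- which(schedule$start[-1L] < schedule$end[-nrow(schedule)])[1L]
      stopf("schedule intervals %d and %d overlap", bad, bad + 1L)
    }
    mv <- schedule$label[schedule$phase == "movement"]
    known <- all_classes(taxonomy)
    if (any(!mv %in% known)) {
      stopf("unknown movement label(s): %s",
            paste(unique(mv[!mv %in% known]), collapse = ", "))
    }
  }
  rownames(schedule) <- NULL
  structure(list(signal = signal, fs = fs, schedule = schedule,
                 subject_id = subject_id, orientation = orientation,
                 taxonomy = taxonomy, meta = meta),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("sEMG recording: %d channels x %d samples (%.2f s at %g Hz)\n",
              nrow(x$signal), ncol(x$signal), ncol(x$signal) / x$fs, x$fs))
  cat(sprintf("  subject %s, orientation %s, %d movement intervals\n",
              x$subject_id, x$orientation,
              sum(x$schedule$phase == "movement")))
  invisible(x)
}

#' Write / read a recording as delimited text plus JSON metadata
#'
#' The signal is stored as tab-separated text, one row per sample and one
#' column per channel, at full precision (`%.17g`); sampling rate, schedule
#' and subject metadata go to a JSON sidecar.  The round trip is lossless.
#'
#' @param rec An [emg_recording()].
#' @param signal_path Path of the delimited-text signal file.
#' @param meta_path Path of the JSON metadata file.
#' @return `write_recording()` returns the paths invisibly; `read_recording()`
#'   returns an [emg_recording()].
#' @export
write_recording <- function(rec, signal_path, meta_path) {
  stopifnot(inherits(rec, "emg_recording"))
  m <- t(rec$signal)  # one row per sample
  con <- file(signal_path, "w")
  on.exit(close(con))
  writeLines(apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t")), con)
  meta <- list(fs = rec$fs, n_channels = nrow(rec$signal),
               subject_id = rec$subject_id, orientation = rec$orientation,
               schedule = rec$schedule, meta = rec$meta,
               basic_classes = rec$taxonomy$basic_classes,
               rotations = rec$taxonomy$rotations,
               functions = rec$taxonomy$functions)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null")
  invisible(c(signal_path, meta_path))
}

#' @rdname write_recording
#' @export
read_recording <- function(signal_path, meta_path) {
  if (!file.exists(signal_path)) stopf("signal file '%s' not found", signal_path)
  if (!file.exists(meta_path)) stopf("metadata file '%s' not found", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs) || meta$fs <= 0) stopf("metadata must declare fs > 0")
  lines <- readLines(signal_path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (length(unique(ncols)) > 1L) {
    bad <- which(ncols != ncols[1L])[1L]
    stopf("ragged signal file: line %d has %d columns, expected %d",
          bad, ncols[bad], ncols[1L])
  }
  if (!is.null(meta$n_channels) && ncols[1L] != meta$n_channels) {
    stopf("signal file has %d columns but metadata declares %d channels",
          ncols[1L], meta$n_channels)
  }
  sig <- matrix(as.double(unlist(parts)), nrow = ncols[1L])  # channels x samples
  sched <- meta$schedule
  if (is.null(sched) || (is.data.frame(sched) && nrow(sched) == 0L) ||
      length(sched) == 0L) {
    sched <- NULL
  } else {
    sched <- as.data.frame(sched, stringsAsFactors = FALSE)
  }
  tx <- if (!is.null(meta$basic_classes)) {
    emg_taxonomy(meta$basic_classes, meta$rotations, meta$functions)
  } else emg_taxonomy()
  emg_recording(sig, fs = meta$fs, schedule = sched,
                subject_id = meta$subject_id %||% "S1",
                orientation = meta$orientation %||% NA_character_,
                taxonomy = tx, meta = meta$meta %||% list())
}
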