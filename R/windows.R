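#' Construct a set of fixed-length labeled sEMG windows
#'
#' The container that feeds every classifier: a stack of windows
#' `[n_windows x n_channels x window_len]` with per-window label, repetition,
#' orientation and subject metadata.
#'
#' @param windows Numeric 3-d array `[n x channels x window_len]` (an
#'   `n x channels x len` slice per window).  A 0-window set is allowed.
#' @param labels Character vector of per-window class tokens.
#' @param repetition Integer vector of per-window repetition ids.
#' @param orientation Character vector of per-window hand orientations.
#' @param subject_id Character vector (or scalar) of per-window subject ids.
#' @param window_len,stride Window length and stride in samples
#'   (defaults 512 and 128, i.e. 250 ms / 62.5 ms at 2048 Hz).
#' @param taxonomy Taxonomy used to validate labels.
#' @return An object of class `"emg_windows"`.
#' @export
emg_windows <- function(windows, labels, repetition = NA_integer_,
                        orientation = NA_character_, subject_id = NA_character_,
                        window_len = 512L, stride = 128L,
                        taxonomy = emg_taxonomy()) {
  if (length(dim(windows)) != 3L) stopf("windows must be a 3-d array")
  storage.mode(windows) <- "double"
  n <- dim(windows)[1L]
  labels <- as.character(labels)
  if (length(labels) != n) stopf("need one label per window (%d != %d)", length(labels), n)
  known <- all_classes(taxonomy)
  if (n > 0L && any(!labels %in% known)) {
    stopf("labels outside the taxonomy: %s",
          paste(unique(labels[!labels %in% known]), collapse = ", "))
  }
  if (stride <= 0L || stride > dim(windows)[3L] && n > 0L) {
    stopf("stride must satisfy 0 < stride <= window_len")
  }
  rep_ <- rep_len(as.integer(repetition), max(n, 0L))
  ori <- rep_len(as.character(orientation), max(n, 0L))
  sub <- rep_len(as.character(subject_id), max(n, 0L))
  structure(list(windows = windows, labels = labels, repetition = rep_,
                 orientation = ori, subject_id = sub,
                 window_len = as.integer(window_len),
                 stride = as.integer(stride), taxonomy = taxonomy),
            class = "emg_windows")
}

#' @export
print.emg_windows <- function(x, ...) {
  cat(sprintf("sEMG window set: %d windows of %d channels x %d samples (stride %d)\n",
              dim(x$windows)[1L], dim(x$windows)[2L], dim(x$windows)[3L], x$stride))
  if (dim(x$windows)[1L] > 0L) {
    tab <- table(x$labels)
    cat("  classes:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

n_windows <- function(ws) dim(ws$windows)[1L]

# Row-subset a window set.
subset_windows <- function(ws, idx) {
  emg_windows(ws$windows[idx, , , drop = FALSE], ws$labels[idx],
              ws$repetition[idx], ws$orientation[idx], ws$subject_id[idx],
              ws$window_len, ws$stride, ws$taxonomy)
}

# Concatenate window sets with identical geometry.
bind_windows <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, n_windows, 1L) > 0L]
  if (length(sets) == 0L) stopf("nothing to bind")
  d <- dim(sets[[1L]]$windows)[-1L]
  for (s in sets) stopifnot(identical(dim(s$windows)[-1L], d))
  arr <- array(0, c(sum(vapply(sets, n_windows, 1L)), d))
  at <- 0L
  for (s in sets) {
    k <- n_windows(s)
    arr[at + seq_len(k), , ] <- s$windows
    at <- at + k
  }
  emg_windows(arr, unlist(lapply(sets, `[[`, "labels")),
              unlist(lapply(sets, `[[`, "repetition")),
              unlist(lapply(sets, `[[`, "orientation")),
              unlist(lapply(sets, `[[`, "subject_id")),
              sets[[1L]]$window_len, sets[[1L]]$stride, sets[[1L]]$taxonomy)
}

#' Write / read a window set as a binary array with a JSON sidecar
#'
#' The window array is stored as IEEE little-endian doubles in C-contiguous
#' `[n, channels, len]` order; dimensions, labels and per-window metadata go
#' to a JSON sidecar beside it (`<path>.json`).  The round trip is lossless;
#' the reader checks array size against the sidecar and fails with an
#' integrity error on any mismatch.
#'
#' @param ws An [emg_windows()] set.
#' @param path Path of the binary array file (sidecar is `<path>.json`).
#' @return `write_windows()` the path, invisibly; `read_windows()` the set.
#' @export
write_windows <- function(ws, path) {
  stopifnot(inherits(ws, "emg_windows"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(ws$windows), con, size = 8L, endian = "little")
  side <- list(dims = dim(ws$windows), labels = ws$labels,
               repetition = ws$repetition, orientation = ws$orientation,
               subject_id = ws$subject_id, window_len = ws$window_len,
               stride = ws$stride,
               basic_classes = ws$taxonomy$basic_classes,
               rotations = ws$taxonomy$rotations,
               functions = ws$taxonomy$functions)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side_path)) {
    stopf("window container '%s' (+ .json sidecar) not found", path)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  dims <- as.integer(side$dims)
  expected <- prod(dims)
  sz <- file.info(path)$size
  if (sz != expected * 8) {
    stopf("integrity error: array file has %d bytes, sidecar implies %d",
          sz, expected * 8)
  }
  if (length(side$labels %||% character()) != dims[1L]) {
    stopf("integrity error: %d labels in sidecar but %d windows in array",
          length(side$labels), dims[1L])
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vec <- readBin(con, "double", n = expected, size = 8L, endian = "little")
  tx <- if (!is.null(side$basic_classes)) {
    emg_taxonomy(side$basic_classes, side$rotations, side$functions)
  } else emg_taxonomy()
  emg_windows(array(vec, dims), as.character(side$labels %||% character()),
              side$repetition %||% NA_integer_,
              side$orientation %||% NA_character_,
              side$subject_id %||% NA_character_,
              side$window_len, side$stride, tx)
}
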