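#' Filter configuration for raw sEMG
#'
#' Band-pass 10-500 Hz (4th-order Butterworth) plus a 50 Hz notch
#' (2nd-order Butterworth band-stop).  Filters are applied zero-phase
#' (forward-backward), so the effective order doubles.
#'
#' @param bp_low,bp_high Band-pass edges, Hz.
#' @param bp_order Band-pass Butterworth order.
#' @param notch_freq Notch center frequency, Hz.
#' @param notch_order Notch Butterworth order.
#' @param notch_halfwidth Half-bandwidth of the band-stop, Hz.
#' @return A list of class `"emg_filter_config"`.
#' @export
emg_filter_config <- function(bp_low = 10, bp_high = 500, bp_order = 4,
                              notch_freq = 50, notch_order = 2,
                              notch_halfwidth = 2) {
  stopifnot(bp_low > 0, bp_high > bp_low, notch_halfwidth > 0)
  structure(list(bp_low = bp_low, bp_high = bp_high, bp_order = bp_order,
                 notch_freq = notch_freq, notch_order = notch_order,
                 notch_halfwidth = notch_halfwidth),
            class = "emg_filter_config")
}

#' Band-pass and notch filter a recording
#'
#' Applies the 10-500 Hz Butterworth band-pass and the 50 Hz notch to every
#' channel, zero-phase (forward-backward via [signal::filtfilt()]).
#'
#' @param rec An [emg_recording()].
#' @param cfg An [emg_filter_config()].
#' @return The filtered recording (same shape and metadata).
#' @export
apply_filters <- function(rec, cfg = emg_filter_config()) {
  stopifnot(inherits(rec, "emg_recording"))
  nyq <- rec$fs / 2
  if (cfg$bp_high >= nyq) stopf("band-pass edge %g Hz >= Nyquist %g Hz", cfg$bp_high, nyq)
  if (cfg$notch_freq + cfg$notch_halfwidth >= nyq) stopf("notch band exceeds Nyquist")
  if (any(!is.finite(rec$signal))) stopf("signal contains non-finite values")
  # the band-pass is realized as a high-pass / low-pass cascade: a direct
  # 8-pole band-pass polynomial is numerically ill-conditioned at the very
  # low normalized corner (10 Hz of a 2048 Hz rate)
  hp <- signal::butter(cfg$bp_order, cfg$bp_low / nyq, type = "high")
  lp <- signal::butter(cfg$bp_order, cfg$bp_high / nyq, type = "low")
  nt <- signal::butter(cfg$notch_order,
                       c(cfg$notch_freq - cfg$notch_halfwidth,
                         cfg$notch_freq + cfg$notch_halfwidth) / nyq,
                       type = "stop")
  out <- rec$signal
  for (ch in seq_len(nrow(out))) {
    y <- signal::filtfilt(hp, out[ch, ])
    y <- signal::filtfilt(lp, y)
    out[ch, ] <- signal::filtfilt(nt, y)
  }
  rec$signal <- out
  rec
}

#' Segment a recording into cue-labeled movement trials
#'
#' One trial per movement-phase interval of the schedule, in schedule order.
#' Rest and preparation intervals are excluded from the trials, but the rest
#' interval immediately preceding each movement is retained as the trial's
#' baseline reference (used by the onset detector).  A movement without a
#' preceding rest interval falls back to the first rest interval of the
#' recording, with a warning.
#'
#' @param rec An [emg_recording()] with a schedule.
#' @return List of trials; each trial is a list with `signal`
#'   (channels x samples), `baseline` (channels x samples of preceding rest),
#'   `label`, `repetition`, `orientation`, `subject_id` and `fs`.
#' @export
segment_by_cues <- function(rec) {
  stopifnot(inherits(rec, "emg_recording"))
  sched <- rec$schedule
  trials <- list()
  if (nrow(sched) == 0L) return(trials)
  rest_rows <- which(sched$phase == "rest")
  first_rest <- if (length(rest_rows)) rest_rows[1L] else NA_integer_
  for (i in which(sched$phase == "movement")) {
    prev_rest <- rest_rows[rest_rows < i]
    base_row <- if (length(prev_rest)) max(prev_rest) else {
      warnf("movement interval %d has no preceding rest; using global baseline", i)
      first_rest
    }
    if (is.na(base_row)) stopf("no rest interval available for baseline")
    # 0-based half-open [start, end) -> R's 1-based (start+1):end
    sl <- rec$signal[, (sched$start[i] + 1L):sched$end[i], drop = FALSE]
    bl <- rec$signal[, (sched$start[base_row] + 1L):sched$end[base_row], drop = FALSE]
    trials[[length(trials) + 1L]] <- list(
      signal = sl, baseline = bl, label = sched$label[i],
      repetition = sched$repetition[i], orientation = sched$orientation[i],
      subject_id = rec$subject_id, fs = rec$fs)
  }
  trials
}

#' Onset-detector configuration
#'
#' The detector thresholds the cross-channel mean of the moving-average
#' smoothed rectified signal against baseline (rest) activity:
#' `T = mean(e_rest) + k_sigma * sd(e_rest)`.
#'
#' @param smooth_ms Moving-average width for the rectified envelope, ms.
#' @param k_sigma Threshold multiplier over the baseline SD.
#' @param min_hold_ms Minimum sustained exceedance counted as activity, ms.
#' @return A list of class `"emg_onset_config"`.
#' @export
emg_onset_config <- function(smooth_ms = 100, k_sigma = 3, min_hold_ms = 50) {
  stopifnot(smooth_ms > 0, k_sigma > 0, min_hold_ms > 0)
  structure(list(smooth_ms = smooth_ms, k_sigma = k_sigma,
                 min_hold_ms = min_hold_ms), class = "emg_onset_config")
}

# Moving-average smoothed rectified envelope, averaged across channels.
activity_envelope <- function(sig, fs, smooth_ms) {
  w <- max(1L, floor(smooth_ms * fs / 1000))
  k <- rep(1 / w, w)
  e <- colMeans(abs(sig))
  sm <- as.numeric(stats::filter(e, k, sides = 2L, circular = FALSE))
  # fill the edge NAs with the nearest computed value
  ok <- which(!is.na(sm))
  if (length(ok) == 0L) return(e)
  sm[seq_len(ok[1L] - 1L)] <- sm[ok[1L]]
  sm[seq((ok[length(ok)] + 1L), length.out = length(sm) - ok[length(ok)])] <- sm[ok[length(ok)]]
  sm
}

#' Detect the active interval of a movement trial
#'
#' @param trial A trial from [segment_by_cues()] (or any list with `signal`,
#'   `baseline`, `fs`).
#' @param cfg An [emg_onset_config()].
#' @return Integer vector `c(onset, offset)` of 0-based sample indices into
#'   the trial (half-open: activity spans `[onset, offset)`).
#' @export
detect_active_interval <- function(trial, cfg = emg_onset_config()) {
  if (is.null(trial$baseline) || ncol(trial$baseline) == 0L) {
    stopf("trial has no baseline segment")
  }
  fs <- trial$fs
  e_base <- activity_envelope(trial$baseline, fs, cfg$smooth_ms)
  e <- activity_envelope(trial$signal, fs, cfg$smooth_ms)
  thr <- mean(e_base) + cfg$k_sigma * stats::sd(e_base)
  above <- e > thr
  hold <- max(1L, floor(cfg$min_hold_ms * fs / 1000))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= hold)
  if (length(keep) == 0L) stopf("no activity: envelope never exceeds threshold for %g ms", cfg$min_hold_ms)
  onset <- starts[keep[1L]]
  offset <- ends[keep[length(keep)]]
  c(onset = onset - 1L, offset = offset)  # 0-based half-open
}

#' Trim the movement transient from an interval
#'
#' Removes `floor(trim_ms * fs / 1000)` samples from each end, discarding the
#' transient at movement onset and release so that classifiers see the
#' steady-state signal.
#'
#' @param interval Integer `c(onset, offset)`, 0-based half-open.
#' @param fs Sampling rate, Hz.
#' @param trim_ms Milliseconds to remove per end (default 100).
#' @return Trimmed `c(onset, offset)`.
#' @export
trim_transient <- function(interval, fs, trim_ms = 100) {
  tr <- floor(trim_ms * fs / 1000)
  out <- c(interval[1L] + tr, interval[2L] - tr)
  if (out[2L] - out[1L] < 1L) {
    stopf("trial too short: %d samples cannot lose 2 x %d",
          interval[2L] - interval[1L], tr)
  }
  names(out) <- c("onset", "offset")
  out
}

#' Windowing configuration
#'
#' @param window_len Window length in samples (512 = 250 ms at 2048 Hz).
#' @param stride Stride in samples (128 = 62.5 ms), giving
#'   `window_len - stride` samples of overlap between consecutive windows.
#' @param trim_ms Transient trim per interval end, ms.
#' @return A list of class `"emg_windowing_config"`.
#' @export
emg_windowing_config <- function(window_len = 512L, stride = 128L, trim_ms = 100) {
  stopifnot(stride > 0L, stride <= window_len)
  structure(list(window_len = as.integer(window_len),
                 stride = as.integer(stride), trim_ms = trim_ms),
            class = "emg_windowing_config")
}

#' Slide fixed-length windows over a trial
#'
#' Extracts `floor((L - window_len) / stride) + 1` overlapping windows from
#' the trial, all inheriting the trial's label and metadata.
#'
#' @param trial A trial (list with `signal`, `label`, `fs`, ...).
#' @param cfg An [emg_windowing_config()].
#' @param taxonomy Taxonomy for the resulting window set.
#' @return An [emg_windows()] set (0 windows, with a warning, if the trial is
#'   shorter than one window).
#' @export
slide_windows <- function(trial, cfg = emg_windowing_config(),
                          taxonomy = emg_taxonomy()) {
  sig <- trial$signal
  L <- ncol(sig)
  W <- cfg$window_len
  S <- cfg$stride
  nch <- nrow(sig)
  if (L < W) {
    warnf("trial of %d samples is shorter than one %d-sample window", L, W)
    return(emg_windows(array(0, c(0L, nch, W)), character(),
                       window_len = W, stride = S, taxonomy = taxonomy))
  }
  nw <- (L - W) %/% S + 1L
  arr <- array(0, c(nw, nch, W))
  for (i in seq_len(nw)) {
    arr[i, , ] <- sig[, ((i - 1L) * S + 1L):((i - 1L) * S + W)]
  }
  emg_windows(arr, rep(trial$label, nw), rep(trial$repetition %||% NA_integer_, nw),
              rep(trial$orientation %||% NA_character_, nw),
              rep(trial$subject_id %||% NA_character_, nw),
              window_len = W, stride = S, taxonomy = taxonomy)
}

#' Full preprocessing pipeline: recording to labeled windows
#'
#' Filters (optionally), segments by cues, detects the active interval within
#' each trial, trims the 100 ms transients, and slides 512/128 windows.
#' Trials in which no activity is detected are dropped with a message.
#'
#' @param rec An [emg_recording()].
#' @param filter_cfg An [emg_filter_config()], or `NULL` to skip filtering
#'   (Ninapro-style inputs arrive already filtered).
#' @param onset_cfg An [emg_onset_config()], or `NULL` to window the full cue
#'   interval without onset detection.
#' @param windowing_cfg An [emg_windowing_config()].
#' @return An [emg_windows()] set.
#' @export
preprocess_recording <- function(rec, filter_cfg = emg_filter_config(),
                                 onset_cfg = emg_onset_config(),
                                 windowing_cfg = emg_windowing_config()) {
  if (!is.null(filter_cfg)) rec <- apply_filters(rec, filter_cfg)
  trials <- segment_by_cues(rec)
  sets <- list()
  for (tr in trials) {
    iv <- c(0L, ncol(tr$signal))
    if (!is.null(onset_cfg)) {
      iv <- tryCatch(detect_active_interval(tr, onset_cfg), error = function(e) NULL)
      if (is.null(iv)) {
        message(sprintf("dropping trial '%s' (rep %s): no activity detected",
                        tr$label, tr$repetition))
        next
      }
    }
    iv <- tryCatch(trim_transient(iv, tr$fs, windowing_cfg$trim_ms),
                   error = function(e) NULL)
    if (is.null(iv)) next
    tr$signal <- tr$signal[, (iv[1L] + 1L):iv[2L], drop = FALSE]
    ws <- suppressWarnings(slide_windows(tr, windowing_cfg, rec$taxonomy))
    if (n_windows(ws) > 0L) sets[[length(sets) + 1L]] <- ws
  }
  if (length(sets) == 0L) {
    return(emg_windows(array(0, c(0L, nrow(rec$signal), windowing_cfg$window_len)),
                       character(), window_len = windowing_cfg$window_len,
                       stride = windowing_cfg$stride, taxonomy = rec$taxonomy))
  }
  do.call(bind_windows, sets)
}

#' Repetition-based train/test split
#'
#' Assigns whole repetitions to train or test so that overlapping windows
#' never leak across the split.  Policies: `"nearlab_3of5"` takes, per
#' (class, orientation), the first 3 of the 5 repetitions in acquisition
#' order for training; `"ninapro_1346"` trains on repetitions 1, 3, 4, 6 and
#' tests on 2, 5; `"custom"` uses the supplied repetition id sets.
#'
#' @param ws An [emg_windows()] set with repetition ids.
#' @param policy One of `"nearlab_3of5"`, `"ninapro_1346"`, `"custom"`.
#' @param train_repetitions,test_repetitions Repetition id sets for
#'   `policy = "custom"`; they must be disjoint.
#' @return List with elements `train` and `test` ([emg_windows()] sets).
#' @export
split_by_repetitions <- function(ws, policy = c("nearlab_3of5", "ninapro_1346", "custom"),
                                 train_repetitions = NULL, test_repetitions = NULL) {
  policy <- match.arg(policy)
  if (anyNA(ws$repetition)) stopf("window set lacks repetition ids")
  n <- n_windows(ws)
  if (policy == "custom") {
    if (length(intersect(train_repetitions, test_repetitions)) > 0L) {
      stopf("train and test repetition sets overlap")
    }
    tr <- ws$repetition %in% train_repetitions
    te <- ws$repetition %in% test_repetitions
  } else if (policy == "ninapro_1346") {
    tr <- ws$repetition %in% c(1L, 3L, 4L, 6L)
    te <- ws$repetition %in% c(2L, 5L)
  } else {
    tr <- logical(n)
    key <- paste(ws$labels, ws$orientation, ws$subject_id)
    for (k in unique(key)) {
      idx <- which(key == k)
      reps <- sort(unique(ws$repetition[idx]))
      take <- reps[seq_len(min(3L, length(reps)))]
      tr[idx] <- ws$repetition[idx] %in% take
    }
    te <- !tr
  }
  list(train = subset_windows(ws, which(tr)), test = subset_windows(ws, which(te)))
}
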