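# ---------------------------------------------------------------------------
# Synergy-structured synthetic sEMG.  Movement classes are coordinated
# channel-activation patterns (synergies); combined movements superpose the
# patterns of their rotation and hand-function components.  The interference
# signal is amplitude-modulated band-limited Gaussian noise, a standard
# surrogate for surface EMG.
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Defaults emulate the Nearlab acquisition: 10 channels at 2048 Hz, a
#' 3 s rest / 2 s preparation / 5 s movement schedule (7 s movements for the
#' combined classes), EMG-band noise (20-450 Hz), and a trapezoidal
#' activation envelope with 250 ms rise and fall.  Subject and orientation
#' channel gains jitter multiplicatively (log-normal, SD 0.15 and 0.05) so
#' that subjects share class structure without being identical.
#'
#' @param fs Sampling rate, Hz.
#' @param n_channels Number of channels.
#' @param noise_band Band of the noise carrier, Hz.
#' @param rise_ms,fall_ms Envelope rise/fall, ms (plateau fills the rest).
#' @param rest_s,prep_s,movement_s,movement_s_combined Schedule durations, s.
#' @param baseline_rms Resting noise RMS per channel, microvolts.
#' @param movement_rms_scale Full-activation RMS scale, microvolts.
#' @param line_hum_amp Amplitude of an optional 50 Hz mains component,
#'   microvolts (0 disables).
#' @param subject_gain_jitter_sd,orientation_gain_jitter_sd Log-normal SDs of
#'   the per-channel multiplicative gain jitters.
#' @return A list of class `"emg_sim_config"`.
#' @export
sim_config <- function(fs = 2048, n_channels = 10L, noise_band = c(20, 450),
                       rise_ms = 250, fall_ms = 250, rest_s = 3, prep_s = 2,
                       movement_s = 5, movement_s_combined = 7,
                       baseline_rms = 5, movement_rms_scale = 50,
                       line_hum_amp = 0, subject_gain_jitter_sd = 0.15,
                       orientation_gain_jitter_sd = 0.05) {
  stopifnot(fs > 0, rest_s > 0, prep_s >= 0, movement_s > 0,
            subject_gain_jitter_sd >= 0, orientation_gain_jitter_sd >= 0)
  structure(list(fs = fs, n_channels = as.integer(n_channels),
                 noise_band = noise_band, rise_ms = rise_ms, fall_ms = fall_ms,
                 rest_s = rest_s, prep_s = prep_s, movement_s = movement_s,
                 movement_s_combined = movement_s_combined,
                 baseline_rms = baseline_rms,
                 movement_rms_scale = movement_rms_scale,
                 line_hum_amp = line_hum_amp,
                 subject_gain_jitter_sd = subject_gain_jitter_sd,
                 orientation_gain_jitter_sd = orientation_gain_jitter_sd),
            class = "emg_sim_config")
}

#' Draw a synergy bank: class-by-channel activation gains
#'
#' Each basic class strongly activates 2-4 of the channels (gains near 1)
#' and leaves the rest nearly silent; banks are redrawn until all basic rows
#' are pairwise distinct (correlation < 0.95).  Combined-class rows are
#' derived, not free: the per-channel maximum of the rotation row and the
#' hand-function row (superposition without doubling shared-channel power;
#' set `combine = "sum"` for additive superposition).
#'
#' @param taxonomy An [emg_taxonomy()].
#' @param n_channels Number of channels (>= 4, so patterns can differ).
#' @param seed RNG seed; the bank is deterministic given the seed.
#' @param combine `"max"` (default) or `"sum"`.
#' @return Matrix `[14 x n_channels]` of class `"emg_synergy_bank"` with all
#'   basic then all combined classes as rows.
#' @export
make_synergy_bank <- function(taxonomy = emg_taxonomy(), n_channels = 10L,
                              seed = 1L, combine = c("max", "sum")) {
  combine <- match.arg(combine)
  if (n_channels < 4L) stopf("need at least 4 channels for distinct patterns")
  nb <- length(taxonomy$basic_classes)
  with_seed(seed, {
    for (attempt in 1:100) {
      basic <- matrix(0, nb, n_channels)
      for (k in seq_len(nb)) {
        n_strong <- sample(2:4, 1L)
        strong <- sample.int(n_channels, n_strong)
        row <- stats::runif(n_channels, 0, 0.08)
        row[strong] <- stats::runif(n_strong, 0.7, 1.2)
        basic[k, ] <- row
      }
      cors <- stats::cor(t(basic))
      if (max(abs(cors[upper.tri(cors)])) < 0.95) break
    }
    comb <- matrix(0, length(taxonomy$combined_classes), n_channels)
    for (k in seq_along(taxonomy$combined_classes)) {
      parts <- decompose_combined(taxonomy$combined_classes[k], taxonomy)
      r1 <- basic[match(parts["rotation"], taxonomy$basic_classes), ]
      r2 <- basic[match(parts["fun"], taxonomy$basic_classes), ]
      comb[k, ] <- if (combine == "max") pmax(r1, r2) else r1 + r2
    }
    gains <- rbind(basic, comb)
    rownames(gains) <- c(taxonomy$basic_classes, taxonomy$combined_classes)
    structure(gains, class = c("emg_synergy_bank", "matrix", "array"),
              taxonomy = taxonomy, combine = combine)
  })
}

# Band-limited unit-RMS Gaussian noise.
bandlimited_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  if (n < 64L) return(x / max(sqrt(mean(x^2)), 1e-12))
  bf <- signal::butter(4, pmin(band / (fs / 2), 0.99), type = "pass")
  y <- signal::filtfilt(bf, x)
  y / max(sqrt(mean(y^2)), 1e-12)
}

trapezoid_envelope <- function(n, fs, rise_ms, fall_ms) {
  r <- min(n %/% 2L, round(rise_ms * fs / 1000))
  f <- min(n - r, round(fall_ms * fs / 1000))
  env <- rep(1, n)
  if (r > 0L) env[seq_len(r)] <- seq(0, 1, length.out = r)
  if (f > 0L) env[(n - f + 1L):n] <- seq(1, 0, length.out = f)
  env
}

#' Simulate one multichannel recording from a synergy bank
#'
#' Each scheduled movement contributes, on channel `c`, the trapezoid
#' envelope times `subject_gain[c] * orientation_gain[c] * bank[class, c] *
#' movement_rms_scale` times a fresh band-limited unit-RMS noise carrier,
#' added on top of continuous baseline noise of RMS `baseline_rms` (plus the
#' optional 50 Hz hum).  Rest and preparation segments contain baseline
#' activity only.  The cue schedule is written into the recording.
#' Bit-reproducible given the seed.
#'
#' @param bank A [make_synergy_bank()].
#' @param cfg A [sim_config()].
#' @param subject_id Subject token.
#' @param trials Data frame with columns `class`, `orientation`,
#'   `repetition`: one movement interval per row, in order.
#' @param seed RNG seed.
#' @return An [emg_recording()].
#' @export
simulate_recording <- function(bank, cfg = sim_config(), subject_id = "S1",
                               trials, seed = 1L) {
  tx <- attr(bank, "taxonomy")
  if (any(!trials$class %in% rownames(bank))) {
    stopf("trial class(es) outside the synergy bank: %s",
          paste(setdiff(trials$class, rownames(bank)), collapse = ", "))
  }
  fs <- cfg$fs
  nch <- cfg$n_channels
  is_combined <- trials$class %in% tx$combined_classes
  mov_s <- ifelse(is_combined, cfg$movement_s_combined, cfg$movement_s)
  n_rest <- round(cfg$rest_s * fs)
  n_prep <- round(cfg$prep_s * fs)
  n_mov <- round(mov_s * fs)
  n_total <- sum(n_rest + n_prep + n_mov)
  with_seed(seed, {
    g_subj <- exp(stats::rnorm(nch, 0, cfg$subject_gain_jitter_sd))
    oris <- unique(as.character(trials$orientation))
    g_ori <- lapply(oris, function(o) exp(stats::rnorm(nch, 0, cfg$orientation_gain_jitter_sd)))
    names(g_ori) <- oris
    sig <- matrix(0, nch, n_total)
    for (ch in seq_len(nch)) {
      sig[ch, ] <- cfg$baseline_rms * bandlimited_noise(n_total, fs, cfg$noise_band)
    }
    if (cfg$line_hum_amp > 0) {
      tt <- seq_len(n_total) / fs
      for (ch in seq_len(nch)) {
        sig[ch, ] <- sig[ch, ] + cfg$line_hum_amp *
          sin(2 * pi * 50 * tt + stats::runif(1, 0, 2 * pi))
      }
    }
    sched <- data.frame()
    at <- 0L
    for (i in seq_len(nrow(trials))) {
      cl <- as.character(trials$class[i])
      ori <- as.character(trials$orientation[i])
      sched <- rbind(sched, data.frame(
        label = c(cl, cl, cl), phase = c("rest", "preparation", "movement"),
        start = c(at, at + n_rest, at + n_rest + n_prep),
        end = c(at + n_rest, at + n_rest + n_prep, at + n_rest + n_prep + n_mov[i]),
        repetition = trials$repetition[i], orientation = ori))
      env <- trapezoid_envelope(n_mov[i], fs, cfg$rise_ms, cfg$fall_ms)
      idx <- (at + n_rest + n_prep + 1L):(at + n_rest + n_prep + n_mov[i])
      for (ch in seq_len(nch)) {
        amp <- g_subj[ch] * g_ori[[ori]][ch] * bank[cl, ch] * cfg$movement_rms_scale
        if (amp > 0) {
          sig[ch, idx] <- sig[ch, idx] +
            env * amp * bandlimited_noise(n_mov[i], fs, cfg$noise_band)
        }
      }
      at <- at + n_rest + n_prep + n_mov[i]
    }
    # channel order mirrors the SENIAM-style montage: a proximal ring of 6
    # electrodes then 4 distal ones, so cross-channel kernels see a defined
    # adjacency
    ch_names <- if (nch == 10L) {
      c(paste0("proximal_", 1:6), paste0("distal_", 1:4))
    } else paste0("ch_", seq_len(nch))
    emg_recording(sig, fs = fs, schedule = sched, subject_id = subject_id,
                  orientation = if (length(oris) == 1L) oris else NA_character_,
                  taxonomy = tx,
                  meta = list(simulated = TRUE, seed = seed,
                              channel_order = ch_names))
  })
}

#' Simulate a multi-subject cohort sharing one synergy bank
#'
#' Emulates the Nearlab protocol shape: every subject performs all
#' (class, orientation, repetition) cells in randomized order with rest and
#' preparation interleaved (defaults: 8 basic classes, 5 repetitions, 3
#' orientations -> 120 movement intervals per subject; the combined protocol
#' is 6 classes x 4 repetitions, sideway orientation).  Subjects share the
#' bank but differ by their multiplicative channel-gain jitter.
#'
#' @param bank A [make_synergy_bank()].
#' @param cfg A [sim_config()].
#' @param n_subjects Number of subjects.
#' @param classes Movement classes to include (default: the basic classes).
#' @param reps Repetitions per (class, orientation).
#' @param orientations Hand orientations.
#' @param seed Seed family; subject `k` derives its own stream from it.
#' @return Named list of [emg_recording()]s, one per subject (`S1`, ...).
#' @export
simulate_cohort <- function(bank, cfg = sim_config(), n_subjects = 11L,
                            classes = NULL, reps = 5L,
                            orientations = c("upward", "sideway", "downward"),
                            seed = 1L) {
  stopifnot(n_subjects >= 1L)
  tx <- attr(bank, "taxonomy")
  classes <- classes %||% tx$basic_classes
  cells <- expand.grid(class = classes, orientation = orientations,
                       repetition = seq_len(reps), stringsAsFactors = FALSE)
  out <- list()
  for (s in seq_len(n_subjects)) {
    ord <- with_seed(derive_seed(seed, 500L + s), sample.int(nrow(cells)))
    sid <- paste0("S", s)
    out[[sid]] <- simulate_recording(bank, cfg, subject_id = sid,
                                     trials = cells[ord, , drop = FALSE],
                                     seed = derive_seed(seed, s))
  }
  out
}
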