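# Direct sinusoid measurements serve as the oracle for the filter cascade:
# feed a known tone, measure steady-state RMS in the middle of the signal.
tone_attenuation_db <- function(freq, fs = 2048, dur = 4) {
  t <- seq(0, dur, by = 1 / fs)
  rec <- emg_recording(matrix(sin(2 * pi * freq * t), 1), fs = fs)
  out <- apply_filters(rec, emg_filter_config())
  mid <- floor(length(t) / 4):floor(3 * length(t) / 4)
  20 * log10(sqrt(mean(out$signal[1, mid]^2)) / sqrt(0.5))
}

test_that("filter cascade removes DC, notches 50 Hz, and passes 100 Hz", {
  fs <- 2048
  # the narrow notch has a ~240-sample time constant, so give its edge
  # transient a generous 2.5 s to die out before measuring
  rec <- emg_recording(matrix(1, 1, 6 * fs), fs = fs)
  out <- apply_filters(rec)
  mid <- (2.5 * fs):(3.5 * fs)
  expect_lt(max(abs(out$signal[1, mid])), 1e-6)
  expect_lt(tone_attenuation_db(50), -20)
  expect_gt(tone_attenuation_db(100), -1)
  expect_lt(tone_attenuation_db(100), 1)
})

test_that("filtering is linear and rejects unusable band edges", {
  set.seed(3)
  sig <- matrix(rnorm(2 * 4096), 2, 4096)
  rec1 <- emg_recording(sig, 2048)
  rec5 <- emg_recording(5 * sig, 2048)
  expect_equal(apply_filters(rec5)$signal, 5 * apply_filters(rec1)$signal,
               tolerance = 1e-7)
  low_fs <- emg_recording(sig, 900)  # 500 Hz edge >= Nyquist 450
  expect_error(apply_filters(low_fs), "Nyquist")
})

test_that("cue segmentation yields one trial per movement with its rest baseline", {
  fs <- 200
  n_block <- (3 + 2 + 5) * fs
  sched <- do.call(rbind, lapply(0:7, function(i) {
    at <- i * n_block
    data.frame(label = "grip", phase = c("rest", "preparation", "movement"),
               start = at + c(0, 3, 5) * fs, end = at + c(3, 5, 10) * fs,
               repetition = i + 1L)
  }))
  rec <- emg_recording(matrix(0, 2, 8 * n_block), fs, sched)
  trials <- segment_by_cues(rec)
  expect_length(trials, 8L)
  expect_true(all(vapply(trials, function(tr) ncol(tr$signal), 1L) == 5 * fs))
  expect_true(all(vapply(trials, function(tr) ncol(tr$baseline), 1L) == 3 * fs))
  empty <- emg_recording(matrix(0, 2, 100), fs)
  expect_length(segment_by_cues(empty), 0L)
})

test_that("onset detector finds a step and covers a trapezoid plateau", {
  fs <- 1000
  set.seed(11)
  base <- matrix(rnorm(2 * fs, 0, 1), 2)
  # step at 0.5 s
  sig <- matrix(rnorm(2 * 2 * fs, 0, 1), 2)
  sig[, (fs / 2 + 1):(2 * fs)] <- sig[, (fs / 2 + 1):(2 * fs)] * 10
  iv <- detect_active_interval(list(signal = sig, baseline = base, fs = fs),
                               emg_onset_config())
  expect_lt(abs(iv["onset"] - fs / 2), 0.1 * fs + 1)  # within one smoothing window
  # pure baseline noise: nothing to detect
  expect_error(
    detect_active_interval(list(signal = base, baseline = base, fs = fs)),
    "no activity")
  # trapezoid envelope: detected interval covers >= 95% of the true plateau
  n <- 3 * fs
  env <- c(seq(0, 1, length.out = fs / 4),
           rep(1, 2 * fs + fs / 2),
           seq(1, 0, length.out = fs / 4))
  burst <- matrix(rnorm(2 * n, 0, 1), 2) * rep(env, each = 2) * 8
  burst <- burst + matrix(rnorm(2 * n, 0, 1), 2)
  iv <- detect_active_interval(list(signal = burst, baseline = base, fs = fs))
  plateau <- c(fs / 4, fs / 4 + 2 * fs + fs / 2)
  covered <- min(iv["offset"], plateau[2]) - max(iv["onset"], plateau[1])
  expect_gt(covered / (plateau[2] - plateau[1]), 0.95)
})

test_that("transient trimming removes floor(trim_ms * fs / 1000) per end", {
  iv <- trim_transient(c(0, 10240), fs = 2048, trim_ms = 100)
  expect_equal(unname(iv[2] - iv[1]), 10240 - 2 * 204)
  iv2 <- trim_transient(c(0, 614), 2048)
  expect_equal(unname(iv2[2] - iv2[1]), 206)
  expect_error(trim_transient(c(0, 307), 2048), "too short")
})

test_that("window count formula holds over randomized trial sizes", {
  set.seed(7)
  for (i in 1:25) {
    W <- sample(16:64, 1)
    S <- sample(1:W, 1)
    L <- sample(W:(5 * W), 1)
    trial <- list(signal = matrix(rnorm(2 * L), 2), label = "grip",
                  repetition = 1L, fs = 1000)
    ws <- slide_windows(trial, emg_windowing_config(W, S))
    expect_equal(dim(ws$windows)[1L], (L - W) %/% S + 1L)
    expect_equal(dim(ws$windows)[3L], W)
  }
  # default geometry: 512/128 -> 384-sample overlap; L = 1024 -> 5 windows
  trial <- list(signal = matrix(0, 1, 1024), label = "grip", fs = 2048)
  ws <- slide_windows(trial, emg_windowing_config(512L, 128L))
  expect_equal(dim(ws$windows)[1L], 5L)
  expect_equal(ws$window_len - ws$stride, 384L)
  short <- list(signal = matrix(0, 1, 100), label = "grip", fs = 2048)
  expect_warning(out <- slide_windows(short), "shorter")
  expect_equal(dim(out$windows)[1L], 0L)
})

test_that("windows inherit the trial label and never cross trial boundaries", {
  fs <- 2048
  sched <- data.frame(label = c("grip", "pinch"), phase = "movement",
                      start = c(0L, 2048L), end = c(2048L, 4096L),
                      repetition = c(1L, 2L))
  sched <- rbind(data.frame(label = "grip", phase = "rest", start = 4096L,
                            end = 6144L, repetition = NA_integer_), sched)
  set.seed(2)
  rec <- emg_recording(matrix(rnorm(2 * 6144), 2), fs, sched)
  ws <- suppressWarnings(preprocess_recording(rec, filter_cfg = NULL,
                                              onset_cfg = NULL))
  # each trimmed 2048-sample trial gives (1640 - 512) %/% 128 + 1 = 9 windows
  expect_equal(dim(ws$windows)[1L], 18L)
  expect_equal(sort(unique(ws$labels)), c("grip", "pinch"))
  expect_true(all(table(ws$labels, ws$repetition)[cbind(c("grip", "pinch"),
                                                        c("1", "2"))] == 9L))
})

test_that("repetition splits follow the stated policies and never leak", {
  tx <- emg_taxonomy()
  n <- 120
  ws <- emg_windows(array(0, c(n, 2, 16)),
                    labels = rep(tx$basic_classes[1:2], each = 60),
                    repetition = rep(rep(1:5, each = 12), 2),
                    orientation = rep(rep(c("upward", "sideway", "downward"),
                                          each = 4), 10),
                    window_len = 16L, stride = 16L)
  sp <- split_by_repetitions(ws, "nearlab_3of5")
  expect_equal(dim(sp$train$windows)[1L], 72L)  # 3/5 per (class, orientation)
  expect_identical(intersect(unique(sp$train$repetition),
                             unique(sp$test$repetition)), integer())
  tab <- table(sp$train$labels, sp$train$orientation)
  expect_true(all(tab == 12L))

  ws6 <- emg_windows(array(0, c(12, 2, 16)), rep("grip", 12),
                     repetition = rep(1:6, 2), window_len = 16L, stride = 16L)
  sp6 <- split_by_repetitions(ws6, "ninapro_1346")
  expect_setequal(unique(sp6$train$repetition), c(1L, 3L, 4L, 6L))
  expect_setequal(unique(sp6$test$repetition), c(2L, 5L))

  expect_error(split_by_repetitions(ws6, "custom", train_repetitions = 1,
                                    test_repetitions = 1),
               "overlap")
})
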