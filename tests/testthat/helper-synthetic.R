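# Shared builders for test fixtures.  Everything is generated in code; no
# stored data.

# Short-schedule simulation config: keeps the Nearlab channel count and
# sampling rate but shrinks the per-trial durations so suites stay fast.
quick_sim_cfg <- function(...) {
  args <- list(rest_s = 0.75, prep_s = 0.25, movement_s = 0.65,
               movement_s_combined = 0.9)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# Small network geometry for engine unit tests (4 channels x 64 samples).
tiny_cnet_cfg <- function(n_classes = 3L, variant = "cnet1d",
                          out_act = "softmax") {
  cnet_config(variant, n_channels = 4L, window_len = 64L,
              n_classes = n_classes, conv_filters = c(3L, 4L, 4L),
              pool_size = 4L, out_act = out_act)
}

# Windows with strongly class-specific channel gains: class k boosts
# channel (k mod channels) + 1, so any sane classifier separates them.
separable_windows <- function(classes, n_per_class, channels = 4L, len = 64L,
                              seed = 1L, boost = 3, reps = NULL) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  arr <- array(rnorm(n * channels * len, 0, 0.3), c(n, channels, len))
  labels <- rep(classes, each = n_per_class)
  for (i in seq_len(n)) {
    k <- match(labels[i], classes)
    ch <- ((k - 1L) %% channels) + 1L
    arr[i, ch, ] <- arr[i, ch, ] + rnorm(len, 0, boost)
  }
  ws <- emg_windows(arr, rep(emg_taxonomy()$basic_classes[1L], n),
                    repetition = rep_len(reps %||% 1L, n),
                    window_len = len, stride = 16L)
  ws$labels <- labels  # free-form labels for engine tests
  ws
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row subset that tolerates the free-form labels used in engine tests.
subset_ws <- function(ws, idx) {
  tmp <- ws
  tmp$labels <- rep(emg_taxonomy()$basic_classes[1L], length(ws$labels))
  out <- emgtransfer:::subset_windows(tmp, idx)
  out$labels <- ws$labels[idx]
  out
}

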