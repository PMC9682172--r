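# ---------------------------------------------------------------------------
# Reduced-scale synthetic transfer-learning experiments.  These are the
# package's desk-scale study harnesses: synergy-structured cohorts with the
# Nearlab channel count and sampling rate but shortened schedules, compact
# convolution stacks, and few-epoch schedules.  The problem sizes are
# documented in the methods vignette.
# ---------------------------------------------------------------------------

bench_sim_cfg <- function() {
  sim_config(rest_s = 0.75, prep_s = 0.25, movement_s = 0.65,
             movement_s_combined = 0.9)
}

bench_arch <- function(n_classes) {
  cnet_config("cnet1d", n_classes = n_classes, conv_filters = c(4L, 6L, 6L))
}

bench_train_cfg <- function(seed, epochs = 8L, batch_size = 64L, lr = 0.002) {
  emg_train_config(epochs = epochs, batch_size = batch_size, lr = lr,
                   seed = seed)
}

# One subject's preprocessed windows for the basic (and optionally combined)
# protocol, split by repetition.
bench_subject_windows <- function(bank, cfg, seed, reps = 3L,
                                  classes = NULL, train_reps = c(1L, 2L)) {
  recs <- simulate_cohort(bank, cfg, n_subjects = 1L, classes = classes,
                          reps = reps, orientations = "sideway", seed = seed)
  ws <- cohort_windows(recs)[[1L]]
  split_by_repetitions(ws, "custom", train_repetitions = train_reps,
                       test_repetitions = setdiff(seq_len(reps), train_reps))
}

#' Synthetic subject-transfer experiment: PFCnet vs target-only training
#'
#' For each seed, simulates a cohort of subjects sharing one synergy bank
#' (subject-specific channel-gain jitter), limits the target subject's
#' training data to a single repetition, trains a target-only Cnet1D and a
#' PFCnet whose source extractor was trained on the pooled remaining
#' subjects, and scores both on the target's held-out repetition.
#'
#' @param n_seeds Number of independent replicates.
#' @param seed Base seed; replicate `k` derives its own stream.
#' @param n_subjects Cohort size (first subject is the target).
#' @param epochs Training epochs for every network.
#' @return Data frame with one row per seed: `acc_target_only`, `acc_pfcnet`.
#' @export
subject_transfer_experiment <- function(n_seeds = 10L, seed = 1L,
                                        n_subjects = 5L, epochs = 8L) {
  cfg <- bench_sim_cfg()
  out <- data.frame()
  for (k in seq_len(n_seeds)) {
    sk <- function(j) derive_seed(seed, 1000L * k + j)
    bank <- make_synergy_bank(n_channels = cfg$n_channels, seed = sk(1L))
    # two held-out repetitions keep the per-seed accuracy estimate tight
    recs <- simulate_cohort(bank, cfg, n_subjects = n_subjects, reps = 4L,
                            orientations = "sideway", seed = sk(2L))
    wsets <- cohort_windows(recs)
    splits <- lapply(wsets, split_by_repetitions, policy = "custom",
                     train_repetitions = c(1L, 2L), test_repetitions = c(3L, 4L))
    target <- splits[[1L]]
    target_1rep <- restrict_repetitions(target$train, 1 / 2)
    source_ws <- do.call(bind_windows,
                         lapply(splits[-1L], function(s) s$train))
    classes <- attr(bank, "taxonomy")$basic_classes
    src <- train_model(build_cnet(bench_arch(8L), classes, seed = sk(3L)),
                       source_ws, bench_train_cfg(sk(4L), epochs))
    tgt <- train_model(build_cnet(bench_arch(8L), classes, seed = sk(5L)),
                       target_1rep,
                       bench_train_cfg(sk(6L), epochs, batch_size = 32L))
    acc_t <- accuracy(target$test$labels, predict_label(tgt, target$test))
    pfc <- build_pfcnet(tgt, src, seed = sk(7L))
    pfc <- train_model(pfc, target_1rep,
                       bench_train_cfg(sk(8L), epochs, batch_size = 32L,
                                       lr = 0.001))
    acc_p <- accuracy(target$test$labels, predict_label(pfc, target$test))
    out <- rbind(out, data.frame(seed = k, acc_target_only = acc_t,
                                 acc_pfcnet = acc_p))
  }
  out
}

#' Synthetic task-transfer experiment: staged fine-tuning vs scratch training
#'
#' For each seed, trains a basic-movement Cnet1D, fine-tunes it (FTnet, both
#' stages) on one repetition of the six combined movements, trains a Cnet1D
#' from scratch on that same repetition, and scores both on the held-out
#' combined repetitions.
#'
#' @inheritParams subject_transfer_experiment
#' @return Data frame with one row per seed: `acc_ftnet`, `acc_scratch`.
#' @export
task_transfer_experiment <- function(n_seeds = 10L, seed = 1L, epochs = 8L) {
  cfg <- bench_sim_cfg()
  out <- data.frame()
  for (k in seq_len(n_seeds)) {
    sk <- function(j) derive_seed(seed, 2000L * k + j)
    bank <- make_synergy_bank(n_channels = cfg$n_channels, seed = sk(1L))
    tx <- attr(bank, "taxonomy")
    basic <- bench_subject_windows(bank, cfg, sk(2L))
    combined <- bench_subject_windows(bank, cfg, sk(3L),
                                      classes = tx$combined_classes,
                                      train_reps = 1L)
    base <- train_model(build_cnet(bench_arch(8L), tx$basic_classes,
                                   seed = sk(4L)),
                        basic$train, bench_train_cfg(sk(5L), epochs))
    ft <- build_ftnet(base, tx, seed = sk(6L))
    # the staged schedules are cheap (frozen prefix), so the full 400/300
    # epoch schedules are used as-is
    ft <- train_ftnet(ft, combined$train,
                      ftnet_train_config(1L, seed = sk(7L)),
                      ftnet_train_config(2L, seed = sk(8L)))
    acc_ft <- accuracy(combined$test$labels, predict_label(ft, combined$test))
    scratch_cfg <- bench_arch(6L)
    scr <- train_model(build_cnet(scratch_cfg, tx$combined_classes,
                                  seed = sk(9L)),
                       combined$train,
                       bench_train_cfg(sk(10L), epochs, batch_size = 32L))
    acc_s <- accuracy(combined$test$labels, predict_label(scr, combined$test))
    out <- rbind(out, data.frame(seed = k, acc_ftnet = acc_ft,
                                 acc_scratch = acc_s))
  }
  out
}

#' Synthetic zero-shot synergy experiment (Syn0net)
#'
#' Trains a basic-movement Cnet1D on one simulated subject and applies the
#' zero-shot rotation/function decision rule to that subject's simulated
#' combined movements (whose synergies superpose the basic patterns).
#'
#' @param seed Base seed.
#' @param epochs Training epochs for the basic-class network.
#' @return List with the basic-class test accuracy and the combined-set
#'   `overall`, `rotation` and `fun` accuracies.
#' @export
syn0_experiment <- function(seed = 1L, epochs = 8L) {
  cfg <- bench_sim_cfg()
  sk <- function(j) derive_seed(seed, 3000L + j)
  bank <- make_synergy_bank(n_channels = cfg$n_channels, seed = sk(1L))
  tx <- attr(bank, "taxonomy")
  basic <- bench_subject_windows(bank, cfg, sk(2L))
  combined <- bench_subject_windows(bank, cfg, sk(3L),
                                    classes = tx$combined_classes,
                                    train_reps = 1L)
  base <- train_model(build_cnet(bench_arch(8L), tx$basic_classes,
                                 seed = sk(4L)),
                      basic$train, bench_train_cfg(sk(5L), epochs))
  acc_basic <- accuracy(basic$test$labels, predict_label(base, basic$test))
  all_combined <- bind_windows(combined$train, combined$test)
  r <- syn0_evaluate(base, all_combined, tx)
  list(basic_test_accuracy = acc_basic, overall = r$overall,
       rotation = r$rotation, fun = r$fun)
}

#' Synthetic Siamese similarity experiment (Sia5net head)
#'
#' Trains the 301-parameter Siamese head on pairs drawn from a simulated
#' subject's basic-movement training windows and compares the mean
#' similarity score of same-class vs different-class pairs from the held-out
#' repetition (0 = same convention: trained scores should be lower for
#' same-class pairs).
#'
#' @param seed Base seed.
#' @param epochs Training epochs for the base network.
#' @param n_pairs Training pairs for the head.
#' @return List with `same_mean`, `diff_mean`, and the few-shot combined
#'   accuracy `sia5_accuracy` with 5 queries per class.
#' @export
siamese_experiment <- function(seed = 1L, epochs = 8L, n_pairs = 1500L) {
  cfg <- bench_sim_cfg()
  sk <- function(j) derive_seed(seed, 4000L + j)
  bank <- make_synergy_bank(n_channels = cfg$n_channels, seed = sk(1L))
  tx <- attr(bank, "taxonomy")
  basic <- bench_subject_windows(bank, cfg, sk(2L))
  base <- train_model(build_cnet(bench_arch(8L), tx$basic_classes,
                                 seed = sk(3L)),
                      basic$train, bench_train_cfg(sk(4L), epochs))
  sia <- build_siamese(base, seed = sk(5L))
  sia <- train_siamese(sia, basic$train, n_pairs = n_pairs,
                       pair_spec(epochs = 40L), seed = sk(6L))
  test_pairs <- generate_pairs(basic$test, 400L, pair_spec(), seed = sk(7L))
  sc <- siamese_score(sia, subset_windows(basic$test, test_pairs$i),
                      subset_windows(basic$test, test_pairs$j))
  combined <- bench_subject_windows(bank, cfg, sk(8L),
                                    classes = tx$combined_classes,
                                    train_reps = 1L)
  bank5 <- query_bank(combined$train, q = 5L, taxonomy = tx)
  pred <- sia5_classify(sia, bank5, combined$test)
  list(same_mean = mean(sc[test_pairs$same == 0L]),
       diff_mean = mean(sc[test_pairs$same == 1L]),
       sia5_accuracy = accuracy(combined$test$labels, pred))
}

#' Measured attenuation of the filter cascade at a given frequency
#'
#' Feeds a pure sinusoid through [apply_filters()] and measures the
#' steady-state output/input RMS ratio away from the filter edges.
#'
#' @param freq Tone frequency, Hz.
#' @param fs Sampling rate, Hz.
#' @return Gain in dB (negative = attenuation).
#' @export
filter_gain_db <- function(freq, fs = 2048) {
  t <- seq(0, 6, by = 1 / fs)
  rec <- emg_recording(matrix(sin(2 * pi * freq * t), 1), fs = fs)
  out <- apply_filters(rec, emg_filter_config())
  mid <- floor(length(t) / 3):floor(2 * length(t) / 3)
  20 * log10(sqrt(mean(out$signal[1, mid]^2)) / sqrt(0.5))
}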