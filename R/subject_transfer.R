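#' Choose source subjects for subject-transfer
#'
#' `"all_others"` uses every subject except the target (the Nearlab-style
#' setting: 10 sources out of 11 subjects).  `"blocks"` restricts the
#' sources to the target's block of a fixed partition (the Ninapro-style
#' setting: subjects 1-15, 16-30, 31-40).
#'
#' @param all_subjects Character/integer vector of subject ids.
#' @param target The target subject id (must be in `all_subjects`).
#' @param grouping `"all_others"` or `"blocks"`.
#' @param blocks For `grouping = "blocks"`: list of id vectors partitioning
#'   the roster.
#' @return Vector of source subject ids.
#' @export
select_source_subjects <- function(all_subjects, target,
                                   grouping = c("all_others", "blocks"),
                                   blocks = NULL) {
  grouping <- match.arg(grouping)
  if (!target %in% all_subjects) stopf("target '%s' not in the subject roster", target)
  if (grouping == "all_others") {
    return(setdiff(all_subjects, target))
  }
  if (is.null(blocks)) stopf("grouping 'blocks' requires a block partition")
  hit <- which(vapply(blocks, function(b) target %in% b, TRUE))
  if (length(hit) != 1L) stopf("target must belong to exactly one block")
  setdiff(blocks[[hit]], target)
}

#' Build a PFCnet from a target-trained and a source-trained network
#'
#' Takes the convolutional feature extractors (everything up to and
#' including the flatten) of the two trained base networks, freezes their
#' convolution weights (batch-norm scale/shift stay trainable and their
#' inference statistics keep updating), concatenates the two flattened
#' feature vectors, and adds a freshly, randomly initialized classifier head
#' of the same 300/50 design as the base networks.
#'
#' @param target_net `emg_net` trained on the target subject.
#' @param source_net `emg_net` of the same architecture family trained on
#'   the source subjects.
#' @param seed Seed for the head initialization.
#' @return An `emg_net` (also classed `"emg_pfcnet"`) ready for
#'   [train_model()] on the target subject's windows.
#' @export
build_pfcnet <- function(target_net, source_net, seed = 1L) {
  stopifnot(inherits(target_net, "emg_net"), inherits(source_net, "emg_net"))
  if (!identical(target_net$input_shape, source_net$input_shape)) {
    stopf("extractors have incompatible input shapes")
  }
  freeze_extractor <- function(net) {
    walk_layers(net$layers[seq_len(net$flatten_index)], function(l) {
      if (l$type %in% c("conv", "dense")) l$trainable <- FALSE
      l  # BN stays trainable
    })
  }
  branches <- list(freeze_extractor(target_net), freeze_extractor(source_net))
  cfg <- target_net$cfg
  concat_dim <- target_net$feature_width + source_net$feature_width
  with_seed(seed, {
    layers <- c(list(layer_parallel(branches)), list(
      layer_dense(concat_dim, cfg$head_dims[1L]),
      layer_bn(cfg$head_dims[1L]),
      layer_rrelu(cfg$rrelu_lower, cfg$rrelu_upper),
      layer_dropout(cfg$dropout_p),
      layer_dense(cfg$head_dims[1L], cfg$head_dims[2L]),
      layer_bn(cfg$head_dims[2L]),
      layer_rrelu(cfg$rrelu_lower, cfg$rrelu_upper),
      layer_dense(cfg$head_dims[2L], cfg$n_classes)))
    structure(list(layers = layers, cfg = cfg,
                   input_shape = target_net$input_shape,
                   classes = target_net$classes, out_act = "softmax",
                   feature_width = concat_dim, flatten_index = 1L,
                   repr_index = 4L, history = NULL, best_epoch = NULL),
              class = c("emg_pfcnet", "emg_net"))
  })
}

#' PFCnet final-stage training schedules
#'
#' Nearlab-style final stage: learning rate 0.001, 200 epochs, patience 80;
#' the corresponding source-network schedule is learning rate 0.003 for 100
#' epochs.  Ninapro-style: source 0.0003 for 200 epochs (patience 80), final
#' stage decaying 0.001 to 1e-6 over 400 epochs.
#'
#' @param style `"nearlab"` or `"ninapro"`.
#' @param stage `"source"` or `"final"`.
#' @param ... Overrides passed to [emg_train_config()].
#' @return An [emg_train_config()].
#' @export
pfcnet_train_config <- function(style = c("nearlab", "ninapro"),
                                stage = c("final", "source"), ...) {
  style <- match.arg(style)
  stage <- match.arg(stage)
  base <- switch(paste(style, stage),
    "nearlab source" = list(epochs = 100L, lr = 0.003, patience = Inf),
    "nearlab final" = list(epochs = 200L, lr = 0.001, patience = 80),
    "ninapro source" = list(epochs = 200L, lr = 0.0003, patience = 80),
    "ninapro final" = list(epochs = 400L, lr = 0.001, lr_end = 1e-6, patience = Inf))
  base$batch_size <- 128L
  over <- list(...)
  base[names(over)] <- over
  do.call(emg_train_config, base)
}

#' Restrict a training set to a whole-repetition fraction
#'
#' Data-budget fractions are realized by whole-repetition removal: per
#' (class, orientation, subject) cell, the first `k` of the `m` repetitions
#' (in id order) are retained, where `fraction = k / m` must be exact.
#'
#' @param ws An [emg_windows()] set with repetition ids.
#' @param fraction Fraction of repetitions to keep (e.g. 1/3, 2/3, 1).
#' @return The restricted [emg_windows()] set.
#' @export
restrict_repetitions <- function(ws, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  if (anyNA(ws$repetition)) stopf("window set lacks repetition ids")
  keep <- logical(n_windows(ws))
  key <- paste(ws$labels, ws$orientation, ws$subject_id)
  for (k in unique(key)) {
    idx <- which(key == k)
    reps <- sort(unique(ws$repetition[idx]))
    k_keep <- fraction * length(reps)
    if (abs(k_keep - round(k_keep)) > 1e-9) {
      stopf("fraction %.3f is not a whole number of the %d repetitions",
            fraction, length(reps))
    }
    keep[idx] <- ws$repetition[idx] %in% reps[seq_len(round(k_keep))]
  }
  subset_windows(ws, which(keep))
}

#' Data-budget comparison of a target-only network and PFCnet
#'
#' For each training-data fraction (realized by whole-repetition removal),
#' trains a target-only base network and a PFCnet on the restricted target
#' training windows (the PFCnet's source extractor is given, pre-trained on
#' other subjects) and reports test accuracy for both.
#'
#' @param train_ws,test_ws Target subject's training and test windows.
#' @param source_net Pre-trained source network (see [build_pfcnet()]).
#' @param arch_cfg [cnet_config()] for the target network.
#' @param fractions Numeric vector of data fractions.
#' @param train_cfg [emg_train_config()] for the target network; the PFCnet
#'   head uses the same schedule.
#' @param seed Seed family for builds and training.
#' @return Data frame with columns `fraction`, `method`, `accuracy`.
#' @export
data_budget_experiment <- function(train_ws, test_ws, source_net, arch_cfg,
                                   fractions = c(1 / 3, 2 / 3, 1),
                                   train_cfg = emg_train_config(), seed = 1L) {
  out <- data.frame()
  for (fi in seq_along(fractions)) {
    fr <- fractions[fi]
    ws_fr <- restrict_repetitions(train_ws, fr)
    tcfg <- train_cfg
    tcfg$seed <- derive_seed(seed, fi)
    target <- build_cnet(arch_cfg, classes = source_net$classes,
                         seed = derive_seed(seed, 100L + fi))
    target <- train_model(target, ws_fr, tcfg)
    acc_t <- accuracy(test_ws$labels, predict_label(target, test_ws))
    pfc <- build_pfcnet(target, source_net, seed = derive_seed(seed, 200L + fi))
    pfc <- train_model(pfc, ws_fr, tcfg)
    acc_p <- accuracy(test_ws$labels, predict_label(pfc, test_ws))
    out <- rbind(out,
                 data.frame(fraction = fr, method = c("target_only", "pfcnet"),
                            accuracy = c(acc_t, acc_p)))
  }
  out
}
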