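# ---------------------------------------------------------------------------
# Task transfer: classifying the 6 combined movements from models trained on
# the 8 basic movements, in three stages: a zero-shot synergy decision rule,
# a Siamese few-shot similarity classifier, and staged fine-tuning.
# ---------------------------------------------------------------------------

#' Zero-shot synergy decision rule over basic-class activations
#'
#' Predicts a combined class from an activation vector over the 8 basic
#' classes: the rotation is the more active of pronation/supination, the
#' hand function the most active of pinch/lateral pinch/grip; the remaining
#' basic-class activations are ignored.  Ties break to the lowest index.
#'
#' @param prob Numeric vector of activations over the basic classes, in
#'   `taxonomy$basic_classes` order (or named by class token).
#' @param taxonomy An [emg_taxonomy()].
#' @return The composed combined-class token.
#' @export
syn0_predict <- function(prob, taxonomy = emg_taxonomy()) {
  if (!is.null(names(prob))) prob <- prob[taxonomy$basic_classes]
  if (length(prob) != length(taxonomy$basic_classes) || any(!is.finite(prob))) {
    stopf("need one finite activation per basic class")
  }
  rot <- taxonomy$rotations[which.max(prob[taxonomy$rotation_indices])]
  fun <- taxonomy$functions[which.max(prob[taxonomy$function_indices])]
  compose_combined(rot, fun, taxonomy)
}

#' Evaluate the zero-shot rule on combined-movement windows
#'
#' Applies [syn0_predict()] to the model's activation rows (softmax or
#' sigmoid head, as the model was trained) and scores the overall, rotation,
#' and hand-function accuracies against the decomposed true labels.
#'
#' @param net A basic-class-trained `emg_net` (8 outputs).
#' @param ws Combined-movement [emg_windows()].
#' @param taxonomy An [emg_taxonomy()].
#' @return List with `overall`, `rotation`, `fun` accuracies and the
#'   predicted label vector.
#' @export
syn0_evaluate <- function(net, ws, taxonomy = emg_taxonomy()) {
  if (n_windows(ws) == 0L) stopf("no windows to evaluate")
  if (any(!ws$labels %in% taxonomy$combined_classes)) {
    stopf("window labels must be combined classes")
  }
  p <- predict_proba(net, ws)
  preds <- apply(p, 1L, syn0_predict, taxonomy = taxonomy)
  truth <- t(vapply(ws$labels, decompose_combined, c(rotation = "", fun = ""),
                    taxonomy = taxonomy))
  pred_parts <- t(vapply(preds, decompose_combined, c(rotation = "", fun = ""),
                         taxonomy = taxonomy))
  list(overall = mean(preds == ws$labels),
       rotation = mean(pred_parts[, "rotation"] == truth[, "rotation"]),
       fun = mean(pred_parts[, "fun"] == truth[, "fun"]),
       predictions = unname(preds))
}

# ---- Siamese few-shot (Sia5net) -------------------------------------------

#' Pair-generation specification for Siamese training
#'
#' Same-class pairs are labeled 0, different-class pairs 1.  Negative pairs
#' are drawn by category: function-function (two different hand functions),
#' rotation-rotation (pronation vs supination), and "other" (any remaining
#' cross-class pair).  The default mix emphasizes separating functions from
#' functions and rotations from rotations, since every combined movement
#' contains one of each, while rotation-vs-function separation matters less.
#'
#' @param positive_fraction Share of same-class pairs.
#' @param negative_mix Named weights over
#'   `c(function_function, rotation_rotation, other)`; must sum to 1.
#' @param batch_size,epochs,lr,lr_end Training schedule of the similarity
#'   head (defaults: 32, 100 epochs, learning rate decaying 0.001 to 5e-5).
#' @return A list of class `"emg_pair_spec"`.
#' @export
pair_spec <- function(positive_fraction = 0.5,
                      negative_mix = c(function_function = 0.4,
                                       rotation_rotation = 0.4, other = 0.2),
                      batch_size = 32L, epochs = 100L, lr = 0.001,
                      lr_end = 5e-5) {
  stopifnot(positive_fraction > 0, positive_fraction < 1,
            abs(sum(negative_mix) - 1) < 1e-9, length(negative_mix) == 3L)
  structure(list(positive_fraction = positive_fraction,
                 negative_mix = negative_mix, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, lr_end = lr_end),
            class = "emg_pair_spec")
}

#' Generate labeled training pairs from basic-class windows
#'
#' @param ws Basic-class [emg_windows()] (every present class needs at least
#'   2 windows for positive sampling).
#' @param n_pairs Number of pairs to draw.
#' @param spec A [pair_spec()].
#' @param seed RNG seed; the stream is reproducible.
#' @return Data frame with window indices `i`, `j`, `same` (0 = same class,
#'   1 = different) and the negative `kind`.
#' @export
generate_pairs <- function(ws, n_pairs, spec = pair_spec(), seed = 1L) {
  labels <- ws$labels
  tab <- table(labels)
  if (any(tab < 2L)) {
    stopf("class '%s' has fewer than 2 windows; cannot sample positive pairs",
          names(tab)[which(tab < 2L)[1L]])
  }
  tx <- ws$taxonomy
  classes <- names(tab)
  by_class <- split(seq_along(labels), labels)
  funs <- intersect(tx$functions, classes)
  rots <- intersect(tx$rotations, classes)
  if (spec$negative_mix[["function_function"]] > 0 && length(funs) < 2L) {
    stopf("function-function pairs need >= 2 hand-function classes in the data")
  }
  if (spec$negative_mix[["rotation_rotation"]] > 0 && length(rots) < 2L) {
    stopf("rotation-rotation pairs need both rotation classes in the data")
  }
  n_pos <- round(spec$positive_fraction * n_pairs)
  with_seed(seed, {
    out_i <- integer(n_pairs); out_j <- integer(n_pairs)
    out_same <- integer(n_pairs); out_kind <- character(n_pairs)
    for (k in seq_len(n_pos)) {
      cl <- sample(classes, 1L)
      ij <- sample(by_class[[cl]], 2L)
      out_i[k] <- ij[1L]; out_j[k] <- ij[2L]
      out_same[k] <- 0L; out_kind[k] <- "positive"
    }
    kinds <- sample(names(spec$negative_mix), n_pairs - n_pos, replace = TRUE,
                    prob = spec$negative_mix)
    for (k in seq_len(n_pairs - n_pos)) {
      pair_cls <- switch(kinds[k],
        function_function = sample(funs, 2L),
        rotation_rotation = sample(rots, 2L),
        other = {
          repeat {
            cand <- sample(classes, 2L)
            ff <- all(cand %in% funs)
            rr <- all(cand %in% rots)
            if (!ff && !rr) break
          }
          cand
        })
      out_i[n_pos + k] <- sample(by_class[[pair_cls[1L]]], 1L)
      out_j[n_pos + k] <- sample(by_class[[pair_cls[2L]]], 1L)
      out_same[n_pos + k] <- 1L
      out_kind[n_pos + k] <- kinds[k]
    }
    data.frame(i = out_i, j = out_j, same = out_same, kind = out_kind)
  })
}

#' Build a Siamese similarity model from a trained base network
#'
#' The two weight-shared branches are the base network up to its 300-unit
#' representation (the 50-unit and output layers are removed); they are
#' joined by an element-wise L1 distance layer and a single sigmoid output
#' unit.  All inherited weights are frozen, leaving 300 weights + 1 bias =
#' 301 trainable parameters.  Output convention: 0 = same class,
#' 1 = different class.
#'
#' @param base A trained `emg_net` with a 300/50 head.
#' @param seed Seed for head initialization.
#' @return An object of class `"emg_siamese"`.
#' @export
build_siamese <- function(base, seed = 1L) {
  stopifnot(inherits(base, "emg_net"))
  if (is.null(base$repr_index) || base$cfg$head_dims[1L] < 1L) {
    stopf("base network lacks the 300-unit representation layer")
  }
  nf <- base$cfg$head_dims[1L]
  base$layers <- walk_layers(base$layers, function(l) { l$trainable <- FALSE; l })
  with_seed(seed, {
    structure(list(base = base, w = stats::rnorm(nf, 0, 0.05), b = 0,
                   n_features = nf, trained = FALSE, history = NULL),
              class = "emg_siamese")
  })
}

#' @export
print.emg_siamese <- function(x, ...) {
  cat(sprintf("Siamese similarity model: %d-d L1 distance head, %d trainable parameters%s\n",
              x$n_features, count_trainable(x),
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

# Similarity scores for index pairs over a precomputed feature matrix.
siamese_score_features <- function(model, feats, i, j) {
  d <- abs(feats[, i, drop = FALSE] - feats[, j, drop = FALSE])
  as.numeric(1 / (1 + exp(-(crossprod(d, model$w) + model$b))))
}

#' Pairwise similarity score of a Siamese model
#'
#' @param model A (trained) [build_siamese()] model.
#' @param ws_a,ws_b [emg_windows()] sets of equal size; scored pairwise.
#' @return Numeric vector of sigmoid scores in (0, 1); 0 = same class.
#' @export
siamese_score <- function(model, ws_a, ws_b) {
  fa <- extract_features(model$base, ws_a)
  fb <- extract_features(model$base, ws_b)
  d <- abs(fa - fb)
  as.numeric(1 / (1 + exp(-(crossprod(d, model$w) + model$b))))
}

#' Train the 301-parameter Siamese similarity head
#'
#' Branch weights are frozen, so branch features are computed once; only the
#' distance-layer weights and bias are optimized (Adam, binary cross-entropy,
#' 0 = same-class convention).
#'
#' @param model A [build_siamese()] model.
#' @param ws Basic-class [emg_windows()] used to draw training pairs.
#' @param n_pairs Number of training pairs.
#' @param spec A [pair_spec()] (mix and schedule).
#' @param seed RNG seed for pair generation and shuffling.
#' @return The trained model with a loss `history`.
#' @export
train_siamese <- function(model, ws, n_pairs = 2000L, spec = pair_spec(),
                          seed = 1L) {
  stopifnot(inherits(model, "emg_siamese"))
  pairs <- generate_pairs(ws, n_pairs, spec, seed = derive_seed(seed, 1L))
  if (nrow(pairs) == 0L) stopf("empty pair stream")
  feats <- extract_features(model$base, ws)
  D <- abs(feats[, pairs$i, drop = FALSE] - feats[, pairs$j, drop = FALSE])
  y <- pairs$same
  with_seed(derive_seed(seed, 2L), {
    w <- model$w; b <- model$b
    mw <- w * 0; vw <- w * 0; mb <- 0; vb <- 0
    t_adam <- 0L
    hist <- numeric(spec$epochs)
    for (ep in seq_len(spec$epochs)) {
      lr <- if (spec$epochs == 1L) spec$lr else
        spec$lr * (spec$lr_end / spec$lr)^((ep - 1) / (spec$epochs - 1))
      ord <- sample.int(nrow(pairs))
      ep_loss <- 0
      for (at in seq(1L, length(ord), by = spec$batch_size)) {
        idx <- ord[at:min(at + spec$batch_size - 1L, length(ord))]
        z <- as.numeric(crossprod(D[, idx, drop = FALSE], w)) + b
        p <- 1 / (1 + exp(-z))
        ep_loss <- ep_loss - sum(y[idx] * log(pmax(p, 1e-12)) +
                                 (1 - y[idx]) * log(pmax(1 - p, 1e-12)))
        dz <- (p - y[idx]) / length(idx)
        gw <- as.numeric(D[, idx, drop = FALSE] %*% dz)
        gb <- sum(dz)
        t_adam <- t_adam + 1L
        mw <- 0.9 * mw + 0.1 * gw; vw <- 0.999 * vw + 0.001 * gw^2
        mb <- 0.9 * mb + 0.1 * gb; vb <- 0.999 * vb + 0.001 * gb^2
        w <- w - lr * (mw / (1 - 0.9^t_adam)) / (sqrt(vw / (1 - 0.999^t_adam)) + 1e-8)
        b <- b - lr * (mb / (1 - 0.9^t_adam)) / (sqrt(vb / (1 - 0.999^t_adam)) + 1e-8)
      }
      hist[ep] <- ep_loss / nrow(pairs)
    }
    model$w <- w; model$b <- b
    model$trained <- TRUE
    model$history <- data.frame(epoch = seq_len(spec$epochs), train_loss = hist)
  })
  model
}

#' Build a query bank for few-shot classification
#'
#' @param ws Combined-class [emg_windows()].
#' @param q Query windows per class (default 5).
#' @param seed `NULL` takes the first `q` windows of each class in window
#'   order; an integer seed samples them randomly.
#' @param taxonomy An [emg_taxonomy()].
#' @return List of class `"emg_query_bank"`: per combined class, a window
#'   array `[q, channels, len]`.
#' @export
query_bank <- function(ws, q = 5L, seed = NULL, taxonomy = emg_taxonomy()) {
  banks <- list()
  for (cl in taxonomy$combined_classes) {
    idx <- which(ws$labels == cl)
    if (length(idx) < q) stopf("class '%s' has %d windows, need %d queries",
                               cl, length(idx), q)
    take <- if (is.null(seed)) idx[seq_len(q)] else
      with_seed(derive_seed(seed, match(cl, taxonomy$combined_classes)),
                sample(idx, q))
    banks[[cl]] <- ws$windows[take, , , drop = FALSE]
  }
  structure(list(queries = banks, q = q, taxonomy = taxonomy,
                 window_len = ws$window_len, stride = ws$stride),
            class = "emg_query_bank")
}

#' Few-shot classification with a trained Siamese model (Sia5net)
#'
#' Scores each sample against the `q` query windows of every combined class.
#' `"mean_score"` predicts the class with the lowest mean similarity score
#' (0 = same convention); `"majority_vote"` gives one vote per query round
#' (the class attaining the round's minimum score) and predicts the most
#' voted class.  All ties break to the lowest class index in taxonomy order.
#'
#' @param model A trained [build_siamese()] model.
#' @param bank A [query_bank()].
#' @param ws Windows to classify.
#' @param mode `"mean_score"` or `"majority_vote"`.
#' @return Character vector of predicted combined-class tokens.
#' @export
sia5_classify <- function(model, bank, ws,
                          mode = c("mean_score", "majority_vote")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "emg_siamese"), inherits(bank, "emg_query_bank"))
  tx <- bank$taxonomy
  classes <- tx$combined_classes
  if (!all(classes %in% names(bank$queries))) stopf("query bank is incomplete")
  f_s <- extract_features(model$base, ws)
  n <- ncol(f_s)
  # scores[n, q, class]
  scores <- array(0, c(n, bank$q, length(classes)))
  for (ci in seq_along(classes)) {
    fq <- extract_features(model$base, bank$queries[[classes[ci]]])
    for (qi in seq_len(bank$q)) {
      d <- abs(f_s - fq[, qi])
      scores[, qi, ci] <- 1 / (1 + exp(-(as.numeric(crossprod(d, model$w)) + model$b)))
    }
  }
  if (mode == "mean_score") {
    m <- apply(scores, c(1L, 3L), mean)
    classes[apply(m, 1L, which.min)]
  } else {
    votes <- matrix(0L, n, length(classes))
    for (qi in seq_len(bank$q)) {
      win <- apply(scores[, qi, , drop = FALSE], 1L, which.min)
      votes[cbind(seq_len(n), win)] <- votes[cbind(seq_len(n), win)] + 1L
    }
    classes[apply(votes, 1L, which.max)]
  }
}

# ---- staged fine-tuning (FTnet) -------------------------------------------

#' Build an FTnet: re-headed basic-class network for combined movements
#'
#' Replaces the base network's output layer with a 6-unit sigmoid layer for
#' the combined classes.  Stage-1 freeze mask: only the new layer trains
#' (50 x 6 + 6 = 306 parameters).  [ftnet_unlock_stage2()] additionally
#' unlocks the 50-unit fully connected block (its dense layer and batch
#' norm), bringing the trainable set to 15,050 + 100 + 306 = 15,456.
#'
#' @param base A trained basic-class `emg_net`.
#' @param taxonomy An [emg_taxonomy()]; the head covers its combined classes.
#' @param seed Seed for the new layer's initialization.
#' @return An `emg_net` (also classed `"emg_ftnet"`) with `stage = 1`.
#' @export
build_ftnet <- function(base, taxonomy = emg_taxonomy(), seed = 1L) {
  stopifnot(inherits(base, "emg_net"))
  n_out <- length(taxonomy$combined_classes)
  last <- length(base$layers)
  if (base$layers[[last]]$type != "dense") stopf("base head is incompatible")
  base$layers <- walk_layers(base$layers, function(l) { l$trainable <- FALSE; l })
  with_seed(seed, {
    base$layers[[last]] <- layer_dense(base$cfg$head_dims[2L], n_out)
  })
  base$classes <- taxonomy$combined_classes
  base$out_act <- "sigmoid"
  base$cfg$n_classes <- n_out
  base$cfg$out_act <- "sigmoid"
  base$stage <- 1L
  class(base) <- c("emg_ftnet", "emg_net")
  base
}

#' @rdname build_ftnet
#' @export
ftnet_unlock_stage2 <- function(net) {
  stopifnot(inherits(net, "emg_ftnet"))
  i_dense50 <- net$flatten_index + 5L  # dense 300 -> 50
  net$layers[[i_dense50]]$trainable <- TRUE
  net$layers[[i_dense50 + 1L]]$trainable <- TRUE  # its batch norm
  net$stage <- 2L
  net
}

#' Staged FTnet training schedules
#'
#' Stage 1 (new 306-parameter layer): 400 epochs, learning rate decaying
#' 0.01 to 2e-6, batch 128.  Stage 2 (15,456-parameter fine-tune): 300
#' epochs at 0.0001, batch 128.
#'
#' @param stage 1 or 2.
#' @param ... Overrides passed to [emg_train_config()].
#' @return An [emg_train_config()].
#' @export
ftnet_train_config <- function(stage = 1L, ...) {
  base <- if (stage == 1L) {
    list(epochs = 400L, batch_size = 128L, lr = 0.01, lr_end = 2e-6)
  } else {
    list(epochs = 300L, batch_size = 128L, lr = 1e-4)
  }
  over <- list(...)
  base[names(over)] <- over
  do.call(emg_train_config, base)
}

#' Train an FTnet in two stages on combined-movement windows
#'
#' Stage 1 trains the new 6-unit sigmoid layer (per-unit binary
#' cross-entropy against one-hot targets); stage 2 unlocks the 50-unit block
#' and fine-tunes.  Typically `ws` is a single repetition of each combined
#' class; all 6 classes must be represented.
#'
#' @param net A [build_ftnet()] model at stage 1.
#' @param ws Combined-class training [emg_windows()].
#' @param stage1_cfg,stage2_cfg [ftnet_train_config()] schedules.
#' @return The trained `emg_ftnet` (stage 2 weights; per-stage histories in
#'   `history_stage1` / `history`).
#' @export
train_ftnet <- function(net, ws,
                        stage1_cfg = ftnet_train_config(1L),
                        stage2_cfg = ftnet_train_config(2L)) {
  stopifnot(inherits(net, "emg_ftnet"))
  if (n_windows(ws) == 0L) stopf("no combined-movement training windows")
  missing <- setdiff(net$classes, unique(ws$labels))
  if (length(missing)) stopf("missing combined class(es): %s",
                             paste(missing, collapse = ", "))
  net <- train_model(net, ws, stage1_cfg)
  net$history_stage1 <- net$history
  net <- ftnet_unlock_stage2(net)
  net <- train_model(net, ws, stage2_cfg)
  net
}
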