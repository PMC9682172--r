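#' Hyperparameters of the reference classical classifiers
#'
#' KNN with 40 neighbors (Euclidean metric), linear-kernel SVM with C = 1,
#' a single-hidden-layer MLP with 300 tanh units trained with Adam at
#' learning rate 1e-4, and LDA (no hyperparameters).
#'
#' @param knn_k Number of neighbors.
#' @param svm_cost SVM regularization parameter.
#' @param mlp_hidden Hidden-layer width.
#' @param mlp_lr MLP learning rate.
#' @param mlp_epochs MLP training epochs.
#' @param seed Seed for the MLP.
#' @return A list of class `"emg_classical_config"`.
#' @export
classical_config <- function(knn_k = 40L, svm_cost = 1, mlp_hidden = 300L,
                             mlp_lr = 1e-4, mlp_epochs = 150L, seed = 1L) {
  structure(list(knn_k = as.integer(knn_k), svm_cost = svm_cost,
                 mlp_hidden = as.integer(mlp_hidden), mlp_lr = mlp_lr,
                 mlp_epochs = as.integer(mlp_epochs), seed = seed),
            class = "emg_classical_config")
}

#' Fit a reference classical classifier on a scaled feature table
#'
#' @param name One of `"knn"`, `"svm"`, `"mlp"`, `"lda"`.
#' @param table A scaled [compute_feature_table()] (see [scale_features()]).
#' @param cfg A [classical_config()].
#' @return A fitted model of class `"emg_classical"`.
#' @export
train_classical <- function(name = c("knn", "svm", "mlp", "lda"), table,
                            cfg = classical_config()) {
  name <- match.arg(name)
  stopifnot(inherits(table, "emg_feature_table"))
  if (is.null(table$center)) stopf("feature table must be scaled first")
  x <- table$x
  y <- factor(table$labels)
  if (nlevels(y) < 2L) stopf("training data has a single class")
  fit <- switch(name,
    knn = {
      if (nrow(x) < cfg$knn_k) {
        stopf("only %d training rows for k = %d neighbors; reduce knn_k",
              nrow(x), cfg$knn_k)
      }
      list(x = x, y = y, k = cfg$knn_k)  # lazy learner
    },
    svm = e1071::svm(x, y, kernel = "linear", cost = cfg$svm_cost, scale = FALSE),
    lda = MASS::lda(x, grouping = y),
    mlp = {
      net <- with_seed(cfg$seed, {
        layers <- list(layer_dense(ncol(x), cfg$mlp_hidden), layer_tanh(),
                       layer_dense(cfg$mlp_hidden, nlevels(y)))
        structure(list(layers = layers, cfg = list(head_dims = c(cfg$mlp_hidden, 0L)),
                       input_shape = NULL, classes = levels(y),
                       out_act = "softmax"), class = "emg_net")
      })
      train_dense_net(net, t(x), y, epochs = cfg$mlp_epochs, lr = cfg$mlp_lr,
                      seed = cfg$seed)
    })
  structure(list(name = name, fit = fit, classes = levels(y), cfg = cfg),
            class = "emg_classical")
}

# Plain Adam training for a dense-only net on a [features x n] matrix.
train_dense_net <- function(net, xm, y, epochs, lr, batch_size = 128L, seed = 1L) {
  Y <- matrix(0, nlevels(y), ncol(xm))
  Y[cbind(as.integer(y), seq_len(ncol(xm)))] <- 1
  with_seed(seed, {
    state <- vector("list", length(net$layers))
    t_adam <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(ncol(xm))
      for (at in seq(1L, length(ord), by = batch_size)) {
        idx <- ord[at:min(at + batch_size - 1L, length(ord))]
        fw <- forward_layers(net$layers, xm[, idx, drop = FALSE], "train")
        lg <- loss_and_grad(fw$out, Y[, idx, drop = FALSE], "softmax")
        bw <- backward_layers(net$layers, fw$caches, lg$dz)
        t_adam <- t_adam + 1L
        up <- adam_step(net$layers, bw$grads, state, lr, t_adam)
        net$layers <- up$layers
        state <- up$state
      }
    }
  })
  net
}

#' @rdname train_classical
#' @param model A fitted `emg_classical`.
#' @export
predict_classical <- function(model, table) {
  stopifnot(inherits(model, "emg_classical"))
  x <- table$x
  out <- switch(model$name,
    knn = as.character(class::knn(model$fit$x, x, model$fit$y, k = model$fit$k)),
    svm = as.character(predict(model$fit, x)),
    lda = as.character(predict(model$fit, x)$class),
    mlp = {
      z <- forward_layers(model$fit$layers, t(x), "eval")$out
      model$fit$classes[apply(z, 2L, which.max)]
    })
  out
}
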