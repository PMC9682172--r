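#' Architecture configuration for the compact sEMG CNNs
#'
#' Both variants stack 3 convolution blocks (convolution, batch
#' normalization, RReLU, max-pool along time, dropout) and a classifier head
#' of two fully connected blocks (300 and 50 units) ending in an `n_classes`
#' output layer.  `cnet2d` kernels span 3 adjacent channels ('valid' along
#' the channel axis, so electrode adjacency matters); `cnet1d` kernels never
#' cross channels.  Kernel time-extents are 13, 9, 5; time padding is 'same'.
#'
#' @param variant `"cnet1d"` or `"cnet2d"`.
#' @param n_channels,window_len Input geometry (default 10 x 512).
#' @param n_classes Number of output classes.
#' @param conv_filters Filters per convolution block.  The fixed
#'   parameter-count targets concern the head only and are independent of
#'   this choice; default `c(32, 64, 64)`.
#' @param pool_size Max-pool width along time: 4 for 2048 Hz Nearlab-style
#'   inputs, 3 for Ninapro-style.
#' @param dropout_p Dropout probability.
#' @param rrelu_lower,rrelu_upper RReLU slope bounds.
#' @param head_dims Fully connected widths before the output layer.
#' @param out_act Output activation, `"softmax"` (default) or `"sigmoid"`.
#' @return A list of class `"emg_cnet_config"`.
#' @export
cnet_config <- function(variant = c("cnet1d", "cnet2d"), n_channels = 10L,
                        window_len = 512L, n_classes = 8L,
                        conv_filters = c(32L, 64L, 64L), pool_size = 4L,
                        dropout_p = 0.3, rrelu_lower = 1 / 8,
                        rrelu_upper = 1 / 3, head_dims = c(300L, 50L),
                        out_act = c("softmax", "sigmoid")) {
  variant <- match.arg(variant)
  out_act <- match.arg(out_act)
  stopifnot(length(conv_filters) == 3L, length(head_dims) == 2L)
  structure(list(variant = variant, n_channels = as.integer(n_channels),
                 window_len = as.integer(window_len),
                 n_classes = as.integer(n_classes),
                 conv_filters = as.integer(conv_filters),
                 kernel_h = if (variant == "cnet2d") c(3L, 3L, 3L) else c(1L, 1L, 1L),
                 kernel_w = c(13L, 9L, 5L),
                 pool_size = as.integer(pool_size), dropout_p = dropout_p,
                 rrelu_lower = rrelu_lower, rrelu_upper = rrelu_upper,
                 head_dims = as.integer(head_dims), out_act = out_act),
            class = "emg_cnet_config")
}

#' Build a Cnet1D / Cnet2D network
#'
#' Assembles the layer stack of [cnet_config()] with seeded random
#' initialization and validates the shape arithmetic (each pool must leave
#' at least one time sample; `cnet2d` kernels shrink the channel extent by 2
#' per block).
#'
#' @param cfg A [cnet_config()].
#' @param classes Character vector of class tokens (length `n_classes`);
#'   column order of [predict_proba()].
#' @param seed Seed for weight initialization.
#' @return An object of class `"emg_net"`.
#' @export
build_cnet <- function(cfg, classes = NULL, seed = 1L) {
  stopifnot(inherits(cfg, "emg_cnet_config"))
  if (is.null(classes)) classes <- paste0("class_", seq_len(cfg$n_classes))
  if (length(classes) != cfg$n_classes) {
    stopf("%d classes supplied for an %d-class head", length(classes), cfg$n_classes)
  }
  with_seed(seed, {
    layers <- list()
    H <- cfg$n_channels; W <- cfg$window_len; C <- 1L
    shapes <- character()
    for (b in 1:3) {
      kh <- cfg$kernel_h[b]
      H_new <- H - kh + 1L
      W_new <- W %/% cfg$pool_size
      shapes <- c(shapes, sprintf("block %d: conv -> [%d x %d x %d], pool -> [%d x %d x %d]",
                                  b, cfg$conv_filters[b], H_new, W,
                                  cfg$conv_filters[b], H_new, W_new))
      if (H_new < 1L || W_new < 1L) {
        stopf("architecture does not fit the input:\n%s", paste(shapes, collapse = "\n"))
      }
      layers <- c(layers, list(
        layer_conv(C, cfg$conv_filters[b], kh, cfg$kernel_w[b]),
        layer_bn(cfg$conv_filters[b]),
        layer_rrelu(cfg$rrelu_lower, cfg$rrelu_upper),
        layer_pool(cfg$pool_size),
        layer_dropout(cfg$dropout_p)))
      C <- cfg$conv_filters[b]; H <- H_new; W <- W_new
    }
    feat_width <- C * H * W
    layers <- c(layers, list(layer_flatten()))
    flatten_index <- length(layers)
    layers <- c(layers, list(
      layer_dense(feat_width, cfg$head_dims[1L]),
      layer_bn(cfg$head_dims[1L]),
      layer_rrelu(cfg$rrelu_lower, cfg$rrelu_upper),
      layer_dropout(cfg$dropout_p)))
    repr_index <- length(layers) - 1L  # RReLU output of the 300-unit block
    layers <- c(layers, list(
      layer_dense(cfg$head_dims[1L], cfg$head_dims[2L]),
      layer_bn(cfg$head_dims[2L]),
      layer_rrelu(cfg$rrelu_lower, cfg$rrelu_upper),
      layer_dense(cfg$head_dims[2L], cfg$n_classes)))
    structure(list(layers = layers, cfg = cfg,
                   input_shape = c(1L, cfg$n_channels, cfg$window_len),
                   classes = classes, out_act = cfg$out_act,
                   feature_width = feat_width,
                   flatten_index = flatten_index, repr_index = repr_index,
                   history = NULL, best_epoch = NULL),
              class = "emg_net")
  })
}

#' @export
print.emg_net <- function(x, ...) {
  cat(sprintf("%s: input [%s], %d classes (%s head), %s trainable parameters\n",
              x$cfg$variant %||% "emg_net",
              paste(x$input_shape, collapse = " x "), length(x$classes),
              x$out_act, format(count_trainable(x), big.mark = ",")))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs; best epoch %d (val loss %.4f)\n",
                nrow(x$history), x$best_epoch,
                min(x$history$val_loss)))
  }
  invisible(x)
}

#' Dataset-style training schedules for the base networks
#'
#' Nearlab-style: constant learning rate 0.001, 400 epochs, early-stopping
#' patience 100.  Ninapro-style: learning rate decaying from 0.001 to 5e-7,
#' 600 epochs, no early stopping.  Batch size 128 for both.  `epochs` (and
#' any other field) can be overridden for reduced-scale runs.
#'
#' @param style `"nearlab"` or `"ninapro"`.
#' @param ... Overrides passed to [emg_train_config()].
#' @return An [emg_train_config()].
#' @export
cnet_train_config <- function(style = c("nearlab", "ninapro"), ...) {
  style <- match.arg(style)
  base <- if (style == "nearlab") {
    list(epochs = 400L, batch_size = 128L, lr = 0.001, lr_end = NULL,
         val_fraction = 0.2, patience = 100, seed = 1L)
  } else {
    list(epochs = 600L, batch_size = 128L, lr = 0.001, lr_end = 5e-7,
         val_fraction = 0.2, patience = Inf, seed = 1L)
  }
  over <- list(...)
  base[names(over)] <- over
  do.call(emg_train_config, base)
}

# Eval-mode activations of the 300-unit representation layer.
extract_features <- function(net, ws, batch_size = 256L) {
  stopifnot(inherits(net, "emg_net"))
  x <- windows_to_input(ws)
  n <- dim(x)[4L]
  out <- matrix(0, net$cfg$head_dims[1L], n)
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    out[, idx] <- net_logits(net, x[, , , idx, drop = FALSE], mode = "eval",
                             upto = net$repr_index)
  }
  out
}
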