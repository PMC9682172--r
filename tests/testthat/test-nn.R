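test_that("RReLU is identity for non-negatives and mean-slope at evaluation", {
  expect_equal(rrelu(2.5, mode = "eval"), 2.5)
  expect_equal(rrelu(2.5, mode = "train"), 2.5)
  expect_equal(rrelu(-1, mode = "eval"), -(1 / 8 + 1 / 3) / 2)
  expect_error(rrelu(1, lower = 0.5, upper = 0.2), "bounds")
})

test_that("train-mode RReLU slopes are uniform with the evaluation mean", {
  set.seed(123)
  x <- rep(-1, 1e5)
  y <- rrelu(x, mode = "train")
  expect_true(all(y >= -1 / 3 & y <= -1 / 8))
  mc_se <- sd(y) / sqrt(length(y))
  expect_lt(abs(mean(y) - (-(1 / 8 + 1 / 3) / 2)), 3 * mc_se)
})

test_that("architecture shape arithmetic matches the two variants", {
  net1 <- build_cnet(cnet_config("cnet1d", conv_filters = c(8L, 8L, 8L)), seed = 1)
  # 1-d kernels never span channels: row extent stays 10; time 512 -> 8
  expect_equal(net1$feature_width, 8L * 10L * 8L)
  net2 <- build_cnet(cnet_config("cnet2d", conv_filters = c(8L, 8L, 8L)), seed = 1)
  # 'valid' along channels: 10 - 2 - 2 - 2 = 4
  expect_equal(net2$feature_width, 8L * 4L * 8L)
  for (l in net1$layers) {
    if (l$type == "conv") expect_equal(l$kh, 1L)
  }
  # pooling a 64-sample input 3 times by 4 leaves exactly 1; channels = 4 works
  expect_silent(build_cnet(tiny_cnet_cfg(), seed = 1))
  # an over-aggressive pool errors with the shape trace
  bad <- cnet_config("cnet1d", window_len = 32L, pool_size = 4L)
  expect_error(build_cnet(bad, seed = 1), "does not fit")
})

test_that("softmax rows are normalized and a zeroed head is uniform", {
  net <- build_cnet(tiny_cnet_cfg(4L), seed = 2)
  set.seed(9)
  ws <- separable_windows(letters[1:4], 3)
  p <- predict_proba(net, ws)
  expect_equal(unname(rowSums(p)), rep(1, 12), tolerance = 1e-9)
  expect_true(all(p >= 0))
  # zero the output layer: logits all equal -> uniform probabilities
  last <- length(net$layers)
  net$layers[[last]]$W[] <- 0
  net$layers[[last]]$b[] <- 0
  p0 <- predict_proba(net, ws)
  expect_equal(unname(p0), matrix(0.25, 12, 4), tolerance = 1e-12)
  # repeated identical windows give identical rows (eval determinism)
  ws2 <- ws
  ws2$windows[2, , ] <- ws2$windows[1, , ]
  p2 <- predict_proba(net, ws2)
  expect_identical(p2[1, ], p2[2, ])
})

test_that("prediction rejects mismatched input geometry", {
  net <- build_cnet(tiny_cnet_cfg(3L), seed = 1)
  bad <- separable_windows(letters[1:3], 2, channels = 6L)
  expect_error(predict_proba(net, bad), "shape")
})

test_that("training is deterministic, learns separable data, and early-stops", {
  ws <- separable_windows(letters[1:3], 30, seed = 41)
  net <- build_cnet(tiny_cnet_cfg(3L), classes = letters[1:3], seed = 5)
  cfg <- emg_train_config(epochs = 12L, batch_size = 32L, lr = 0.003, seed = 6)
  m1 <- train_model(net, ws, cfg)
  expect_gte(accuracy(ws$labels, predict_label(m1, ws)), 0.95)
  m2 <- train_model(net, ws, cfg)
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$best_epoch, m2$best_epoch)
  # saved weights correspond to the minimum-validation-loss epoch
  expect_equal(m1$best_epoch, which.min(m1$history$val_loss))
  # patience 1 with a destructive learning rate stops before the epoch cap
  diverge <- emg_train_config(epochs = 50L, batch_size = 32L, lr = 50,
                              patience = 1L, seed = 6)
  m3 <- train_model(net, ws, diverge)
  expect_lt(nrow(m3$history), 50L)
})

test_that("training rejects empty or single-class inputs", {
  net <- build_cnet(tiny_cnet_cfg(3L), classes = letters[1:3], seed = 1)
  empty <- emg_windows(array(0, c(0, 4, 64)), character(),
                       window_len = 64L, stride = 16L)
  expect_error(train_model(net, empty), "empty")
  ws1 <- separable_windows("a", 10)
  expect_error(train_model(net, ws1), "single class")
})

test_that("trainable-parameter counts follow the freeze mask", {
  net <- build_cnet(tiny_cnet_cfg(3L), seed = 1)
  frozen <- net
  frozen$layers <- emgtransfer:::walk_layers(frozen$layers,
                                             function(l) { l$trainable <- FALSE; l })
  expect_equal(count_trainable(frozen), 0L)
  # a lone trainable dense 300 -> 50 contributes 15,050 parameters
  one <- frozen
  big <- build_cnet(cnet_config("cnet1d", conv_filters = c(3L, 4L, 4L)), seed = 1)
  i50 <- big$flatten_index + 5L
  expect_equal(length(big$layers[[i50]]$W) + length(big$layers[[i50]]$b), 15050L)
})

test_that("freezing a layer leaves its weights bit-identical across training", {
  ws <- separable_windows(letters[1:3], 20, seed = 51)
  net <- build_cnet(tiny_cnet_cfg(3L), classes = letters[1:3], seed = 7)
  net$layers[[1L]]$trainable <- FALSE
  net$layers[[2L]]$trainable <- FALSE  # its batch norm too
  before_W <- net$layers[[1L]]$W
  trained <- train_model(net, ws, emg_train_config(epochs = 4L, batch_size = 32L,
                                                   lr = 0.01, seed = 8))
  expect_identical(trained$layers[[1L]]$W, before_W)
  expect_false(identical(trained$layers[[6L]]$W, net$layers[[6L]]$W))
})

test_that("evaluation-mode inference is a pure function of weights and input", {
  net <- build_cnet(tiny_cnet_cfg(3L), seed = 3)
  ws <- separable_windows(letters[1:3], 2, seed = 9)
  p1 <- predict_proba(net, ws)
  set.seed(999)  # global RNG state must not matter
  p2 <- predict_proba(net, ws)
  expect_identical(p1, p2)
})
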