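test_that("the zero-shot rule composes the two argmaxes and ignores the rest", {
  tx <- emg_taxonomy()
  p <- setNames(rep(0, 8), tx$basic_classes)
  p["pronation"] <- 0.40; p["supination"] <- 0.05
  p["grip"] <- 0.30; p["pinch"] <- 0.10; p["lateral_pinch"] <- 0.02
  expect_identical(syn0_predict(p, tx), "pronation+grip")
  # uniform vector: tie-break to the lowest index of each set
  u <- setNames(rep(1 / 8, 8), tx$basic_classes)
  expect_identical(syn0_predict(u, tx), "pronation+pinch")
  # mass on a class that is neither rotation nor function is ignored
  q <- setNames(rep(0.01, 8), tx$basic_classes)
  q["basic_6"] <- 0.9
  q["supination"] <- 0.02; q["lateral_pinch"] <- 0.03
  expect_identical(syn0_predict(q, tx), "supination+lateral_pinch")
  expect_error(syn0_predict(c(0.5, 0.5), tx), "basic class")
})

test_that("every activation vector maps into the 6 combined classes", {
  tx <- emg_taxonomy()
  set.seed(17)
  preds <- replicate(500, syn0_predict(runif(8), tx))
  expect_true(all(preds %in% tx$combined_classes))
  expect_setequal(unique(preds), tx$combined_classes)  # all 6 reachable
})

test_that("zero-shot evaluation scores overall, rotation and function parts", {
  tx <- emg_taxonomy()
  net <- build_cnet(tiny_cnet_cfg(8L), classes = tx$basic_classes, seed = 1)
  # force constant logits favoring pronation & grip
  last <- length(net$layers)
  net$layers[[last]]$W[] <- 0
  net$layers[[last]]$b <- c(5, 0, 0, 0, 4, 0, 0, 0)  # pronation, grip high
  ws <- separable_windows(rep("x", 6), 2)
  ws$labels <- rep("pronation+grip", 12)
  r <- syn0_evaluate(net, ws, tx)
  expect_equal(c(r$overall, r$rotation, r$fun), c(1, 1, 1))
  # rotation right, function wrong -> overall 0, rotation 1, function 0
  ws$labels <- rep("pronation+pinch", 12)
  r2 <- syn0_evaluate(net, ws, tx)
  expect_equal(c(r2$overall, r2$rotation, r2$fun), c(0, 1, 0))
  ws$labels <- rep("grip", 12)
  expect_error(syn0_evaluate(net, ws, tx), "combined")
})

test_that("a sigmoid-head variant trains and feeds the zero-shot rule", {
  tx <- emg_taxonomy()
  cfg <- cnet_config("cnet1d", n_channels = 4L, window_len = 64L,
                     n_classes = 8L, conv_filters = c(3L, 4L, 4L),
                     pool_size = 4L, out_act = "sigmoid")
  net <- build_cnet(cfg, classes = tx$basic_classes, seed = 71)
  ws <- separable_windows(tx$basic_classes, 6, seed = 72)
  ws$labels <- rep(tx$basic_classes, each = 6)
  net <- train_model(net, ws, emg_train_config(epochs = 5L, batch_size = 24L,
                                               lr = 0.003, seed = 73))
  p <- predict_proba(net, ws)
  expect_true(all(p > 0 & p < 1))     # per-unit sigmoid activations
  expect_false(isTRUE(all.equal(unname(rowSums(p)), rep(1, nrow(p)))))
  cws <- separable_windows(tx$combined_classes[1], 3, seed = 74)
  cws$labels <- rep(tx$combined_classes[1], 3)
  r <- syn0_evaluate(net, cws, tx)
  expect_true(all(r$predictions %in% tx$combined_classes))
})

test_that("the Siamese head has 301 parameters, is symmetric, and bounded", {
  net <- build_cnet(tiny_cnet_cfg(8L), classes = emg_taxonomy()$basic_classes,
                    seed = 2)
  sia <- build_siamese(net, seed = 3)
  expect_equal(count_trainable(sia), 301L)
  ws <- separable_windows(letters[1:2], 2)
  s_ab <- siamese_score(sia, subset_ws(ws, 1:2), subset_ws(ws, 3:4))
  s_ba <- siamese_score(sia, subset_ws(ws, 3:4), subset_ws(ws, 1:2))
  expect_equal(s_ab, s_ba)  # |a - b| symmetry
  expect_true(all(s_ab > 0 & s_ab < 1))
  # identical inputs: zero distance vector -> sigmoid(bias)
  s_aa <- siamese_score(sia, subset_ws(ws, 1L), subset_ws(ws, 1L))
  expect_equal(s_aa, 1 / (1 + exp(-sia$b)), tolerance = 1e-12)
})

test_that("pair generation honors counts, mixes, and the 0 = same convention", {
  tx <- emg_taxonomy()
  ws <- separable_windows(tx$basic_classes, 6, channels = 4L, seed = 21)
  ws$labels <- rep(tx$basic_classes, each = 6)  # taxonomy labels
  spec <- pair_spec(positive_fraction = 0.5)
  pairs <- generate_pairs(ws, 1000L, spec, seed = 1)
  expect_equal(sum(pairs$same == 0L), 500L)  # exact allocation
  expect_true(all(ws$labels[pairs$i[pairs$same == 0L]] ==
                  ws$labels[pairs$j[pairs$same == 0L]]))
  expect_true(all(ws$labels[pairs$i[pairs$same == 1L]] !=
                  ws$labels[pairs$j[pairs$same == 1L]]))
  # all-function negatives
  ff <- generate_pairs(ws, 400L,
                       pair_spec(negative_mix = c(function_function = 1,
                                                  rotation_rotation = 0,
                                                  other = 0)), seed = 2)
  neg <- ff[ff$same == 1L, ]
  expect_true(all(ws$labels[neg$i] %in% tx$functions))
  expect_true(all(ws$labels[neg$j] %in% tx$functions))
  # category histogram within 3-sigma multinomial bounds
  mix <- c(function_function = 0.4, rotation_rotation = 0.4, other = 0.2)
  big <- generate_pairs(ws, 20000L, pair_spec(negative_mix = mix), seed = 3)
  counts <- table(big$kind[big$same == 1L])
  n_neg <- sum(big$same == 1L)
  for (k in names(mix)) {
    expect_lt(abs(counts[[k]] - n_neg * mix[[k]]),
              3 * sqrt(n_neg * mix[[k]] * (1 - mix[[k]])))
  }
  # reproducibility of the stream
  expect_identical(generate_pairs(ws, 100L, spec, seed = 9),
                   generate_pairs(ws, 100L, spec, seed = 9))
  tiny <- subset_ws(ws, c(1L, 7L))  # a class with a single window
  expect_error(generate_pairs(tiny, 10L, spec, seed = 1), "fewer than 2")
})

test_that("Siamese training touches only the 301 head parameters", {
  tx <- emg_taxonomy()
  ws <- separable_windows(tx$basic_classes, 8, seed = 23)
  ws$labels <- rep(tx$basic_classes, each = 8)
  net <- build_cnet(tiny_cnet_cfg(8L), classes = tx$basic_classes, seed = 4)
  sia <- build_siamese(net, seed = 5)
  branch_snapshot <- emgtransfer:::snapshot_params(sia$base$layers)
  spec <- pair_spec(epochs = 25L)
  tr <- train_siamese(sia, ws, n_pairs = 600L, spec, seed = 6)
  expect_identical(emgtransfer:::snapshot_params(tr$base$layers), branch_snapshot)
  expect_false(identical(tr$w, sia$w))
  # determinism
  tr2 <- train_siamese(sia, ws, n_pairs = 600L, spec, seed = 6)
  expect_identical(tr$w, tr2$w)
  expect_identical(tr$b, tr2$b)
  # learned similarity: same-class pairs score below different-class pairs
  pr <- generate_pairs(ws, 400L, spec, seed = 7)
  sc <- siamese_score(tr, subset_ws(ws, pr$i), subset_ws(ws, pr$j))
  expect_lt(mean(sc[pr$same == 0L]), mean(sc[pr$same == 1L]))
})

test_that("few-shot classification aggregates query scores with tie-breaks", {
  tx <- emg_taxonomy()
  cfg8 <- cnet_config("cnet1d", n_channels = 8L, window_len = 64L,
                      n_classes = 8L, conv_filters = c(3L, 4L, 4L),
                      pool_size = 4L)
  net <- build_cnet(cfg8, classes = tx$basic_classes, seed = 8)
  bws <- separable_windows(tx$basic_classes, 8, channels = 8L, seed = 26)
  bws$labels <- rep(tx$basic_classes, each = 8)
  net <- train_model(net, bws, emg_train_config(epochs = 6L, batch_size = 32L,
                                                lr = 0.003, seed = 18))
  sia <- build_siamese(net, seed = 9)
  cws <- separable_windows(tx$combined_classes, 7, channels = 8L, seed = 25)
  cws$labels <- rep(tx$combined_classes, each = 7)
  bank <- query_bank(cws, q = 5L, taxonomy = tx)
  expect_error(query_bank(subset_ws(cws, 1:3), q = 5L, taxonomy = tx), "need")
  # untrained head with w = 0 scores everything 0.5: full tie -> lowest index
  sia0 <- sia; sia0$w[] <- 0; sia0$b <- 0
  pred0 <- sia5_classify(sia0, bank, subset_ws(cws, 1:3), "mean_score")
  expect_true(all(pred0 == tx$combined_classes[1L]))
  predv <- sia5_classify(sia0, bank, subset_ws(cws, 1:3), "majority_vote")
  expect_true(all(predv == tx$combined_classes[1L]))
  # head trained on source-domain (basic-class) pairs classifies separable
  # combined movements above chance from 5 queries per class
  tr <- train_siamese(sia, bws, n_pairs = 600L, pair_spec(epochs = 25L), seed = 10)
  test_idx <- which(!seq_len(42L) %in% unlist(lapply(0:5, function(k) 7L * k + 1:5)))
  pred <- sia5_classify(tr, bank, subset_ws(cws, test_idx), "mean_score")
  expect_gt(accuracy(cws$labels[test_idx], pred), 2 / 6)
})

test_that("FTnet staging exposes 306 then 15,456 parameters and freezes the rest", {
  tx <- emg_taxonomy()
  base <- build_cnet(cnet_config("cnet1d", n_channels = 4L, window_len = 64L,
                                 n_classes = 8L, conv_filters = c(3L, 4L, 4L),
                                 pool_size = 4L),
                     classes = tx$basic_classes, seed = 11)
  ft <- build_ftnet(base, tx, seed = 12)
  expect_equal(count_trainable(ft), 306L)
  expect_identical(ft$out_act, "sigmoid")
  ft2 <- ftnet_unlock_stage2(ft)
  expect_equal(count_trainable(ft2), 15456L)

  cws <- separable_windows(tx$combined_classes, 6, seed = 27)
  cws$labels <- rep(tx$combined_classes, each = 6)
  conv_before <- ft$layers[[1L]]$W
  dense300_before <- ft$layers[[ft$flatten_index + 1L]]$W
  tr <- train_ftnet(ft, cws,
                    ftnet_train_config(1L, epochs = 40L),
                    ftnet_train_config(2L, epochs = 30L))
  expect_identical(tr$layers[[1L]]$W, conv_before)
  expect_identical(tr$layers[[tr$flatten_index + 1L]]$W, dense300_before)
  expect_equal(tr$stage, 2L)
  # the stage-2 set did move
  expect_false(identical(tr$layers[[tr$flatten_index + 5L]]$W,
                         ft$layers[[ft$flatten_index + 5L]]$W))
  # errors: missing classes / empty input
  expect_error(train_ftnet(ft, subset_ws(cws, 1:6)), "missing combined class")
  empty <- emg_windows(array(0, c(0, 4, 64)), character(),
                       window_len = 64L, stride = 16L)
  expect_error(train_ftnet(ft, empty), "no combined-movement")
})
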