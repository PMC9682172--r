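# Brute-force O(n^2) sample-entropy oracle: explicit template counting with
# Chebyshev distance, self-matches excluded, common n-m template count.
sampen_oracle <- function(x, m, r_abs) {
  n <- length(x)
  count <- function(mm) {
    nt <- n - m
    tot <- 0L
    for (i in seq_len(nt - 1L)) {
      for (j in (i + 1L):nt) {
        if (max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)])) <= r_abs) {
          tot <- tot + 1L
        }
      }
    }
    tot
  }
  B <- count(m); A <- count(m + 1L)
  if (A == 0L || B == 0L) return(0)
  -log(A / B)
}

test_that("closed forms hold on constant and sinusoidal windows", {
  cfg <- emg_feature_config(zc_ssc_eps = 0)
  x <- rep(2.5, 32)
  expect_equal(compute_feature(x, "MAV", cfg), 2.5)
  expect_equal(compute_feature(x, "IEMG", cfg), 80)
  expect_equal(compute_feature(x, "WL", cfg), 0)
  expect_equal(compute_feature(x, "ZC", cfg), 0)
  expect_equal(compute_feature(x, "SSC", cfg), 0)
  expect_equal(compute_feature(x, "HP_A", cfg), 0)
  # unit sine with exactly 8 periods in 512 samples: 2 crossings per period
  # (a phase offset keeps all 16 crossings strictly inside the sampled span)
  s <- sin(2 * pi * 8 * (0:511) / 512 + 0.9)
  expect_equal(compute_feature(s, "ZC", cfg), 16)
  expect_equal(compute_feature(s, "RMS", cfg), sqrt(mean(s^2)))
})

test_that("sample entropy matches the brute-force oracle", {
  cfg <- emg_feature_config(sampen_m = 2L, sampen_r = 0.2)
  x16 <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3, 1)
  r_abs <- 0.2 * sd(x16)
  expect_equal(compute_feature(x16, "SampEn", cfg),
               sampen_oracle(x16, 2L, r_abs))
  set.seed(99)
  for (i in 1:20) {
    n <- sample(10:64, 1)
    x <- rnorm(n)
    expect_equal(compute_feature(x, "SampEn", cfg),
                 sampen_oracle(x, 2L, 0.2 * sd(x)),
                 info = sprintf("series %d (n=%d)", i, n))
  }
})

test_that("ZC and SSC with eps = 0 equal direct sign-pattern counts", {
  cfg <- emg_feature_config(zc_ssc_eps = 0)
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(10:100, 1))
    zc_direct <- sum(sign(x[-length(x)]) * sign(x[-1]) < 0)
    d <- diff(x)
    ssc_direct <- sum(sign(d[-length(d)]) * sign(d[-1]) < 0)
    expect_equal(compute_feature(x, "ZC", cfg), zc_direct)
    expect_equal(compute_feature(x, "SSC", cfg), ssc_direct)
  }
})

test_that("cepstral coefficients follow the AR recursion", {
  # independent oracle: Yule-Walker AR fit (stats::ar) + direct recursion
  set.seed(8)
  x <- as.numeric(arima.sim(list(ar = 0.7), 512))
  fit <- stats::ar(x, aic = FALSE, order.max = 4, method = "yule-walker",
                   demean = TRUE)
  a <- -fit$ar  # prediction-polynomial sign convention
  cc_oracle <- numeric(4)
  cc_oracle[1] <- -a[1]
  for (nn in 2:4) {
    k <- seq_len(nn - 1)
    cc_oracle[nn] <- -a[nn] - sum((1 - k / nn) * a[k] * cc_oracle[nn - k])
  }
  cfg <- emg_feature_config()
  got <- vapply(paste0("CC", 1:4), function(f) compute_feature(x, f, cfg), 0)
  expect_equal(unname(got), cc_oracle, tolerance = 0.02)
  expect_equal(compute_feature(x, "CC1", cfg), -a[1], tolerance = 0.02)
})

test_that("Hjorth complexity separates white noise from a pure sine", {
  set.seed(21)
  s <- sin(2 * pi * 5 * (0:511) / 512)
  noise_c <- replicate(10, compute_feature(rnorm(512), "HP_C"))
  expect_gt(min(noise_c), compute_feature(s, "HP_C"))
})

test_that("degenerate windows yield sentinel values with warnings", {
  x <- rep(1, 16)
  expect_warning(v <- compute_feature(x, "SampEn"), "undefined")
  expect_equal(v, 0)
  expect_warning(compute_feature(x, "HP_M"), "undefined")
  expect_error(compute_feature(rnorm(16), "NOPE"), "unknown feature")
})

test_that("feature sets have the documented sizes and channel-major layout", {
  expect_length(feature_set("TD"), 4L)
  expect_length(feature_set("ITD"), 9L)
  expect_length(feature_set("CB"), 7L)
  expect_length(feature_set("Full"), 15L)
  expect_error(feature_set("XXL"))

  set.seed(4)
  ws <- separable_windows(c("a", "b"), 3, channels = 10L, len = 64L)
  for (s in c("TD", "ITD", "CB", "Full")) {
    ft <- compute_feature_table(ws, s)
    expect_equal(ncol(ft$x), length(feature_set(s)) * 10L)
    expect_false(any(!is.finite(ft$x)))
  }
  td <- compute_feature_table(ws, "TD")
  expect_identical(colnames(td$x)[1:4], paste0(c("MAV", "ZC", "SSC", "WL"), "_ch1"))
})

test_that("channel permutation permutes feature columns accordingly", {
  set.seed(14)
  arr <- array(rnorm(4 * 3 * 64), c(4, 3, 64))
  ws <- emg_windows(arr, rep("grip", 4), window_len = 64L, stride = 16L)
  perm <- c(2L, 3L, 1L)
  wsp <- emg_windows(arr[, perm, , drop = FALSE], rep("grip", 4),
                     window_len = 64L, stride = 16L)
  ft <- compute_feature_table(ws, "TD", emg_feature_config(zc_ssc_eps = 0))
  ftp <- compute_feature_table(wsp, "TD", emg_feature_config(zc_ssc_eps = 0))
  for (ch in 1:3) {
    cols_new <- (ch - 1L) * 4L + 1:4
    cols_old <- (perm[ch] - 1L) * 4L + 1:4
    expect_equal(unname(ftp$x[, cols_new]), unname(ft$x[, cols_old]))
  }
})

test_that("scaling z-scores with train statistics and winsorizes outliers", {
  set.seed(6)
  ws <- separable_windows(c("a", "b"), 20, channels = 2L)
  ft <- compute_feature_table(ws, "TD")
  sc <- scale_features(ft, ft)
  expect_lt(max(abs(colMeans(sc$train$x))), 1e-9)
  expect_equal(unname(apply(sc$train$x, 2, sd)), rep(1, ncol(sc$train$x)),
               tolerance = 1e-9)
  expect_identical(sc$train$x, sc$apply_to$x)  # same table, train stats

  # a 10-SD outlier is clamped before statistics are computed
  x <- matrix(rnorm(200), 100, 2)
  x[1, 1] <- mean(x[-1, 1]) + 10 * sd(x[-1, 1])
  tb <- structure(list(x = x, labels = rep("a", 100), features = c("f1", "f2"),
                       set_name = "TD", center = NULL, scale = NULL),
                  class = "emg_feature_table")
  sc2 <- suppressMessages(scale_features(tb))
  # unwinsorized, the outlier would sit ~9 scaled SDs out; clamped at the
  # 3-SD bound of the raw column it stays close to the rest of the data
  expect_lt(max(sc2$train$x[, 1]), 4.5)
})

test_that("all four classical baselines separate well-separated clouds", {
  set.seed(31)
  ws_train <- separable_windows(c("a", "b", "c"), 30, seed = 31)
  ws_test <- separable_windows(c("a", "b", "c"), 10, seed = 32)
  ft_train <- compute_feature_table(ws_train, "TD")
  ft_test <- compute_feature_table(ws_test, "TD")
  sc <- scale_features(ft_train, ft_test)
  for (m in c("knn", "svm", "mlp", "lda")) {
    fit <- train_classical(m, sc$train,
                           classical_config(knn_k = 5L, mlp_epochs = 250L))
    expect_equal(accuracy(ws_test$labels, predict_classical(fit, sc$apply_to)),
                 1.0, info = m)
  }
})

test_that("classical training rejects degenerate inputs", {
  ws <- separable_windows("a", 30)
  ft <- compute_feature_table(ws, "TD")
  sc <- scale_features(ft)
  expect_error(train_classical("lda", sc$train), "single class")
  ws2 <- separable_windows(c("a", "b"), 5)
  sc2 <- scale_features(compute_feature_table(ws2, "TD"))
  expect_error(train_classical("knn", sc2$train, classical_config(knn_k = 40L)),
               "reduce knn_k")
  expect_error(train_classical("svm", ft), "scaled")
})

test_that("label-permuted balanced problems classify at chance", {
  set.seed(77)
  n_per <- 25L
  classes <- paste0("k", 1:8)
  ws <- separable_windows(classes, n_per, channels = 10L, boost = 0)  # no signal
  ws$labels <- sample(ws$labels)
  ws_test <- separable_windows(classes, n_per, channels = 10L, boost = 0,
                               seed = 78)
  ws_test$labels <- sample(ws_test$labels)
  ft <- compute_feature_table(ws, "TD")
  ft_test <- compute_feature_table(ws_test, "TD")
  sc <- scale_features(ft, ft_test)
  fit <- train_classical("lda", sc$train, classical_config())
  acc <- accuracy(ws_test$labels, predict_classical(fit, sc$apply_to))
  # held-out accuracy of a labelless problem: 1/8 within ~4 binomial SDs
  expect_lt(acc, 0.125 + 4 * sqrt(0.125 * 0.875 / 200))
  expect_gt(acc, 0.125 - 4 * sqrt(0.125 * 0.875 / 200))
})
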