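#' Feature-extraction configuration
#'
#' @param zc_ssc_eps Amplitude threshold for zero-crossing and slope-sign
#'   counting.  The default `NULL` uses `0.01 * sd(window)` per window;
#'   pass a number (microvolts) for a fixed threshold, or 0 for none.
#' @param sampen_m Sample-entropy embedding dimension.
#' @param sampen_r Sample-entropy tolerance as a fraction of the window SD.
#' @param ar_order Autoregressive order for the cepstral coefficients.
#' @return A list of class `"emg_feature_config"`.
#' @export
emg_feature_config <- function(zc_ssc_eps = NULL, sampen_m = 2L,
                               sampen_r = 0.2, ar_order = 4L) {
  stopifnot(sampen_m >= 1L, sampen_r > 0, sampen_r < 1, ar_order == 4L)
  structure(list(zc_ssc_eps = zc_ssc_eps, sampen_m = as.integer(sampen_m),
                 sampen_r = sampen_r, ar_order = as.integer(ar_order)),
            class = "emg_feature_config")
}

#' @rdname compute_feature
#' @export
feature_names <- function() {
  c("MAV", "IEMG", "RMS", "WL", "ZC", "SSC", "HP_A", "HP_M", "HP_C",
    "SKEW", "SampEn", "CC1", "CC2", "CC3", "CC4")
}

#' The four feature sets
#'
#' `TD` (time domain, 4 features), `ITD` (improved time domain, 9),
#' `CB` (correlation based, 7) and `Full` (all 15).
#'
#' @param set_name One of `"TD"`, `"ITD"`, `"CB"`, `"Full"`.
#' @return Character vector of feature tokens.
#' @export
feature_set <- function(set_name = c("TD", "ITD", "CB", "Full")) {
  set_name <- match.arg(set_name)
  switch(set_name,
    TD = c("MAV", "ZC", "SSC", "WL"),
    ITD = c("MAV", "ZC", "SSC", "WL", "RMS", "IEMG", "HP_A", "HP_M", "HP_C"),
    CB = c("CC1", "ZC", "SSC", "WL", "HP_M", "HP_C", "SampEn"),
    Full = feature_names())
}

# Levinson-Durbin AR fit on the biased autocorrelation; returns a_1..a_p for
# the model x[t] = -sum(a_k x[t-k]) + e[t] (prediction-polynomial convention).
ar_levinson <- function(x, p) {
  n <- length(x)
  x <- x - mean(x)
  r <- vapply(0:p, function(k) sum(x[1:(n - k)] * x[(1 + k):n]) / n, 0)
  if (r[1L] <= 0) return(rep(0, p))
  a <- numeric(0)
  err <- r[1L]
  for (k in 1:p) {
    acc <- r[k + 1L]
    if (k > 1L) acc <- acc + sum(a * r[k:2L])
    refl <- -acc / err
    a_new <- c(a + refl * rev(a), refl)
    a <- a_new
    err <- err * (1 - refl^2)
    if (err <= 0) break
  }
  length(a) <- p
  a[is.na(a)] <- 0
  a
}

# Cepstral coefficients from AR coefficients via the standard recursion.
cc_from_ar <- function(a) {
  p <- length(a)
  cc <- numeric(p)
  cc[1L] <- -a[1L]
  if (p > 1L) {
    for (nn in 2:p) {
      k <- seq_len(nn - 1L)
      cc[nn] <- -a[nn] - sum((1 - k / nn) * a[k] * cc[nn - k])
    }
  }
  cc
}

# Sample entropy -ln(A/B): B = m-length template matches, A = (m+1)-length,
# Chebyshev distance, tolerance r_abs, self-matches excluded.
sampen <- function(x, m, r_abs) {
  n <- length(x)
  if (n <= m + 1L) return(0)
  # unordered template pairs within tolerance, Chebyshev distance,
  # self-matches excluded; both lengths use the common n-m template count
  count_pairs <- function(mm) {
    nt <- n - m
    d <- matrix(0, nt, nt)
    for (j in seq_len(mm)) {
      v <- x[j:(j + nt - 1L)]
      d <- pmax(d, abs(outer(v, v, "-")))
    }
    (sum(d <= r_abs) - nt) / 2
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1L)
  if (A == 0 || B == 0) return(0)
  -log(A / B)
}

#' Compute one handcrafted feature of a single-channel window
#'
#' Implements the 15 window features used by the classical baselines:
#' amplitude summaries (MAV, IEMG, RMS, WL), threshold-gated zero crossings
#' (ZC) and slope-sign changes (SSC), the three Hjorth parameters (activity =
#' variance, mobility, complexity, with derivatives taken as first
#' differences), bias-adjusted sample skewness (SKEW), sample entropy
#' (SampEn, template length `m`, tolerance `r * sd(x)`, self-matches
#' excluded), and cepstral coefficients CC1-CC4 derived recursively from an
#' AR(4) fit (Levinson-Durbin on the biased autocorrelation).
#'
#' @param x Numeric vector: one channel of one window.
#' @param name Feature token, one of `feature_names()`.
#' @param cfg An [emg_feature_config()].
#' @return A scalar.  Degenerate inputs (zero variance) yield 0 with a
#'   warning for SampEn and the Hjorth mobility/complexity.
#' @export
compute_feature <- function(x, name, cfg = emg_feature_config()) {
  stopifnot(is.numeric(x), length(x) >= 3L)
  if (any(!is.finite(x))) stopf("window contains non-finite values")
  eps <- cfg$zc_ssc_eps %||% (0.01 * stats::sd(x))
  switch(name,
    MAV = mean(abs(x)),
    IEMG = sum(abs(x)),
    RMS = sqrt(mean(x^2)),
    WL = sum(abs(diff(x))),
    ZC = {
      x1 <- x[-length(x)]; x2 <- x[-1L]
      sum(x1 * x2 < 0 & abs(x1 - x2) >= eps)
    },
    SSC = {
      d1 <- x[2:(length(x) - 1L)] - x[1:(length(x) - 2L)]
      d2 <- x[2:(length(x) - 1L)] - x[3:length(x)]
      sum(d1 * d2 > 0 & abs(d1) >= eps & abs(d2) >= eps)
    },
    HP_A = stats::var(x),
    HP_M = {
      v <- stats::var(x)
      if (v == 0) { warnf("zero-variance window: mobility undefined"); 0 }
      else sqrt(stats::var(diff(x)) / v)
    },
    HP_C = {
      v <- stats::var(x); vd <- stats::var(diff(x))
      if (v == 0 || vd == 0) { warnf("degenerate window: complexity undefined"); 0 }
      else {
        m1 <- sqrt(vd / v)
        m2 <- sqrt(stats::var(diff(diff(x))) / vd)
        m2 / m1
      }
    },
    SKEW = {
      n <- length(x)
      s <- stats::sd(x)
      if (s == 0) { warnf("zero-variance window: skewness undefined"); 0 }
      else (n / ((n - 1) * (n - 2))) * sum(((x - mean(x)) / s)^3)
    },
    SampEn = {
      s <- stats::sd(x)
      if (s == 0) { warnf("zero-variance window: SampEn undefined"); 0 }
      else sampen(x, cfg$sampen_m, cfg$sampen_r * s)
    },
    CC1 = cc_from_ar(ar_levinson(x, cfg$ar_order))[1L],
    CC2 = cc_from_ar(ar_levinson(x, cfg$ar_order))[2L],
    CC3 = cc_from_ar(ar_levinson(x, cfg$ar_order))[3L],
    CC4 = cc_from_ar(ar_levinson(x, cfg$ar_order))[4L],
    stopf("unknown feature '%s'", name)
  )
}

#' Compute a feature table for a window set
#'
#' One row per window; columns are `<feature>_<channel>` in channel-major
#' order (all features of channel 1, then channel 2, ...).
#'
#' @param ws An [emg_windows()] set.
#' @param set_name Feature set name, see [feature_set()].
#' @param cfg An [emg_feature_config()].
#' @return A list of class `"emg_feature_table"` with `x` (numeric matrix),
#'   `labels`, `features`, `set_name`, and (after [scale_features()]) the
#'   training `center`/`scale` vectors.
#' @export
compute_feature_table <- function(ws, set_name = "Full",
                                  cfg = emg_feature_config()) {
  feats <- feature_set(set_name)
  n <- n_windows(ws)
  nch <- dim(ws$windows)[2L]
  cols <- as.vector(outer(feats, seq_len(nch), function(f, c) paste0(f, "_ch", c)))
  x <- matrix(NA_real_, n, length(feats) * nch,
              dimnames = list(NULL, cols))
  need_cc <- any(grepl("^CC", feats))
  for (i in seq_len(n)) {
    for (ch in seq_len(nch)) {
      w <- ws$windows[i, ch, ]
      cc <- if (need_cc) cc_from_ar(ar_levinson(w, cfg$ar_order)) else NULL
      for (j in seq_along(feats)) {
        f <- feats[j]
        v <- if (grepl("^CC", f)) cc[as.integer(sub("CC", "", f))]
             else compute_feature(w, f, cfg)
        x[i, (ch - 1L) * length(feats) + j] <- v
      }
    }
  }
  structure(list(x = x, labels = ws$labels, features = feats,
                 set_name = set_name, center = NULL, scale = NULL),
            class = "emg_feature_table")
}

#' @export
print.emg_feature_table <- function(x, ...) {
  cat(sprintf("sEMG feature table (%s): %d windows x %d columns%s\n",
              x$set_name, nrow(x$x), ncol(x$x),
              if (is.null(x$center)) "" else ", scaled"))
  invisible(x)
}

#' Scale feature tables with train-set statistics
#'
#' Winsorizes training values beyond 3 SD of their column (outlier handling
#' that keeps rows aligned with labels), then z-scores every column with the
#' winsorized training mean and SD.  Any further tables are scaled with the
#' training statistics only.
#'
#' @param train Training [compute_feature_table()] output.
#' @param apply_to Optional second table (e.g. the test set) to scale with
#'   the training statistics.
#' @return A list with scaled `train` and (if given) `apply_to` tables.
#' @export
scale_features <- function(train, apply_to = NULL) {
  stopifnot(inherits(train, "emg_feature_table"), nrow(train$x) > 0L)
  x <- train$x
  mu0 <- colMeans(x)
  sd0 <- apply(x, 2L, stats::sd)
  n_wins <- 0L
  for (j in seq_len(ncol(x))) {
    if (sd0[j] == 0) next
    lo <- mu0[j] - 3 * sd0[j]; hi <- mu0[j] + 3 * sd0[j]
    out <- x[, j] < lo | x[, j] > hi
    n_wins <- n_wins + sum(out)
    x[out & x[, j] < lo, j] <- lo
    x[out & x[, j] > hi, j] <- hi
  }
  if (n_wins > 0L) message(sprintf("winsorized %d outlying feature values", n_wins))
  center <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  zero <- scl == 0
  if (any(zero)) {
    warnf("%d zero-SD feature column(s); scaling by 1", sum(zero))
    scl[zero] <- 1
  }
  train$x <- sweep(sweep(x, 2L, center), 2L, scl, "/")
  train$center <- center
  train$scale <- scl
  out <- list(train = train)
  if (!is.null(apply_to)) {
    apply_to$x <- sweep(sweep(apply_to$x, 2L, center), 2L, scl, "/")
    apply_to$center <- center
    apply_to$scale <- scl
    out$apply_to <- apply_to
  }
  out
}
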