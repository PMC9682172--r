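#' Classification accuracy and confusion matrix
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @return `accuracy()`: the fraction of correct classifications.
#'   `confusion()`: a contingency matrix with true classes as rows.
#' @export
accuracy <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stopf("label vectors differ in length (%d vs %d)",
          length(true_labels), length(predicted_labels))
  }
  if (length(true_labels) == 0L) stopf("empty label vectors")
  mean(as.character(true_labels) == as.character(predicted_labels))
}

#' @rdname accuracy
#' @export
confusion <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stopf("label vectors differ in length")
  }
  lv <- sort(unique(c(true_labels, predicted_labels)))
  table(true = factor(true_labels, lv), predicted = factor(predicted_labels, lv))
}

#' Compare methods across subjects: Friedman, pairwise Wilcoxon, Holm
#'
#' Runs a Friedman rank test across all methods (subjects as blocks), then
#' pairwise Wilcoxon signed-rank tests of the reference method against every
#' other method, and applies Holm's step-down correction as adjusted
#' significance thresholds: with the m p-values sorted ascending, the i-th
#' is tested against `alpha / (m - i + 1)`.  Wilcoxon uses the exact
#' distribution for n <= 25 subjects (when free of ties and zeros) and the
#' normal approximation with continuity correction otherwise; zero
#' differences are dropped.  A comparison with no nonzero differences
#' degenerates to p = 1 with a warning.
#'
#' @param acc Accuracy matrix: rows = subjects, columns = methods (named).
#' @param reference Column name of the reference method.
#' @param alpha Family-wise significance level.
#' @return A list of class `"emg_comparison"`: `friedman_p` and a `pairwise`
#'   data frame with `method`, `p`, `holm_alpha`, `p_holm`, `significant`.
#' @export
compare_methods <- function(acc, reference, alpha = 0.05) {
  acc <- as.matrix(acc)
  if (is.null(colnames(acc))) stopf("accuracy matrix needs method column names")
  if (!reference %in% colnames(acc)) stopf("unknown reference method '%s'", reference)
  if (ncol(acc) < 2L) stopf("need at least 2 methods to compare")
  if (anyNA(acc)) stopf("accuracy matrix has missing entries")
  if (nrow(acc) < 5L) warnf("fewer than 5 subjects; rank tests have little power")
  friedman_p <- stats::friedman.test(acc)$p.value
  others <- setdiff(colnames(acc), reference)
  p <- vapply(others, function(m) {
    d <- acc[, reference] - acc[, m]
    d <- d[d != 0]
    if (length(d) == 0L) {
      warnf("'%s' vs '%s': all differences zero; p = 1", reference, m)
      return(1)
    }
    exact <- length(d) <= 25L && !any(duplicated(abs(d)))
    suppressWarnings(stats::wilcox.test(acc[, reference], acc[, m],
                                        paired = TRUE, exact = exact,
                                        correct = TRUE)$p.value)
  }, 0)
  m <- length(p)
  ord <- order(p)
  holm_alpha <- numeric(m)
  holm_alpha[ord] <- alpha / (m - seq_len(m) + 1L)
  # step-down: once a sorted p exceeds its threshold, later ones cannot be
  # significant
  sig <- logical(m)
  running <- TRUE
  for (i in seq_len(m)) {
    k <- ord[i]
    running <- running && p[k] <= holm_alpha[k]
    sig[k] <- running
  }
  structure(list(
    friedman_p = friedman_p,
    reference = reference,
    alpha = alpha,
    pairwise = data.frame(method = others, p = unname(p),
                          holm_alpha = holm_alpha,
                          p_holm = stats::p.adjust(p, "holm"),
                          significant = sig, row.names = NULL)),
    class = "emg_comparison")
}

#' @export
print.emg_comparison <- function(x, ...) {
  cat(sprintf("Friedman test across methods: p = %.4g\n", x$friedman_p))
  cat(sprintf("Pairwise Wilcoxon signed-rank vs '%s' (Holm-adjusted thresholds, alpha = %g):\n",
              x$reference, x$alpha))
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' Holm-adjusted significance thresholds
#'
#' For m comparisons at family level `alpha`, the sorted p-values are tested
#' against `alpha / m, alpha / (m-1), ..., alpha`.
#'
#' @param m Number of comparisons.
#' @param alpha Family-wise level.
#' @return Numeric vector of thresholds, smallest first.
#' @export
holm_thresholds <- function(m, alpha = 0.05) {
  alpha / (m - seq_len(m) + 1L)
}

#' Chance accuracy of a uniform K-class guesser
#'
#' @param n_classes Number of classes.
#' @return Chance level as a percentage (e.g. 5.88 for 17 classes).
#' @export
chance_level_pct <- function(n_classes) round(100 / n_classes, 2)
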