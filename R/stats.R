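#' Confusion matrix and accuracy
#'
#' @param true_labels,predicted_labels Integer labels in `0..k-1`, equal
#'   length.
#' @param k Number of classes.
#' @return A list with `confusion` (`k x k` integer matrix, rows = true
#'   class, columns = predicted) and `accuracy` (percent,
#'   `100 * trace / total`).
#' @export
confusion_and_accuracy <- function(true_labels, predicted_labels, k) {
  true_labels <- as.integer(true_labels)
  predicted_labels <- as.integer(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  if (any(c(true_labels, predicted_labels) < 0L) ||
      any(c(true_labels, predicted_labels) >= k))
    stop("labels must lie in 0..k-1")
  cm <- matrix(0L, k, k,
               dimnames = list(true = 0:(k - 1), predicted = 0:(k - 1)))
  for (j in seq_along(true_labels))
    cm[true_labels[j] + 1L, predicted_labels[j] + 1L] <-
      cm[true_labels[j] + 1L, predicted_labels[j] + 1L] + 1L
  list(confusion = cm,
       accuracy = 100 * sum(diag(cm)) / max(1L, length(true_labels)))
}

#' Two-sample t-test
#'
#' Pooled-variance (Student) two-sample t-test by default, with a Welch
#' option; two-tailed p-value by default.
#'
#' @param a,b Numeric samples (each of length >= 2).
#' @param two_tailed If `FALSE`, the one-tailed p for the observed
#'   direction.
#' @param var_equal Pooled variance (default) or Welch.
#' @return A list with `t`, `p`, and `df`.
#' @export
two_sample_ttest <- function(a, b, two_tailed = TRUE, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = if (two_tailed) 1 else 0.5,
                  df = length(a) + length(b) - 2))
    stop("zero variance in both samples with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  t_stat <- unname(ht$statistic)
  df <- unname(ht$parameter)
  p <- if (two_tailed) ht$p.value else stats::pt(-abs(t_stat), df)
  list(t = t_stat, p = p, df = df)
}

#' One-way fixed-effects ANOVA
#'
#' Classical between/within sum-of-squares decomposition,
#' `F = MS_between / MS_within` on `(k - 1, N - k)` degrees of freedom.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @return An `anova_result`: list with `F`, `p`, `df_between`, `df_within`,
#'   `group_means`, `ms_within`, `group_sizes`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(lengths(groups) < 2L)) stop("every group needs >= 2 values")
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, 0)
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- k - 1L
  df_w <- N - k
  msb <- ssb / df_b
  msw <- ssw / df_w
  f_stat <- if (msw == 0) { if (msb == 0) 0 else Inf } else msb / msw
  p <- if (is.infinite(f_stat)) 0 else
    stats::pf(f_stat, df_b, df_w, lower.tail = FALSE)
  structure(list(F = f_stat, p = p, df_between = df_b, df_within = df_w,
                 group_means = means, ms_within = msw, group_sizes = n),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Tukey HSD post hoc comparisons
#'
#' All pairwise mean differences after a one-way ANOVA, with adjusted
#' p-values from the studentized range distribution on `(k, N - k)`
#' (via [stats::ptukey()]) and rejection flags at level `alpha`.
#'
#' @param groups List of numeric vectors.
#' @param names Optional group names.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `tukey_result` data.frame with columns `group1`, `group2`,
#'   `mean_difference` (`mean(group2) - mean(group1)`), `p_adj`, `reject`.
#' @export
tukey_hsd <- function(groups, names = NULL, alpha = 0.05) {
  an <- one_way_anova(groups)
  k <- length(groups)
  if (is.null(names)) names <- names(groups)
  if (is.null(names)) names <- paste0("group", seq_len(k))
  pairs <- utils::combn(k, 2L)
  res <- data.frame(group1 = character(), group2 = character(),
                    mean_difference = numeric(), p_adj = numeric(),
                    reject = logical())
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    diff <- an$group_means[b] - an$group_means[a]
    se <- sqrt(an$ms_within / 2 *
                 (1 / an$group_sizes[a] + 1 / an$group_sizes[b]))
    q <- abs(diff) / se
    p <- stats::ptukey(q, k, an$df_within, lower.tail = FALSE)
    res <- rbind(res, data.frame(group1 = names[a], group2 = names[b],
                                 mean_difference = unname(diff),
                                 p_adj = p, reject = p < alpha))
  }
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  class(res) <- c("tukey_result", "data.frame")
  res
}

#' Per-algorithm accuracy summary of a subject result table
#'
#' @param results A data.frame with one row per subject: a `subject` column
#'   plus one numeric accuracy column (percent) per algorithm.
#' @return A data.frame with columns `algorithm`, `mean`, `sd` (sample SD,
#'   `n - 1` denominator) and `n`.
#' @export
summarize_cohort <- function(results) {
  stopifnot(is.data.frame(results))
  cols <- setdiff(names(results), "subject")
  cols <- cols[vapply(results[cols], is.numeric, TRUE)]
  if (!length(cols)) stop("no numeric algorithm columns")
  if (nrow(results) < 2L) stop("need at least two subjects")
  data.frame(algorithm = cols,
             mean = vapply(cols, function(cn) mean(results[[cn]]), 0),
             sd = vapply(cols, function(cn) stats::sd(results[[cn]]), 0),
             n = nrow(results), row.names = NULL)
}

#' Bundled two-class subject accuracy table
#'
#' Per-subject test accuracies (percent) of the LSTM, ICGN and Bi-LSTM
#' classifiers on a published 20-subject two-class hand-gripping dataset,
#' bundled for regression tests of the cohort statistics.
#'
#' @return A data.frame with columns `subject`, `lstm`, `icgn`, `bilstm`.
#' @export
subject_accuracy_reference <- function() {
  path <- system.file("extdata", "two_class_subject_accuracy.csv",
                      package = "icgn", mustWork = TRUE)
  utils::read.csv(path)
}

#' Recompute the reference cohort statistics
#'
#' Recomputes, from the bundled per-subject accuracy table, the one-way
#' ANOVA F statistic, the Tukey HSD mean differences, and the per-algorithm
#' mean/SD, and compares each (at its published rounding) with the published
#' values shipped alongside the table.
#'
#' @return A data.frame with columns `quantity`, `computed`, `reference`,
#'   `matches` (agreement within one unit in the reference's last printed
#'   digit, accommodating either rounding or truncation of the published
#'   figures).
#' @export
verify_reference_stats <- function() {
  tab <- subject_accuracy_reference()
  ref <- jsonlite::read_json(
    system.file("extdata", "two_class_reference_stats.json",
                package = "icgn", mustWork = TRUE),
    simplifyVector = TRUE)
  groups <- list(bilstm = tab$bilstm, icgn = tab$icgn, lstm = tab$lstm)
  an <- one_way_anova(groups)
  tk <- tukey_hsd(groups, names = names(groups))
  sm <- summarize_cohort(tab)
  get_diff <- function(g1, g2) {
    r <- tk[tk$group1 == g1 & tk$group2 == g2, "mean_difference"]
    if (!length(r)) -tk[tk$group1 == g2 & tk$group2 == g1, "mean_difference"]
    else r
  }
  computed <- c(anova_f = an$F,
                tukey_lstm_to_icgn = get_diff("lstm", "icgn"),
                tukey_bilstm_to_icgn = get_diff("bilstm", "icgn"),
                tukey_bilstm_to_lstm = get_diff("bilstm", "lstm"),
                lstm_mean = sm$mean[sm$algorithm == "lstm"],
                lstm_sd = sm$sd[sm$algorithm == "lstm"],
                icgn_sd = sm$sd[sm$algorithm == "icgn"],
                bilstm_sd = sm$sd[sm$algorithm == "bilstm"])
  out <- data.frame(quantity = names(computed), computed = unname(computed),
                    reference = unname(unlist(ref[names(computed)])))
  digits <- vapply(out$reference, function(v) {
    s <- sub("^[^.]*\\.?", "", format(v, trim = TRUE))
    nchar(s)
  }, 0L)
  out$matches <- abs(out$computed - out$reference) <= 10^(-digits)
  out
}
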