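#' Per-feature Welch t-test between relapse and relapse-free groups
#'
#' Computes the two-sided unequal-variance (Welch) t statistic, the
#' Welch-Satterthwaite degrees of freedom, and the p-value for every
#' feature row. The computation is vectorized across features; results
#' agree with `stats::t.test(var.equal = FALSE)` to numerical precision.
#'
#' Degenerate cases: a feature with fewer than 2 non-missing values in
#' either group is flagged untestable (`NA` statistics); a feature with
#' zero variance in both groups gets `t = 0, p = 1` when the group means
#' are equal and `t = +/-Inf, p = 0` otherwise (documented convention).
#'
#' @param fm A [feature_matrix()].
#' @param labels Named label vector covering all samples of `fm`.
#' @return data.frame with columns `feature`, `t`, `df`, `p`, `testable`.
#' @export
welch_test <- function(fm, labels) {
  labels <- check_labels(labels, sample_ids(fm))
  v <- fm$values
  g1 <- labels == RELAPSE
  g2 <- labels == RELAPSE_FREE
  if (!any(g1) || !any(g2)) stopf("both groups must be present")
  n1 <- rowSums(!is.na(v[, g1, drop = FALSE]))
  n2 <- rowSums(!is.na(v[, g2, drop = FALSE]))
  m1 <- rowMeans(v[, g1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(v[, g2, drop = FALSE], na.rm = TRUE)
  s1 <- row_var(v[, g1, drop = FALSE], m1, n1)
  s2 <- row_var(v[, g2, drop = FALSE], m2, n2)
  testable <- n1 >= 2 & n2 >= 2
  se2 <- s1 / n1 + s2 / n2
  t_ <- (m1 - m2) / sqrt(se2)
  df_ <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_), df_)
  # zero variance in both groups: exact convention instead of 0/0
  degen <- testable & se2 == 0
  t_[degen] <- ifelse(m1[degen] == m2[degen], 0, Inf * sign(m1 - m2)[degen])
  df_[degen] <- n1[degen] + n2[degen] - 2
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  t_[!testable] <- NA_real_; df_[!testable] <- NA_real_; p[!testable] <- NA_real_
  data.frame(feature = feature_ids(fm), t = unname(t_), df = unname(df_),
             p = unname(p), testable = unname(testable),
             stringsAsFactors = FALSE)
}

row_var <- function(m, means, n) {
  ss <- rowSums((m - means)^2, na.rm = TRUE)
  ifelse(n > 1, ss / (n - 1), NA_real_)
}

#' Threshold a test-result table
#'
#' Keeps features with `p <= alpha`, preserving the original matrix order.
#' Untestable features (missing p) are excluded, never passed silently.
#'
#' @param table Output of [welch_test()].
#' @param alpha Significance threshold in (0, 1\].
#' @param adjust_bh Apply Benjamini-Hochberg adjustment before
#'   thresholding.
#' @return Character vector of passing feature ids.
#' @export
filter_significant <- function(table, alpha = 0.05, adjust_bh = FALSE) {
  if (!is_prob(alpha)) stopf("alpha must be in (0, 1]")
  p <- table$p
  if (isTRUE(adjust_bh)) p <- stats::p.adjust(p, method = "BH")
  table$feature[!is.na(p) & p <= alpha]
}

#' Prefilter result as a writable table
#'
#' @param table Output of [welch_test()].
#' @param alpha Threshold used for the `pass` column.
#' @param path Optional TSV output path.
#' @return The table with a `pass` 0/1 column, invisibly written if `path`
#'   is given.
#' @export
prefilter_table <- function(table, alpha = 0.05, path = NULL) {
  table$pass <- as.integer(!is.na(table$p) & table$p <= alpha)
  if (!is.null(path))
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  table
}
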