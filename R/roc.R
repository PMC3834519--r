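#' ROC curve and AUC from decision scores
#'
#' Operating points over all score thresholds with tied scores handled by
#' a simultaneous step, and the trapezoidal AUC — equivalently the
#' Mann-Whitney statistic with half credit for ties.
#'
#' @param scores Numeric decision scores (larger = more relapse-like).
#' @param labels Binary labels, positive class `"relapse"` (or the first
#'   sorted level).
#' @return A `roc_result`: list with `points` (data.frame threshold, fpr,
#'   tpr), `auc`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- positive_mask(scores, labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n0, 0)
  points <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                       tpr = c(0, tpr))
  structure(list(points = points, auc = auc_mw(scores, pos)),
            class = "roc_result")
}

positive_mask <- function(scores, labels) {
  if (length(scores) != length(labels))
    stopf("scores and labels differ in length")
  yf <- as_binary_factor(labels)
  if (nlevels(droplevels(yf)) < 2) stopf("both classes must be present")
  yf == levels(yf)[1]
}

# Mann-Whitney AUC with half credit for ties (equals trapezoidal area).
auc_mw <- function(scores, pos) {
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples relapse and relapse-free samples separately with replacement
#' (preserving the group design, so no resample can lose a class) and
#' returns the percentile interval of the bootstrap AUC distribution.
#'
#' @param scores Numeric decision scores.
#' @param labels Binary labels.
#' @param reps Bootstrap resamples (>= 100).
#' @param level Confidence level.
#' @param seed RNG seed.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(scores, labels, reps = 2000L, level = 0.95,
                         seed = 1L) {
  if (reps < 100) stopf("reps must be >= 100")
  if (!is_prob(level)) stopf("level must be in (0, 1]")
  pos <- positive_mask(scores, labels)
  i1 <- which(pos); i0 <- which(!pos)
  with_seed(seed, {
    boot <- vapply(seq_len(reps), function(b) {
      ix <- c(sample(i1, length(i1), replace = TRUE),
              sample(i0, length(i0), replace = TRUE))
      auc_mw(scores[ix], pos[ix])
    }, 0)
    a <- (1 - level) / 2
    q <- stats::quantile(boot, c(a, 1 - a), names = FALSE, type = 7)
    c(low = q[1], high = q[2])
  })
}

#' ROC summary with bootstrap confidence interval
#'
#' @inheritParams bootstrap_ci
#' @return A `roc_result` augmented with `ci`, `level`, `boot_reps`,
#'   `seed`.
#' @export
roc_with_ci <- function(scores, labels, reps = 2000L, level = 0.95,
                        seed = 1L) {
  r <- roc_auc(scores, labels)
  r$ci <- bootstrap_ci(scores, labels, reps = reps, level = level,
                       seed = seed)
  r$level <- level; r$boot_reps <- as.integer(reps); r$seed <- as.integer(seed)
  r
}

#' @exportS3Method base::print
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f", x$auc))
  if (!is.null(x$ci))
    cat(sprintf(" (%.0f%% CI %.4f-%.4f, %d bootstrap reps)",
                100 * x$level, x$ci["low"], x$ci["high"], x$boot_reps))
  cat("\n")
  invisible(x)
}
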