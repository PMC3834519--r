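#' Train a soft-margin linear SVM
#'
#' Thin wrapper around [e1071::svm()] (linear kernel, no internal scaling)
#' that returns the primal weight vector and bias oriented so that a
#' positive decision value predicts the positive class. The per-feature
#' RFE ranking criterion is the squared weight.
#'
#' @param X Samples-by-features numeric matrix, already standardized with
#'   training statistics.
#' @param y Binary labels (anything coercible to a 2-level factor; the
#'   level `"relapse"` is taken as positive if present, otherwise the
#'   first level).
#' @param cost Soft-margin cost C.
#' @return List with `weights` (named per feature), `bias`, `positive`
#'   (positive class label) and `criterion` (squared weights).
#' @export
train_linear_svm <- function(X, y, cost = 1.0) {
  X <- as.matrix(X)
  yf <- as_binary_factor(y)
  if (nlevels(droplevels(yf)) < 2) stopf("training data contain a single class")
  # libsvm orients decision values by the first class seen in the data;
  # put positives first so positive f(x) always means the positive class
  ord <- order(yf != levels(yf)[1])
  m <- e1071::svm(X[ord, , drop = FALSE], yf[ord], kernel = "linear",
                  cost = cost, scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  names(w) <- colnames(X)
  list(weights = w, bias = -m$rho, positive = levels(yf)[1],
       criterion = w^2)
}

as_binary_factor <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.logical(y)) y <- ifelse(y, RELAPSE, RELAPSE_FREE)
  lev <- unique(y)
  if (length(lev) > 2) stopf("labels must be binary")
  pos <- if (RELAPSE %in% lev) RELAPSE else sort(lev)[1]
  factor(y, levels = c(pos, setdiff(sort(lev), pos)))
}

svm_decision <- function(fit, X) {
  drop(as.matrix(X) %*% fit$weights) + fit$bias
}

# Standardize train/test with training-fold statistics only.
std_train_test <- function(Xtr, Xte) {
  n <- nrow(Xtr); p <- ncol(Xtr)
  mu <- colMeans(Xtr)
  v <- (colSums(Xtr * Xtr) - n * mu * mu) / (n - 1)
  sd_ <- sqrt(pmax(v, 0))
  sd_[sd_ == 0 | is.na(sd_)] <- 1
  ctr <- matrix(mu, n, p, byrow = TRUE)
  scl <- matrix(1 / sd_, n, p, byrow = TRUE)
  tr <- (Xtr - ctr) * scl
  te <- (Xte - matrix(mu, nrow(Xte), p, byrow = TRUE)) *
    matrix(1 / sd_, nrow(Xte), p, byrow = TRUE)
  list(train = tr, test = te)
}

fit_score <- function(Xtr, ytr, Xte, cost) {
  s <- std_train_test(Xtr, Xte)
  fit <- train_linear_svm(s$train, ytr, cost)
  list(fit = fit, scores = svm_decision(fit, s$test))
}

#' Monte-Carlo 2-fold cross-validation accuracy
#'
#' Repeatedly splits the cohort into two stratified random halves, trains
#' a linear SVM on each half and tests on the other, recording both
#' accuracies per repetition (so `2 * reps` values are returned).
#' Standardization uses training-half statistics only.
#'
#' @param X Samples-by-features matrix (raw scale).
#' @param y Binary labels.
#' @param cost SVM cost.
#' @param reps Number of random halvings.
#' @param seed RNG seed.
#' @return Numeric vector of `2 * reps` test accuracies.
#' @export
mc_two_fold_cv <- function(X, y, cost = 1.0, reps = 200L, seed = 1L) {
  X <- as.matrix(X)
  yf <- as_binary_factor(y)
  if (reps < 1) stopf("reps must be >= 1")
  idx_by_class <- split(seq_len(nrow(X)), yf)
  if (nlevels(droplevels(yf)) < 2 || any(lengths(idx_by_class) < 2))
    stopf("each class needs >= 2 samples to stratify halves")
  pos <- yf == levels(yf)[1]
  with_seed(seed, {
    acc <- numeric(2L * reps)
    for (r in seq_len(reps)) {
      d0 <- unlist(lapply(idx_by_class, function(ix) {
        ix <- sample(ix)
        ix[seq_len(length(ix) %/% 2L)]
      }), use.names = FALSE)
      d1 <- setdiff(seq_len(nrow(X)), d0)
      for (j in 1:2) {
        tr <- if (j == 1) d0 else d1
        te <- if (j == 1) d1 else d0
        sc <- fit_score(X[tr, , drop = FALSE], yf[tr],
                        X[te, , drop = FALSE], cost)$scores
        acc[2L * (r - 1L) + j] <- mean((sc > 0) == pos[te])
      }
    }
    acc
  })
}

#' SVM recursive feature elimination with minimal-panel selection
#'
#' Classic RFE: train the linear SVM on all samples, rank features by
#' squared weight, remove the lowest-ranked feature (ties broken by
#' lexicographically smallest id), repeat until no features remain. At
#' every surviving-set size the Monte-Carlo 2-fold CV accuracy is
#' recorded; the selected panel is the smallest size attaining the maximal
#' mean accuracy, made of the longest-surviving features.
#'
#' @param fm A prefiltered [feature_matrix()].
#' @param labels Named label vector.
#' @param cfg A [pipeline_config()] (uses `svm_cost`, `rfe_step`,
#'   `mc_reps`).
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return An `rfe_result`: list with `elimination_order` (first-removed
#'   first), `accuracy_curve` (data.frame k, mean, sd), `selected_panel`
#'   (rank 1 = longest surviving) and `selected_k`.
#' @export
rfe <- function(fm, labels, cfg = pipeline_config(), seed = cfg$seed) {
  labels <- check_labels(labels, sample_ids(fm))
  X <- t(fm$values)
  yf <- as_binary_factor(labels)
  remaining <- feature_ids(fm)
  if (length(remaining) < 1) stopf("rfe needs >= 1 feature")
  removal <- character(0)
  ks <- integer(0); means <- numeric(0); sds <- numeric(0)
  all_std <- std_train_test(X, X)$train
  while (length(remaining) > 0) {
    k <- length(remaining)
    acc <- mc_two_fold_cv(X[, remaining, drop = FALSE], yf,
                          cost = cfg$svm_cost, reps = cfg$mc_reps,
                          seed = derive_seed(seed, k))
    ks <- c(ks, k); means <- c(means, mean(acc)); sds <- c(sds, stats::sd(acc))
    if (k == 1L) {
      removal <- c(removal, remaining)
      break
    }
    fit <- train_linear_svm(all_std[, remaining, drop = FALSE], yf,
                            cost = cfg$svm_cost)
    crit <- fit$criterion
    n_drop <- min(cfg$rfe_step, k - 1L)
    # ties resolved toward the lexicographically smallest id
    drop_ids <- remaining[order(crit, remaining)][seq_len(n_drop)]
    removal <- c(removal, drop_ids)
    remaining <- setdiff(remaining, drop_ids)
  }
  curve <- data.frame(k = ks, mean = means, sd = sds)
  best <- max(curve$mean)
  selected_k <- min(curve$k[curve$mean == best])
  panel <- rev(utils::tail(removal, selected_k))
  structure(list(elimination_order = removal, accuracy_curve = curve,
                 selected_panel = panel, selected_k = selected_k),
            class = "rfe_result")
}

#' @exportS3Method base::print
print.rfe_result <- function(x, ...) {
  cat(sprintf("<rfe_result> %d features ranked; selected panel of %d (CV accuracy %.3f)\n",
              length(x$elimination_order), x$selected_k,
              max(x$accuracy_curve$mean)))
  invisible(x)
}

#' Leave-one-out validation of a feature panel
#'
#' Trains on n-1 samples and scores the held-out sample, for every sample;
#' accuracy is the fraction of held-out decision values with the correct
#' sign. The per-sample scores feed the ROC analysis.
#'
#' @param fm [feature_matrix()] restricted to the selected panel.
#' @param labels Named label vector.
#' @param cost SVM cost.
#' @return List with `scores` (named, positive = relapse side), `accuracy`.
#' @export
loo_validate <- function(fm, labels, cost = 1.0) {
  labels <- check_labels(labels, sample_ids(fm))
  X <- t(fm$values)
  yf <- as_binary_factor(labels)
  pos <- yf == levels(yf)[1]
  n <- nrow(X)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- yf[-i]
    if (nlevels(droplevels(ytr)) < 2)
      stopf("untrainable fold: training set for sample %s has a single class",
            rownames(X)[i])
    scores[i] <- fit_score(X[-i, , drop = FALSE], ytr,
                           X[i, , drop = FALSE], cost)$scores
  }
  names(scores) <- rownames(X)
  list(scores = scores, accuracy = mean((scores > 0) == pos))
}
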