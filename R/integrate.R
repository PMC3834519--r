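#' Combine per-type panels into one matrix
#'
#' Row-binds the selected features of each data type into a single
#' combined matrix over the shared sample set. Feature ids are namespaced
#' by data type (`gene:GENE0001`) and every row is z-scored across
#' samples so heterogeneous scales are comparable.
#'
#' @param panels Named list (by data type) of feature id vectors.
#' @param matrices Named list of [feature_matrix()] objects covering those
#'   types.
#' @return A combined `feature_matrix` with a `provenance` attribute
#'   (data.frame: feature, data_type, source_id).
#' @export
combine_panels <- function(panels, matrices) {
  types <- names(panels)
  if (is.null(types) || !all(types %in% names(matrices)))
    stopf("every panel needs a matrix of the same data type")
  samples <- sample_ids(matrices[[types[1]]])
  blocks <- list(); prov <- list()
  for (ty in types) {
    fm <- matrices[[ty]]
    missing <- setdiff(samples, sample_ids(fm))
    if (length(missing) > 0)
      stopf("sample-set mismatch in %s: missing %s", ty,
            paste(missing, collapse = ", "))
    if (length(setdiff(sample_ids(fm), samples)) > 0)
      stopf("sample-set mismatch in %s: extra samples", ty)
    ids <- panels[[ty]]
    if (anyDuplicated(ids))
      stopf("duplicate feature '%s' in the %s panel",
            ids[duplicated(ids)][1], ty)
    if (length(ids) == 0) next
    v <- fm_subset(fm, ids)$values[, samples, drop = FALSE]
    mu <- rowMeans(v)
    sd_ <- apply(v, 1, stats::sd)
    sd_[sd_ == 0] <- 1
    v <- (v - mu) / sd_
    rownames(v) <- paste(ty, ids, sep = ":")
    blocks[[ty]] <- v
    prov[[ty]] <- data.frame(feature = rownames(v), data_type = ty,
                             source_id = ids, stringsAsFactors = FALSE)
  }
  if (length(blocks) == 0) stopf("all panels are empty")
  out <- feature_matrix(do.call(rbind, blocks), "combined")
  attr(out, "provenance") <- do.call(rbind, unname(prov))
  out
}

#' Random-forest feature ranking against artificial contrasts
#'
#' Repeats `forests` times: augment the matrix with one independently
#' permuted copy of every feature (the artificial contrasts), grow a
#' random-forest classifier, and record out-of-bag permutation importance
#' for every real feature and every contrast. Each real feature is then
#' compared across repetitions with the `quantile` of the contrast
#' importances of the same repetition via a one-sided paired t-test; its
#' normalized score is its mean importance divided by the mean contrast
#' quantile. Constant features get importance 0 with a warning.
#'
#' @param combined A combined [feature_matrix()] from [combine_panels()].
#' @param labels Named label vector.
#' @param forests Number of forest repetitions (>= 2).
#' @param trees Trees per forest (>= 10).
#' @param quantile Contrast-importance quantile tested against.
#' @param seed RNG seed.
#' @return data.frame: `feature`, `data_type`, `score`, `p`, `rank`
#'   (1 = best; sorted by score, ties broken by feature id).
#' @export
ace_rank <- function(combined, labels, forests = 20L, trees = 100L,
                     quantile = 0.75, seed = 1L) {
  if (forests < 2) stopf("forests must be >= 2")
  if (trees < 10) stopf("trees must be >= 10")
  labels <- check_labels(labels, sample_ids(combined))
  yf <- as_binary_factor(labels)
  X <- t(combined$values)
  p <- ncol(X)
  const <- apply(X, 2, function(c) length(unique(c)) == 1L)
  if (any(const))
    warnf("%d constant feature(s); their importance is defined as 0",
          sum(const))
  imp <- matrix(0, p, forests, dimnames = list(colnames(X), NULL))
  cq <- numeric(forests)
  with_seed(seed, {
    for (f in seq_len(forests)) {
      contrasts <- make_contrasts(X)
      Xa <- cbind(X, contrasts)
      rf <- randomForest::randomForest(Xa, yf, ntree = trees,
                                       mtry = ceiling(sqrt(ncol(Xa))),
                                       importance = TRUE)
      all_imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
      imp[, f] <- all_imp[seq_len(p)]
      cq[f] <- stats::quantile(all_imp[-seq_len(p)], quantile, names = FALSE)
    }
  })
  imp[const, ] <- 0
  pvals <- vapply(seq_len(p), function(i) {
    d <- imp[i, ] - cq
    if (stats::sd(d) == 0) return(if (mean(d) > 0) 0 else 1)
    stats::t.test(d, alternative = "greater")$p.value
  }, 0)
  denom <- max(mean(cq), 1e-8)
  score <- pmax(0, rowMeans(imp)) / denom
  prov <- attr(combined, "provenance")
  dtype <- if (!is.null(prov))
    prov$data_type[match(colnames(X), prov$feature)]
  else sub(":.*$", "", colnames(X))
  out <- data.frame(feature = colnames(X), data_type = dtype,
                    score = unname(score), p = unname(pvals),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Threshold the integrated ranking into selected and top tiers
#'
#' @param ranked Output of [ace_rank()].
#' @param p_select Selected-set p-value threshold.
#' @param p_top Top-tier p-value threshold (must not exceed `p_select`'s
#'   set: the top tier is nested in the selected set).
#' @return List with `selected`, `top` (data.frames) and `composition`
#'   (per-data-type counts of the selected set).
#' @export
select_top <- function(ranked, p_select = 0.01, p_top = 1e-30) {
  if (!is_prob(p_select) || !is_prob(p_top))
    stopf("thresholds must be in (0, 1]")
  selected <- ranked[ranked$p <= p_select, , drop = FALSE]
  top <- ranked[ranked$p <= min(p_top, p_select), , drop = FALSE]
  comp <- table(factor(selected$data_type,
                       levels = unique(ranked$data_type)))
  list(selected = selected, top = top,
       composition = as.data.frame(comp, responseName = "n",
                                   stringsAsFactors = FALSE))
}

#' Kendall tau-b with significance
#'
#' Tie-corrected rank correlation; p-value from the tie-corrected normal
#' approximation for n >= 10 and exhaustive permutation enumeration for
#' n < 10.
#'
#' @param x,y Numeric vectors of equal length (n >= 2).
#' @return List with `tau` and `p`.
#' @export
kendall_taub <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 2) stopf("x and y must share length >= 2")
  S <- taub_numerator(x, y)
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  Tx <- sum(tx * (tx - 1) / 2); Ty <- sum(ty * (ty - 1) / 2)
  den <- sqrt((n0 - Tx) * (n0 - Ty))
  tau <- if (den == 0) 0 else S / den
  if (n >= 10) {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    v <- (v0 - vt - vu) / 18 + v1 + v2
    p <- if (v <= 0) 1 else 2 * stats::pnorm(-abs(S) / sqrt(v))
  } else {
    perms <- all_perms(n)
    stat <- abs(vapply(seq_len(nrow(perms)),
                       function(i) taub_numerator(x, y[perms[i, ]]), 0))
    p <- mean(stat >= abs(S))
  }
  list(tau = tau, p = min(1, p))
}

# One artificial contrast per column: an independent permutation of the
# column's values (same multiset, association with the labels destroyed).
make_contrasts <- function(X) {
  contrasts <- apply(X, 2, sample)
  colnames(contrasts) <- paste0("contrast:", colnames(X))
  contrasts
}

taub_numerator <- function(x, y) {
  sx <- sign(outer(x, x, "-")); sy <- sign(outer(y, y, "-"))
  sum(sx * sy * upper.tri(sx))
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, ifelse(sub >= i, sub + 1L, sub))))
}

#' Kendall association network over selected features
#'
#' Computes tau-b for every unordered pair of selected features and keeps
#' edges significant at `alpha_edge`.
#'
#' @param fm A [feature_matrix()] restricted to the selected set (>= 2
#'   features).
#' @param alpha_edge Edge p-value threshold.
#' @return data.frame of edges: `a`, `b`, `tau`, `p`.
#' @export
kendall_network <- function(fm, alpha_edge = 0.01) {
  ids <- feature_ids(fm)
  if (length(ids) < 2) stopf("need >= 2 selected features")
  v <- fm$values
  pairs <- utils::combn(length(ids), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    kt <- kendall_taub(v[i, ], v[j, ])
    data.frame(a = ids[i], b = ids[j], tau = kt$tau, p = kt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[out$p <= alpha_edge, , drop = FALSE]
}

#' Map integrated features to genomic coordinates
#'
#' Genes and miRNAs are looked up in a BED-style annotation, cytoband
#' features in the cytoband map; metabolite features are unmapped by
#' design (they have no genomic locus).
#'
#' @param ranked Output of [ace_rank()] (or any data.frame with `feature`
#'   and `data_type`).
#' @param annotation Optional data.frame (`chrom`, `start`, `end`,
#'   `name`) locating gene/miRNA ids.
#' @param bands Optional [cytoband_map()] locating cytoband features.
#' @return data.frame: `feature`, `chrom`, `start`, `end`; unmappable
#'   features get `chrom = "unmapped"`.
#' @export
map_coordinates <- function(ranked, annotation = NULL, bands = NULL) {
  if (!is.null(annotation) && anyDuplicated(annotation$name))
    stopf("duplicate annotation for id '%s'",
          annotation$name[duplicated(annotation$name)][1])
  src <- sub("^[^:]*:", "", ranked$feature)
  out <- data.frame(feature = ranked$feature, chrom = "unmapped",
                    start = NA_real_, end = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    ty <- ranked$data_type[i]
    if (ty %in% c("gene", "mirna") && !is.null(annotation)) {
      j <- match(src[i], annotation$name)
      if (!is.na(j)) {
        out$chrom[i] <- annotation$chrom[j]
        out$start[i] <- annotation$start[j]
        out$end[i] <- annotation$end[j]
      }
    } else if (ty == "cin_cytoband" && !is.null(bands)) {
      j <- match(src[i], bands$band)
      if (!is.na(j)) {
        out$chrom[i] <- bands$chrom[j]
        out$start[i] <- bands$start[j]
        out$end[i] <- bands$end[j]
      }
    }
  }
  out
}
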