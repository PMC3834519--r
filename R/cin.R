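#' Chromosomal instability index per cytoband
#'
#' For a band of length L, the gain index is the sum over segments whose
#' log2 ratio reaches the gain threshold of `ratio * overlap / L`, the
#' loss index the analogous sum of `|ratio| * overlap / L` over segments
#' at or below the negated loss threshold, and the total index their sum.
#' Unsegmented bases contribute nothing. This amplitude-weighted,
#' length-normalized definition is the package's definition of the CIN
#' index (see the methods vignette).
#'
#' @param profile One sample's segment data.frame (`chrom`, `start`,
#'   `end`, `log2_ratio`; 0-based half-open).
#' @param bands A [cytoband_map()].
#' @param t_gain,t_loss Positive log2-ratio thresholds; a segment counts as
#'   gained when `log2_ratio >= t_gain` and lost when
#'   `log2_ratio <= -t_loss`.
#' @return data.frame with `region`, `gain`, `loss`, `total` per band.
#' @export
cytoband_cin <- function(profile, bands, t_gain = 0.2, t_loss = 0.2) {
  check_cin_input(profile, bands, t_gain, t_loss)
  out <- region_cin(profile, bands$chrom, bands$start, bands$end, t_gain,
                    t_loss)
  data.frame(region = bands$band, gain = out$gain, loss = out$loss,
             total = out$gain + out$loss, stringsAsFactors = FALSE)
}

#' Chromosomal instability index per whole chromosome
#'
#' Same definition as [cytoband_cin()] with the chromosome (the span of
#' its bands) as the region; equivalently the band-length-weighted average
#' of the band indices.
#'
#' @inheritParams cytoband_cin
#' @return data.frame with `region`, `gain`, `loss`, `total` per
#'   chromosome.
#' @export
chromosome_cin <- function(profile, bands, t_gain = 0.2, t_loss = 0.2) {
  check_cin_input(profile, bands, t_gain, t_loss)
  chroms <- unique(bands$chrom)
  lo <- vapply(chroms, function(ch) min(bands$start[bands$chrom == ch]), 0)
  hi <- vapply(chroms, function(ch) max(bands$end[bands$chrom == ch]), 0)
  out <- region_cin(profile, chroms, lo, hi, t_gain, t_loss)
  data.frame(region = chroms, gain = out$gain, loss = out$loss,
             total = out$gain + out$loss, stringsAsFactors = FALSE)
}

check_cin_input <- function(profile, bands, t_gain, t_loss) {
  if (!(t_gain > 0) || !(t_loss > 0))
    stopf("t_gain and t_loss must be positive")
  if (any(bands$end <= bands$start)) stopf("band of zero length")
  for (ch in unique(profile$chrom)) {
    b <- bands[bands$chrom == ch, ]
    if (nrow(b) == 0)
      stopf("segment on chromosome '%s' absent from the cytoband map", ch)
    s <- profile[profile$chrom == ch, ]
    if (any(s$start < min(b$start)) || any(s$end > max(b$end)))
      stopf("segment beyond chromosome bounds on %s", ch)
  }
}

# Interval-overlap accumulation of gain/loss indices for arbitrary regions.
region_cin <- function(profile, chrom, start, end, t_gain, t_loss) {
  gain <- numeric(length(chrom)); loss <- numeric(length(chrom))
  for (i in seq_along(chrom)) {
    s <- profile[profile$chrom == chrom[i], , drop = FALSE]
    if (nrow(s) == 0) next
    ov <- pmin(s$end, end[i]) - pmax(s$start, start[i])
    ov[ov < 0] <- 0
    L <- end[i] - start[i]
    g <- s$log2_ratio >= t_gain
    l <- s$log2_ratio <= -t_loss
    gain[i] <- sum(s$log2_ratio[g] * ov[g]) / L
    loss[i] <- sum(-s$log2_ratio[l] * ov[l]) / L
  }
  list(gain = gain, loss = loss)
}

#' CIN feature matrix across samples
#'
#' Computes the CIN index for every sample and region and assembles the
#' chosen channel into a [feature_matrix()] (data type `cin_cytoband`)
#' ready for the significance prefilter and SVM-RFE.
#'
#' @param profiles A [segment_profiles()] list.
#' @param bands A [cytoband_map()].
#' @param t_gain,t_loss Thresholds, see [cytoband_cin()].
#' @param level `"cytoband"` or `"chromosome"`.
#' @param channel `"total"`, `"gain"` or `"loss"`.
#' @return A `feature_matrix` of CIN indices (regions x samples).
#' @export
cin_matrix <- function(profiles, bands, t_gain = 0.2, t_loss = 0.2,
                       level = c("cytoband", "chromosome"),
                       channel = c("total", "gain", "loss")) {
  level <- match.arg(level); channel <- match.arg(channel)
  if (length(profiles) < 1) stopf("need >= 1 segment profile")
  known <- unique(bands$chrom)
  for (sm in names(profiles)) {
    bad <- setdiff(unique(profiles[[sm]]$chrom), known)
    if (length(bad) > 0)
      stopf("sample %s uses chromosome name(s) not in the cytoband map: %s",
            sm, paste(bad, collapse = ", "))
  }
  fn <- if (level == "cytoband") cytoband_cin else chromosome_cin
  cols <- lapply(profiles, function(p) fn(p, bands, t_gain, t_loss))
  regions <- cols[[1]]$region
  v <- vapply(cols, function(df) df[[channel]], numeric(length(regions)))
  v <- matrix(v, nrow = length(regions),
              dimnames = list(regions, names(profiles)))
  feature_matrix(v, "cin_cytoband")
}

#' Naive fixed-window fallback segmenter
#'
#' A deliberately simple segmenter for probe-level input that has not been
#' segmented upstream: probes are averaged in fixed genomic windows and
#' adjacent windows whose means differ by less than `merge_tol` are
#' merged. This is not a substitute for a proper change-point method and
#' is flagged as such; segmented input should be preferred.
#'
#' @param probes data.frame with `chrom`, `pos` (0-based), `log2_ratio`.
#' @param window Window width in bases.
#' @param merge_tol Merge adjacent windows closer than this in mean log2.
#' @return Segment data.frame (`chrom`, `start`, `end`, `log2_ratio`).
#' @export
naive_segment <- function(probes, window = 1e6, merge_tol = 0.1) {
  out <- lapply(split(probes, probes$chrom), function(p) {
    w <- floor(p$pos / window)
    agg <- stats::aggregate(p$log2_ratio, list(w = w), mean)
    segs <- data.frame(chrom = p$chrom[1], start = agg$w * window,
                       end = (agg$w + 1) * window, log2_ratio = agg$x)
    segs <- segs[order(segs$start), ]
    keep <- segs[1, ]
    for (i in seq_len(nrow(segs))[-1]) {
      last <- nrow(keep)
      if (segs$start[i] == keep$end[last] &&
          abs(segs$log2_ratio[i] - keep$log2_ratio[last]) < merge_tol) {
        n_old <- (keep$end[last] - keep$start[last]) / window
        keep$log2_ratio[last] <- (keep$log2_ratio[last] * n_old +
                                    segs$log2_ratio[i]) / (n_old + 1)
        keep$end[last] <- segs$end[i]
      } else keep <- rbind(keep, segs[i, ])
    }
    keep
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
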