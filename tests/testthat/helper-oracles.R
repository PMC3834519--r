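# Independent brute-force oracles used to validate the analytical
# implementations. These deliberately take the slowest, most literal route.

# Welch test through stats::t.test (reference implementation).
oracle_welch <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

# Two-sided Fisher exact p by exhaustive enumeration over all 2x2 tables
# with the observed margins (point-probability method).
oracle_fisher2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)), 0)
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hypergeometric upper tail P(X >= a).
oracle_hyper_tail <- function(a, m, n, k) {
  sum(stats::dhyper(a:min(k, m), m, n, k))
}

# Kendall tau-b by explicit pair loops.
oracle_taub <- function(x, y) {
  n <- length(x); C <- 0; D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(choose(table(x), 2)); ty <- sum(choose(table(y), 2))
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) 0 else (C - D) / den
}

# AUC by explicit concordant-pair counting with half credit for ties.
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# CIN indices by per-base accumulation (integer coordinates only).
oracle_cin_band <- function(profile, b_start, b_end, b_chrom, t_gain, t_loss) {
  on_chrom <- profile$chrom == b_chrom
  starts <- profile$start[on_chrom]; ends <- profile$end[on_chrom]
  ratios <- profile$log2_ratio[on_chrom]
  gain <- 0; loss <- 0
  for (base in seq(b_start, b_end - 1)) {
    hit <- which(starts <= base & ends > base)
    if (length(hit) == 1) {
      r <- ratios[hit]
      if (r >= t_gain) gain <- gain + r
      if (r <= -t_loss) loss <- loss + abs(r)
    }
  }
  L <- b_end - b_start
  c(gain = gain / L, loss = loss / L)
}

# Random small segment-profile instance on one chromosome with integer
# coordinates (for per-base oracle comparisons).
random_cin_instance <- function(max_segments = 5, max_bands = 3, span = 60) {
  n_bands <- sample(seq_len(max_bands), 1)
  cuts <- sort(sample(seq_len(span - 1), n_bands - 1))
  bstarts <- c(0, cuts); bends <- c(cuts, span)
  bands <- cytoband_map(rep("chr1", n_bands), bstarts, bends,
                        sprintf("b%02d", seq_len(n_bands)))
  n_seg <- sample(seq_len(max_segments), 1)
  pos <- sort(sample(0:span, 2 * n_seg, replace = TRUE))
  segs <- data.frame(chrom = "chr1", start = pos[seq(1, 2 * n_seg, 2)],
                     end = pos[seq(2, 2 * n_seg, 2)],
                     log2_ratio = round(stats::runif(n_seg, -1.5, 1.5), 2))
  segs <- segs[segs$end > segs$start, , drop = FALSE]
  # enforce non-overlap by clipping successive starts
  if (nrow(segs) > 1)
    for (i in 2:nrow(segs))
      segs$start[i] <- max(segs$start[i], segs$end[i - 1])
  segs <- segs[segs$end > segs$start, , drop = FALSE]
  list(bands = bands, segs = segs)
}
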