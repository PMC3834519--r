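# Small fixtures built in code.

two_group_labels <- function(n1 = 20, n2 = 20, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n1 + n2))
  stats::setNames(c(rep("relapse", n1), rep("relapse_free", n2)), ids)
}

# A features-x-samples matrix with optional planted mean shifts in the
# relapse group.
toy_matrix <- function(p = 20, n1 = 10, n2 = 10, shift_rows = integer(0),
                       shift = 2, data_type = "gene", seed = 1) {
  labels <- two_group_labels(n1, n2)
  v <- relapsig:::with_seed(seed, {
    m <- matrix(stats::rnorm(p * (n1 + n2)), p, n1 + n2)
    m[shift_rows, seq_len(n1)] <- m[shift_rows, seq_len(n1), drop = FALSE] + shift
    m
  })
  dimnames(v) <- list(sprintf("F%03d", seq_len(p)), names(labels))
  list(fm = feature_matrix(v, data_type), labels = labels)
}

# Variant table with explicit per-variant carrier sets.
toy_variants <- function(rows, samples) {
  va <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = "chr1", pos = r$pos, ref = "A", alt = "T",
               gene = r$gene, csq = r$csq, del = r$del,
               af = if (is.null(r$af)) NA_real_ else r$af,
               stringsAsFactors = FALSE)))
  geno <- do.call(rbind, lapply(rows, function(r) {
    g <- rep("0/0", length(samples))
    names(g) <- samples
    g[r$carriers] <- "0/1"
    if (!is.null(r$missing)) g[r$missing] <- "./."
    g
  }))
  colnames(geno) <- samples
  variant_table(va, geno)
}

small_synth_spec <- function(seed = 1L, n_features = 200L,
                             n_informative = 6L, effect = 2) {
  synthetic_spec(
    types = list(gene = list(n_features = n_features,
                             n_informative = n_informative,
                             effect_size = effect, block_corr = 0.6,
                             block_size = 4L)),
    variants = list(n_genes = 40L, n_signal_genes = 6L,
                    carrier_rate_relapse = 0.4, carrier_rate_free = 0.1),
    seed = seed)
}

# Compact all-component spec for end-to-end pipeline tests.
small_cnv_spec <- function(n_altered = 4L) {
  bands_per_chrom <- 10L; band_len <- 1e6
  chrom <- rep(paste0("chr", 1:2), each = bands_per_chrom)
  idx <- rep(seq_len(bands_per_chrom), 2)
  map <- cytoband_map(chrom, (idx - 1) * band_len, idx * band_len,
                      sprintf("%dq%02d", rep(1:2, each = bands_per_chrom),
                              idx))
  altered <- data.frame(
    band = sprintf("%dq%02d", rep(1:2, each = 2), rep(c(3L, 7L), 2)),
    direction = rep(c("gain", "loss"), 2),
    amplitude = 0.6, penetrance = 0.8,
    stringsAsFactors = FALSE)[seq_len(n_altered), ]
  list(cytoband_map = map, altered_cytobands = altered, noise_sd = 0.05)
}

small_full_spec <- function(seed = 1L) {
  mk <- function(n, k) list(n_features = n, n_informative = k,
                            effect_size = 2, block_corr = 0.6,
                            block_size = 4L)
  synthetic_spec(
    types = list(gene = mk(120L, 6L), serum_pos = mk(80L, 5L)),
    cnv = small_cnv_spec(),
    variants = list(n_genes = 50L, n_signal_genes = 8L,
                    carrier_rate_relapse = 0.4, carrier_rate_free = 0.1),
    seed = seed)
}

fast_cfg <- function(seed = 1L, ...) {
  pipeline_config(mc_reps = 20L, boot_reps = 200L, rface_forests = 4L,
                  rface_trees = 50L, seed = seed, ...)
}
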