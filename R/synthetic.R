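#' Specification of a synthetic multi-omics cohort
#'
#' Describes a two-group (relapse vs relapse-free) cohort with planted
#' differential signal in every data type: log2-scale expression and
#' metabolite matrices with informative features shifted between groups and
#' organised into correlated redundant blocks, copy-number segment profiles
#' with altered cytobands in a fraction of relapse samples, and annotated
#' variants whose signal genes carry deleterious alleles only in relapse
#' samples. Defaults emulate a 20/20 cohort whose per-type informative
#' feature counts match the published relapse panels (12 genes, 25 miRNAs,
#' 16 cytobands, 15/9 serum and 16/18 urine metabolites).
#'
#' @param n_relapse,n_free Samples per group.
#' @param types Named list (gene, mirna, serum_pos, serum_neg, urine_pos,
#'   urine_neg) of lists with `n_features`, `n_informative`,
#'   `effect_size` (standardized mean shift, z units), `block_corr`
#'   (within-block correlation in \[0,1)), `block_size`.
#' @param cnv List with `cytoband_map` (a [cytoband_map()]),
#'   `altered_cytobands` (data.frame: band, direction gain/loss, amplitude
#'   log2, penetrance in (0,1\]) and `noise_sd` (segment-level log2 noise).
#' @param variants List with `n_genes`, `n_signal_genes`,
#'   `carrier_rate_relapse`, `carrier_rate_free` (per-sample carrier
#'   probabilities in (0,1\]).
#' @param seed Integer; fixes all randomness of the bundle.
#' @return A `synthetic_spec` object for [generate_cohort()].
#' @export
synthetic_spec <- function(n_relapse = 20L, n_free = 20L,
                           types = default_type_specs(),
                           cnv = default_cnv_spec(),
                           variants = list(n_genes = 500L,
                                           n_signal_genes = 20L,
                                           carrier_rate_relapse = 0.4,
                                           carrier_rate_free = 0.1),
                           seed = 1L) {
  if (!is_count(n_relapse) || n_relapse < 1) stopf("invalid field n_relapse")
  if (!is_count(n_free) || n_free < 1) stopf("invalid field n_free")
  if (!is_count(seed)) stopf("invalid field seed")
  for (ty in names(types)) {
    t <- types[[ty]]
    if (!is_count(t$n_features) || t$n_features < 1)
      stopf("invalid field types$%s$n_features", ty)
    if (!is_count(t$n_informative) || t$n_informative > t$n_features)
      stopf("invalid field types$%s$n_informative (must be <= n_features)", ty)
    if (!is.numeric(t$effect_size) || !is.finite(t$effect_size))
      stopf("invalid field types$%s$effect_size", ty)
    if (!is.numeric(t$block_corr) || t$block_corr < 0 || t$block_corr >= 1)
      stopf("invalid field types$%s$block_corr", ty)
    if (!is_count(t$block_size) || t$block_size < 1)
      stopf("invalid field types$%s$block_size", ty)
  }
  ac <- cnv$altered_cytobands
  if (nrow(ac) > 0) {
    if (!all(ac$band %in% cnv$cytoband_map$band))
      stopf("invalid field cnv$altered_cytobands$band (unknown band)")
    if (!all(ac$direction %in% c("gain", "loss")))
      stopf("invalid field cnv$altered_cytobands$direction")
    if (!all(is.finite(ac$amplitude) & ac$amplitude > 0))
      stopf("invalid field cnv$altered_cytobands$amplitude")
    if (!all(ac$penetrance > 0 & ac$penetrance <= 1))
      stopf("invalid field cnv$altered_cytobands$penetrance")
  }
  if (!is_count(variants$n_genes) || variants$n_genes < 1)
    stopf("invalid field variants$n_genes")
  if (!is_count(variants$n_signal_genes) ||
      variants$n_signal_genes > variants$n_genes)
    stopf("invalid field variants$n_signal_genes")
  if (!is_prob(variants$carrier_rate_relapse))
    stopf("invalid field variants$carrier_rate_relapse")
  if (!is_prob(variants$carrier_rate_free))
    stopf("invalid field variants$carrier_rate_free")
  structure(list(n_relapse = as.integer(n_relapse),
                 n_free = as.integer(n_free), types = types, cnv = cnv,
                 variants = variants, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default per-type feature specifications
#' @return Named list of per-type generator settings.
#' @export
default_type_specs <- function() {
  mk <- function(n, k) list(n_features = n, n_informative = k,
                            effect_size = 2.0, block_corr = 0.6,
                            block_size = 4L)
  list(gene = mk(2000L, 12L), mirna = mk(800L, 25L),
       serum_pos = mk(600L, 15L), serum_neg = mk(600L, 9L),
       urine_pos = mk(600L, 16L), urine_neg = mk(600L, 18L))
}

#' Default synthetic genome and copy-number alterations
#'
#' A compact synthetic karyotype: 8 chromosomes of 40 cytobands (3 Mb
#' each), with 16 altered bands (2 per chromosome, alternating gain/loss,
#' log2 amplitude 0.6, penetrance 0.8 among relapse samples).
#'
#' @return List with `cytoband_map`, `altered_cytobands`, `noise_sd`.
#' @export
default_cnv_spec <- function() {
  bands_per_chrom <- 40L
  band_len <- 3e6
  chrom <- rep(paste0("chr", 1:8), each = bands_per_chrom)
  idx <- rep(seq_len(bands_per_chrom), 8)
  map <- cytoband_map(chrom, (idx - 1) * band_len, idx * band_len,
                      sprintf("%dq%02d", rep(1:8, each = bands_per_chrom), idx))
  altered <- data.frame(
    band = sprintf("%dq%02d", rep(1:8, each = 2), rep(c(10L, 30L), 8)),
    direction = rep(c("gain", "loss"), 8),
    amplitude = 0.6, penetrance = 0.8, stringsAsFactors = FALSE)
  list(cytoband_map = map, altered_cytobands = altered, noise_sd = 0.05)
}

type_prefix <- c(gene = "GENE", mirna = "MIR", serum_pos = "SPOS",
                 serum_neg = "SNEG", urine_pos = "UPOS", urine_neg = "UNEG")

#' Generate a synthetic multi-omics cohort
#'
#' Draws one complete cohort bundle from a [synthetic_spec()]: all feature
#' matrices on log2 scale with per-feature SD 1 (informative features get a
#' mean shift of `effect_size` in the relapse group and sit in latent-factor
#' blocks with within-block correlation `block_corr`), copy-number segment
#' profiles with a neutral noisy background plus one covering segment per
#' altered cytoband in carrier relapse samples, and a variant table whose
#' signal genes carry rare deleterious alleles exclusively in relapse
#' samples. Identical spec and seed give a bit-identical bundle.
#'
#' @param spec A [synthetic_spec()].
#' @return A `cohort_bundle`: list with `labels`, `matrices` (named list of
#'   [feature_matrix()]), `segments`, `variants`, `cytobands`, and `truth`
#'   (planted feature ids per type, altered bands, signal genes).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_relapse + spec$n_free
    samples <- sprintf("S%03d", seq_len(n))
    labels <- stats::setNames(
      c(rep(RELAPSE, spec$n_relapse), rep(RELAPSE_FREE, spec$n_free)),
      samples)
    relapse <- labels == RELAPSE

    matrices <- list()
    truth <- list()
    for (ty in names(spec$types)) {
      g <- gen_type_matrix(spec$types[[ty]], ty, samples, relapse)
      matrices[[ty]] <- g$fm
      truth[[ty]] <- g$informative
    }
    seg <- gen_segments(spec$cnv, samples, relapse)
    vt <- gen_variants(spec$variants, spec$cnv$cytoband_map, samples, relapse)
    truth$cin_cytoband <- spec$cnv$altered_cytobands$band
    truth$variant_genes <- vt$signal_genes
    structure(list(labels = labels, matrices = matrices,
                   segments = seg, variants = vt$table,
                   cytobands = spec$cnv$cytoband_map, truth = truth,
                   spec = spec),
              class = "cohort_bundle")
  })
}

gen_type_matrix <- function(t, ty, samples, relapse) {
  n <- length(samples)
  p <- t$n_features
  ids <- sprintf("%s%04d", type_prefix[[ty]], seq_len(p))
  informative <- sort(sample(ids, t$n_informative))
  v <- matrix(stats::rnorm(p * n), p, n, dimnames = list(ids, samples))
  # redundant background blocks sharing a latent factor:
  # x = sqrt(r) f + sqrt(1-r) e; about 5% of the non-informative features,
  # exchangeable between groups (no shift), so per-feature null p-values
  # stay uniform while cross-feature redundancy is present
  background <- setdiff(ids, informative)
  n_redundant <- min(length(background),
                     t$block_size * (floor(0.05 * p) %/% t$block_size))
  if (n_redundant > 0 && t$block_corr > 0) {
    redundant <- sample(background, n_redundant)
    blocks <- split(redundant, ceiling(seq_along(redundant) / t$block_size))
    for (b in blocks) {
      f <- stats::rnorm(n)
      v[b, ] <- sqrt(t$block_corr) * matrix(f, length(b), n, byrow = TRUE) +
        sqrt(1 - t$block_corr) * v[b, , drop = FALSE]
    }
  }
  v[informative, relapse] <- v[informative, relapse] + t$effect_size
  list(fm = feature_matrix(v, ty), informative = informative)
}

# Overwrite interval [s, e) of a per-chromosome segment set with one new
# segment of the given log2 ratio, clipping whatever it covers.
overwrite_segment <- function(segs, s, e, value) {
  keep <- segs[segs$end <= s | segs$start >= e, , drop = FALSE]
  left <- segs[segs$start < s & segs$end > s, , drop = FALSE]
  if (nrow(left) > 0) { left$end <- s; keep <- rbind(keep, left) }
  right <- segs[segs$start < e & segs$end > e, , drop = FALSE]
  if (nrow(right) > 0) { right$start <- e; keep <- rbind(keep, right) }
  out <- rbind(keep, data.frame(chrom = segs$chrom[1], start = s, end = e,
                                log2_ratio = value))
  out[order(out$start), ]
}

gen_segments <- function(cnv, samples, relapse) {
  map <- cnv$cytoband_map
  ac <- cnv$altered_cytobands
  chrom_span <- do.call(rbind, lapply(split(map, map$chrom), function(b)
    data.frame(chrom = b$chrom[1], start = min(b$start), end = max(b$end))))
  # carrier draw per altered band x relapse sample
  carriers <- matrix(FALSE, nrow(ac), length(samples),
                     dimnames = list(ac$band, samples))
  if (nrow(ac) > 0)
    carriers[, relapse] <- matrix(
      stats::runif(nrow(ac) * sum(relapse)) < ac$penetrance,
      nrow(ac), sum(relapse))
  profiles <- lapply(samples, function(sm) {
    per_chrom <- lapply(seq_len(nrow(chrom_span)), function(ci) {
      ch <- chrom_span$chrom[ci]
      lo <- chrom_span$start[ci]; hi <- chrom_span$end[ci]
      nseg <- sample(3:6, 1)
      cuts <- sort(sample(seq(lo + 1e5, hi - 1e5, by = 1e5), nseg - 1))
      bounds <- c(lo, cuts, hi)
      segs <- data.frame(chrom = ch, start = bounds[-length(bounds)],
                         end = bounds[-1],
                         log2_ratio = stats::rnorm(nseg, 0, cnv$noise_sd))
      hits <- which(carriers[, sm] & ac$band %in% map$band[map$chrom == ch])
      for (i in hits) {
        b <- map[map$band == ac$band[i], ]
        amp <- if (ac$direction[i] == "gain") ac$amplitude[i] else -ac$amplitude[i]
        segs <- overwrite_segment(segs, b$start, b$end, amp)
      }
      segs
    })
    do.call(rbind, per_chrom)
  })
  names(profiles) <- samples
  segment_profiles(profiles)
}

CSQ_DAMAGING <- c("missense_variant", "stop_gained", "stop_lost",
                  "frameshift_variant", "splice_donor_variant",
                  "splice_acceptor_variant", "inframe_insertion",
                  "inframe_deletion")
CSQ_BENIGN <- c("synonymous_variant", "intron_variant", "3_prime_UTR_variant")

gen_variants <- function(vs, map, samples, relapse) {
  n <- length(samples)
  genes <- sprintf("GN%04d", seq_len(vs$n_genes))
  signal <- sort(sample(genes, vs$n_signal_genes))
  chroms <- unique(map$chrom)
  rows <- list(); geno <- list()
  draw_geno <- function(carrier) {
    g <- rep("0/0", n)
    g[carrier] <- ifelse(stats::runif(sum(carrier)) < 0.9, "0/1", "1/1")
    miss <- !carrier & stats::runif(n) < 0.02
    g[miss] <- "./."
    g
  }
  vid <- 0L
  for (gi in seq_along(genes)) {
    gene <- genes[gi]
    is_signal <- gene %in% signal
    n_var <- if (is_signal) sample(1:2, 1) else sample(1:3, 1)
    for (k in seq_len(n_var)) {
      vid <- vid + 1L
      carrier <- rep(FALSE, n)
      if (is_signal) {
        csq <- sample(CSQ_DAMAGING, 1)
        del <- 1L
        af <- stats::runif(1, 1e-4, 0.01)
        carrier[relapse] <- stats::runif(sum(relapse)) < vs$carrier_rate_relapse
      } else {
        kind <- sample(c("benign", "nondel", "shared_del"), 1)
        csq <- if (kind == "benign") sample(CSQ_BENIGN, 1)
               else sample(CSQ_DAMAGING, 1)
        del <- if (kind == "shared_del") 1L else 0L
        af <- if (stats::runif(1) < 0.2) NA_real_ else stats::runif(1, 0.001, 0.5)
        carrier <- stats::runif(n) < vs$carrier_rate_free
      }
      rows[[vid]] <- data.frame(
        chrom = chroms[(gi - 1L) %% length(chroms) + 1L],
        pos = 1000L * gi + 10L * k, ref = "A",
        alt = sample(c("C", "G", "T"), 1), gene = gene, csq = csq,
        del = del, af = af, stringsAsFactors = FALSE)
      geno[[vid]] <- draw_geno(carrier)
    }
  }
  gt <- do.call(rbind, geno)
  colnames(gt) <- samples
  list(table = variant_table(do.call(rbind, rows), gt),
       signal_genes = signal)
}

#' Write a cohort bundle to a directory
#'
#' Emits one TSV per feature matrix, a SEG file, a VCF 4.2, a BED4 cytoband
#' map, a labels TSV and the planted truth as JSON. Everything round-trips
#' through the package readers to 6 significant digits.
#'
#' @param bundle A [generate_cohort()] bundle.
#' @param directory Output directory (created if needed).
#' @return Invisibly, a named character vector of written paths.
#' @export
write_bundle <- function(bundle, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (file.access(directory, mode = 2) != 0)
    stopf("directory not writable: %s", directory)
  paths <- c()
  for (ty in names(bundle$matrices)) {
    p <- file.path(directory, paste0(ty, ".tsv"))
    write_matrix(bundle$matrices[[ty]], p)
    paths[ty] <- p
  }
  paths["segments"] <- write_segments(bundle$segments,
                                      file.path(directory, "segments.seg"))
  paths["variants"] <- write_vcf(bundle$variants,
                                 file.path(directory, "variants.vcf"))
  paths["cytobands"] <- write_cytobands(bundle$cytobands,
                                        file.path(directory, "cytobands.bed"))
  paths["labels"] <- write_labels(bundle$labels,
                                  file.path(directory, "labels.tsv"))
  truth_path <- file.path(directory, "truth.json")
  jsonlite::write_json(bundle$truth, truth_path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  paths["truth"] <- truth_path
  invisible(paths)
}

#' Read a cohort bundle written by [write_bundle()]
#' @param directory Directory containing the bundle files.
#' @return A `cohort_bundle` (without the generating spec).
#' @export
read_bundle <- function(directory) {
  types <- names(default_type_specs())
  matrices <- list()
  for (ty in types) {
    p <- file.path(directory, paste0(ty, ".tsv"))
    if (file.exists(p)) matrices[[ty]] <- read_matrix(p, ty)
  }
  truth_path <- file.path(directory, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  structure(list(
    labels = read_labels(file.path(directory, "labels.tsv")),
    matrices = matrices,
    segments = read_segments(file.path(directory, "segments.seg")),
    variants = read_vcf(file.path(directory, "variants.vcf")),
    cytobands = read_cytobands(file.path(directory, "cytobands.bed")),
    truth = truth), class = "cohort_bundle")
}
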