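#' Omics feature matrix
#'
#' A features-by-samples real-valued matrix tagged with its data type. Row
#' names are feature ids, column names are sample ids; both must be unique.
#' This is the common currency of the pipeline: expression arrays, miRNA
#' panels, LC-MS feature intensities and CIN indices all travel as
#' `feature_matrix` objects.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   unique dimnames.
#' @param data_type One of `"gene"`, `"mirna"`, `"cin_cytoband"`,
#'   `"serum_pos"`, `"serum_neg"`, `"urine_pos"`, `"urine_neg"`,
#'   `"combined"`.
#' @param allow_missing Permit `NA` cells (raw input before imputation).
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, data_type, allow_missing = FALSE) {
  data_type <- match.arg(data_type, DATA_TYPES)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("values must have feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate feature id(s): %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample id(s): %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]),
                collapse = ", "))
  if (!allow_missing && anyNA(values))
    stopf("matrix contains missing values; impute or pass allow_missing = TRUE")
  if (any(!is.finite(values) & !is.na(values)))
    stopf("matrix contains non-finite values")
  structure(list(values = values, data_type = data_type),
            class = "feature_matrix")
}

DATA_TYPES <- c("gene", "mirna", "cin_cytoband", "serum_pos", "serum_neg",
                "urine_pos", "urine_neg", "combined")

#' @exportS3Method base::print
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d features x %d samples\n",
              x$data_type, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

feature_ids <- function(fm) rownames(fm$values)
sample_ids <- function(fm) colnames(fm$values)

# Subset rows of a feature_matrix by feature id, preserving order of `ids`.
fm_subset <- function(fm, ids) {
  missing <- setdiff(ids, feature_ids(fm))
  if (length(missing) > 0)
    stopf("unknown feature id(s): %s", paste(missing, collapse = ", "))
  feature_matrix(fm$values[ids, , drop = FALSE], fm$data_type)
}

#' Drop and impute missing cells
#'
#' Features missing in more than `max_missing` of samples are dropped with a
#' warning; remaining `NA` cells are replaced by the feature (row) mean.
#'
#' @param fm A [feature_matrix()] possibly containing `NA` cells.
#' @param max_missing Maximum tolerated per-feature missing fraction.
#' @return A complete `feature_matrix`.
#' @export
impute_missing <- function(fm, max_missing = 0.2) {
  v <- fm$values
  frac <- rowMeans(is.na(v))
  drop <- frac > max_missing
  if (any(drop)) {
    warnf("dropping %d feature(s) with > %.0f%% missing values: %s",
          sum(drop), 100 * max_missing,
          paste(utils::head(rownames(v)[drop], 5), collapse = ", "))
    v <- v[!drop, , drop = FALSE]
  }
  if (anyNA(v)) {
    rm_ <- rowMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- rm_[idx[, 1]]
  }
  feature_matrix(v, fm$data_type)
}

#' Cytoband map
#'
#' Genomic intervals naming chromosome staining bands, the resolution at
#' which copy-number instability is summarised. Coordinates are 0-based
#' half-open; within a chromosome bands must be sorted and non-overlapping.
#'
#' @param chrom,start,end,band Parallel vectors describing the bands.
#' @return A `cytoband_map` data.frame.
#' @export
cytoband_map <- function(chrom, start, end, band) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), band = as.character(band),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stopf("cytoband with start >= end")
  if (anyDuplicated(df$band)) stopf("duplicate cytoband name(s)")
  for (ch in unique(df$chrom)) {
    b <- df[df$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE) && nrow(b) > 1)
      stopf("cytobands on %s are not sorted by start", ch)
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stopf("overlapping cytobands on %s", ch)
  }
  class(df) <- c("cytoband_map", "data.frame")
  df
}

#' Per-sample copy-number segment profiles
#'
#' A named list (one element per sample) of data.frames with columns
#' `chrom`, `start`, `end`, `log2_ratio`; 0-based half-open coordinates,
#' non-overlapping within a sample and chromosome. Ratios are tumor over
#' matched normal on log2 scale (normalization is assumed upstream).
#'
#' @param profiles Named list of segment data.frames.
#' @return A validated `segment_profiles` list.
#' @export
segment_profiles <- function(profiles) {
  if (is.null(names(profiles)) || anyDuplicated(names(profiles)))
    stopf("profiles must be a uniquely named list (one element per sample)")
  profiles <- lapply(profiles, function(df) {
    df <- as.data.frame(df)
    need <- c("chrom", "start", "end", "log2_ratio")
    if (!all(need %in% names(df)))
      stopf("segment profile lacks column(s): %s",
            paste(setdiff(need, names(df)), collapse = ", "))
    if (any(df$start >= df$end)) stopf("segment with start >= end")
    for (ch in unique(df$chrom)) {
      s <- df[df$chrom == ch, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
        stopf("overlapping segments on %s within one sample", ch)
    }
    df[order(df$chrom, df$start), c("chrom", "start", "end", "log2_ratio")]
  })
  structure(profiles, class = "segment_profiles")
}

#' Annotated multi-sample variant table
#'
#' Variant records (1-based positions, as in VCF) with gene, consequence
#' class, a 0/1 deleteriousness flag and an optional population allele
#' frequency, plus a variants-by-samples genotype matrix with entries
#' `0/0`, `0/1`, `1/1` or `./.`.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `csq`, `del`, `af` (`af` may be `NA`).
#' @param geno Character genotype matrix, rows matching `variants`,
#'   columns named by sample id.
#' @return A `variant_table` object.
#' @export
variant_table <- function(variants, geno) {
  variants <- as.data.frame(variants)
  need <- c("chrom", "pos", "ref", "alt", "gene", "csq", "del", "af")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0)
    stopf("variant annotation missing key(s): %s", paste(miss, collapse = ", "))
  if (any(variants$ref == variants$alt)) stopf("variant with alt == ref")
  if (!is.matrix(geno) || nrow(geno) != nrow(variants))
    stopf("genotype matrix must have one row per variant")
  if (is.null(colnames(geno))) stopf("genotype matrix must name its samples")
  ok <- geno %in% c("0/0", "0/1", "1/1", "./.")
  if (!all(ok))
    stopf("invalid genotype value(s): %s",
          paste(unique(geno[!ok]), collapse = ", "))
  structure(list(variants = variants, geno = geno), class = "variant_table")
}

#' @exportS3Method base::print
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d variants x %d samples (%d genes)\n",
              nrow(x$variants), ncol(x$geno), length(unique(x$variants$gene))))
  invisible(x)
}

# TRUE for samples carrying the alternate allele; ./. counts as non-carrier.
geno_carrier <- function(g) g == "0/1" | g == "1/1"
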