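#' Read a feature matrix from TSV
#'
#' Expects a header row of sample ids and one row per feature, first column
#' the feature id. Blank cells become `NA` (flagged missing); anything else
#' non-numeric is a parse error reported with its line number.
#'
#' @param path TSV file path.
#' @param data_type Data type tag, see [feature_matrix()].
#' @return A [feature_matrix()] (possibly with `NA` cells; see
#'   [impute_missing()]).
#' @export
read_matrix <- function(path, data_type) {
  lines <- readLines(path)
  if (length(lines) < 2) stopf("%s: expected a header row and >= 1 feature", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  # header may or may not carry a leading id-column name
  ncol_data <- length(fields[[2]]) - 1L
  samples <- utils::tail(header, ncol_data)
  for (i in seq_along(fields)[-1]) {
    if (length(fields[[i]]) != ncol_data + 1L)
      stopf("%s line %d: ragged row (%d fields, expected %d)",
            path, i, length(fields[[i]]), ncol_data + 1L)
  }
  ids <- vapply(fields[-1], `[[`, "", 1L)
  if (anyDuplicated(ids))
    stopf("%s: duplicate feature id '%s'", path, ids[duplicated(ids)][1])
  vals <- matrix(NA_real_, length(ids), ncol_data,
                 dimnames = list(ids, samples))
  for (i in seq_along(ids)) {
    cells <- fields[[i + 1L]][-1L]
    blank <- cells == "" | cells == "NA"
    num <- suppressWarnings(as.numeric(cells))
    bad <- !blank & is.na(num)
    if (any(bad))
      stopf("%s line %d: non-numeric cell '%s'", path, i + 1L,
            cells[bad][1])
    vals[i, ] <- num
  }
  feature_matrix(vals, data_type, allow_missing = TRUE)
}

#' Write a feature matrix as TSV
#'
#' Values are written with 6 significant digits, which [read_matrix()]
#' round-trips exactly.
#'
#' @param fm A [feature_matrix()].
#' @param path Output file path.
#' @export
write_matrix <- function(fm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature", sample_ids(fm)), collapse = "\t"), con)
  body <- apply(fm$values, 1, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(paste(feature_ids(fm), body, sep = "\t"), con)
  invisible(path)
}

#' Read copy-number segments (SEG format)
#'
#' SEG columns: sample, chrom, start, end, num_probes, seg_mean, with a
#' header line. On-disk coordinates are 1-based inclusive and are converted
#' to the package's internal 0-based half-open convention.
#'
#' @param path SEG file path.
#' @return A [segment_profiles()] list, one element per sample.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stopf("%s: SEG needs 6 columns", path)
  names(df)[1:6] <- c("sample", "chrom", "start", "end", "num_probes",
                      "seg_mean")
  out <- lapply(split(df, df$sample), function(s)
    data.frame(chrom = as.character(s$chrom), start = s$start - 1,
               end = as.numeric(s$end), log2_ratio = s$seg_mean,
               stringsAsFactors = FALSE))
  segment_profiles(out[unique(df$sample)])
}

#' Write copy-number segments (SEG format)
#'
#' @param profiles A [segment_profiles()] list.
#' @param path Output file path.
#' @export
write_segments <- function(profiles, path) {
  rows <- lapply(names(profiles), function(sm) {
    s <- profiles[[sm]]
    data.frame(sample = sm, chrom = s$chrom, start = s$start + 1,
               end = s$end, num_probes = pmax(1L, round((s$end - s$start) / 1e4)),
               seg_mean = fmt_num(s$log2_ratio), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cytoband map (BED4)
#'
#' BED coordinates are already 0-based half-open; column 4 is the band name.
#'
#' @param path BED file path.
#' @return A [cytoband_map()].
#' @export
read_cytobands <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 4) stopf("%s: BED4 needs 4 columns", path)
  cytoband_map(df[[1]], df[[2]], df[[3]], df[[4]])
}

#' Write a cytoband map (BED4)
#' @param bands A [cytoband_map()].
#' @param path Output file path.
#' @export
write_cytobands <- function(bands, path) {
  utils::write.table(bands[, c("chrom", "start", "end", "band")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read sample labels
#'
#' Two-column TSV (sample id, label) with header; labels must be
#' `relapse` or `relapse_free`.
#'
#' @param path TSV file path.
#' @return Named character vector of labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("%s: labels need 2 columns", path)
  labels <- stats::setNames(df[[2]], df[[1]])
  check_labels(labels, names(labels))
}

#' Write sample labels
#' @param labels Named label vector.
#' @param path Output file path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(sample = names(labels), label = labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets (GMT)
#'
#' One set per line: name, description, then one or more gene symbols,
#' tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0)
    stopf("%s line %d: GMT line needs name, description and >= 1 gene",
          path, bad[1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stopf("%s: duplicate gene-set name", path)
  sets
}

#' Read an annotated multi-sample VCF
#'
#' Parses a VCF 4.2 with INFO keys `GENE`, `CSQ` (consequence class),
#' `DEL` (0/1 deleteriousness flag) and optional `AF`, plus per-sample GT.
#'
#' @param path VCF file path.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  info <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (all(is.na(x)) && !key %in% c("AF"))
      stopf("%s: INFO key '%s' absent", path, key)
    x
  }
  gt <- vcfR::extract.gt(v)
  gt[is.na(gt)] <- "./."
  rownames(gt) <- NULL
  variants <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    gene = info("GENE"), csq = info("CSQ"),
    del = as.integer(info("DEL")),
    af = suppressWarnings(as.numeric(vcfR::extract.info(v, element = "AF"))),
    stringsAsFactors = FALSE)
  if (anyNA(variants$gene)) stopf("%s: INFO key 'GENE' absent", path)
  if (anyNA(variants$csq)) stopf("%s: INFO key 'CSQ' absent", path)
  if (anyNA(variants$del)) stopf("%s: INFO key 'DEL' absent", path)
  variant_table(variants, gt)
}

#' Write an annotated multi-sample VCF 4.2
#' @param vt A [variant_table()].
#' @param path Output file path.
#' @export
write_vcf <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=DEL,Number=1,Type=Integer,Description=\"Deleterious flag\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(vt$geno)), collapse = "\t")), con)
  va <- vt$variants
  info <- sprintf("GENE=%s;CSQ=%s;DEL=%d%s", va$gene, va$csq, va$del,
                  ifelse(is.na(va$af), "", sprintf(";AF=%s", fmt_num(va$af))))
  ids <- sprintf("v%d", seq_len(nrow(va)))
  body <- paste(va$chrom, va$pos, ids, va$ref, va$alt, ".", "PASS", info,
                "GT", sep = "\t")
  gt <- apply(vt$geno, 1, paste, collapse = "\t")
  writeLines(paste(body, gt, sep = "\t"), con)
  invisible(path)
}

#' Metabolomics normalization chain
#'
#' Sequential normalization for raw LC-MS intensity matrices: per-sample
#' total-intensity scaling (each column rescaled so its total matches the
#' cohort median total), `log2(x + 1)`, then per-feature z-scoring.
#' Constant features after transformation are left centred at 0.
#'
#' @param fm A [feature_matrix()] of non-negative raw intensities.
#' @return A normalized `feature_matrix`; the applied chain is recorded in
#'   attribute `"normalization"`.
#' @export
normalize_chain <- function(fm) {
  v <- fm$values
  if (any(v < 0, na.rm = TRUE))
    stopf("normalize_chain expects non-negative raw intensities")
  totals <- colSums(v, na.rm = TRUE)
  if (any(totals == 0)) stopf("sample with zero total intensity")
  v <- sweep(v, 2, stats::median(totals) / totals, `*`)
  v <- log2(v + 1)
  mu <- rowMeans(v, na.rm = TRUE)
  sd_ <- apply(v, 1, stats::sd, na.rm = TRUE)
  sd_[sd_ == 0 | is.na(sd_)] <- 1
  v <- (v - mu) / sd_
  out <- feature_matrix(v, fm$data_type, allow_missing = TRUE)
  attr(out, "normalization") <- c("total_intensity_scale", "log2", "zscore")
  out
}
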