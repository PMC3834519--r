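#' Keep non-synonymous, deleterious variants
#'
#' Retains variants whose consequence class is protein-altering (missense,
#' stop gained/lost, frameshift, splice donor/acceptor, inframe indel) and
#' whose deleteriousness flag is 1.
#'
#' @param vt A [variant_table()].
#' @return Filtered `variant_table`.
#' @export
filter_deleterious <- function(vt) {
  stopifnot(inherits(vt, "variant_table"))
  keep <- vt$variants$csq %in% CSQ_DAMAGING & vt$variants$del == 1L
  subset_variants(vt, keep)
}

#' Keep relapse-exclusive variants
#'
#' Retains variants carried (genotype 0/1 or 1/1) by at least one relapse
#' sample and by no relapse-free sample; missing genotypes count as
#' non-carrier.
#'
#' @param vt A [variant_table()].
#' @param labels Named label vector covering all genotype columns.
#' @return Filtered `variant_table`.
#' @export
relapse_exclusive <- function(vt, labels) {
  stopifnot(inherits(vt, "variant_table"))
  labels <- check_labels(labels, colnames(vt$geno))
  carrier <- geno_carrier(vt$geno)
  in_rel <- rowSums(carrier[, labels == RELAPSE, drop = FALSE]) > 0
  in_free <- rowSums(carrier[, labels == RELAPSE_FREE, drop = FALSE]) > 0
  subset_variants(vt, in_rel & !in_free)
}

subset_variants <- function(vt, keep) {
  if (!any(keep)) {
    va <- vt$variants[keep, , drop = FALSE]
    return(structure(list(variants = va,
                          geno = vt$geno[keep, , drop = FALSE]),
                     class = "variant_table"))
  }
  variant_table(vt$variants[keep, , drop = FALSE],
                vt$geno[keep, , drop = FALSE])
}

# Rare-variant mask: annotated population AF below the cutoff, or, when AF
# is missing, cohort alternate-allele frequency below the cutoff.
rare_mask <- function(vt, af_cutoff) {
  g <- vt$geno
  alt <- (g == "0/1") + 2 * (g == "1/1")
  called <- g != "./."
  cohort_af <- rowSums(alt) / pmax(1, 2 * rowSums(called))
  ifelse(is.na(vt$variants$af), cohort_af < af_cutoff,
         vt$variants$af < af_cutoff)
}

#' Gene-level collapsing burden test
#'
#' Collapses rare qualifying variants per gene into a per-sample carrier
#' indicator and tests carrier-by-group 2x2 tables with a two-sided Fisher
#' exact test. A variant is rare when its annotated population allele
#' frequency is below `af_cutoff`, falling back to the cohort alternate
#' allele frequency when no annotation is present.
#'
#' @param vt A [variant_table()] (typically after [filter_deleterious()]).
#' @param labels Named label vector.
#' @param af_cutoff Rare-variant allele-frequency cutoff in (0, 1\].
#' @return data.frame with one row per gene: `gene`, `carriers_relapse`,
#'   `carriers_free`, `n_variants`, `p`.
#' @export
gene_burden <- function(vt, labels, af_cutoff = 0.05) {
  stopifnot(inherits(vt, "variant_table"))
  if (!is_prob(af_cutoff)) stopf("af_cutoff must be in (0, 1]")
  labels <- check_labels(labels, colnames(vt$geno))
  rel <- labels == RELAPSE
  rare <- rare_mask(vt, af_cutoff)
  genes <- sort(unique(vt$variants$gene))
  n1 <- sum(rel); n0 <- sum(!rel)
  rows <- lapply(genes, function(g) {
    rows_g <- which(vt$variants$gene == g & rare)
    carrier <- if (length(rows_g) == 0) rep(FALSE, length(labels)) else
      colSums(geno_carrier(vt$geno[rows_g, , drop = FALSE])) > 0
    c1 <- sum(carrier[rel]); c0 <- sum(carrier[!rel])
    p <- stats::fisher.test(matrix(c(c1, n1 - c1, c0, n0 - c0), 2))$p.value
    data.frame(gene = g, carriers_relapse = c1, carriers_free = c0,
               n_variants = length(rows_g), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p, out$gene), ]
}

#' Gene-set aggregation of qualifying variants
#'
#' Mirrors a pathway-level variant summary: per gene set, the number of
#' set genes carrying qualifying variants, the number of such variants,
#' and the number of relapse (`n_cases`) and relapse-free (`n_controls`)
#' samples carrying at least one of them. After [relapse_exclusive()]
#' filtering `n_controls` is 0 for every set by construction. Enrichment
#' is a one-sided Fisher exact test of variant-bearing genes against the
#' background gene universe.
#'
#' @param vt A filtered [variant_table()].
#' @param labels Named label vector.
#' @param gene_sets Named list of gene symbol vectors (see
#'   [read_gene_sets()]).
#' @param background Character vector: the gene universe (defaults to all
#'   genes annotated in `vt`).
#' @return data.frame: `set`, `n_genes`, `n_variants`, `n_cases`,
#'   `n_controls`, `p`.
#' @export
set_aggregate <- function(vt, labels, gene_sets,
                          background = unique(vt$variants$gene)) {
  stopifnot(inherits(vt, "variant_table"))
  if (length(background) == 0) stopf("empty background gene universe")
  labels <- check_labels(labels, colnames(vt$geno))
  rel <- labels == RELAPSE
  hit_genes <- unique(vt$variants$gene)
  carrier <- geno_carrier(vt$geno)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], background)
    set_hits <- intersect(set, hit_genes)
    vrows <- vt$variants$gene %in% set_hits
    samp <- if (any(vrows))
      colSums(carrier[vrows, , drop = FALSE]) > 0 else
        rep(FALSE, length(labels))
    k <- length(set_hits)
    p <- stats::fisher.test(matrix(c(
      k, length(set) - k,
      length(setdiff(hit_genes, set)),
      length(setdiff(background, union(set, hit_genes)))), 2),
      alternative = "greater")$p.value
    data.frame(set = nm, n_genes = k, n_variants = sum(vrows),
               n_cases = sum(samp[rel]), n_controls = sum(samp[!rel]),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p, out$set), ]
}
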