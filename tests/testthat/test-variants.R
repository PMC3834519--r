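samples6 <- sprintf("S%03d", 1:6)
labels6 <- two_group_labels(3, 3)

test_that("deleterious filter keeps protein-altering DEL=1 variants only", {
  vt <- toy_variants(list(
    list(pos = 1, gene = "G1", csq = "synonymous_variant", del = 1L,
         carriers = "S001"),
    list(pos = 2, gene = "G1", csq = "missense_variant", del = 1L,
         carriers = "S001"),
    list(pos = 3, gene = "G2", csq = "missense_variant", del = 0L,
         carriers = "S002"),
    list(pos = 4, gene = "G3", csq = "stop_gained", del = 1L,
         carriers = "S003"),
    list(pos = 5, gene = "G4", csq = "frameshift_variant", del = 1L,
         carriers = "S004"),
    list(pos = 6, gene = "G5", csq = "intron_variant", del = 1L,
         carriers = "S005"),
    list(pos = 7, gene = "G6", csq = "splice_donor_variant", del = 1L,
         carriers = "S006"),
    list(pos = 8, gene = "G7", csq = "inframe_deletion", del = 0L,
         carriers = "S001"),
    list(pos = 9, gene = "G8", csq = "3_prime_UTR_variant", del = 0L,
         carriers = "S002"),
    list(pos = 10, gene = "G9", csq = "stop_lost", del = 0L,
         carriers = "S003")), samples6)
  out <- filter_deleterious(vt)
  expect_equal(out$variants$pos, c(2, 4, 5, 7))  # 4 of 10 qualify
})

test_that("relapse-exclusive filter follows the carrier rules", {
  vt <- toy_variants(list(
    list(pos = 1, gene = "G1", csq = "missense_variant", del = 1L,
         carriers = c("S001", "S002", "S003")),            # 3 relapse, 0 free
    list(pos = 2, gene = "G2", csq = "missense_variant", del = 1L,
         carriers = c("S001", "S002", "S004")),            # 2 relapse, 1 free
    list(pos = 3, gene = "G3", csq = "missense_variant", del = 1L,
         carriers = character(0), missing = samples6)),     # all ./.
    samples6)
  out <- relapse_exclusive(vt, labels6)
  expect_equal(out$variants$pos, 1)
})

test_that("the two row filters commute", {
  b <- generate_cohort(small_synth_spec(seed = 3L))
  vt <- b$variants
  a <- relapse_exclusive(filter_deleterious(vt), b$labels)
  bb <- filter_deleterious(relapse_exclusive(vt, b$labels))
  expect_identical(a$variants, bb$variants)
  expect_identical(a$geno, bb$geno)
})

test_that("carrier counts are invariant to variant order", {
  b <- generate_cohort(small_synth_spec(seed = 4L))
  vt <- b$variants
  perm <- relapsig:::with_seed(1, sample(nrow(vt$variants)))
  vt2 <- variant_table(vt$variants[perm, ], vt$geno[perm, , drop = FALSE])
  g1 <- gene_burden(vt, b$labels)
  g2 <- gene_burden(vt2, b$labels)
  expect_equal(g1, g2)
})

test_that("burden p-values match the hypergeometric/enumeration oracle", {
  # 8/20 relapse carriers vs 0/20: one-sided tail = C(20,8)/C(40,8)
  labels <- two_group_labels(20, 20)
  carriers <- names(labels)[1:8]
  vt <- toy_variants(list(
    list(pos = 1, gene = "G1", csq = "missense_variant", del = 1L,
         af = 0.001, carriers = carriers)), names(labels))
  res <- gene_burden(vt, labels, af_cutoff = 0.05)
  one_sided <- choose(20, 8) / choose(40, 8)
  expect_equal(one_sided, oracle_hyper_tail(8, 20, 20, 8), tolerance = 1e-12)
  expect_equal(res$p, oracle_fisher2(8, 12, 0, 20), tolerance = 1e-10)
  expect_equal(res$carriers_relapse, 8)
  expect_equal(res$carriers_free, 0)
})

test_that("burden degenerate tables: no carriers p = 1; 20/20 vs 0/20 extreme", {
  labels <- two_group_labels(20, 20)
  vt0 <- toy_variants(list(
    list(pos = 1, gene = "G1", csq = "missense_variant", del = 1L,
         af = 0.001, carriers = character(0))), names(labels))
  expect_equal(gene_burden(vt0, labels)$p, 1)
  vt_all <- toy_variants(list(
    list(pos = 1, gene = "G1", csq = "missense_variant", del = 1L,
         af = 0.001, carriers = names(labels)[1:20])), names(labels))
  p_ext <- gene_burden(vt_all, labels)$p
  expect_equal(p_ext, oracle_fisher2(20, 0, 0, 20), tolerance = 1e-10)
  # smallest attainable p over all tables with these margins
  all_p <- vapply(0:20, function(a) oracle_fisher2(a, 20 - a, 20 - a, a), 0)
  expect_equal(p_ext, min(all_p), tolerance = 1e-10)
})

test_that("Fisher p equals exhaustive enumeration on random 2x2 tables", {
  set.seed(31)
  for (i in 1:200) {
    n1 <- sample(2:20, 1); n0 <- sample(2:20, 1)
    a <- sample(0:n1, 1); c_ <- sample(0:n0, 1)
    p_ref <- oracle_fisher2(a, n1 - a, c_, n0 - c_)
    p_imp <- stats::fisher.test(matrix(c(a, n1 - a, c_, n0 - c_), 2))$p.value
    expect_equal(p_imp, p_ref, tolerance = 1e-10)
  }
})

test_that("rare-variant mask uses the cohort AF fallback", {
  labels <- two_group_labels(3, 3)
  vt <- toy_variants(list(
    list(pos = 1, gene = "G1", csq = "missense_variant", del = 1L,
         carriers = samples6[1:4]),                  # cohort AF 4/12 = 0.33
    list(pos = 2, gene = "G2", csq = "missense_variant", del = 1L,
         carriers = "S001")),                        # cohort AF 1/12 = 0.083
    samples6)
  res <- gene_burden(vt, labels, af_cutoff = 0.1)
  expect_equal(res$n_variants[res$gene == "G1"], 0)
  expect_equal(res$n_variants[res$gene == "G2"], 1)
})

test_that("set aggregation mirrors the pathway table shape with zero controls", {
  b <- generate_cohort(small_synth_spec(seed = 6L))
  vt <- relapse_exclusive(filter_deleterious(b$variants), b$labels)
  sets <- list(sig = b$truth$variant_genes[1:4],
               off = setdiff(sprintf("GN%04d", 1:40),
                             unique(b$variants$variants$gene)))
  res <- set_aggregate(vt, b$labels, sets,
                       background = unique(b$variants$variants$gene))
  expect_true(all(res$n_controls == 0))
  off_row <- res[res$set == "off", ]
  expect_equal(off_row$n_genes, 0)
  expect_equal(off_row$p, 1)
  sig_row <- res[res$set == "sig", ]
  expect_gte(sig_row$n_cases, 1)
})

test_that("set enrichment p equals the hypergeometric tail oracle", {
  labels <- two_group_labels(3, 3)
  # background 20 genes, 5 carry variants, set holds 4 genes of which 2 hit
  background <- sprintf("B%02d", 1:20)
  hit <- background[1:5]
  vt <- toy_variants(lapply(seq_along(hit), function(i)
    list(pos = i, gene = hit[i], csq = "missense_variant", del = 1L,
         carriers = "S001")), samples6)
  sets <- list(s = c(background[c(1, 2)], background[c(10, 11)]))
  res <- set_aggregate(vt, labels, sets, background = background)
  expect_equal(res$p, oracle_hyper_tail(2, 5, 15, 4), tolerance = 1e-10)
  expect_equal(res$n_genes, 2)
  expect_error(set_aggregate(vt, labels, sets, background = character(0)),
               "background")
})
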