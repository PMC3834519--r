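test_that("generated bundle has the dimensions and truth the generator settings force", {
  spec <- small_synth_spec(seed = 1L)
  b <- generate_cohort(spec)
  expect_length(b$labels, 40)
  expect_equal(sum(b$labels == "relapse"), 20)
  expect_equal(dim(b$matrices$gene), c(200L, 40L))
  expect_length(b$truth$gene, 6)
  expect_true(all(b$truth$gene %in% rownames(b$matrices$gene$values)))
  # all components share the sample set
  expect_setequal(names(b$segments), names(b$labels))
  expect_setequal(colnames(b$variants$geno), names(b$labels))
})

test_that("seeding contract: same seed identical, different seeds differ", {
  b1 <- generate_cohort(small_synth_spec(seed = 1L))
  b2 <- generate_cohort(small_synth_spec(seed = 1L))
  b3 <- generate_cohort(small_synth_spec(seed = 2L))
  expect_identical(b1$matrices$gene$values, b2$matrices$gene$values)
  expect_identical(b1$variants$geno, b2$variants$geno)
  expect_false(identical(b1$matrices$gene$values, b3$matrices$gene$values))
})

test_that("invalid spec fields are rejected by name", {
  expect_error(small_synth_spec(n_informative = 300L), "n_informative")
  expect_error(synthetic_spec(n_relapse = 0), "n_relapse")
  expect_error(synthetic_spec(variants = list(
    n_genes = 10L, n_signal_genes = 2L, carrier_rate_relapse = 1.5,
    carrier_rate_free = 0.1)), "carrier_rate_relapse")
  cnv <- default_cnv_spec()
  cnv$altered_cytobands$penetrance[1] <- 0
  expect_error(synthetic_spec(cnv = cnv), "penetrance")
})

test_that("null cohort gives uniform Welch p-values and calibrated pass rate", {
  spec <- synthetic_spec(
    types = list(gene = list(n_features = 2000L, n_informative = 0L,
                             effect_size = 0, block_corr = 0, block_size = 4L)),
    seed = 11L)
  b <- generate_cohort(spec)
  wt <- welch_test(b$matrices$gene, b$labels)
  ks <- suppressWarnings(stats::ks.test(wt$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  rate <- mean(wt$p <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  # realized group-mean differences centred at zero
  diffs <- rowMeans(b$matrices$gene$values[, b$labels == "relapse"]) -
    rowMeans(b$matrices$gene$values[, b$labels == "relapse_free"])
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(2000))
})

test_that("planted signal at effect 2 has near-complete per-feature power", {
  hits <- 0L; total <- 0L
  for (s in 1:3) {
    b <- generate_cohort(small_synth_spec(seed = s, n_features = 100L,
                                          n_informative = 12L, effect = 2))
    wt <- welch_test(b$matrices$gene, b$labels)
    p_true <- wt$p[match(b$truth$gene, wt$feature)]
    hits <- hits + sum(p_true <= 0.05); total <- total + length(p_true)
  }
  expect_gte(hits / total, 0.97)
})

test_that("redundant background blocks carry the stated correlation", {
  spec <- synthetic_spec(
    types = list(gene = list(n_features = 400L, n_informative = 0L,
                             effect_size = 0, block_corr = 0.6,
                             block_size = 4L)),
    seed = 3L)
  b <- generate_cohort(spec)
  v <- b$matrices$gene$values
  cm <- cor(t(v))
  off <- cm[upper.tri(cm)]
  # 20 blocks of 4 -> 120 pairs at rho ~0.6 among 79800 pairs
  expect_gt(sum(off > 0.4), 60)
})

test_that("altered cytobands appear in relapse carriers at stated amplitude", {
  b <- generate_cohort(synthetic_spec(seed = 5L))
  cm <- cin_matrix(b$segments, b$cytobands)
  planted <- b$truth$cin_cytoband
  rel <- names(b$labels)[b$labels == "relapse"]
  fre <- names(b$labels)[b$labels == "relapse_free"]
  v <- cm$values[planted, , drop = FALSE]
  # penetrance 0.8, amplitude 0.6: mean relapse CIN near 0.48, free near 0
  expect_gt(mean(v[, rel]), 0.3)
  expect_lt(mean(v[, fre]), 0.05)
})

test_that("signal-gene deleterious variants are relapse-exclusive by construction", {
  b <- generate_cohort(small_synth_spec(seed = 9L))
  vt <- b$variants
  sig <- vt$variants$gene %in% b$truth$variant_genes
  carrier <- relapsig:::geno_carrier(vt$geno[sig, , drop = FALSE])
  fre <- b$labels[colnames(vt$geno)] == "relapse_free"
  expect_equal(sum(carrier[, fre]), 0)
  expect_true(all(vt$variants$del[sig] == 1L))
})

test_that("write_bundle emits the full inventory and round-trips", {
  b <- generate_cohort(small_synth_spec(seed = 2L))
  dir <- withr::local_tempdir()
  paths <- write_bundle(b, dir)
  expect_setequal(basename(unname(paths)),
                  c("gene.tsv", "segments.seg", "variants.vcf",
                    "cytobands.bed", "labels.tsv", "truth.json"))
  rt <- read_bundle(dir)
  expect_setequal(names(rt$labels), names(b$labels))
  expect_equal(rt$matrices$gene$values, b$matrices$gene$values,
               tolerance = 1e-5)  # 6 significant digits on disk
  expect_identical(rt$variants$geno, b$variants$geno)
  expect_setequal(rt$truth$gene, b$truth$gene)
})

test_that("writing twice with the same seed is byte-identical", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(generate_cohort(small_synth_spec(seed = 4L)), d1)
  write_bundle(generate_cohort(small_synth_spec(seed = 4L)), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("unusable output location is a clear error", {
  target <- withr::local_tempfile()
  writeLines("x", target)  # a regular file where a directory is expected
  b <- generate_cohort(small_synth_spec(seed = 1L))
  expect_error(suppressWarnings(write_bundle(b, target)),
               "writable|cannot open|directory")
})
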