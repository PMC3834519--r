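combined_fixture <- function(seed = 1) {
  labels <- two_group_labels()
  mk <- function(p, ty, shift_rows = integer(0)) {
    tm <- toy_matrix(p = p, n1 = 20, n2 = 20, shift_rows = shift_rows,
                     data_type = ty, seed = seed + p)
    tm$fm
  }
  matrices <- list(gene = mk(30, "gene", 1:3), mirna = mk(40, "mirna"),
                   cin_cytoband = mk(20, "cin_cytoband"))
  panels <- list(gene = sprintf("F%03d", 1:12),
                 mirna = sprintf("F%03d", 1:25),
                 cin_cytoband = sprintf("F%03d", 1:16))
  list(panels = panels, matrices = matrices, labels = labels)
}

test_that("combine_panels stacks 12+25+16 features into a 53x40 z-scored matrix", {
  fx <- combined_fixture()
  cb <- combine_panels(fx$panels, fx$matrices)
  expect_equal(dim(cb), c(53L, 40L))
  expect_true(all(startsWith(rownames(cb$values)[1:12], "gene:")))
  expect_equal(unname(rowMeans(cb$values)), rep(0, 53), tolerance = 1e-10)
  expect_equal(unname(apply(cb$values, 1, sd)), rep(1, 53),
               tolerance = 1e-10)
  prov <- attr(cb, "provenance")
  expect_equal(as.vector(table(prov$data_type)[c("gene", "mirna",
                                                 "cin_cytoband")]),
               c(12L, 25L, 16L))
})

test_that("combine_panels rejects duplicates and sample mismatches", {
  fx <- combined_fixture()
  fx$panels$gene <- c("F001", "F001")
  expect_error(combine_panels(fx$panels, fx$matrices), "duplicate")
  fx <- combined_fixture()
  fx$matrices$mirna$values <- fx$matrices$mirna$values[, 1:39]
  expect_error(combine_panels(fx$panels, fx$matrices), "S040")
})

test_that("artificial contrasts are exact permutations of their source columns", {
  set.seed(2)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  ct <- relapsig:::make_contrasts(X)
  expect_equal(colnames(ct), paste0("contrast:", colnames(X)))
  for (j in 1:10) {
    expect_equal(sort(ct[, j]), sort(X[, j]))
    expect_false(identical(ct[, j], X[, j]) && var(X[, j]) > 0)
  }
})

test_that("a perfectly separating feature attains rank 1 with tiny p", {
  for (s in 1:5) {
    labels <- two_group_labels()
    v <- relapsig:::with_seed(s, {
      m <- matrix(rnorm(100 * 40), 100, 40)
      m[1, ] <- c(rnorm(20, 4), rnorm(20, -4))
      m
    })
    dimnames(v) <- list(c("sig", sprintf("n%03d", 1:99)), names(labels))
    cb <- feature_matrix(v, "combined")
    rk <- ace_rank(cb, labels, forests = 10L, trees = 50L, seed = s)
    expect_equal(rk$feature[1], "sig")
    expect_lte(rk$p[rk$feature == "sig"], 1e-4)
  }
})

test_that("ace_rank is deterministic under a fixed seed", {
  labels <- two_group_labels(8, 8)
  v <- matrix(rnorm(20 * 16), 20, 16,
              dimnames = list(sprintf("f%02d", 1:20), names(labels)))
  cb <- feature_matrix(v, "combined")
  r1 <- ace_rank(cb, labels, forests = 3L, trees = 20L, seed = 4)
  r2 <- ace_rank(cb, labels, forests = 3L, trees = 20L, seed = 4)
  expect_identical(r1, r2)
  expect_setequal(r1$rank, seq_len(20))
})

test_that("constant features are flagged and scored zero", {
  labels <- two_group_labels(8, 8)
  v <- rbind(matrix(rnorm(5 * 16), 5, 16), 3)
  dimnames(v) <- list(c(sprintf("f%d", 1:5), "const"), names(labels))
  cb <- feature_matrix(v, "combined")
  expect_warning(rk <- ace_rank(cb, labels, forests = 2L, trees = 20L,
                                seed = 1), "constant")
  expect_equal(rk$score[rk$feature == "const"], 0)
})

test_that("select_top builds nested tiers with a composition that adds up", {
  ranked <- data.frame(feature = c("a", "b", "c"),
                       data_type = c("gene", "mirna", "gene"),
                       score = c(3, 2, 1), p = c(1e-40, 1e-3, 0.5),
                       rank = 1:3)
  out <- select_top(ranked, p_select = 0.01, p_top = 1e-30)
  expect_equal(out$selected$feature, c("a", "b"))
  expect_equal(out$top$feature, "a")
  expect_equal(sum(out$composition$n), nrow(out$selected))
  all1 <- transform(ranked, p = 1)
  out1 <- select_top(all1)
  expect_equal(nrow(out1$selected), 0L)
  expect_equal(nrow(out1$top), 0L)
})

test_that("tau-b matches hand counts, duplicates, and the brute-force oracle", {
  expect_equal(kendall_taub(c(1, 2, 3, 4), c(1, 2, 4, 3))$tau, 2 / 3,
               tolerance = 1e-12)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(kendall_taub(x, x)$tau, 1)
  set.seed(41)
  for (i in 1:100) {
    n <- sample(4:15, 1)
    a <- sample(1:6, n, replace = TRUE)
    b <- sample(1:6, n, replace = TRUE)
    expect_equal(kendall_taub(a, b)$tau, oracle_taub(a, b),
                 tolerance = 1e-12)
    expect_equal(kendall_taub(a, b)$tau, cor(a, b, method = "kendall"),
                 tolerance = 1e-12)
  }
})

test_that("tau-b p-values: exact enumeration for small n, conservative null rate", {
  # n = 4, perfect concordance without ties: p = 2/4! (both extremes)
  res <- kendall_taub(1:4, 1:4)
  expect_equal(res$p, 2 / 24, tolerance = 1e-12)
  set.seed(42)
  hits <- 0L
  for (i in 1:200) {
    kt <- kendall_taub(rnorm(40), rnorm(40))
    hits <- hits + (kt$p <= 0.01)
  }
  expect_lte(hits / 200, 0.03)
})

test_that("kendall_network keeps only significant edges, no self pairs", {
  labels <- two_group_labels(10, 10)
  v <- relapsig:::with_seed(8, {
    base <- rnorm(20)
    rbind(a = base, b = base + rnorm(20, 0, 0.1), c = rnorm(20))
  })
  colnames(v) <- names(labels)
  net <- kendall_network(feature_matrix(v, "combined"), alpha_edge = 0.01)
  expect_true(all(net$a != net$b))
  expect_true(any(net$a == "a" & net$b == "b"))
  expect_true(all(net$p <= 0.01))
})

test_that("map_coordinates locates genes and cytobands, leaves metabolites unmapped", {
  ranked <- data.frame(
    feature = c("gene:G1", "serum_pos:M1", "cin_cytoband:1q10"),
    data_type = c("gene", "serum_pos", "cin_cytoband"),
    score = 1, p = 0.5, rank = 1:3, stringsAsFactors = FALSE)
  ann <- data.frame(chrom = "chr7", start = 100, end = 500, name = "G1")
  bands <- cytoband_map("chr1", 0, 1000, "1q10")
  out <- map_coordinates(ranked, ann, bands)
  expect_equal(out$chrom, c("chr7", "unmapped", "chr1"))
  expect_equal(out$start, c(100, NA, 0))
  expect_error(map_coordinates(ranked, rbind(ann, ann), bands), "duplicate")
})
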