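# toy gene x cell count matrix with controlled QC properties
toy_counts <- function() {
  m <- matrix(0L, 6, 5,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:5)))
  m["g1", ] <- c(10L, 10L, 10L, 10L, 10L)   # in 5 cells
  m["g2", ] <- c(5L, 5L, 5L, 5L, 0L)        # in 4 cells
  m["g3", ] <- c(3L, 3L, 3L, 0L, 0L)        # in 3 cells
  m["g4", ] <- c(2L, 2L, 0L, 0L, 0L)        # in 2 cells -> removed at 3
  m["g5", ] <- c(1L, 0L, 0L, 0L, 0L)        # in 1 cell  -> removed
  m["g6", ] <- c(4L, 4L, 4L, 4L, 4L)        # mito gene, in 5 cells
  m
}

test_that("QC removes under-detected genes first, then cells, with strict thresholds", {
  m <- toy_counts()
  out <- qc_filter(m, mito_genes = "g6", min_cells_per_gene = 3,
                   min_genes = 2, min_umi = 5, max_umi = 100,
                   max_mito_frac = 0.5)
  expect_false(any(c("g4", "g5") %in% rownames(out$counts)))
  expect_equal(out$report$genes_removed_low_detection, 2L)

  # strict mito rule: exactly at the threshold is retained, above is removed
  m2 <- matrix(c(94L, 95L,
                 6L,  5L), 2, 2, byrow = TRUE,
               dimnames = list(c("g1", "MT-1"), c("cA", "cB")))
  # cA: 6/100 = 0.06 > 0.05 -> removed; cB: 5/100 = 0.05 -> retained
  out2 <- qc_filter(m2, mito_genes = "MT-1", min_cells_per_gene = 0,
                    min_genes = 0, min_umi = 0, max_umi = Inf,
                    max_mito_frac = 0.05)
  expect_equal(colnames(out2$counts), "cB")
  expect_equal(out2$report$cells_removed_mito, 1L)

  # no-op thresholds give the identity
  out3 <- qc_filter(m, min_cells_per_gene = 0, min_genes = 0,
                    min_umi = 0, max_umi = Inf, max_mito_frac = 1)
  expect_equal(dim(out3$counts), dim(m))

  # UMI bounds are strict on both sides
  m4 <- matrix(c(500L, 499L, 30000L, 30001L), 1, 4,
               dimnames = list("g1", paste0("c", 1:4)))
  out4 <- qc_filter(m4, min_cells_per_gene = 0, min_genes = 0)
  expect_equal(colnames(out4$counts), c("c1", "c3"))

  expect_error(qc_filter(m, min_umi = 1e9), "removed everything")
})

test_that("QC filtering is idempotent on typical matrices", {
  set.seed(8)
  m <- matrix(rpois(200 * 60, 5), 200, 60,
              dimnames = list(paste0("g", 1:200), paste0("c", 1:60)))
  once <- qc_filter(m, min_cells_per_gene = 3, min_genes = 50,
                    min_umi = 100, max_umi = 5000, max_mito_frac = 0.05)
  twice <- qc_filter(once$counts, min_cells_per_gene = 3, min_genes = 50,
                     min_umi = 100, max_umi = 5000, max_mito_frac = 0.05)
  expect_equal(dim(twice$counts), dim(once$counts))
  expect_equal(as.matrix(twice$counts), as.matrix(once$counts))
})

test_that("doublet clusters are removed only above the 50% rule", {
  cl <- rep(c("k1", "k2", "k3"), each = 10)
  dbl <- c(rep(TRUE, 6), rep(FALSE, 4),      # k1: 0.6 -> removed
           rep(TRUE, 5), rep(FALSE, 5),      # k2: 0.5 -> retained
           rep(FALSE, 10))                   # k3: none
  out <- doublet_cluster_filter(cl, dbl)
  expect_equal(out$removed_clusters, "k1")
  expect_equal(sum(out$keep), 20L)
  # retained clusters keep their flagged doublets
  expect_true(all(out$keep[cl == "k2"]))

  none <- doublet_cluster_filter(cl, rep(FALSE, 30))
  expect_true(all(none$keep))
  expect_length(none$removed_clusters, 0L)
})

test_that("proportion ANOVA reproduces the sums-of-squares F and Holm family adjustment", {
  # one cell type with group proportions scaled from (1,2,3),(2,3,4),(3,4,5)
  counts <- matrix(c(1L, 2L, 3L, 2L, 3L, 4L, 3L, 4L, 5L), 9, 1)
  counts <- cbind(counts, 10L - counts)
  colnames(counts) <- c("typeA", "typeB")
  comp <- composition_matrix(counts, rep(c("g1", "g2", "g3"), each = 3))
  res <- proportion_anova_holm(comp)
  expect_equal(res$table$F, c(3, 3), tolerance = 1e-9)  # SSb=6/df2, SSw=6/df6
  expect_equal(res$table$df1, c(2L, 2L))
  expect_equal(res$table$df2, c(6L, 6L))

  # identical proportions everywhere: F = 0
  eq <- composition_matrix(matrix(5L, 4, 3), rep(c("a", "b"), each = 2))
  expect_equal(proportion_anova_holm(eq)$table$F, c(0, 0, 0))

  expect_error(proportion_anova_holm(
    composition_matrix(matrix(5L, 3, 2), c("a", "a", "b"))), "2 samples")
})

test_that("Holm adjustment equals the brute-force step-down on random p-vectors", {
  # (0.01, 0.04, 0.03) -> (0.03, 0.06, 0.06)
  expect_equal(holm_brute(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "holm"), c(0.03, 0.06, 0.06))
  set.seed(10)
  for (i in 1:1000) {
    p <- runif(sample(1:8, 1))
    expect_equal(p.adjust(p, "holm"), holm_brute(p), tolerance = 1e-12)
  }
})

test_that("interleaved samples give exactly zero KL everywhere", {
  ring <- interleaved_ring(120)
  res <- knn_kl_variability(ring$embedding, ring$labels, k = 28,
                            n_permutations = 5, seed = 1)
  expect_equal(max(abs(res$kl)), 0, tolerance = 1e-12)
})

test_that("a pure neighbourhood of one of two equal samples gives KL = ln 2", {
  emb <- rbind(cbind(rnorm(31, 0, 0.1), rnorm(31, 0, 0.1)),
               cbind(rnorm(31, 100, 0.1), rnorm(31, 100, 0.1)))
  labs <- rep(c("A", "B"), each = 31)
  res <- knn_kl_variability(emb, labs, k = 30, n_permutations = 5, seed = 1)
  expect_equal(unname(res$kl), rep(log(2), 62), tolerance = 1e-12)
  expect_equal(unname(res$class_mean["A"]), log(2), tolerance = 1e-12)
})

test_that("KL is non-negative, zero only when the neighbourhood matches the global mix", {
  set.seed(5)
  for (i in 1:20) {
    emb <- matrix(rnorm(80 * 3), 80, 3)
    labs <- sample(c("A", "B", "C"), 80, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2))
    if (length(unique(labs)) < 2) next
    res <- knn_kl_variability(emb, labs, k = 10, n_permutations = 2, seed = i)
    expect_true(all(res$kl >= -1e-12))
    # direct formula check on one cell
    q <- res$global_freq
    nb <- gliaquant:::.knn_index(emb, 10)[1, ]
    p <- as.numeric(table(factor(labs[nb], levels = names(q)))) / 10
    expect_equal(res$kl[1], kl_brute(p, q), tolerance = 1e-12)
  }
})

test_that("planted sample separation is detected against shuffled controls", {
  hits <- 0
  n_seeds <- 100
  for (seed in seq_len(n_seeds)) {
    set.seed(seed)
    emb <- rbind(matrix(rnorm(100 * 2, 0), 100, 2),
                 matrix(rnorm(100 * 2, 4), 100, 2))
    labs <- rep(c("s1", "s2"), each = 100)
    res <- knn_kl_variability(emb, labs, k = 30, n_permutations = 50,
                              seed = seed)
    if (res$observed_mean > quantile(res$control_means, 0.95)) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("DEG overlap counts are consistent and strict at the boundaries", {
  study <- data.frame(gene = c("a", "b", "x", "y"),
                      log2fc = c(1, 1, 0.25, 1),
                      fdr = c(0.001, 0.001, 0.001, 0.01))
  # x fails log2FC (exactly 0.25), y fails FDR (exactly 0.01)
  ov <- deg_filter_overlap(study, c("b", "c"))
  expect_equal(ov$n_shared, 1L)
  expect_equal(ov$n_ref_only, 1L)
  expect_equal(ov$n_study_only, 1L)
  expect_equal(ov$shared, "b")

  # counts tie out against the set sizes
  expect_equal(ov$n_shared + ov$n_ref_only, 2L)
  expect_equal(ov$n_shared + ov$n_study_only, 2L)

  dupped <- rbind(study, study[1, ])
  expect_error(deg_filter_overlap(dupped, c("b")), "duplicate")
  expect_error(deg_filter_overlap(study, c("b", "b")), "duplicate")
})

test_that("counts matrices round-trip through MTX with labels", {
  set.seed(11)
  m <- Matrix::rsparsematrix(30, 12, density = 0.2,
                             rand.x = function(n) rpois(n, 4) + 1)
  m <- methods::as(m, "CsparseMatrix")
  rownames(m) <- paste0("g", 1:30)
  colnames(m) <- paste0("c", 1:12)
  meta <- data.frame(barcode = colnames(m),
                     sample_id = rep(c("s1", "s2"), 6))
  d <- file.path(tempdir(), "mtx_roundtrip")
  write_counts_mtx(m, d, cell_meta = meta)
  back <- read_counts_mtx(d)
  expect_equal(as.matrix(back$counts), as.matrix(m))
  expect_equal(back$cell_meta$sample_id, meta$sample_id)
})
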