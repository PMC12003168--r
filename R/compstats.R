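#' Per-sample cell-type composition counts
#'
#' @param counts Integer matrix, samples x cell types (named dimensions).
#' @param genotype Genotype/group label per sample (length = nrow(counts)).
#' @return Object of class `composition_matrix`.
#' @export
composition_matrix <- function(counts, genotype) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (length(genotype) != nrow(counts))
    stop("one genotype label per sample required")
  if (any(rowSums(counts) <= 0)) stop("every sample needs total count > 0")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("s%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("type%d", seq_len(ncol(counts)))
  structure(list(counts = counts,
                 genotype = setNames(as.character(genotype),
                                     rownames(counts))),
            class = "composition_matrix")
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat(sprintf("<composition_matrix> %d samples x %d cell types; groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$genotype), collapse = ", ")))
  invisible(x)
}

#' Quality-control filtering of a gene x cell counts matrix
#'
#' Default thresholds: genes detected in fewer than 3 nuclei are removed
#' first; then, on the reduced matrix, nuclei expressing fewer than 200
#' genes, fewer than 500 or more than 30,000 UMIs, or with more than 5%
#' mitochondrial reads are removed. All inequalities are strict, matching
#' the stated "fewer than"/"more than" wording (a cell at exactly 5%
#' mitochondrial reads is retained).
#'
#' @param counts Gene x cell matrix (base or `Matrix` sparse), genes in
#'   rows.
#' @param mito_genes Character vector of mitochondrial gene names, or
#'   logical per-gene flag vector.
#' @param min_cells_per_gene,min_genes,min_umi,max_umi,max_mito_frac
#'   Thresholds; defaults are the values above (3, 200, 500, 30000,
#'   0.05).
#' @return List with `counts` (filtered matrix), and `report` (named list
#'   of removal counts per criterion plus retained dimensions).
#' @export
qc_filter <- function(counts, mito_genes = character(0),
                      min_cells_per_gene = 3, min_genes = 200,
                      min_umi = 500, max_umi = 30000,
                      max_mito_frac = 0.05) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%d", seq_len(ncol(counts)))
  m <- if (methods::is(counts, "Matrix"))
    methods::as(counts, "CsparseMatrix") else
      methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (any(m@x < 0) || any(m@x != round(m@x)))
    stop("counts must be non-negative integers")
  mito <- if (is.logical(mito_genes)) {
    if (length(mito_genes) != nrow(m)) stop("logical mito flag length mismatch")
    mito_genes
  } else rownames(m) %in% mito_genes

  detected_in <- Matrix::rowSums(m > 0)
  gene_keep <- detected_in >= min_cells_per_gene
  m2 <- m[gene_keep, , drop = FALSE]
  mito2 <- mito[gene_keep]

  umi <- Matrix::colSums(m2)
  genes_per_cell <- Matrix::colSums(m2 > 0)
  mito_frac <- if (any(mito2)) {
    mf <- Matrix::colSums(m2[mito2, , drop = FALSE]) / pmax(umi, 1)
    mf[umi == 0] <- 0
    mf
  } else rep(0, ncol(m2))

  fail_genes <- genes_per_cell < min_genes
  fail_low <- umi < min_umi
  fail_high <- umi > max_umi
  fail_mito <- mito_frac > max_mito_frac
  cell_keep <- !(fail_genes | fail_low | fail_high | fail_mito)

  out <- m2[, cell_keep, drop = FALSE]
  if (nrow(out) == 0L || ncol(out) == 0L)
    stop("QC filtering removed everything (",
         sum(!gene_keep), " genes, ", sum(!cell_keep), " cells)")
  list(counts = out,
       report = list(
         genes_removed_low_detection = sum(!gene_keep),
         cells_removed_few_genes = sum(fail_genes),
         cells_removed_low_umi = sum(fail_low),
         cells_removed_high_umi = sum(fail_high),
         cells_removed_mito = sum(fail_mito),
         cells_removed_total = sum(!cell_keep),
         genes_retained = nrow(out),
         cells_retained = ncol(out)))
}

#' Remove doublet-dominated clusters
#'
#' Clusters containing strictly more than `threshold` (default 50%)
#' flagged doublets are removed entirely; all other clusters are retained
#' including their individually flagged doublet cells — the cluster-level
#' rule used after external doublet scoring.
#'
#' @param cluster_id Cluster assignment per cell.
#' @param is_doublet Logical doublet flag per cell.
#' @param threshold Doublet-fraction cutoff (strict; default 0.5).
#' @return List with `keep` (logical per cell), `removed_clusters`
#'   (cluster ids) and `cluster_doublet_frac` (named vector).
#' @export
doublet_cluster_filter <- function(cluster_id, is_doublet, threshold = 0.5) {
  if (length(cluster_id) != length(is_doublet))
    stop("per-cell vectors must have equal length")
  if (anyNA(cluster_id) || anyNA(is_doublet))
    stop("every cell needs a cluster and a doublet flag")
  cl <- as.character(cluster_id)
  frac <- tapply(as.logical(is_doublet), cl, mean)
  removed <- names(frac)[frac > threshold]
  list(keep = !(cl %in% removed),
       removed_clusters = removed,
       cluster_doublet_frac = frac)
}

#' Cell-type proportion ANOVA with Holm-Bonferroni adjustment
#'
#' Per sample, cell-type counts are converted to proportions; per cell
#' type, a one-way ANOVA tests whether proportions differ by genotype, and
#' the family of raw p-values (one per cell type in the call) is adjusted
#' by Holm's step-down procedure. Bartlett (variance homogeneity) and
#' Shapiro-Wilk (normality of residuals) diagnostics are reported per cell
#' type but never gate the test.
#'
#' @param comp A [composition_matrix] with at least 2 genotypes and 2
#'   samples per genotype.
#' @return Object of class `proportion_anova`: data frame `table` with
#'   columns `cell_type`, `F`, `df1`, `df2`, `p`, `p_holm`, `bartlett_p`,
#'   `shapiro_p`, plus the `proportions` matrix.
#' @export
proportion_anova_holm <- function(comp) {
  stopifnot(inherits(comp, "composition_matrix"))
  geno <- factor(comp$genotype)
  if (nlevels(geno) < 2L) stop("need at least 2 genotypes")
  if (any(table(geno) < 2L))
    stop("every genotype needs at least 2 samples")
  prop <- comp$counts / rowSums(comp$counts)
  res <- do.call(rbind, lapply(colnames(prop), function(ct) {
    y <- prop[, ct]
    fit <- aov(y ~ geno)
    at <- anova(fit)
    Fv <- at$`F value`[1]; pv <- at$`Pr(>F)`[1]
    if (!is.finite(Fv) && isTRUE(all.equal(at$`Sum Sq`[1], 0))) {
      # all samples identical: no between-group variation at all
      Fv <- 0; pv <- 1
    }
    bart <- tryCatch(bartlett.test(y, geno)$p.value, error = function(e) NA)
    shap <- tryCatch(shapiro.test(residuals(fit))$p.value,
                     error = function(e) NA)
    data.frame(cell_type = ct, F = Fv, df1 = at$Df[1],
               df2 = at$Df[2], p = pv,
               bartlett_p = bart, shapiro_p = shap)
  }))
  res$p_holm <- p.adjust(res$p, method = "holm")
  res <- res[c("cell_type", "F", "df1", "df2", "p", "p_holm",
               "bartlett_p", "shapiro_p")]
  rownames(res) <- NULL
  structure(list(table = res, proportions = prop,
                 genotype = comp$genotype),
            class = "proportion_anova")
}

#' @export
print.proportion_anova <- function(x, ...) {
  cat("One-way ANOVA on cell-type proportions (Holm-adjusted):\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' k-nearest-neighbour Kullback-Leibler neighbourhood variability
#'
#' Measures how cells are distributed among samples: for every cell, the
#' label distribution over its k Euclidean nearest neighbours (self
#' excluded) is compared to the global label distribution by KL divergence
#' (natural log; `0 * log(0) = 0`). Shuffled controls permute the labels
#' uniformly on the same neighbour graph.
#'
#' @param embedding Numeric matrix, cells x dimensions.
#' @param labels Sample (replicate x genotype) or genotype label per cell.
#' @param k Number of neighbours (default 30; must be < number of cells).
#' @param n_permutations Number of label shuffles (default 100).
#' @param seed Seed for the permutations.
#' @return Object of class `kl_result`: per-cell `kl` (nats), `k`,
#'   `labels`, `global_freq`, per-class mean KL (`class_mean`), overall
#'   `observed_mean`, matrix `control_kl` (n_permutations x cells),
#'   `control_means` and the empirical percentile of the observed mean in
#'   the control distribution.
#' @export
knn_kl_variability <- function(embedding, labels, k = 30L,
                               n_permutations = 100L, seed = 1L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per cell required")
  present <- unique(labels)
  if (length(present) < 2L) stop("need at least 2 label classes")
  if (k >= n) stop("k must be smaller than the number of cells")

  nbr <- .knn_index(embedding, k)
  q <- as.numeric(table(factor(labels, levels = present))) / n
  names(q) <- present

  kl_given <- function(lab) {
    # neighbour label counts per cell, classes in columns
    p <- vapply(present, function(cl)
      rowSums(matrix(lab[nbr], n, k) == cl), numeric(n)) / k
    rowSums(ifelse(p > 0, p * log(p / rep(q, each = n)), 0))
  }
  kl <- kl_given(labels)

  set.seed(seed)
  ctrl <- matrix(NA_real_, n_permutations, n)
  for (b in seq_len(n_permutations))
    ctrl[b, ] <- kl_given(sample(labels))
  ctrl_means <- rowMeans(ctrl)
  obs_mean <- mean(kl)
  structure(list(
    kl = kl, k = as.integer(k), labels = labels, global_freq = q,
    class_mean = tapply(kl, labels, mean),
    observed_mean = obs_mean,
    control_kl = ctrl, control_means = ctrl_means,
    n_permutations = as.integer(n_permutations), seed = as.integer(seed),
    percentile = mean(ctrl_means < obs_mean) +
      0.5 * mean(ctrl_means == obs_mean)),
    class = "kl_result")
}

# brute-force exact kNN (Euclidean), chunked to bound memory;
# ties broken by cell index (deterministic)
.knn_index <- function(x, k, chunk = 512L) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  nbr <- matrix(NA_integer_, n, k)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(sq[s:e], sq, `+`) - 2 * x[s:e, , drop = FALSE] %*% t(x)
    for (i in seq_len(e - s + 1L)) {
      di <- d2[i, ]
      di[s + i - 1L] <- Inf          # exclude self
      nbr[s + i - 1L, ] <- order(di)[seq_len(k)]
    }
  }
  nbr
}

#' @export
print.kl_result <- function(x, ...) {
  cat(sprintf("<kl_result> %d cells, k = %d, %d classes\n",
              length(x$kl), x$k, length(x$global_freq)))
  cat(sprintf("  observed mean KL = %.4f nats; shuffled-control mean = %.4f\n",
              x$observed_mean, mean(x$control_means)))
  cat(sprintf("  observed mean at percentile %.3f of %d control shuffles\n",
              x$percentile, x$n_permutations))
  invisible(x)
}

#' Significance filtering and overlap of DEG tables
#'
#' Applies the strict significance filter (log2 fold change
#' > 0.25 and FDR < 0.01) to the study table — and to the reference table
#' when a table rather than a gene set is given — then intersects the
#' significant sets by exact symbol match after whitespace trimming.
#'
#' @param study Data frame with columns `gene`, `log2fc`, `fdr`.
#' @param reference Either a character vector (an already-derived
#'   signature gene set) or a DEG data frame filtered the same way.
#' @param logfc_min,fdr_max Strict thresholds (defaults 0.25, 0.01).
#' @return Object of class `deg_overlap`: counts `n_shared`, `n_ref_only`,
#'   `n_study_only` and sorted gene lists `shared`, `ref_only`,
#'   `study_only`.
#' @export
deg_filter_overlap <- function(study, reference, logfc_min = 0.25,
                               fdr_max = 0.01) {
  study_set <- .deg_significant(study, logfc_min, fdr_max, "study")
  ref_set <- if (is.character(reference)) {
    r <- trimws(reference)
    dup <- unique(r[duplicated(r)])
    if (length(dup))
      stop("duplicate gene symbols in reference: ",
           paste(head(dup), collapse = ", "))
    r
  } else .deg_significant(reference, logfc_min, fdr_max, "reference")
  shared <- sort(intersect(ref_set, study_set))
  structure(list(
    n_shared = length(shared),
    n_ref_only = length(setdiff(ref_set, study_set)),
    n_study_only = length(setdiff(study_set, ref_set)),
    shared = shared,
    ref_only = sort(setdiff(ref_set, study_set)),
    study_only = sort(setdiff(study_set, ref_set)),
    logfc_min = logfc_min, fdr_max = fdr_max),
    class = "deg_overlap")
}

.deg_significant <- function(tab, logfc_min, fdr_max, what) {
  need <- c("gene", "log2fc", "fdr")
  if (!all(need %in% names(tab)))
    stop(what, " table must have columns ", paste(need, collapse = ", "))
  if (any(tab$fdr < 0 | tab$fdr > 1, na.rm = TRUE))
    stop(what, " FDR values must lie in [0, 1]")
  g <- trimws(as.character(tab$gene))
  dup <- unique(g[duplicated(g)])
  if (length(dup))
    stop("duplicate gene symbols in ", what, ": ",
         paste(head(dup), collapse = ", "))
  g[tab$log2fc > logfc_min & tab$fdr < fdr_max]
}

#' @export
print.deg_overlap <- function(x, ...) {
  cat(sprintf(
    "<deg_overlap> log2FC > %g & FDR < %g: %d shared, %d reference-only, %d study-only\n",
    x$logfc_min, x$fdr_max, x$n_shared, x$n_ref_only, x$n_study_only))
  invisible(x)
}

# ---- Matrix Market I/O ----------------------------------------------------

#' Write a counts matrix as MTX with feature/barcode TSVs
#' @param counts Gene x cell matrix.
#' @param dir Output directory.
#' @param cell_meta Optional per-cell data frame written as `labels.tsv`.
#' @return Invisibly, `dir`.
#' @export
write_counts_mtx <- function(counts, dir, cell_meta = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- if (methods::is(counts, "Matrix"))
    methods::as(counts, "CsparseMatrix") else
      methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  if (!is.null(cell_meta))
    write.table(cell_meta, file.path(dir, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a counts matrix written by [write_counts_mtx()]
#' @param dir Directory with `matrix.mtx`, `features.tsv`, `barcodes.tsv`.
#' @return List with `counts` (sparse matrix) and `cell_meta` (data frame
#'   or NULL).
#' @export
read_counts_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  lab <- file.path(dir, "labels.tsv")
  meta <- if (file.exists(lab))
    read.delim(lab, stringsAsFactors = FALSE) else NULL
  list(counts = m, cell_meta = meta)
}
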