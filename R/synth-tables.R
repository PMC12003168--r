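#' Generate a synthetic EM axon-measurement table
#'
#' Emulates per-axon area annotations from EM images: for each group
#' (genotype) and animal, axon (inner) diameters are sampled lognormal and
#' g-ratios truncated-normal around the group mean; the emitted inner
#' (axon) and outer (fiber) areas are exactly consistent with the sampled
#' diameters, so `2 * sqrt(A / pi)` recovers them.
#'
#' @param params A [sim_params]; uses `gratio_mean_by_group`, `gratio_sd`,
#'   `n_animals`, `n_axons` (axons per image; one image per animal here)
#'   and the axon-diameter lognormal parameters.
#' @return Data frame with columns `image_id`, `animal_id`, `group`,
#'   `axon_area_um2`, `fiber_area_um2` and the generating truth `g_true`.
#' @export
generate_axon_table <- function(params = sim_params()) {
  p <- validate_sim_params(params)
  set.seed(.sub_seed(p, "axons"))
  groups <- names(p$gratio_mean_by_group)
  out <- list()
  for (g in groups) {
    mu <- p$gratio_mean_by_group[[g]]
    for (a in seq_len(p$n_animals)) {
      n <- p$n_axons
      d_in <- rlnorm(n, p$axon_diameter_meanlog, p$axon_diameter_sdlog)
      gr <- .rtruncnorm01(n, mu, p$gratio_sd)
      d_out <- d_in / gr
      out[[length(out) + 1L]] <- data.frame(
        image_id = sprintf("%s_a%d_img1", g, a),
        animal_id = sprintf("%s_a%d", g, a),
        group = g,
        axon_area_um2 = pi * (d_in / 2)^2,
        fiber_area_um2 = pi * (d_out / 2)^2,
        g_true = gr
      )
    }
  }
  do.call(rbind, out)
}

# truncated normal on (lo, hi) by rejection; degenerate sd -> point mass
.rtruncnorm01 <- function(n, mean, sd, lo = 0.02, hi = 0.995) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x > lo & x < hi])
  }
  out[seq_len(n)]
}

#' Generate zero-inflated bead-uptake counts
#'
#' Per-cell microbead counts for the phagocytosis assay: each counted
#' microglial cell draws a structural zero with probability
#' `zero_inflation`, otherwise a Poisson count at its group's rate.
#'
#' @param params A [sim_params]; uses `bead_rate_by_group`,
#'   `zero_inflation`, `n_animals`, `n_fields`, `n_cells_per_field`.
#' @return Data frame with columns `animal_id`, `group`, `field_id`,
#'   `cell_id`, `n_beads`.
#' @export
generate_bead_counts <- function(params = sim_params()) {
  p <- validate_sim_params(params)
  set.seed(.sub_seed(p, "beads"))
  groups <- names(p$bead_rate_by_group)
  out <- list()
  for (g in groups) {
    rate <- p$bead_rate_by_group[[g]]
    for (a in seq_len(p$n_animals)) {
      for (f in seq_len(p$n_fields)) {
        n <- p$n_cells_per_field
        zero <- rbinom(n, 1L, p$zero_inflation) == 1L
        cnt <- rpois(n, rate)
        cnt[zero] <- 0L
        out[[length(out) + 1L]] <- data.frame(
          animal_id = sprintf("%s_a%d", g, a), group = g,
          field_id = sprintf("%s_a%d_f%d", g, a, f),
          cell_id = seq_len(n), n_beads = cnt
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Generate multinomial cell-type composition counts
#'
#' Per sample, cell-type counts are drawn multinomially with the group's
#' probability vector at size `n_cells_per_sample`, emulating per-sample
#' cell-type tallies from clustered single-nucleus data.
#'
#' @param params A [sim_params]; uses `composition_by_group`, `n_animals`
#'   (samples per group), `n_cells_per_sample`.
#' @return A `composition_matrix`: list with `counts` (samples x cell types)
#'   and `genotype` (named factor mapping samples to groups). See
#'   [composition_matrix()].
#' @export
generate_composition <- function(params = sim_params()) {
  p <- validate_sim_params(params)
  set.seed(.sub_seed(p, "composition"))
  groups <- names(p$composition_by_group)
  types <- names(p$composition_by_group[[1]])
  counts <- NULL
  genotype <- character(0)
  for (g in groups) {
    prob <- p$composition_by_group[[g]]
    draw <- t(rmultinom(p$n_animals, p$n_cells_per_sample, prob))
    rownames(draw) <- sprintf("%s_s%d", g, seq_len(p$n_animals))
    counts <- rbind(counts, draw)
    genotype <- c(genotype, rep(g, p$n_animals))
  }
  colnames(counts) <- types
  composition_matrix(counts, genotype)
}

#' Generate paired DEG tables with controlled significant-set overlap
#'
#' Builds a reference table and a study table whose significant sets under
#' the strict filter `log2FC > 0.25 & FDR < 0.01` have exactly the
#' requested sizes and intersection. Both tables also carry non-significant
#' decoy genes that fail the filter on fold change, on FDR, or sit exactly
#' at the `log2FC = 0.25` boundary (excluded by strictness).
#'
#' @param params A [sim_params]; uses `deg_set_sizes` and `deg_n_decoys`.
#' @return List with data frames `reference` and `study`, each with columns
#'   `gene`, `log2fc`, `fdr`.
#' @export
generate_deg_tables <- function(params = sim_params()) {
  p <- validate_sim_params(params)
  set.seed(.sub_seed(p, "degs"))
  s <- p$deg_set_sizes
  n_ref <- s[["reference"]]; n_stu <- s[["study"]]; n_sh <- s[["shared"]]
  gene_id <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))
  shared <- gene_id("SHRD", n_sh)
  ref_only <- gene_id("REFO", n_ref - n_sh)
  stu_only <- gene_id("STUO", n_stu - n_sh)
  decoys <- gene_id("DCOY", p$deg_n_decoys)

  sig_rows <- function(genes) data.frame(
    gene = genes,
    log2fc = runif(length(genes), 0.3, 3),
    fdr = 10^runif(length(genes), -12, log10(0.009))
  )
  decoy_rows <- function(genes) {
    n <- length(genes)
    kind <- sample(rep_len(c("lowfc", "highfdr", "boundary"), n))
    data.frame(
      gene = genes,
      log2fc = ifelse(kind == "lowfc", runif(n, -1, 0.2),
                      ifelse(kind == "boundary", 0.25, runif(n, 0.3, 3))),
      fdr = ifelse(kind == "highfdr", runif(n, 0.05, 1),
                   10^runif(n, -6, log10(0.009)))
    )
  }
  reference <- rbind(sig_rows(c(shared, ref_only)), decoy_rows(decoys))
  study <- rbind(sig_rows(c(shared, stu_only)), decoy_rows(decoys))
  # shuffle row order so set identity never leans on position
  reference <- reference[sample.int(nrow(reference)), , drop = FALSE]
  study <- study[sample.int(nrow(study)), , drop = FALSE]
  rownames(reference) <- rownames(study) <- NULL
  list(reference = reference, study = study)
}
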