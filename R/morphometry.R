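#' Axon and myelin metrics from cross-section areas
#'
#' Converts per-axon inner (axon) and outer (fiber, including myelin)
#' cross-section areas into diameters via `d = 2 * sqrt(A / pi)`, the
#' g-ratio `d_axon / d_fiber`, and the sheath thickness
#' `d_fiber - d_axon`. Exact formula application, vectorised.
#'
#' @param axon_area_um2 Inner areas, µm² (> 0).
#' @param fiber_area_um2 Outer areas, µm² (>= axon area).
#' @return Data frame with `axon_diameter_um`, `fiber_diameter_um`,
#'   `g_ratio`, `sheath_thickness_um`.
#' @export
axon_metrics <- function(axon_area_um2, fiber_area_um2) {
  a <- as.numeric(axon_area_um2); f <- as.numeric(fiber_area_um2)
  if (length(a) != length(f)) stop("area vectors must have equal length")
  if (any(!is.finite(a)) || any(!is.finite(f))) stop("areas must be finite")
  if (any(a <= 0)) stop("axon areas must be > 0")
  if (any(a > f))
    stop("annotation inconsistency: axon area exceeds fiber area in row(s) ",
         paste(head(which(a > f)), collapse = ", "))
  d_in <- 2 * sqrt(a / pi)
  d_out <- 2 * sqrt(f / pi)
  data.frame(axon_diameter_um = d_in, fiber_diameter_um = d_out,
             g_ratio = d_in / d_out, sheath_thickness_um = d_out - d_in)
}

#' Augment an axon table with derived morphometry columns
#'
#' @param tab Data frame with columns `axon_area_um2`, `fiber_area_um2`.
#' @return `tab` with the [axon_metrics()] columns appended.
#' @export
axon_table_metrics <- function(tab) {
  need <- c("axon_area_um2", "fiber_area_um2")
  if (!all(need %in% names(tab)))
    stop("table must have columns ", paste(need, collapse = ", "))
  cbind(tab, axon_metrics(tab$axon_area_um2, tab$fiber_area_um2))
}

#' Unbiased grid sampling of axons
#'
#' Overlays a square grid on a labelled image and selects the objects whose
#' mask contains a grid intersection point, emulating the blinded rule of
#' measuring the axons that touch grid points, 20 per image. Nodes are
#' visited in reading order (along rows of nodes); each object is selected
#' at its first touching node; if more than `n_target` qualify, the first
#' `n_target` in node order are kept. Deterministic.
#'
#' @param objects A [label_map].
#' @param grid_spacing_um Grid spacing in micrometres (> 0).
#' @param n_target Number of objects to keep (default 20).
#' @param origin_um Grid origin offset `c(x, y)` in micrometres; nodes sit
#'   at `origin + k * spacing`.
#' @return Integer vector of selected labels, in selection order. Fewer
#'   than `n_target` qualifying objects returns all with a warning.
#' @export
grid_sample_axons <- function(objects, grid_spacing_um, n_target = 20L,
                              origin_um = c(0, 0)) {
  stopifnot(inherits(objects, "label_map"))
  if (grid_spacing_um <= 0) stop("`grid_spacing_um` must be > 0")
  lab <- objects$labels
  ps <- objects$pixel_size
  W <- ncol(lab) * ps; H <- nrow(lab) * ps
  gx <- seq(origin_um[1], W, by = grid_spacing_um)
  gy <- seq(origin_um[2], H, by = grid_spacing_um)
  gx <- gx[gx > 0 & gx <= W]; gy <- gy[gy > 0 & gy <= H]
  picked <- integer(0)
  for (y in gy) {          # reading order: rows of nodes, left to right
    row <- pmin(pmax(ceiling(y / ps), 1L), nrow(lab))
    for (x in gx) {
      col <- pmin(pmax(ceiling(x / ps), 1L), ncol(lab))
      l <- lab[row, col]
      if (l > 0L && !(l %in% picked)) picked <- c(picked, l)
    }
  }
  if (length(picked) < n_target)
    warning("only ", length(picked), " objects touch grid nodes (target ",
            n_target, "); returning all")
  head(picked, n_target)
}

#' Nonparametric multi-group comparison with normality diagnostics
#'
#' The testing scheme for g-ratio and sheath-thickness data:
#' Shapiro-Wilk normality per group (diagnostic only, never gating),
#' Kruskal-Wallis rank test across all groups (with tie correction), and
#' pairwise two-group Wilcoxon rank-sum tests whose p-values are multiplied
#' by the number of comparisons (Bonferroni) and capped at 1.
#'
#' @param values Numeric vector of observations.
#' @param group Group label per observation (>= 2 groups, >= 2 values each).
#' @return Object of class `np_group_test`: list with `shapiro`
#'   (per group: W, p; NA for n < 3), `kruskal` (H statistic, df, p) and
#'   `pairwise` (data frame: group1, group2, W, p_raw, p_bonferroni).
#' @export
nonparametric_group_test <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  ns <- table(group)
  if (any(ns < 2L)) stop("every group needs at least 2 observations")
  shap <- do.call(rbind, lapply(levels(group), function(g) {
    v <- values[group == g]
    if (length(v) >= 3L && length(unique(v)) > 1L) {
      s <- shapiro.test(v)
      data.frame(group = g, n = length(v), W = unname(s$statistic),
                 p = s$p.value)
    } else data.frame(group = g, n = length(v), W = NA_real_, p = NA_real_)
  }))
  kw <- kruskal.test(values, group)
  pairs <- utils::combn(levels(group), 2)
  m <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(m), function(i) {
    a <- values[group == pairs[1, i]]; b <- values[group == pairs[2, i]]
    wt <- suppressWarnings(wilcox.test(a, b, exact = (length(a) <= 10 &&
                                                        length(b) <= 10)))
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               W = unname(wt$statistic), p_raw = wt$p.value,
               p_bonferroni = min(1, wt$p.value * m))
  }))
  structure(list(shapiro = shap,
                 kruskal = list(H = unname(kw$statistic),
                                df = unname(kw$parameter), p = kw$p.value),
                 pairwise = pw),
            class = "np_group_test")
}

#' @export
print.np_group_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.3g\n",
              x$kruskal$H, x$kruskal$df, x$kruskal$p))
  cat("Shapiro-Wilk (diagnostic):\n")
  print(x$shapiro, row.names = FALSE)
  cat("Pairwise Wilcoxon, Bonferroni-adjusted:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
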