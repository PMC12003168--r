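#' Bead-uptake grade of a microglial cell
#'
#' Grading convention for engulfed microbeads: 0 beads -> grade 0
#' (non-phagocytic), 1-3 -> grade 1, 4-6 -> grade 2, 7-10 -> grade 3,
#' more than 10 -> grade 4.
#'
#' @param n_beads Non-negative integer bead counts (vectorised).
#' @return Integer grades in 0..4.
#' @export
bead_grade <- function(n_beads) {
  n <- as.numeric(n_beads)
  if (any(!is.finite(n)) || any(n < 0) || any(n != round(n)))
    stop("`n_beads` must be non-negative integers")
  findInterval(n, c(1, 4, 7, 11))
}

#' Grade profile of one counting unit
#'
#' @param n_beads Bead counts of all counted microglia in the unit.
#' @param denominator `"all"` (default): grade percentages are of all
#'   counted microglia, so they sum to the phagocytic percentage and the
#'   index is bounded by 400. `"phagocytic"`: percentages are of phagocytic
#'   cells only (the alternative convention; see the methods vignette).
#' @return List with `n_cells`, `pct_phagocytic`, `pct_by_grade`
#'   (grades 1-4) and `phagocytic_index`
#'   (`sum(grade * pct_by_grade[grade])`).
#' @export
grade_profile <- function(n_beads, denominator = c("all", "phagocytic")) {
  denominator <- match.arg(denominator)
  g <- bead_grade(n_beads)
  n <- length(g)
  if (n == 0L) stop("empty counting unit")
  n_phago <- sum(g >= 1L)
  denom <- if (denominator == "all") n else max(n_phago, 1L)
  pct <- 100 * tabulate(g, nbins = 4L) / denom
  names(pct) <- paste0("grade", 1:4)
  list(n_cells = n,
       pct_phagocytic = 100 * n_phago / n,
       pct_by_grade = pct,
       phagocytic_index = sum((1:4) * pct))
}

#' Phagocytosis scoring: percentage of phagocytic microglia and index
#'
#' Scores bead uptake hierarchically: per counting unit (field of view),
#' the percentage of phagocytic microglia (>= 1 bead), the percentage in
#' each grade and the phagocytic index (each grade multiplied by its
#' percentage and summed); per animal, the mean over that animal's units;
#' per group, mean and s.e.m. over animals. With the default `"all"`
#' denominator the index equals `100 * mean(grade)` over the unit's cells.
#'
#' @param beads Data frame with columns `animal_id`, `group`, `field_id`,
#'   `n_beads` (one row per counted cell), e.g. from
#'   [generate_bead_counts()].
#' @param denominator See [grade_profile()].
#' @return Object of class `phagocytosis_summary`: list of data frames
#'   `per_field`, `per_animal`, `per_group`.
#' @export
phagocytosis_summary <- function(beads, denominator = c("all", "phagocytic")) {
  denominator <- match.arg(denominator)
  need <- c("animal_id", "group", "field_id", "n_beads")
  if (!all(need %in% names(beads)))
    stop("`beads` must have columns ", paste(need, collapse = ", "))
  keep <- !is.na(beads$n_beads)
  beads <- beads[keep, , drop = FALSE]
  fields <- unique(beads[c("animal_id", "group", "field_id")])
  per_field <- do.call(rbind, lapply(seq_len(nrow(fields)), function(i) {
    sel <- beads$field_id == fields$field_id[i] &
      beads$animal_id == fields$animal_id[i]
    gp <- grade_profile(beads$n_beads[sel], denominator)
    cbind(fields[i, , drop = FALSE],
          data.frame(n_cells = gp$n_cells,
                     pct_phagocytic = gp$pct_phagocytic,
                     t(gp$pct_by_grade),
                     phagocytic_index = gp$phagocytic_index))
  }))
  rownames(per_field) <- NULL
  num <- c("pct_phagocytic", paste0("grade", 1:4), "phagocytic_index")
  agg <- function(df, by) {
    sp <- split(df, df[[by]])
    out <- do.call(rbind, lapply(sp, function(d) {
      data.frame(d[1, setdiff(c("group", by), "field_id"), drop = FALSE],
                 as.list(colMeans(d[num])),
                 n_units = nrow(d))
    }))
    rownames(out) <- NULL
    out
  }
  per_animal <- agg(per_field, "animal_id")
  sp <- split(per_animal, per_animal$group)
  per_group <- do.call(rbind, lapply(names(sp), function(g) {
    d <- sp[[g]]
    data.frame(group = g, n_animals = nrow(d),
               as.list(setNames(colMeans(d[num]), paste0(num, "_mean"))),
               as.list(setNames(apply(d[num], 2, sd) / sqrt(nrow(d)),
                                paste0(num, "_sem"))))
  }))
  rownames(per_group) <- NULL
  structure(list(per_field = per_field, per_animal = per_animal,
                 per_group = per_group, denominator = denominator),
            class = "phagocytosis_summary")
}

#' @export
print.phagocytosis_summary <- function(x, ...) {
  cat(sprintf("<phagocytosis_summary> (%s-cell denominator)\n", x$denominator))
  cols <- c("group", "n_animals", "pct_phagocytic_mean",
            "phagocytic_index_mean", "phagocytic_index_sem")
  print(x$per_group[cols], row.names = FALSE, digits = 4)
  invisible(x)
}
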