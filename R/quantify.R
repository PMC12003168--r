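#' Measure per-cell marker intensities over segmented nuclei
#'
#' For every label in the nucleus map: area, intensity-unweighted centroid
#' and the mean of each supplied channel over the label's pixel set — the
#' per-nucleus mean intensity being the measure of marker (e.g. Iba1,
#' Clec7a) expression.
#'
#' @param nuclei A [label_map] of nucleus instances.
#' @param channels Named list of [channel_image]s sharing shape and pixel
#'   size with `nuclei`.
#' @param image_id,animal_id,group Identifiers attached to every record.
#' @return Data frame of cell records: `cell_id`, `image_id`, `animal_id`,
#'   `group`, `centroid_x_um`, `centroid_y_um`, `area_um2` and one
#'   `mean_<channel>` column per channel.
#' @export
measure_cells <- function(nuclei, channels, image_id = "img1",
                          animal_id = "a1", group = "g1") {
  stopifnot(inherits(nuclei, "label_map"))
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop("`channels` must be a named list")
  for (ch in channels) {
    stopifnot(inherits(ch, "channel_image"))
    if (!identical(dim(ch$pixels), dim(nuclei$labels)))
      stop("channel shape does not match the label map")
    if (abs(ch$pixel_size - nuclei$pixel_size) > 1e-9)
      stop("channel pixel size does not match the label map")
  }
  tab <- object_table(nuclei)
  if (nrow(tab) == 0L) {
    out <- data.frame(cell_id = integer(), image_id = character(),
                      animal_id = character(), group = character(),
                      centroid_x_um = numeric(), centroid_y_um = numeric(),
                      area_um2 = numeric())
    for (nm in names(channels)) out[[paste0("mean_", nm)]] <- numeric()
    return(out)
  }
  lab <- nuclei$labels
  idx <- which(lab > 0L)
  l <- lab[idx]
  out <- data.frame(cell_id = tab$label, image_id = image_id,
                    animal_id = animal_id, group = group,
                    centroid_x_um = as.numeric(tab$centroid_x_um),
                    centroid_y_um = as.numeric(tab$centroid_y_um),
                    area_um2 = tab$area_um2)
  for (nm in names(channels))
    out[[paste0("mean_", nm)]] <-
      as.numeric(tapply(channels[[nm]]$pixels[idx], l, mean))
  out
}

#' Classify cells as marker-positive by per-image Otsu thresholding
#'
#' The Otsu threshold is computed over all cell mean intensities of the
#' stated channel within each image separately; a cell is positive when its
#' mean lies strictly above its own image's threshold. Thresholds are never
#' shared across images.
#'
#' @param records Cell-record data frame from [measure_cells()] (may pool
#'   several images; the `image_id` column defines the threshold scope).
#' @param channel Channel name (matching a `mean_<channel>` column).
#' @return `records` with added logical column `positive_<channel>` (NA for
#'   images with fewer than two distinct means, which are reported).
#' @export
classify_positive <- function(records, channel) {
  col <- paste0("mean_", channel)
  if (!col %in% names(records)) stop("no column ", col, " in records")
  poscol <- paste0("positive_", channel)
  records[[poscol]] <- NA
  for (im in unique(records$image_id)) {
    sel <- records$image_id == im
    v <- records[[col]][sel]
    if (length(unique(v)) < 2L) {
      message("image ", im, ": fewer than 2 distinct means; ",
              "cells flagged indeterminate")
      next
    }
    thr <- otsu_threshold(v)
    records[[poscol]][sel] <- v > thr
  }
  records
}

#' Distance to the nearest plaque and proximity selection
#'
#' Computes, for every cell, the Euclidean distance (µm) from its centroid
#' to the nearest plaque pixel (0 if the centroid lies inside a plaque),
#' and flags the cells used for plaque-proximal analysis: marker-positive
#' cells within `radius_um` of a plaque.
#'
#' @param records Cell records carrying `centroid_x_um`, `centroid_y_um`
#'   and (for the flag) a `positive_<positive_channel>` column.
#' @param plaques A [label_map] of plaque instances (same pixel grid).
#' @param radius_um Selection band around plaques, µm (default 30).
#' @param positive_channel Channel whose positivity gates the selection
#'   (default `"iba1"`); set `NULL` to flag on distance alone.
#' @return `records` with columns `dist_to_plaque_um` and `in_proximity`.
#' @export
plaque_proximity <- function(records, plaques, radius_um = 30,
                             positive_channel = "iba1") {
  stopifnot(inherits(plaques, "label_map"))
  lab <- plaques$labels
  ps <- plaques$pixel_size
  n <- nrow(records)
  if (max(lab) == 0L) {
    warning("no plaques in the label map; all distances infinite")
    records$dist_to_plaque_um <- rep(Inf, n)
    records$in_proximity <- rep(FALSE, n)
    return(records)
  }
  idx <- which(lab > 0L)
  nr <- nrow(lab)
  px <- ((idx - 1L) %/% nr + 1L - 0.5) * ps   # x of plaque pixel centres
  py <- ((idx - 1L) %% nr + 1L - 0.5) * ps    # y
  d <- numeric(n)
  for (i in seq_len(n)) {
    cx <- records$centroid_x_um[i]; cy <- records$centroid_y_um[i]
    row <- pmin(pmax(ceiling(cy / ps), 1L), nr)
    col <- pmin(pmax(ceiling(cx / ps), 1L), ncol(lab))
    d[i] <- if (lab[row, col] > 0L) 0 else
      sqrt(min((px - cx)^2 + (py - cy)^2))
  }
  records$dist_to_plaque_um <- d
  poscol <- paste0("positive_", positive_channel)
  posflag <- if (is.null(positive_channel)) rep(TRUE, n) else {
    if (!poscol %in% names(records))
      stop("run classify_positive() for channel '", positive_channel,
           "' before plaque_proximity(), or pass positive_channel = NULL")
    records[[poscol]] %in% TRUE
  }
  records$in_proximity <- posflag & d <= radius_um
  records
}

#' Pooled, integral-normalised expression profiles
#'
#' Builds the pooled histogram summary of marker expression: per image,
#' cell mean intensities are binned on shared fixed bin edges and each
#' image's histogram is divided by its own sum (integral normalisation);
#' per animal, the element-wise median across that animal's image profiles;
#' per group, the element-wise mean and s.e.m. (SD with n-1 denominator
#' over the number of animals) across animal profiles.
#'
#' @param records Cell records (typically pre-filtered to `in_proximity`).
#' @param channel Channel name (`mean_<channel>` column).
#' @param bins Either a single bin count (equal-width bins spanning the
#'   pooled min-max; default 20) or an explicit vector of bin edges.
#' @return An object of class `expression_profile`: list with `bin_edges`,
#'   `image_profiles` (matrix image x bin), `animal_profiles`,
#'   `group_mean`, `group_sem` (matrices group x bin) and bookkeeping maps.
#' @export
expression_profile <- function(records, channel, bins = 20) {
  col <- paste0("mean_", channel)
  if (!col %in% names(records)) stop("no column ", col, " in records")
  records <- records[is.finite(records[[col]]), , drop = FALSE]
  if (nrow(records) == 0L) stop("no eligible cells")
  v <- records[[col]]
  if (length(bins) == 1L) {
    rng <- range(v)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  } else {
    edges <- sort(as.numeric(bins))
  }
  nb <- length(edges) - 1L
  if (nb < 2L) stop("need at least 2 bins")

  images <- unique(records$image_id)
  imat <- matrix(NA_real_, length(images), nb,
                 dimnames = list(images, NULL))
  img_animal <- character(length(images))
  img_group <- character(length(images))
  dropped <- character(0)
  for (i in seq_along(images)) {
    sel <- records$image_id == images[i]
    x <- records[[col]][sel]
    cnt <- .hist_counts(x, edges)
    if (sum(cnt) == 0) { dropped <- c(dropped, images[i]); next }
    imat[i, ] <- cnt / sum(cnt)
    img_animal[i] <- records$animal_id[sel][1]
    img_group[i] <- as.character(records$group[sel][1])
  }
  if (length(dropped))
    message("images with no cells in range excluded: ",
            paste(dropped, collapse = ", "))
  ok <- !is.na(imat[, 1])
  imat <- imat[ok, , drop = FALSE]
  img_animal <- img_animal[ok]; img_group <- img_group[ok]

  animals <- unique(img_animal)
  amat <- matrix(NA_real_, length(animals), nb,
                 dimnames = list(animals, NULL))
  an_group <- character(length(animals))
  for (i in seq_along(animals)) {
    sub <- imat[img_animal == animals[i], , drop = FALSE]
    amat[i, ] <- apply(sub, 2, median)
    an_group[i] <- img_group[img_animal == animals[i]][1]
  }
  groups <- unique(an_group)
  gmean <- gsem <- matrix(NA_real_, length(groups), nb,
                          dimnames = list(groups, NULL))
  for (i in seq_along(groups)) {
    sub <- amat[an_group == groups[i], , drop = FALSE]
    gmean[i, ] <- colMeans(sub)
    gsem[i, ] <- apply(sub, 2, sd) / sqrt(nrow(sub))
  }
  structure(list(channel = channel, bin_edges = edges,
                 image_profiles = imat, animal_profiles = amat,
                 group_mean = gmean, group_sem = gsem,
                 image_animal = setNames(img_animal, rownames(imat)),
                 animal_group = setNames(an_group, animals)),
            class = "expression_profile")
}

# histogram counts on fixed edges; values on an interior edge go to the
# lower bin (right-closed), values at the first edge to bin 1
.hist_counts <- function(x, edges) {
  x <- x[x >= edges[1] & x <= edges[length(edges)]]
  if (length(x) == 0L) return(rep(0L, length(edges) - 1L))
  b <- findInterval(x, edges, rightmost.closed = TRUE, left.open = TRUE)
  b[b == 0L] <- 1L
  tabulate(b, nbins = length(edges) - 1L)
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile '%s'> %d bins, %d images, %d animals, %d groups\n",
              x$channel, length(x$bin_edges) - 1L, nrow(x$image_profiles),
              nrow(x$animal_profiles), nrow(x$group_mean)))
  invisible(x)
}

#' Histological count and coverage metrics
#'
#' The simple ratio metrics used for oligodendrocyte, interneuron and
#' myelin quantification: marker-to-reference count ratios (Olig2+/DAPI+,
#' CC1+/Olig2+), cell density per stated ROI area (PV+ per 2e4 µm² in CA1,
#' per 3e4 µm² in cortex) and the MBP/DAPI mean-gray ratio within an ROI.
#'
#' @param mode One of `"count_ratio"`, `"density"`, `"mean_gray_ratio"`.
#' @param n_marker,n_reference Counts for `"count_ratio"`.
#' @param n,area_um2 Count and ROI area (µm²) for `"density"`.
#' @param marker,reference [channel_image]s for `"mean_gray_ratio"`.
#' @param roi Optional logical matrix restricting `"mean_gray_ratio"`.
#' @return A single number: ratio, cells/µm², or mean-gray ratio.
#' @export
marker_metrics <- function(mode = c("count_ratio", "density",
                                    "mean_gray_ratio"),
                           n_marker = NULL, n_reference = NULL,
                           n = NULL, area_um2 = NULL,
                           marker = NULL, reference = NULL, roi = NULL) {
  mode <- match.arg(mode)
  switch(mode,
    count_ratio = {
      if (is.null(n_marker) || is.null(n_reference))
        stop("count_ratio needs n_marker and n_reference")
      if (n_reference <= 0) stop("reference count must be > 0")
      n_marker / n_reference
    },
    density = {
      if (is.null(n) || is.null(area_um2))
        stop("density needs n and area_um2")
      if (area_um2 <= 0) stop("ROI area must be > 0")
      n / area_um2
    },
    mean_gray_ratio = {
      stopifnot(inherits(marker, "channel_image"),
                inherits(reference, "channel_image"))
      sel <- if (is.null(roi)) rep(TRUE, length(marker$pixels)) else as.logical(roi)
      denom <- mean(reference$pixels[sel])
      if (denom <= 0) stop("reference mean gray value must be > 0")
      mean(marker$pixels[sel]) / denom
    })
}
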