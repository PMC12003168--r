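#' Segmentation configuration
#'
#' Physical parameters of the two instance-segmentation pipelines. The
#' defaults are the pipeline's processing constants: DAPI denoising cutoff
#' 2.6 µm, Gaussian blur sigma 520 nm, plaque-channel cutoff 26 µm,
#' rolling-ball radius 52 µm and plaque minimum area 130 µm². The nucleus
#' minimum area (10 µm²) and watershed seed separation (4 µm) are
#' package conventions sized to typical nuclear diameters.
#'
#' @param dapi_min_structure DAPI Fourier-filter cutoff, µm.
#' @param dapi_blur_sigma DAPI Gaussian blur sigma, µm.
#' @param dapi_filter_mode Direction of the DAPI size filter
#'   (`"pass-large"` keeps structures above the cutoff).
#' @param plaque_min_structure Plaque-channel Fourier cutoff, µm.
#' @param plaque_filter_mode Direction of the plaque-channel size filter;
#'   both readings of a size filter are available (see the methods vignette).
#' @param rolling_ball_radius Rolling-ball radius, µm.
#' @param plaque_min_area Minimum plaque area, µm² (strictly above).
#' @param nucleus_min_area Minimum nucleus area, µm².
#' @param watershed_min_peak_separation Minimum separation of watershed
#'   seed peaks, µm.
#' @param fill_holes Fill holes in the nuclear binary mask before the
#'   distance transform (ring-like staining artifacts).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(dapi_min_structure = 2.6,
                                dapi_blur_sigma = 0.52,
                                dapi_filter_mode = "pass-large",
                                plaque_min_structure = 26,
                                plaque_filter_mode = "pass-small",
                                rolling_ball_radius = 52,
                                plaque_min_area = 130,
                                nucleus_min_area = 10,
                                watershed_min_peak_separation = 4,
                                fill_holes = TRUE) {
  cfg <- list(dapi_min_structure = dapi_min_structure,
              dapi_blur_sigma = dapi_blur_sigma,
              dapi_filter_mode = dapi_filter_mode,
              plaque_min_structure = plaque_min_structure,
              plaque_filter_mode = plaque_filter_mode,
              rolling_ball_radius = rolling_ball_radius,
              plaque_min_area = plaque_min_area,
              nucleus_min_area = nucleus_min_area,
              watershed_min_peak_separation = watershed_min_peak_separation,
              fill_holes = isTRUE(fill_holes))
  num <- cfg[!(names(cfg) %in% c("fill_holes", "dapi_filter_mode",
                                 "plaque_filter_mode"))]
  if (any(unlist(num) <= 0)) stop("all segmentation parameters must be > 0")
  structure(cfg, class = "segmentation_config")
}

#' Segment nuclei from a DAPI channel
#'
#' Pipeline: Fourier size filter (cutoff `dapi_min_structure`) ->
#' Gaussian blur (`dapi_blur_sigma`) -> Otsu binarisation -> hole filling
#' -> Euclidean distance transform -> watershed seeded at distance-map
#' maxima separated by at least `watershed_min_peak_separation` -> area
#' filter (`nucleus_min_area`). A classical substitute for the pretrained
#' star-convex segmenter used interactively in the field; any callable with
#' the same signature returning a [label_map] can replace it (see
#' `segmenter` argument).
#'
#' @param dapi A [channel_image] of the nuclear stain.
#' @param cfg A [segmentation_config].
#' @param segmenter Optional plug-in: a `function(dapi, cfg)` returning a
#'   [label_map], used instead of the classical pipeline (e.g. a wrapper
#'   around a pretrained instance-segmentation model).
#' @return A [label_map] of nucleus instances.
#' @export
segment_nuclei <- function(dapi, cfg = segmentation_config(),
                           segmenter = NULL) {
  stopifnot(inherits(dapi, "channel_image"),
            inherits(cfg, "segmentation_config"))
  if (!is.null(segmenter)) {
    out <- segmenter(dapi, cfg)
    if (!inherits(out, "label_map"))
      stop("plug-in segmenter must return a label_map")
    return(filter_labels(out, cfg$nucleus_min_area))
  }
  img <- fourier_size_filter(dapi, cfg$dapi_min_structure,
                             mode = cfg$dapi_filter_mode)
  img <- gaussian_blur(img, cfg$dapi_blur_sigma)
  thr <- tryCatch(otsu_threshold(as.numeric(img$pixels)),
                  error = function(e) NA_real_)
  bin <- if (is.na(thr)) img$pixels > Inf else img$pixels > thr
  if (!any(bin)) {
    warning("no foreground after binarisation; returning empty label map")
    return(label_map(matrix(0L, nrow(bin), ncol(bin)), dapi$pixel_size))
  }
  if (cfg$fill_holes)
    bin <- EBImage::fillHull(bin * 1) > 0
  dm <- EBImage::distmap(bin * 1)
  sep_px <- cfg$watershed_min_peak_separation / dapi$pixel_size
  seeds <- .dm_seeds(dm, sep_px)
  ws <- .cpp_seeded_watershed(dm, seeds, bin)
  lm <- label_map(ws, dapi$pixel_size)
  filter_labels(lm, cfg$nucleus_min_area)
}

#' Segment amyloid plaques from a 4G8 channel
#'
#' Pipeline: Fourier size filter (cutoff `plaque_min_structure`) ->
#' rolling-ball background subtraction (`rolling_ball_radius`) -> Otsu
#' binarisation -> 8-connected labelling keeping objects strictly above
#' `plaque_min_area`.
#'
#' @param plaque_chan A [channel_image] of the amyloid stain.
#' @param cfg A [segmentation_config].
#' @return A [label_map]; the per-plaque area table (see [object_table()])
#'   is attached as attribute `"areas"`.
#' @export
segment_plaques <- function(plaque_chan, cfg = segmentation_config()) {
  stopifnot(inherits(plaque_chan, "channel_image"),
            inherits(cfg, "segmentation_config"))
  img <- fourier_size_filter(plaque_chan, cfg$plaque_min_structure,
                             mode = cfg$plaque_filter_mode)
  img <- rolling_ball_subtract(img, cfg$rolling_ball_radius)
  vals <- as.numeric(img$pixels)
  empty <- function() {
    lm <- label_map(matrix(0L, nrow(img$pixels), ncol(img$pixels)),
                    img$pixel_size)
    attr(lm, "areas") <- object_table(lm)
    lm
  }
  if (length(unique(vals)) < 2L) return(empty())
  thr <- otsu_threshold(vals)
  bin <- img$pixels > thr
  if (!any(bin)) return(empty())
  lm <- label_and_filter(bin, img$pixel_size, cfg$plaque_min_area,
                         strict = TRUE)
  attr(lm, "areas") <- object_table(lm)
  lm
}

# Watershed seeds: local maxima of the distance map (plateau components
# collapsed to their centroid pixel), with maxima closer than sep_px
# suppressed in favour of the higher peak.
.dm_seeds <- function(dm, sep_px) {
  br_size <- 2L * max(1L, as.integer(round(sep_px / 2))) + 1L
  dil <- EBImage::dilate(dm, EBImage::makeBrush(br_size, shape = "disc"))
  pk <- (dm == dil) & (dm > 0)
  lab <- .cpp_label8(pk)
  k <- max(lab)
  seeds <- matrix(0L, nrow(dm), ncol(dm))
  if (k == 0L) return(seeds)
  idx <- which(lab > 0L)
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  cr <- round(tapply(rows, l, mean))
  cc <- round(tapply(cols, l, mean))
  ph <- tapply(dm[idx], l, max)
  # a concave plateau's centroid can fall off the object; fall back to the
  # plateau's first pixel
  off <- dm[cbind(cr, cc)] <= 0
  cr[off] <- tapply(rows, l, `[`, 1L)[off]
  cc[off] <- tapply(cols, l, `[`, 1L)[off]
  keep <- logical(k)
  for (i in order(-ph)) {
    if (any(keep & sqrt((cr - cr[i])^2 + (cc - cc[i])^2) < sep_px)) next
    keep[i] <- TRUE
  }
  sid <- 0L
  for (i in which(keep)) {
    sid <- sid + 1L
    seeds[cr[i], cc[i]] <- sid
  }
  seeds
}

#' Maximum-intensity projection of an image stack
#'
#' Utility for confocal stacks quantified from maximum projections.
#'
#' @param stack 3D numeric array (rows x cols x slices) or list of
#'   [channel_image]s sharing shape and pixel size.
#' @param pixel_size Required when `stack` is an array.
#' @param name Channel label of the projection.
#' @return A [channel_image].
#' @export
max_project <- function(stack, pixel_size = NULL, name = "max_projection") {
  if (is.list(stack) && all(vapply(stack, inherits, TRUE, "channel_image"))) {
    pixel_size <- stack[[1]]$pixel_size
    stack <- simplify2array(lapply(stack, `[[`, "pixels"))
  }
  if (!(is.array(stack) && length(dim(stack)) == 3L))
    stop("`stack` must be a 3D array or list of channel_image")
  if (is.null(pixel_size)) stop("`pixel_size` required for array input")
  channel_image(apply(stack, c(1, 2), max), pixel_size, name)
}
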