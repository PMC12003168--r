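#' Single-channel image with physical pixel size
#'
#' The basic unit all image operators act on: a 2D grid of non-negative,
#' finite intensities together with the physical size of a pixel in
#' micrometres. All physically parameterised operators (Fourier size filter,
#' Gaussian blur, rolling-ball background subtraction, area filters) convert
#' their micrometre arguments to pixels through `pixel_size`.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities.
#' @param pixel_size Physical pixel size in micrometres per pixel (> 0).
#' @param name Optional channel label (e.g. `"dapi"`, `"iba1"`).
#' @return An object of class `channel_image` with fields `pixels`,
#'   `pixel_size` and `name`.
#' @export
channel_image <- function(pixels, pixel_size, name = "channel") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("`pixels` must contain finite values only")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (µm/pixel)")
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size),
         name = as.character(name)),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<channel_image '%s'> %d x %d px @ %g µm/px (%.1f x %.1f µm)\n",
              x$name, d[1], d[2], x$pixel_size,
              d[1] * x$pixel_size, d[2] * x$pixel_size))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Instance-segmentation label map
#'
#' Integer grid where 0 is background and labels 1..K identify segmented
#' objects (nuclei or plaques). Labels are contiguous and each object's pixel
#' set is 8-connected.
#'
#' @param labels Integer matrix, values in 0..K.
#' @param pixel_size Micrometres per pixel (> 0).
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, pixel_size) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE) || anyNA(labels))
    stop("labels must be non-negative integers")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  structure(list(labels = labels, pixel_size = as.numeric(pixel_size)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  k <- max(x$labels)
  cat(sprintf("<label_map> %d x %d px @ %g µm/px, %d object%s\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size, k,
              if (k == 1) "" else "s"))
  invisible(x)
}

#' Number of objects in a label map
#' @param x A [label_map].
#' @return Integer count of labelled objects.
#' @export
n_objects <- function(x) {
  stopifnot(inherits(x, "label_map"))
  as.integer(max(x$labels))
}

#' Per-object area and centroid table
#'
#' @param x A [label_map].
#' @return Data frame with columns `label`, `area_um2`, `centroid_x_um`,
#'   `centroid_y_um`. Coordinates use pixel-centre convention: the centre of
#'   pixel (row i, col j) is at x = (j - 0.5) * pixel_size,
#'   y = (i - 0.5) * pixel_size.
#' @export
object_table <- function(x) {
  stopifnot(inherits(x, "label_map"))
  lab <- x$labels
  idx <- which(lab > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(), area_um2 = numeric(),
                      centroid_x_um = numeric(), centroid_y_um = numeric()))
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  npix <- tabulate(l)
  ps <- x$pixel_size
  data.frame(
    label = seq_along(npix),
    area_um2 = npix * ps^2,
    centroid_x_um = (tapply(cols, l, mean) - 0.5) * ps,
    centroid_y_um = (tapply(rows, l, mean) - 0.5) * ps,
    row.names = NULL
  )
}

# ---- TIFF I/O -------------------------------------------------------------

#' Write a channel image as 16-bit TIFF with a pixel-size sidecar
#'
#' Intensities are scaled into the 16-bit range by `scale` (default: no
#' scaling, values must then fit in 0..65535). The pixel size is written both
#' to the TIFF resolution tags and to a `<file>.json` sidecar, which is the
#' authoritative source on read.
#'
#' @param img A [channel_image].
#' @param path Output file path (`.tif`).
#' @param scale Multiplicative factor applied before rounding to 16 bit.
#' @return Invisibly, `path`.
#' @export
write_channel_tiff <- function(img, path, scale = 1) {
  stopifnot(inherits(img, "channel_image"))
  px <- img$pixels * scale
  if (min(px) < 0 || max(px) > 65535)
    stop("scaled intensities outside the 16-bit range; adjust `scale`")
  # tiff::writeTIFF takes [0,1]; 16 bits per sample
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                  reduce = TRUE, compression = "none")
  meta <- list(pixel_size_um = img$pixel_size, name = img$name, scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a channel image written by [write_channel_tiff()]
#'
#' @param path TIFF file path.
#' @param pixel_size Pixel size in micrometres; overrides the sidecar if
#'   given (a mismatch is reported with a message).
#' @return A [channel_image].
#' @export
read_channel_tiff <- function(path, pixel_size = NULL) {
  px <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  scale <- if (!is.null(meta$scale)) meta$scale else 1
  ps_meta <- meta$pixel_size_um
  if (is.null(pixel_size)) {
    if (is.null(ps_meta))
      stop("no pixel size in sidecar; pass `pixel_size` explicitly")
    ps <- ps_meta
  } else {
    if (!is.null(ps_meta) && abs(pixel_size - ps_meta) > 1e-9)
      message(sprintf("pixel_size %g overrides sidecar value %g",
                      pixel_size, ps_meta))
    ps <- pixel_size
  }
  nm <- if (!is.null(meta$name)) meta$name else sub("\\.tiff?$", "", basename(path))
  channel_image(px * 65535 / scale, ps, name = nm)
}

#' Write a label map as 16-bit TIFF
#' @param x A [label_map].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_label_tiff <- function(x, path) {
  stopifnot(inherits(x, "label_map"))
  if (max(x$labels) > 65535) stop("more than 65535 labels")
  tiff::writeTIFF(x$labels / 65535, path, bits.per.sample = 16L,
                  reduce = TRUE, compression = "none")
  jsonlite::write_json(list(pixel_size_um = x$pixel_size, labels = TRUE),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
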