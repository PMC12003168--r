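#' Fourier-domain size filter
#'
#' Denoises a channel by suppressing structures smaller (default) or larger
#' than a physical cutoff. The filter is a radially symmetric Gaussian
#' applied in the Fourier domain, equivalent to spatial convolution with a
#' Gaussian of FWHM equal to `min_structure_um`. In `"pass-large"` mode the
#' low-pass result is returned (structures above the cutoff pass, sub-cutoff
#' noise is removed); in `"pass-small"` mode the complement
#' `img - lowpass(img)` is returned, which removes smooth background larger
#' than the cutoff. The DC component of the low-pass is preserved exactly,
#' so in `"pass-large"` mode the image mean is unchanged.
#'
#' The transfer function at period lambda is
#' `exp(-2 * pi^2 * sigma^2 / lambda^2)` with `sigma = FWHM / 2.355`:
#' a sinusoid at the cutoff period keeps < 3% of its amplitude, one at ten
#' times the cutoff keeps > 96%.
#'
#' @param img A [channel_image].
#' @param min_structure_um Physical cutoff (FWHM of the equivalent spatial
#'   Gaussian), micrometres.
#' @param mode `"pass-large"` (default) or `"pass-small"`.
#' @return A [channel_image] of the same shape.
#' @export
fourier_size_filter <- function(img, min_structure_um,
                                mode = c("pass-large", "pass-small")) {
  stopifnot(inherits(img, "channel_image"))
  mode <- match.arg(mode)
  if (!is.numeric(min_structure_um) || min_structure_um <= 0)
    stop("`min_structure_um` must be > 0")
  if (!all(dim(img$pixels) >= 8L))
    stop("image must be at least 8 x 8 for Fourier filtering")
  if (min_structure_um < img$pixel_size) {
    warning("cutoff below one pixel; returning input unchanged")
    return(img)
  }
  sigma_px <- (min_structure_um / img$pixel_size) / 2.355
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  fr <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[1:nr] / nr
  fc <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[1:nc] / nc
  h <- exp(-2 * pi^2 * sigma_px^2 * outer(fr^2, fc^2, `+`))
  low <- Re(fft(fft(img$pixels) * h, inverse = TRUE)) / (nr * nc)
  out <- if (mode == "pass-large") low else img$pixels - low
  channel_image(pmax(out, 0), img$pixel_size, img$name)
}

# reflective padding (symmetric, edge pixel repeated: ... 2 1 | 1 2 ...)
# for positions 1-k .. n+k; this reflection makes the blur mass-conserving
.reflect_idx <- function(n, k) {
  idx <- seq(1 - k, n + k)
  idx[idx < 1] <- 1 - idx[idx < 1]
  idx[idx > n] <- 2 * n + 1 - idx[idx > n]
  pmin(pmax(idx, 1L), n)
}

#' Gaussian blur with physical sigma
#'
#' Separable convolution with an isotropic Gaussian of standard deviation
#' `sigma_um / pixel_size` pixels, reflective boundary. The kernel is
#' normalised to unit sum, so total intensity is preserved.
#'
#' @param img A [channel_image].
#' @param sigma_um Standard deviation in micrometres (>= 0; 0 is identity).
#' @return A [channel_image].
#' @export
gaussian_blur <- function(img, sigma_um) {
  stopifnot(inherits(img, "channel_image"))
  if (!is.numeric(sigma_um) || length(sigma_um) != 1L || sigma_um < 0)
    stop("`sigma_um` must be a single non-negative number")
  if (sigma_um == 0) return(img)
  s <- sigma_um / img$pixel_size
  k <- max(1L, ceiling(3 * s))
  kern <- exp(-(seq(-k, k))^2 / (2 * s^2))
  kern <- kern / sum(kern)
  x <- img$pixels
  nr <- nrow(x); nc <- ncol(x)
  # rows
  xp <- x[.reflect_idx(nr, k), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (q in seq_len(2 * k + 1))
    out <- out + kern[q] * xp[q:(q + nr - 1), , drop = FALSE]
  # cols
  xp <- out[, .reflect_idx(nc, k), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (q in seq_len(2 * k + 1))
    out <- out + kern[q] * xp[, q:(q + nc - 1), drop = FALSE]
  channel_image(out, img$pixel_size, img$name)
}

# ball structuring element: offsets within radius r (pixels) and their
# heights sqrt(r^2 - d^2), the classic sphere rolled under the intensity
# surface (1 intensity unit per pixel of ball height)
.ball_kernel <- function(r) {
  k <- floor(r)
  g <- expand.grid(dx = -k:k, dy = -k:k)
  d2 <- g$dx^2 + g$dy^2
  keep <- d2 <= r^2
  list(dx = as.integer(g$dx[keep]), dy = as.integer(g$dy[keep]),
       h = sqrt(r^2 - d2[keep]))
}

# block-shrink by factor s using the block minimum (background estimate must
# never ride on foreground peaks), replicate-padding the ragged edge
.block_min <- function(x, s) {
  nr <- nrow(x); nc <- ncol(x)
  nr2 <- ceiling(nr / s); nc2 <- ceiling(nc / s)
  ri <- pmin((rep(seq_len(nr2), each = s) - 1) * s + rep(seq_len(s), nr2), nr)
  ci <- pmin((rep(seq_len(nc2), each = s) - 1) * s + rep(seq_len(s), nc2), nc)
  xp <- x[ri, ci, drop = FALSE]
  # fold s x s blocks via pmin over shifted submatrices
  out <- matrix(Inf, nr2, nc2)
  for (a in seq_len(s)) for (b in seq_len(s))
    out <- pmin(out, xp[seq(a, by = s, length.out = nr2),
                        seq(b, by = s, length.out = nc2), drop = FALSE])
  out
}

# bilinear enlargement back to (nr, nc); shrunk pixel (i,j) represents the
# block centred at ((i-0.5)*s, (j-0.5)*s) in original pixel coordinates
.bilinear_enlarge <- function(x, s, nr, nc) {
  nr2 <- nrow(x); nc2 <- ncol(x)
  pos_r <- (seq_len(nr) - 0.5) / s + 0.5   # position in shrunk-grid units
  pos_c <- (seq_len(nc) - 0.5) / s + 0.5
  r0 <- pmin(pmax(floor(pos_r), 1L), nr2); r1 <- pmin(r0 + 1L, nr2)
  c0 <- pmin(pmax(floor(pos_c), 1L), nc2); c1 <- pmin(c0 + 1L, nc2)
  wr <- pmin(pmax(pos_r - r0, 0), 1); wc <- pmin(pmax(pos_c - c0, 0), 1)
  a00 <- x[r0, c0, drop = FALSE]; a01 <- x[r0, c1, drop = FALSE]
  a10 <- x[r1, c0, drop = FALSE]; a11 <- x[r1, c1, drop = FALSE]
  WR <- matrix(wr, nr, nc); WC <- matrix(wc, nr, nc, byrow = TRUE)
  a00 * (1 - WR) * (1 - WC) + a10 * WR * (1 - WC) +
    a01 * (1 - WR) * WC + a11 * WR * WC
}

#' Rolling-ball background subtraction
#'
#' Estimates the slowly varying background as the grayscale morphological
#' opening of the image with a ball (spherical, non-flat) structuring
#' element of the stated physical radius, then subtracts it and clips at
#' zero. For large radii the image is first block-shrunk (block minimum),
#' the opening run at proportionally reduced radius, and the background
#' bilinearly enlarged — the standard acceleration for this operator. The
#' background is clipped to lie below the image, so the output always
#' satisfies `0 <= out <= img`.
#'
#' @param img A [channel_image].
#' @param radius_um Ball radius in micrometres (must be at least one pixel).
#' @param max_kernel_px Largest ball radius (pixels) applied at full
#'   resolution; larger radii trigger the shrink acceleration. Set to `Inf`
#'   to force the exact opening.
#' @return A [channel_image]; the estimated background is attached as
#'   attribute `"background"`.
#' @export
rolling_ball_subtract <- function(img, radius_um, max_kernel_px = 20) {
  stopifnot(inherits(img, "channel_image"))
  if (!is.numeric(radius_um) || radius_um <= 0)
    stop("`radius_um` must be > 0")
  r_px <- radius_um / img$pixel_size
  if (r_px < 1) stop("ball radius is below one pixel at this resolution")
  x <- img$pixels
  s <- max(1L, as.integer(ceiling(r_px / max_kernel_px)))
  if (s > 1L) {
    xs <- .block_min(x, s)
    kb <- .ball_kernel(r_px / s)
    er <- .cpp_gray_erode(xs, kb$dx, kb$dy, kb$h)
    op <- .cpp_gray_dilate(er, kb$dx, kb$dy, kb$h)
    bg <- .bilinear_enlarge(op, s, nrow(x), ncol(x))
  } else {
    kb <- .ball_kernel(r_px)
    er <- .cpp_gray_erode(x, kb$dx, kb$dy, kb$h)
    bg <- .cpp_gray_dilate(er, kb$dx, kb$dy, kb$h)
  }
  bg <- pmin(pmax(bg, 0), x)
  out <- channel_image(x - bg, img$pixel_size, img$name)
  attr(out, "background") <- bg
  out
}

#' Otsu threshold over a 256-bin histogram
#'
#' Classic between-class-variance maximisation on a 256-bin histogram
#' spanning the observed minimum to maximum (the ImageJ convention).
#' Candidate thresholds are the interior bin edges; ties are broken towards
#' the smallest maximising threshold. Foreground is defined as values
#' strictly greater than the returned threshold.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold (a value on the original intensity scale).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  lo <- min(values); hi <- max(values)
  if (lo == hi) stop("all values identical: Otsu threshold undefined")
  w <- (hi - lo) / n_bins
  bin <- pmin(floor((values - lo) / w) + 1L, n_bins)
  cnt <- tabulate(bin, nbins = n_bins)
  n <- length(values)
  mids <- lo + (seq_len(n_bins) - 0.5) * w
  cw <- cumsum(cnt)                 # cumulative count up to bin k
  cm <- cumsum(cnt * mids)          # cumulative intensity mass
  mu_t <- cm[n_bins] / n
  k <- seq_len(n_bins - 1L)
  w0 <- cw[k] / n
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, n_bins - 1L)
  mu0 <- cm[k][valid] / cw[k][valid]
  bcv[valid] <- w0[valid] * (1 - w0[valid]) *
    (mu0 - (mu_t - w0[valid] * mu0) / (1 - w0[valid]))^2
  kbest <- which.max(bcv)           # which.max returns the first (smallest)
  lo + kbest * w
}

#' Label 8-connected components and filter by physical area
#'
#' Components are labelled with 8-connectivity and kept if their area
#' (pixel count times `pixel_size^2`) exceeds `min_area_um2` — strictly
#' (`strict = TRUE`, mirroring an "above X" rule) or non-strictly. Surviving
#' components are renumbered 1..K in reading order of their first pixel.
#'
#' @param binary Logical (or 0/1 numeric) matrix.
#' @param pixel_size Micrometres per pixel.
#' @param min_area_um2 Area threshold in square micrometres (default 0:
#'   keep everything).
#' @param strict If `TRUE`, keep areas `> min_area_um2`; else `>=`.
#' @return A [label_map].
#' @export
label_and_filter <- function(binary, pixel_size, min_area_um2 = 0,
                             strict = TRUE) {
  if (inherits(binary, "channel_image")) {
    pixel_size <- binary$pixel_size
    binary <- binary$pixels > 0
  }
  if (!is.matrix(binary)) stop("`binary` must be a matrix")
  b <- matrix(as.logical(binary), nrow(binary), ncol(binary))
  lab <- .cpp_label8(b)
  filter_labels(label_map(lab, pixel_size), min_area_um2, strict)
}

#' Drop small objects from a label map and renumber
#'
#' @param x A [label_map].
#' @inheritParams label_and_filter
#' @return A [label_map] with surviving objects renumbered in reading order
#'   of their first pixel.
#' @export
filter_labels <- function(x, min_area_um2 = 0, strict = TRUE) {
  stopifnot(inherits(x, "label_map"))
  lab <- x$labels
  k <- max(lab)
  if (k == 0L) return(x)
  areas <- tabulate(lab[lab > 0L], nbins = k) * x$pixel_size^2
  keep <- if (strict) areas > min_area_um2 else areas >= min_area_um2
  # renumber survivors by first pixel in reading order (along rows)
  tl <- t(lab)
  first <- rep(NA_integer_, k)
  hit <- which(tl > 0L)
  f <- tl[hit]
  first[f[!duplicated(f)]] <- hit[!duplicated(f)]
  ord <- order(first)
  newid <- integer(k)
  newid[ord[keep[ord]]] <- seq_len(sum(keep))
  out <- lab
  out[lab > 0L] <- newid[lab[lab > 0L]]
  label_map(out, x$pixel_size)
}
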