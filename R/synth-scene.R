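#' Generate a ground-truthed synthetic multichannel scene
#'
#' Renders a four-channel fluorescence field (`nuclei`, `iba1`, `clec7a`,
#' `plaque`) with exact ground truth, emulating sections stained for DAPI,
#' Iba1, Clec7a and amyloid (4G8). Nuclei are isotropic Gaussian-profile
#' disks (sigma = radius / 2, truncated at 2 sigma) whose rendering
#' amplitude is scaled so that the mean intensity over the truth disk equals
#' the recorded true mean. Marker channels (`iba1`, `clec7a`) are rendered
#' as uniform disks at the true mean, so the mean over any subregion of a
#' nucleus equals its truth value. A declared fraction of nuclei is
#' Iba1-positive;
#' the true Clec7a mean of each Iba1-positive nucleus follows the planted
#' linear gradient `baseline + slope * distance_to_plaque`. Plaques are
#' unions of 3-6 jittered disks with an exact truth mask. A smooth additive
#' background and per-pixel noise (Gaussian by default, Poisson behind the
#' `noise_model` flag) complete the scene.
#'
#' Identical `rng_seed` and parameters give bit-identical output.
#'
#' @param params A [sim_params] object.
#' @return An object of class `synthetic_scene`: list with `channels`
#'   (named [channel_image]s), `truth_nuclei` (data frame: centre, radius,
#'   true per-channel means, `iba1_positive`, `dist_to_plaque_um`),
#'   `truth_plaque_mask` (logical matrix) and `params`.
#' @export
generate_scene <- function(params = sim_params()) {
  p <- validate_sim_params(params)
  set.seed(.sub_seed(p, "scene"))
  nr <- p$image_shape[1]; nc <- p$image_shape[2]; ps <- p$pixel_size
  W <- nc * ps; H <- nr * ps

  # ---- plaques: unions of jittered disks -------------------------------
  disks <- list()
  if (p$n_plaques > 0) {
    rmax <- max(p$plaque_radius_range)
    if (W <= 4 * rmax || H <= 4 * rmax)
      stop("placement failure: image too small for the requested plaques")
    for (q in seq_len(p$n_plaques)) {
      cx <- runif(1, 2 * rmax, W - 2 * rmax)
      cy <- runif(1, 2 * rmax, H - 2 * rmax)
      nsub <- sample(3:6, 1)
      rad <- runif(nsub, p$plaque_radius_range[1], p$plaque_radius_range[2])
      jit <- mean(p$plaque_radius_range) * 0.5
      disks[[q]] <- data.frame(
        plaque = q,
        cx = cx + runif(nsub, -jit, jit),
        cy = cy + runif(nsub, -jit, jit),
        r = rad)
    }
  }
  disks <- if (length(disks)) do.call(rbind, disks) else
    data.frame(plaque = integer(), cx = numeric(), cy = numeric(),
               r = numeric())

  xs <- (seq_len(nc) - 0.5) * ps   # pixel-centre coordinates
  ys <- (seq_len(nr) - 0.5) * ps
  mask <- matrix(FALSE, nr, nc)
  for (q in seq_len(nrow(disks))) {
    dx2 <- (matrix(xs, nr, nc, byrow = TRUE) - disks$cx[q])^2
    dy2 <- (matrix(ys, nr, nc) - disks$cy[q])^2
    mask <- mask | (dx2 + dy2 <= disks$r[q]^2)
  }

  # ---- nuclei placement: rejection sampling ----------------------------
  n <- p$n_nuclei
  rad <- runif(n, p$nucleus_radius_range[1], p$nucleus_radius_range[2])
  cx <- cy <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 500L * max(n, 1L)
  while (placed < n) {
    if (tries >= max_tries)
      stop("placement failure: could not place ", n,
           " nuclei without centre overlap in a ",
           round(W), " x ", round(H), " µm field")
    tries <- tries + 1L
    r <- rad[placed + 1L]
    if (W <= 2 * r || H <= 2 * r)
      stop("placement failure: image too small for a nucleus of radius ", r)
    x <- runif(1, r, W - r); y <- runif(1, r, H - r)
    ok <- TRUE
    if (placed > 0L) {
      d <- sqrt((cx[seq_len(placed)] - x)^2 + (cy[seq_len(placed)] - y)^2)
      ok <- all(d >= pmax(rad[seq_len(placed)], r))
    }
    if (ok) {
      placed <- placed + 1L
      cx[placed] <- x; cy[placed] <- y
    }
  }

  # distance of every nucleus centre to the nearest plaque pixel (exact,
  # brute force over the truth-mask pixel centres; 0 if the centre lies in
  # the mask)
  dist_um <- rep(Inf, n)
  if (any(mask)) {
    midx <- which(mask)
    mx <- xs[(midx - 1L) %/% nr + 1L]
    my <- ys[(midx - 1L) %% nr + 1L]
    for (i in seq_len(n)) {
      px_col <- pmin(pmax(ceiling(cx[i] / ps), 1L), nc)
      px_row <- pmin(pmax(ceiling(cy[i] / ps), 1L), nr)
      if (mask[px_row, px_col]) {
        dist_um[i] <- 0
      } else {
        dist_um[i] <- sqrt(min((mx - cx[i])^2 + (my - cy[i])^2))
      }
    }
  }

  # ---- true per-channel means ------------------------------------------
  n_pos <- round(p$iba1_pos_frac * n)
  pos <- rep(FALSE, n)
  if (n_pos > 0) pos[sample.int(n, n_pos)] <- TRUE
  mean_dapi <- runif(n, p$nucleus_mean_range[1], p$nucleus_mean_range[2])
  mean_iba1 <- ifelse(pos,
                      runif(n, p$iba1_pos_range[1], p$iba1_pos_range[2]),
                      runif(n, p$iba1_neg_range[1], p$iba1_neg_range[2]))
  base <- p$marker_gradient["baseline"]; slope <- p$marker_gradient["slope"]
  clec_neg <- 20  # dim constitutive level of Iba1-negative cells
  mean_clec <- ifelse(pos & is.finite(dist_um), base + slope * dist_um,
                      clec_neg)

  # ---- render ----------------------------------------------------------
  # Gaussian-profile disk, sigma = R/2, truncated at 2 sigma (= R); the
  # mean of that profile over the disk is (1 - exp(-2)) / 2 of the peak,
  # so peak = true_mean / 0.432332...
  disk_mean_factor <- (1 - exp(-2)) / 2
  render <- function(means) {
    img <- matrix(0, nr, nc)
    for (i in seq_len(n)) {
      if (means[i] <= 0) next
      R <- rad[i]; sig <- R / 2
      j0 <- max(1L, floor((cx[i] - R) / ps)); j1 <- min(nc, ceiling((cx[i] + R) / ps))
      i0 <- max(1L, floor((cy[i] - R) / ps)); i1 <- min(nr, ceiling((cy[i] + R) / ps))
      if (j1 < j0 || i1 < i0) next
      gx <- (xs[j0:j1] - cx[i]); gy <- (ys[i0:i1] - cy[i])
      r2 <- outer(gy^2, gx^2, `+`)
      amp <- means[i] / disk_mean_factor
      patch <- amp * exp(-r2 / (2 * sig^2))
      patch[r2 > R^2] <- 0
      img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + patch
    }
    img
  }
  # marker channels are uniform disks at the true mean, so the mean over
  # any subregion of the nucleus equals the truth value exactly
  render_flat <- function(means) {
    img <- matrix(0, nr, nc)
    for (i in seq_len(n)) {
      if (means[i] <= 0) next
      R <- rad[i]
      j0 <- max(1L, floor((cx[i] - R) / ps)); j1 <- min(nc, ceiling((cx[i] + R) / ps))
      i0 <- max(1L, floor((cy[i] - R) / ps)); i1 <- min(nr, ceiling((cy[i] + R) / ps))
      if (j1 < j0 || i1 < i0) next
      r2 <- outer((ys[i0:i1] - cy[i])^2, (xs[j0:j1] - cx[i])^2, `+`)
      img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + means[i] * (r2 <= R^2)
    }
    img
  }
  ch <- list(
    nuclei = render(mean_dapi),
    iba1 = render_flat(mean_iba1),
    clec7a = render_flat(pmax(mean_clec, 0)),
    plaque = p$plaque_amplitude * mask
  )

  # smooth background (shared shape across channels) + noise
  if (p$background_amplitude > 0) {
    ph <- runif(2, 0, 2 * pi)
    bgx <- sin(2 * pi * xs / W + ph[1])
    bgy <- sin(2 * pi * ys / H + ph[2])
    bg <- p$background_amplitude *
      (0.5 + 0.25 * matrix(bgx, nr, nc, byrow = TRUE) +
         0.25 * matrix(bgy, nr, nc))
  } else bg <- matrix(0, nr, nc)

  for (nm in names(ch)) {
    clean <- ch[[nm]] + bg
    if (p$noise_model == "poisson") {
      ch[[nm]] <- matrix(rpois(nr * nc, pmax(clean, 0)), nr, nc)
    } else if (p$noise_sd > 0) {
      ch[[nm]] <- pmax(clean + matrix(rnorm(nr * nc, 0, p$noise_sd), nr, nc), 0)
    } else {
      ch[[nm]] <- clean
    }
  }
  channels <- lapply(names(ch), function(nm) channel_image(ch[[nm]], ps, nm))
  names(channels) <- names(ch)

  truth <- data.frame(
    nucleus = seq_len(n), x_um = cx, y_um = cy, radius_um = rad,
    mean_nuclei = mean_dapi, mean_iba1 = mean_iba1, mean_clec7a = mean_clec,
    iba1_positive = pos, dist_to_plaque_um = dist_um
  )
  structure(list(channels = channels, truth_nuclei = truth,
                 truth_plaque_mask = mask, truth_plaque_disks = disks,
                 params = p),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d nuclei (%d Iba1+), %d plaques, %s\n",
              nrow(x$truth_nuclei), sum(x$truth_nuclei$iba1_positive),
              x$params$n_plaques,
              paste(names(x$channels), collapse = "/")))
  invisible(x)
}

#' Write a synthetic scene to disk
#'
#' One 16-bit TIFF per channel (with pixel-size sidecars), the truth-nuclei
#' table as CSV and the truth plaque mask as a 0/1 CSV grid.
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(scene$channels)) {
    img <- scene$channels[[nm]]
    sc <- min(1, 65535 / max(max(img$pixels), 1))
    write_channel_tiff(img, file.path(dir, paste0(nm, ".tif")), scale = sc)
  }
  write.csv(scene$truth_nuclei, file.path(dir, "truth_nuclei.csv"),
            row.names = FALSE)
  write.csv(scene$truth_plaque_mask * 1L,
            file.path(dir, "truth_plaque_mask.csv"), row.names = FALSE)
  invisible(dir)
}
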