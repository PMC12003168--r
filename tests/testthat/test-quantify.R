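# label map drawn from a scene's truth disks: measurement tests use exact
# regions so they probe measure_cells, not the segmenter
truth_label_map <- function(sc) {
  ps <- sc$params$pixel_size
  nr <- sc$params$image_shape[1]; nc <- sc$params$image_shape[2]
  lab <- matrix(0L, nr, nc)
  xs <- (seq_len(nc) - 0.5) * ps; ys <- (seq_len(nr) - 0.5) * ps
  tr <- sc$truth_nuclei
  for (i in seq_len(nrow(tr))) {
    r2 <- outer((ys - tr$y_um[i])^2, (xs - tr$x_um[i])^2, `+`)
    lab[r2 <= tr$radius_um[i]^2] <- i
  }
  label_map(lab, ps)
}

test_that("per-cell means are the plain average over the label's pixels", {
  lab <- matrix(0L, 4, 4); lab[1, 1:4] <- 1L
  ch <- channel_image(matrix(0, 4, 4), 1)
  ch$pixels[1, ] <- c(1, 2, 3, 4)
  rec <- measure_cells(label_map(lab, 1), list(m = ch))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$mean_m, 2.5)
  expect_equal(rec$area_um2, 4)

  lab2 <- matrix(0L, 8, 8); lab2[1:2, 1:2] <- 1L; lab2[5:6, 5:8] <- 2L
  rec2 <- measure_cells(label_map(lab2, 1), list(m = channel_image(matrix(1, 8, 8), 1)))
  expect_equal(nrow(rec2), 2L)   # K labels -> K records

  bad <- channel_image(matrix(1, 4, 4), 1)
  expect_error(measure_cells(label_map(lab2, 1), list(m = bad)), "shape")
})

test_that("noiseless scene means are recovered from truth regions", {
  sc <- generate_scene(sim_params(rng_seed = 5, noise_sd = 0,
                                  background_amplitude = 0))
  rec <- measure_cells(truth_label_map(sc),
                       sc$channels[c("nuclei", "iba1", "clec7a")])
  tr <- sc$truth_nuclei
  # separated nuclei only: overlapping disks add their intensities
  d <- as.matrix(dist(cbind(tr$x_um, tr$y_um))); diag(d) <- Inf
  sep <- apply(d, 1, min) > tr$radius_um + max(tr$radius_um)
  expect_gt(sum(sep), 10)
  expect_equal(rec$mean_iba1[sep], tr$mean_iba1[sep], tolerance = 1e-9)
  expect_equal(rec$mean_clec7a[sep], tr$mean_clec7a[sep], tolerance = 1e-9)
  expect_equal(rec$mean_nuclei[sep], tr$mean_nuclei[sep],
               tolerance = 0.01 * mean(tr$mean_nuclei))
})

test_that("positivity is a per-image Otsu call on cell means", {
  rec <- data.frame(cell_id = 1:5, image_id = "im1",
                    mean_m = c(1, 1, 1, 9, 9))
  out <- classify_positive(rec, "m")
  expect_equal(out$positive_m, c(FALSE, FALSE, FALSE, TRUE, TRUE))

  # duplicating every cell leaves the threshold (hence calls) unchanged
  dup <- classify_positive(rbind(rec, rec), "m")
  expect_equal(dup$positive_m, rep(out$positive_m, 2))

  # thresholds are per image, never shared
  two <- data.frame(cell_id = 1:8,
                    image_id = rep(c("a", "b"), each = 4),
                    mean_m = c(1, 2, 8, 9, 101, 102, 108, 109))
  ot <- classify_positive(two, "m")
  expect_equal(ot$positive_m, rep(c(FALSE, FALSE, TRUE, TRUE), 2))

  # indeterminate image: flagged NA with a message
  onev <- data.frame(cell_id = 1:2, image_id = "c", mean_m = c(5, 5))
  expect_message(oc <- classify_positive(onev, "m"), "indeterminate")
  expect_true(all(is.na(oc$positive_m)))
})

test_that("planted positives are recalled accurately across scenes", {
  acc <- sapply(1:5, function(seed) {
    sc <- generate_scene(sim_params(rng_seed = seed))
    rec <- measure_cells(truth_label_map(sc), sc$channels["iba1"])
    rec <- classify_positive(rec, "iba1")
    mean(rec$positive_iba1 == sc$truth_nuclei$iba1_positive)
  })
  expect_gte(mean(acc), 0.98)
})

test_that("plaque distance follows centroid-to-nearest-pixel geometry with the 30 µm band", {
  ps <- 0.5
  n <- 256
  lab <- matrix(0L, n, n)
  xs <- (seq_len(n) - 0.5) * ps
  r2 <- outer((xs - 60)^2, (xs - 60)^2, `+`)  # disk radius 10 µm at (60, 60)
  lab[t(r2) <= 10^2] <- 1L
  plaques <- label_map(lab, ps)
  rec <- data.frame(cell_id = 1:3,
                    centroid_x_um = c(95, 105, 60),
                    centroid_y_um = c(60, 60, 60),
                    positive_iba1 = c(TRUE, TRUE, TRUE))
  out <- plaque_proximity(rec, plaques, radius_um = 30)
  expect_equal(out$dist_to_plaque_um, c(25, 35, 0), tolerance = ps)
  expect_equal(out$in_proximity, c(TRUE, FALSE, TRUE))

  # negativity excludes even nearby cells
  rec$positive_iba1 <- c(FALSE, TRUE, TRUE)
  out2 <- plaque_proximity(rec, plaques, radius_um = 30)
  expect_equal(out2$in_proximity, c(FALSE, FALSE, TRUE))

  # no plaques: infinite distances, all flags off, warning
  none <- label_map(matrix(0L, 16, 16), ps)
  expect_warning(out3 <- plaque_proximity(rec, none), "no plaques")
  expect_true(all(is.infinite(out3$dist_to_plaque_um)))
  expect_false(any(out3$in_proximity))
})

test_that("expression profiles normalise per image and pool by animal median then group mean", {
  mk <- function(image, animal, means)
    data.frame(cell_id = seq_along(means), image_id = image,
               animal_id = animal, group = "g", mean_m = means)
  edges <- c(0, 1, 2, 3, 4)
  # one image with bin counts (2, 4, 2, 2)
  r1 <- mk("i1", "a1", c(.5, .5, 1.5, 1.5, 1.5, 1.5, 2.5, 2.5, 3.5, 3.5))
  pr <- expression_profile(r1, "m", bins = edges)
  expect_equal(as.numeric(pr$image_profiles[1, ]), c(0.2, 0.4, 0.2, 0.2))
  expect_equal(sum(pr$image_profiles[1, ]), 1, tolerance = 1e-9)

  # three identical images: animal median equals the common profile
  r3 <- rbind(mk("i1", "a1", c(.5, 1.5)), mk("i2", "a1", c(.5, 1.5)),
              mk("i3", "a1", c(.5, 1.5)))
  p3 <- expression_profile(r3, "m", bins = edges)
  expect_equal(as.numeric(p3$animal_profiles["a1", ]),
               as.numeric(p3$image_profiles[1, ]))

  # per-bin medians are element-wise across images
  r4 <- rbind(mk("i1", "a1", c(.5, rep(1.5, 9))),   # bin1 share 0.1
              mk("i2", "a1", c(.5, .5, rep(1.5, 8))),
              mk("i3", "a1", c(.5, .5, .5, rep(1.5, 7))))
  p4 <- expression_profile(r4, "m", bins = edges)
  expect_equal(unname(p4$animal_profiles["a1", 1]), 0.2)
})

test_that("profiles ignore relabelling and already-filtered rows", {
  sc <- generate_scene(sim_params(rng_seed = 8))
  rec <- measure_cells(truth_label_map(sc), sc$channels["clec7a"])
  rec$group <- "g"
  rec$in_proximity <- sc$truth_nuclei$dist_to_plaque_um <= 30 &
    sc$truth_nuclei$iba1_positive
  sel <- rec[rec$in_proximity, ]
  edges <- seq(0, 400, length.out = 21)
  a <- expression_profile(sel, "clec7a", bins = edges)
  # shuffling row order changes nothing
  b <- expression_profile(sel[sample.int(nrow(sel)), ], "clec7a", bins = edges)
  expect_equal(a$image_profiles, b$image_profiles)
  # re-filtering an already-filtered table is a no-op
  c2 <- expression_profile(sel[sel$in_proximity, ], "clec7a", bins = edges)
  expect_equal(a$group_mean, c2$group_mean)
})

test_that("count, density and mean-gray metrics apply the stated arithmetic", {
  expect_equal(marker_metrics("count_ratio", n_marker = 30, n_reference = 300), 0.1)
  expect_equal(marker_metrics("density", n = 12, area_um2 = 2e4), 6e-4)
  mbp <- channel_image(matrix(50, 8, 8), 1)
  dapi <- channel_image(matrix(100, 8, 8), 1)
  expect_equal(marker_metrics("mean_gray_ratio", marker = mbp, reference = dapi), 0.5)
  expect_error(marker_metrics("count_ratio", n_marker = 1, n_reference = 0), "> 0")
})
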