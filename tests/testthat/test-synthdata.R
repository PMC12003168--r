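test_that("scene generation honours counts, truth means and determinism", {
  p <- sim_params(rng_seed = 7)
  sc <- generate_scene(p)
  expect_equal(nrow(sc$truth_nuclei), 50L)
  expect_named(sc$channels, c("nuclei", "iba1", "clec7a", "plaque"))

  # identical seed => bit-identical output
  sc2 <- generate_scene(sim_params(rng_seed = 7))
  expect_identical(sc$channels$nuclei$pixels, sc2$channels$nuclei$pixels)
  expect_identical(sc$truth_nuclei, sc2$truth_nuclei)

  # different seed differs
  sc3 <- generate_scene(sim_params(rng_seed = 8))
  expect_false(identical(sc$truth_nuclei$x_um, sc3$truth_nuclei$x_um))
})

test_that("sub-seeding isolates generators from each other", {
  p <- sim_params(rng_seed = 5)
  a1 <- generate_axon_table(p)
  invisible(generate_scene(p))          # interleaved call must not matter
  invisible(generate_bead_counts(p))
  a2 <- generate_axon_table(p)
  expect_identical(a1, a2)
})

test_that("noiseless rendering reproduces the recorded true means", {
  p <- sim_params(rng_seed = 2, n_nuclei = 1, n_plaques = 0, noise_sd = 0,
                  background_amplitude = 0, iba1_pos_frac = 1,
                  nucleus_mean_range = c(100, 100))
  sc <- generate_scene(p)
  tr <- sc$truth_nuclei
  ps <- p$pixel_size
  xs <- (seq_len(512) - 0.5) * ps; ys <- (seq_len(512) - 0.5) * ps
  disk <- outer((ys - tr$y_um)^2, (xs - tr$x_um)^2, `+`) <= tr$radius_um^2
  # DAPI channel: Gaussian profile scaled so the disk mean is the truth
  expect_equal(mean(sc$channels$nuclei$pixels[disk]), 100, tolerance = 1)
  # marker channels are uniform at the true mean: exact over the disk
  expect_equal(mean(sc$channels$iba1$pixels[disk]), tr$mean_iba1,
               tolerance = 1e-9)
  expect_equal(mean(sc$channels$clec7a$pixels[disk]), tr$mean_clec7a,
               tolerance = 1e-9)
})

test_that("planted marker gradient is exactly linear in the truth table", {
  p <- sim_params(rng_seed = 9,
                  marker_gradient = c(baseline = 200, slope = -2))
  sc <- generate_scene(p)
  tr <- sc$truth_nuclei
  pos <- tr$iba1_positive & is.finite(tr$dist_to_plaque_um)
  fit <- lm(mean_clec7a ~ dist_to_plaque_um, data = tr[pos, ])
  expect_equal(unname(coef(fit)[2]), -2, tolerance = 1e-9)
  expect_equal(unname(coef(fit)[1]), 200, tolerance = 1e-9)
})

test_that("truth distances equal a brute-force scan over plaque pixels", {
  p <- sim_params(rng_seed = 4, image_shape = c(96L, 96L), n_nuclei = 8,
                  n_plaques = 1, plaque_radius_range = c(4, 6),
                  nucleus_radius_range = c(2, 3))
  sc <- generate_scene(p)
  ps <- p$pixel_size
  idx <- which(sc$truth_plaque_mask)
  nr <- nrow(sc$truth_plaque_mask)
  px <- ((idx - 1) %/% nr + 1 - 0.5) * ps
  py <- ((idx - 1) %% nr + 1 - 0.5) * ps
  for (i in seq_len(nrow(sc$truth_nuclei))) {
    cx <- sc$truth_nuclei$x_um[i]; cy <- sc$truth_nuclei$y_um[i]
    inside <- sc$truth_plaque_mask[min(max(ceiling(cy / ps), 1), nr),
                                   min(max(ceiling(cx / ps), 1), nr)]
    want <- if (inside) 0 else sqrt(min((px - cx)^2 + (py - cy)^2))
    expect_equal(sc$truth_nuclei$dist_to_plaque_um[i], want, tolerance = 1e-12)
  }
})

test_that("nuclei respect the centre-separation rule and image bounds; impossible requests error", {
  p <- sim_params(rng_seed = 1)
  sc <- generate_scene(p)
  tr <- sc$truth_nuclei
  W <- p$image_shape[2] * p$pixel_size
  expect_true(all(tr$x_um >= tr$radius_um & tr$x_um <= W - tr$radius_um))
  d <- as.matrix(dist(cbind(tr$x_um, tr$y_um))); diag(d) <- Inf
  rmax <- outer(tr$radius_um, tr$radius_um, pmax)
  expect_true(all(d >= rmax - 1e-9))

  expect_error(
    generate_scene(sim_params(rng_seed = 1, image_shape = c(32L, 32L),
                              n_nuclei = 500)),
    "placement failure")
})

test_that("axon table: degenerate spread gives exact g-ratio, areas are consistent", {
  p0 <- sim_params(rng_seed = 3, gratio_mean_by_group = c(A = 0.8),
                   gratio_sd = 0)
  t0 <- generate_axon_table(p0)
  m <- axon_metrics(t0$axon_area_um2, t0$fiber_area_um2)
  expect_equal(m$g_ratio, rep(0.8, nrow(t0)), tolerance = 1e-9)

  # Monte-Carlo mean at n = 1000: CLT bound 0.75 +/- 0.005
  p1 <- sim_params(rng_seed = 5, gratio_mean_by_group = c(A = 0.75),
                   gratio_sd = 0.05, n_animals = 1, n_axons = 1000)
  t1 <- generate_axon_table(p1)
  expect_equal(mean(t1$g_true), 0.75, tolerance = 0.005)

  expect_true(all(t1$fiber_area_um2 >= t1$axon_area_um2))
  # diameters recompute the sampled g-ratio exactly
  m1 <- axon_metrics(t1$axon_area_um2, t1$fiber_area_um2)
  expect_equal(m1$g_ratio, t1$g_true, tolerance = 1e-9)
})

test_that("bead counts follow the zero-inflated Poisson structure", {
  z0 <- generate_bead_counts(sim_params(rng_seed = 1,
                                        bead_rate_by_group = c(A = 0),
                                        zero_inflation = 0))
  expect_true(all(z0$n_beads == 0))

  z1 <- generate_bead_counts(sim_params(rng_seed = 2,
                                        bead_rate_by_group = c(A = 5),
                                        zero_inflation = 1))
  expect_true(all(z1$n_beads == 0))

  # closed-form zero mass: pi + (1 - pi) e^-lambda
  pz <- sim_params(rng_seed = 3, bead_rate_by_group = c(A = 3),
                   zero_inflation = 0.5, n_animals = 2, n_fields = 10,
                   n_cells_per_field = 500)
  z <- generate_bead_counts(pz)
  expect_equal(nrow(z), 10000L)
  expect_equal(mean(z$n_beads == 0), 0.5 + 0.5 * exp(-3), tolerance = 0.02)
})

test_that("composition draws are multinomial with the stated size and group vectors", {
  p <- sim_params(rng_seed = 6,
                  composition_by_group = list(A = c(x = 0.6, y = 0.4),
                                              B = c(x = 0.4, y = 0.6)),
                  n_cells_per_sample = 10L, n_animals = 3)
  cm <- generate_composition(p)
  expect_true(all(rowSums(cm$counts) == 10))
  expect_equal(dim(cm$counts), c(6L, 2L))

  # identical vectors across groups: planted effect 0 (proportions i.i.d.)
  p0 <- sim_params(rng_seed = 6,
                   composition_by_group = list(A = c(x = 0.5, y = 0.5),
                                               B = c(x = 0.5, y = 0.5)),
                   n_cells_per_sample = 2000L, n_animals = 50)
  cm0 <- generate_composition(p0)
  pa <- mean(cm0$counts[cm0$genotype == "A", "x"]) / 2000
  pb <- mean(cm0$counts[cm0$genotype == "B", "x"]) / 2000
  expect_equal(pa, pb, tolerance = 0.02)
})

test_that("DEG tables have exactly the requested significant sets and overlap", {
  ov <- function(sizes, seed = 1) {
    p <- sim_params(rng_seed = seed,
                    deg_set_sizes = setNames(sizes, c("reference", "study", "shared")))
    tabs <- generate_deg_tables(p)
    deg_filter_overlap(tabs$study, tabs$reference)
  }
  o1 <- ov(c(461L, 488L, 96L))
  expect_equal(o1$n_shared, 96L)
  expect_equal(o1$n_ref_only, 365L)
  expect_equal(o1$n_study_only, 392L)

  o2 <- ov(c(2L, 2L, 2L))
  expect_equal(c(o2$n_shared, o2$n_ref_only, o2$n_study_only), c(2L, 0L, 0L))

  o3 <- ov(c(3L, 5L, 0L))
  expect_equal(c(o3$n_shared, o3$n_ref_only, o3$n_study_only), c(0L, 3L, 5L))

  expect_error(sim_params(deg_set_sizes = c(3L, 5L, 4L)), "shared")
})

test_that("parameter validation rejects malformed settings", {
  expect_error(sim_params(pixel_size = 0), "pixel_size")
  expect_error(sim_params(gratio_mean_by_group = c(A = 1.2)), "g-ratio")
  expect_error(sim_params(zero_inflation = 1.5), "zero_inflation")
  expect_error(sim_params(composition_by_group = list(A = c(x = 0.6, y = 0.5))),
               "sum to 1")
  expect_error(sim_params(nucleus_radius_range = c(-1, 2)), "physical sizes")
})
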