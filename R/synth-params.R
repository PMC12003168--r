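#' Parameters for the synthetic data generators
#'
#' One parameter object drives all five generators (imaging scene, axon
#' table, bead counts, cell-type composition, DEG tables). Defaults describe
#' the study conditions the generators emulate: 512 x 512 px fields at
#' 0.3 µm/px with 50 nuclei and 3 plaques; three genotypes (WT, APPPS1 and
#' APPPS1 lacking IL-12 signalling, written `APPPS1.Il12b-/-`) with 3
#' animals each; 20 axons per EM image with genotype-specific g-ratio
#' means; zero-inflated bead counts; multinomial hippocampal cell-type
#' composition; and DEG tables sized to a reference/study signature overlap.
#'
#' The marker gradient plants a linear dependence of the Clec7a mean of each
#' Iba1-positive cell on its distance to the nearest plaque:
#' `true_mean = baseline + slope * distance_um`.
#'
#' @param rng_seed Integer seed. Each generator derives its own sub-seed
#'   from it (fixed documented offsets), so adding one generator call never
#'   perturbs the output of another.
#' @param image_shape Image height and width in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param n_nuclei,nucleus_radius_range Number of nuclei and their radius
#'   range (µm).
#' @param n_plaques,plaque_radius_range Number of plaques and the radius
#'   range (µm) of the disks whose union forms each plaque.
#' @param marker_gradient `c(baseline, slope)`: Clec7a true mean at distance
#'   0 and its change per micrometre of plaque distance.
#' @param iba1_pos_frac Fraction of nuclei that are Iba1-positive.
#' @param nucleus_mean_range True DAPI-channel mean range per nucleus.
#' @param iba1_neg_range,iba1_pos_range True Iba1 mean ranges for negative
#'   and positive cells (kept >= 5 noise SDs apart by validation).
#' @param plaque_amplitude Plaque-channel intensity of plaque pixels.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param noise_model `"gaussian"` (default) or `"poisson"`.
#' @param background_amplitude Amplitude of the smooth additive background.
#' @param n_axons Axons per EM image (the grid-sampling target).
#' @param n_animals Animals per group (all table generators).
#' @param gratio_mean_by_group,gratio_sd Named g-ratio means in (0,1) and
#'   the common truncated-normal SD.
#' @param axon_diameter_meanlog,axon_diameter_sdlog Lognormal parameters of
#'   the axon (inner) diameter, µm.
#' @param bead_rate_by_group Named Poisson rates of bead uptake.
#' @param zero_inflation Probability of a structural zero in bead counts.
#' @param n_fields,n_cells_per_field Fields per animal and microglia per
#'   field in the bead generator.
#' @param composition_by_group Named list of cell-type probability vectors
#'   (must share names and sum to 1).
#' @param n_cells_per_sample Multinomial size per sample.
#' @param deg_set_sizes `c(n_reference, n_study, n_shared)` significant-set
#'   sizes for the DEG-table generator.
#' @param deg_n_decoys Non-significant decoy genes added to each table.
#' @return A validated object of class `sim_params` (a named list).
#' @export
sim_params <- function(
    rng_seed = 1L,
    image_shape = c(512L, 512L),
    pixel_size = 0.3,
    n_nuclei = 50L,
    nucleus_radius_range = c(3, 5),
    n_plaques = 3L,
    plaque_radius_range = c(6, 12),
    marker_gradient = c(baseline = 200, slope = -1.5),
    iba1_pos_frac = 0.5,
    nucleus_mean_range = c(400, 600),
    iba1_neg_range = c(40, 80),
    iba1_pos_range = c(250, 350),
    plaque_amplitude = 800,
    noise_sd = 8,
    noise_model = c("gaussian", "poisson"),
    background_amplitude = 30,
    n_axons = 20L,
    n_animals = 3L,
    gratio_mean_by_group = c("WT" = 0.75, "APPPS1" = 0.85,
                             "APPPS1.Il12b-/-" = 0.77),
    gratio_sd = 0.05,
    axon_diameter_meanlog = log(0.8),
    axon_diameter_sdlog = 0.35,
    bead_rate_by_group = c("WT" = 4, "APPPS1" = 1.5,
                           "APPPS1.Il12b-/-" = 3.5),
    zero_inflation = 0.3,
    n_fields = 5L,
    n_cells_per_field = 30L,
    composition_by_group = NULL,
    n_cells_per_sample = 1000L,
    deg_set_sizes = c(reference = 461L, study = 488L, shared = 96L),
    deg_n_decoys = 500L) {
  noise_model <- match.arg(noise_model)
  if (is.null(composition_by_group)) {
    base <- c(ExN = 0.52, InN = 0.10, Astro = 0.12, Oligo = 0.12,
              OPC = 0.04, Micro = 0.06, Endo = 0.04)
    app <- c(ExN = 0.50, InN = 0.10, Astro = 0.12, Oligo = 0.08,
             OPC = 0.04, Micro = 0.12, Endo = 0.04)
    ko <- c(ExN = 0.51, InN = 0.10, Astro = 0.12, Oligo = 0.11,
            OPC = 0.04, Micro = 0.08, Endo = 0.04)
    composition_by_group <- list("WT" = base / sum(base),
                                 "APPPS1" = app / sum(app),
                                 "APPPS1.Il12b-/-" = ko / sum(ko))
  }
  p <- list(
    rng_seed = as.integer(rng_seed), image_shape = as.integer(image_shape),
    pixel_size = pixel_size, n_nuclei = as.integer(n_nuclei),
    nucleus_radius_range = nucleus_radius_range,
    n_plaques = as.integer(n_plaques),
    plaque_radius_range = plaque_radius_range,
    marker_gradient = setNames(as.numeric(marker_gradient),
                               c("baseline", "slope")),
    iba1_pos_frac = iba1_pos_frac,
    nucleus_mean_range = nucleus_mean_range,
    iba1_neg_range = iba1_neg_range, iba1_pos_range = iba1_pos_range,
    plaque_amplitude = plaque_amplitude, noise_sd = noise_sd,
    noise_model = noise_model, background_amplitude = background_amplitude,
    n_axons = as.integer(n_axons), n_animals = as.integer(n_animals),
    gratio_mean_by_group = gratio_mean_by_group, gratio_sd = gratio_sd,
    axon_diameter_meanlog = axon_diameter_meanlog,
    axon_diameter_sdlog = axon_diameter_sdlog,
    bead_rate_by_group = bead_rate_by_group,
    zero_inflation = zero_inflation, n_fields = as.integer(n_fields),
    n_cells_per_field = as.integer(n_cells_per_field),
    composition_by_group = composition_by_group,
    n_cells_per_sample = as.integer(n_cells_per_sample),
    deg_set_sizes = setNames(as.integer(deg_set_sizes),
                             c("reference", "study", "shared")),
    deg_n_decoys = as.integer(deg_n_decoys)
  )
  validate_sim_params(structure(p, class = "sim_params"))
}

#' Validate simulation parameters
#' @param p A `sim_params` object.
#' @return `p`, invisibly checked; stops on violation.
#' @export
validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  chk <- function(cond, msg) if (!cond) stop("sim_params: ", msg, call. = FALSE)
  chk(length(p$image_shape) == 2L && all(p$image_shape >= 8L),
      "image_shape must be two integers >= 8")
  chk(p$pixel_size > 0, "pixel_size must be > 0")
  chk(all(p$nucleus_radius_range > 0) && all(p$plaque_radius_range > 0),
      "all physical sizes must be > 0")
  chk(p$n_nuclei >= 0 && p$n_plaques >= 0, "object counts must be >= 0")
  chk(p$noise_sd >= 0 && p$background_amplitude >= 0,
      "noise_sd and background_amplitude must be >= 0")
  chk(p$iba1_pos_frac >= 0 && p$iba1_pos_frac <= 1,
      "iba1_pos_frac must be in [0, 1]")
  chk(min(p$iba1_pos_range) - max(p$iba1_neg_range) >= 5 * p$noise_sd,
      "Iba1 positive/negative means must be separated by >= 5 noise SDs")
  chk(all(p$gratio_mean_by_group > 0 & p$gratio_mean_by_group < 1),
      "g-ratio group means must lie in (0, 1)")
  chk(p$gratio_sd >= 0, "gratio_sd must be >= 0")
  chk(all(p$bead_rate_by_group >= 0), "bead rates must be >= 0")
  chk(p$zero_inflation >= 0 && p$zero_inflation <= 1,
      "zero_inflation must be in [0, 1]")
  nm <- names(p$composition_by_group[[1]])
  for (v in p$composition_by_group) {
    chk(abs(sum(v) - 1) <= 1e-9, "probability vectors must sum to 1")
    chk(all(v >= 0), "probabilities must be >= 0")
    chk(identical(names(v), nm), "composition vectors must share cell types")
  }
  s <- p$deg_set_sizes
  chk(s["shared"] <= min(s["reference"], s["study"]),
      "shared DEG set cannot exceed either full set")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  seed %d | image %d x %d px @ %g µm/px\n", x$rng_seed,
              x$image_shape[1], x$image_shape[2], x$pixel_size))
  cat(sprintf("  %d nuclei (r %g-%g µm), %d plaques (r %g-%g µm)\n",
              x$n_nuclei, x$nucleus_radius_range[1], x$nucleus_radius_range[2],
              x$n_plaques, x$plaque_radius_range[1], x$plaque_radius_range[2]))
  cat(sprintf("  marker gradient: baseline %g, slope %g per µm\n",
              x$marker_gradient["baseline"], x$marker_gradient["slope"]))
  cat(sprintf("  groups: %s\n",
              paste(names(x$gratio_mean_by_group), collapse = ", ")))
  invisible(x)
}

# Sub-seeding rule: each generator draws from seed rng_seed + offset, with
# fixed offsets documented here. Offsets are spaced so user seeds up to
# ~2e9 - 600 stay below .Machine$integer.max.
.SUBSEED <- c(scene = 101L, axons = 202L, beads = 303L,
              composition = 404L, degs = 505L)

.sub_seed <- function(p, what) {
  s <- (as.numeric(p$rng_seed) + .SUBSEED[[what]]) %% 2147483647
  as.integer(s)
}
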