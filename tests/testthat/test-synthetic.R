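test_that("simulated decays are deterministic in the seed and honest about noise", {
  comp <- lifetime_components(c(0.4, 3.2), c(0.6, 0.4))
  h1 <- simulate_decay(comp, total_photons = 2000, seed = 5)
  h2 <- simulate_decay(comp, total_photons = 2000, seed = 5)
  expect_identical(h1$counts, h2$counts)
  h3 <- simulate_decay(comp, total_photons = 2000, seed = 6)
  expect_false(identical(h1$counts, h3$counts))
  # zero photon budget -> all-zero histogram
  h0 <- simulate_decay(comp, total_photons = 0, seed = 1)
  expect_true(all(h0$counts == 0))
  # noise-free fluorescein decay matches the closed form
  p <- decay_to_phasor(simulate_decay(lifetime_components(4.04),
                                      total_photons = 1, noise_free = TRUE))
  truth <- single_exp_phasor(4.04, angular_frequency())
  expect_equal(c(p$g, p$s), c(truth$g, truth$s), tolerance = 1e-3)
  expect_error(simulate_decay(data.frame(tau = 1, fraction = 0.5)), "sum to 1")
  expect_error(simulate_decay(comp, total_photons = -5), ">= 0")
})

test_that("population images are pure functions of (spec, seed)", {
  args <- list(preset = condition_preset("E16"), n_cells = 3,
               frame = c(64, 64), cell_radius = 9, n_bins = 32L)
  a <- do.call(simulate_population, c(args, seed = 42))
  b <- do.call(simulate_population, c(args, seed = 42))
  expect_identical(a$image$counts, b$image$counts)
  expect_identical(a$rois$labels, b$rois$labels)
  expect_identical(a$truth, b$truth)
})

test_that("misconfigured presets fail fast on the metabolic ordering", {
  expect_error(condition_preset("neuron", mean_fraction = 0.8), "ordering")
  expect_error(condition_preset("KCN", mean_fraction = 0.5), "ordering")
  expect_error(condition_preset("glucose_high", mean_fraction = 0.45), "ordering")
  expect_error(condition_preset("H2O2", mean_fraction = 0.6), "ordering")
  # valid overrides pass
  expect_s3_class(condition_preset("neuron", mean_fraction = 0.45),
                  "condition_preset")
  expect_error(condition_preset("E12", sd_fraction = -1), "out of range")
  # defaults respect every stated direction
  mf <- function(cond) condition_preset(cond)$mean_fraction
  expect_true(mf("E12") > mf("E16") && mf("E16") > mf("neuron"))
  expect_true(mf("KCN") > mf("control") && mf("glucose_high") > mf("control"))
  expect_true(mf("control") > mf("H2O2") && mf("control") > mf("DCA"))
  expect_true(mf("glucose_high") > mf("glucose_low"))
})

test_that("condition presets shift populations in the documented directions", {
  cur <- species_cursor()
  mean_frac <- function(cond, seed) {
    mean(simulate_cell_records(cond, 25, cur, seed = seed)$free_fraction)
  }
  expect_gt(mean_frac("E12", 51), mean_frac("neuron", 52))
  expect_gt(mean_frac("KCN", 53), mean_frac("control", 54))
  expect_lt(mean_frac("DCA", 55), mean_frac("control", 56))
  expect_gt(mean_frac("glucose_high", 57), mean_frac("glucose_low", 58))
})

test_that("a one-compartment frame is homogeneous at the mixture phasor", {
  comp <- list(compartment_spec("cytoplasm", 0.6, 500, list(type = "full")))
  sim <- simulate_cell_image(comp, frame = c(16, 16), n_bins = 128L,
                             noise_free = TRUE)
  field <- image_phasor_field(sim$image, min_counts = 1)
  # oracle: intensity-weighted mix of the binned pure-species phasors
  pf <- decay_to_phasor(decay_histogram(oracle_exp_shape(0.4, 128L)))
  pb <- decay_to_phasor(decay_histogram(oracle_exp_shape(3.2, 128L)))
  mixed <- mix_phasors(list(pf, pb), c(0.6, 0.4))
  expect_equal(max(abs(field$g - mixed$g)), 0, tolerance = 1e-9)
  expect_equal(max(abs(field$s - mixed$s)), 0, tolerance = 1e-9)
})

test_that("phantom geometry is validated against the frame", {
  bad <- list(compartment_spec("nucleus", 0.8, 100,
                               list(type = "ellipse", center = c(5, 5),
                                    radii = c(10, 10))))
  expect_error(simulate_cell_image(bad, frame = c(16, 16), n_bins = 16L),
               "outside the frame")
  expect_error(
    simulate_population(condition_preset("E12"), n_cells = 50,
                        frame = c(64, 64), cell_radius = 15, n_bins = 16L),
    "cannot place"
  )
  expect_error(compartment_spec("x", 1.2, 10, list(type = "full")), "\\[0, 1\\]")
  expect_error(compartment_spec("x", 0.5, -1, list(type = "full")), ">= 0")
})

test_that("per-cell truth tables line up with the ROI labels", {
  pop <- simulate_population(condition_preset("E12"), n_cells = 5,
                             frame = c(96, 96), cell_radius = 10,
                             n_bins = 64L, seed = 61)
  expect_identical(pop$truth$roi_label, 1:5)
  expect_setequal(setdiff(unique(as.vector(pop$rois$labels)), 0L), 1:5)
  expect_true(all(pop$truth$group == "E12"))
  expect_true(all(pop$truth$true_fraction >= 0 & pop$truth$true_fraction <= 1))
  # cells do not overlap: each labelled pixel belongs to one cell and cell
  # areas match the disc area
  area <- sum(pop$rois$labels > 0)
  expect_equal(area / 5, pi * 10^2, tolerance = 0.05)
})

test_that("pipeline estimates recover per-cell fractions from noisy images", {
  pop <- simulate_population(condition_preset("E16"), n_cells = 8,
                             frame = c(128, 128), cell_radius = 12,
                             photons = 1e4, n_bins = 256L, seed = 62)
  field <- image_phasor_field(pop$image)
  cur <- species_cursor(n_bins = 256L)
  recs <- cell_phasors(field, pop$rois, cursor = cur)
  err <- recs$free_fraction - pop$truth$true_fraction[
    match(recs$roi_label, pop$truth$roi_label)
  ]
  expect_lte(mean(abs(err)), 0.02)
  expect_lte(abs(mean(err)), 0.01) # unbiased
})

test_that("the two-exponential bound pool stays on the analysis segment", {
  sim <- simulate_cell_image(
    compartments = list(compartment_spec("cytoplasm", 0.5, 3000,
                                         list(type = "full"))),
    bound_tau = c(1.8, 4.4), bound_weights = c(0.5, 0.5),
    frame = c(12, 12), n_bins = 128L, noise_free = TRUE
  )
  field <- image_phasor_field(sim$image, min_counts = 1)
  p <- phasor_point(field$g[1, 1], field$s[1, 1])
  expect_lte(semicircle_distance(p), 0.5 + 1e-6)
  # the effective bound phasor is the mix of the two bound components
  pf <- decay_to_phasor(decay_histogram(oracle_exp_shape(0.4, 128L)))
  pb <- mix_phasors(list(
    decay_to_phasor(decay_histogram(oracle_exp_shape(1.8, 128L))),
    decay_to_phasor(decay_histogram(oracle_exp_shape(4.4, 128L)))
  ), c(0.5, 0.5))
  cur <- species_cursor(free_ref = pf, bound_ref = pb)
  expect_equal(free_bound_fraction(p, cur), 0.5, tolerance = 1e-9)
})

test_that("frame stacks honour n_frames and the drift schedule", {
  stack <- simulate_frame_stack(two_cell_phantom(c(24, 24), photons = 200),
                                n_frames = 1, frame = c(24, 24),
                                n_bins = 32L, seed = 63)
  expect_length(stack$frames, 1)
  stack2 <- simulate_frame_stack(two_cell_phantom(c(24, 24), photons = 200),
                                 n_frames = 3, drift = -0.2,
                                 frame = c(24, 24), n_bins = 32L, seed = 64)
  tf <- stack2$truth
  cell1 <- tf[tf$compartment == "cell_1", ]
  expect_equal(cell1$true_fraction, c(0.7, 0.6, 0.5))
})
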