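test_that("cell phasors average pixel phasors with intensity weights", {
  # uniform ROI -> the common pixel phasor
  field <- make_field(matrix(0.4, 4, 4), matrix(0.3, 4, 4))
  rec <- cell_phasors(field, matrix(1L, 4, 4))
  expect_equal(rec$g_mean, 0.4)
  expect_equal(rec$s_mean, 0.3)
  expect_equal(rec$n_pixels, 16L)
  # two pixels with equal intensity at (1,0) and (0,0) -> (0.5, 0)
  g <- matrix(c(1, 0), 1, 2)
  s <- matrix(0, 1, 2)
  rec2 <- cell_phasors(make_field(g, s, intensity = matrix(50, 1, 2)),
                       matrix(1L, 1, 2))
  expect_equal(rec2$g_mean, 0.5)
  expect_equal(rec2$s_mean, 0)
  # unequal intensities shift the weighted mean but not the unweighted one
  f3 <- make_field(g, s, intensity = matrix(c(300, 100), 1, 2))
  expect_equal(cell_phasors(f3, matrix(1L, 1, 2))$g_mean, 0.75)
  expect_equal(cell_phasors(f3, matrix(1L, 1, 2), weighted = FALSE)$g_mean, 0.5)
})

test_that("the ROI phasor equals the phasor of the pooled ROI decay", {
  sim <- simulate_cell_image(
    compartments = default_cell_phantom(c(48, 48), photons = 800),
    frame = c(48, 48), n_bins = 128L, seed = 4
  )
  field <- image_phasor_field(sim$image, min_counts = 30)
  recs <- cell_phasors(field, sim$rois)
  for (id in recs$roi_label) {
    in_roi <- sim$rois$labels == id & !is.na(field$g)
    pooled <- numeric(sim$image$n_bins)
    for (k in seq_len(sim$image$n_bins)) {
      slab <- sim$image$counts[, , k]
      pooled[k] <- sum(slab[in_roi])
    }
    p <- decay_to_phasor(decay_histogram(pooled, period = sim$image$period))
    rec <- recs[recs$roi_label == id, ]
    expect_equal(rec$g_mean, p$g, tolerance = 1e-9)
    expect_equal(rec$s_mean, p$s, tolerance = 1e-9)
    expect_equal(rec$total_counts, sum(pooled))
  }
})

test_that("ROI bookkeeping is closed and empty ROIs error", {
  sim <- simulate_cell_image(
    compartments = default_cell_phantom(c(48, 48), photons = 800),
    frame = c(48, 48), n_bins = 64L, seed = 6
  )
  field <- image_phasor_field(sim$image, min_counts = 0)
  recs <- cell_phasors(field, sim$rois)
  labelled <- sum(sim$rois$labels > 0)
  expect_equal(sum(recs$n_pixels), labelled)
  # every labelled pixel belongs to exactly one ROI by construction
  expect_equal(labelled + sum(sim$rois$labels == 0), prod(sim$image$dim))
  # an ROI with no defined pixels errors
  labs <- sim$rois$labels
  dark <- labs == 0
  labs[which(dark)[1]] <- 99L
  field2 <- image_phasor_field(sim$image, min_counts = 30)
  expect_error(cell_phasors(field2, labs), "without defined pixels|no ROI")
})

test_that("phasor-plot regions back-project to the expected image pixels", {
  om <- angular_frequency()
  pa <- single_exp_phasor(0.4, om)  # free-like cluster
  pb <- single_exp_phasor(3.2, om)  # bound-like cluster
  set.seed(8)
  n <- 1200
  left <- matrix(FALSE, 30, 40)
  left[, 1:20] <- TRUE
  g <- ifelse(left, pa$g, pb$g) + rnorm(n, 0, 0.004)
  s <- ifelse(left, pa$s, pb$s) + rnorm(n, 0, 0.004)
  field <- make_field(matrix(g, 30, 40), matrix(s, 30, 40))
  # a region covering the whole semicircle selects every defined pixel
  all_mask <- phasor_cursor_select(field, list(center = c(0.5, 0), radius = 0.75))
  expect_true(all(all_mask))
  # two disjoint circles partition the clusters with < 1% cross-assignment
  ma <- phasor_cursor_select(field, list(center = c(pa$g, pa$s), radius = 0.05))
  mb <- phasor_cursor_select(field, list(center = c(pb$g, pb$s), radius = 0.05))
  expect_false(any(ma & mb))
  expect_lt(mean(ma[!left]), 0.01)
  expect_lt(mean(mb[left]), 0.01)
  expect_gt(mean(ma[left]), 0.99)
  # polygon regions work too (a box around the bound cluster)
  box <- cbind(g = pb$g + c(-0.05, 0.05, 0.05, -0.05),
               s = pb$s + c(-0.05, -0.05, 0.05, 0.05))
  mpoly <- phasor_cursor_select(field, list(vertices = box))
  expect_gt(mean(mpoly[!left]), 0.99)
  # undefined pixels are never selected
  g2 <- field$g
  g2[1, 1] <- NA_real_
  f2 <- make_field(g2, field$s)
  expect_false(phasor_cursor_select(f2, list(center = c(0.5, 0.25), radius = 1))[1, 1])
})

test_that("bound-end selection on the phantom concentrates on mitochondria", {
  sim <- simulate_cell_image(
    compartments = default_cell_phantom(c(96, 96), photons = 1e4),
    frame = c(96, 96), n_bins = 64L, seed = 10
  )
  field <- image_phasor_field(sim$image)
  pb <- decay_to_phasor(
    decay_histogram(oracle_exp_shape(3.2, 64L), period = 12.5)
  )
  # region around the bound-rich mitochondrial mixture (fraction 0.30)
  mito_id <- sim$truth$roi_label[sim$truth$compartment == "mitochondria"]
  mito_p <- cell_phasor(field, sim$rois, mito_id)
  mask <- phasor_cursor_select(
    field, list(center = c(mito_p$g_mean, mito_p$s_mean), radius = 0.03)
  )
  expect_gt(mean(sim$rois$labels[mask] == mito_id), 0.9)
})

test_that("identical repeated frames give delta_g = 0 and no drift", {
  sim <- simulate_cell_image(
    compartments = two_cell_phantom(c(32, 32), photons = 2000),
    frame = c(32, 32), n_bins = 64L, seed = 12
  )
  frames <- rep(list(sim$image), 6)
  st <- frame_stability(frames, sim$rois, frame_group_size = 2L)
  expect_equal(st$summary$delta_g, rep(0, nrow(st$summary)))
  expect_false(any(st$summary$drift_detected))
  expect_error(frame_stability(frames[1:2], sim$rois, frame_group_size = 2L),
               "at least 2")
})

test_that("Poisson-only stacks are stationary; injected drift is detected", {
  stack <- simulate_frame_stack(
    two_cell_phantom(c(48, 48), photons = 400), n_frames = 70,
    frame = c(48, 48), n_bins = 128L, seed = 14
  )
  st <- frame_stability(stack$frames, stack$rois, frame_group_size = 10L)
  # no monotone drift: the 95% CI of the g trend contains 0 for every cell
  expect_true(all(st$summary$slope_lo <= 0 & st$summary$slope_hi >= 0))
  # delta_g is at the shot-noise scale, far below the cell separation
  expect_lt(max(st$summary$delta_g), 0.01)
  # drift toward the bound end (fraction falls) lowers g monotonically
  drifted <- simulate_frame_stack(
    two_cell_phantom(c(48, 48), photons = 400), n_frames = 70,
    drift = -0.3, frame = c(48, 48), n_bins = 128L, seed = 15
  )
  std <- frame_stability(drifted$frames, drifted$rois, frame_group_size = 10L)
  expect_true(all(std$summary$drift_detected))
  expect_true(all(std$summary$slope < 0))
  # accessors
  expect_s3_class(tidy(std), "tbl_df")
  expect_identical(glance(std), std$summary)
})

test_that("cell phasors beat single pixels on noise (variance ~ 1/n_pixels)", {
  comps <- two_cell_phantom(c(32, 32), photons = 300)
  reps <- 40
  cellg <- numeric(reps)
  pixg <- numeric(reps)
  set.seed(16)
  for (i in seq_len(reps)) {
    sim <- simulate_cell_image(compartments = comps, frame = c(32, 32),
                               n_bins = 64L)
    field <- image_phasor_field(sim$image)
    rec <- cell_phasors(field, sim$rois)
    cellg[i] <- rec$g_mean[rec$roi_label == 1]
    px <- which(sim$rois$labels == 1, arr.ind = TRUE)[1, ]
    pixg[i] <- field$g[px[1], px[2]]
  }
  n_pix <- sum(sim$rois$labels == 1)
  ratio <- var(pixg) / var(cellg)
  expect_gt(ratio, n_pix / 2)
  expect_lt(ratio, n_pix * 2)
})
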