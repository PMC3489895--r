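test_that("single-exponential phasors obey the universal-circle geometry", {
  om <- angular_frequency()
  p0 <- single_exp_phasor(0, om)
  expect_identical(c(p0$g, p0$s), c(1, 0))
  pinf <- single_exp_phasor(Inf, om)
  expect_identical(c(pinf$g, pinf$s), c(0, 0))
  papex <- single_exp_phasor(1 / om, om)
  expect_equal(c(papex$g, papex$s), c(0.5, 0.5))
  for (tau in c(0.01, 0.1, 0.4, 1, 2.5, 3.2, 4.04, 10, 40, 100)) {
    p <- single_exp_phasor(tau, om)
    expect_lt(abs(semicircle_distance(p) - 0.5), 1e-12)
    expect_gte(p$s, 0)
  }
  expect_error(single_exp_phasor(-1, om), "non-negative")
})

test_that("higher harmonics equal the first harmonic at scaled frequency", {
  om <- angular_frequency()
  for (n in 2:4) {
    pn <- single_exp_phasor(2.2, angular_frequency(harmonic = n), harmonic = n)
    p1 <- single_exp_phasor(2.2, n * om)
    expect_equal(c(pn$g, pn$s), c(p1$g, p1$s))
  }
  # and the discrete transform agrees at harmonic 2 within binning tolerance
  h <- oracle_mix_hist(2.2, 1, n_bins = 512L)
  p2 <- decay_to_phasor(h, harmonic = 2L)
  ref <- single_exp_phasor(2.2, 2 * om)
  expect_equal(c(p2$g, p2$s), c(ref$g, ref$s), tolerance = 1e-3)
})

test_that("decay_to_phasor reproduces Fourier limits and the closed form", {
  # delta at t ~ 0 on a fine grid -> (1, 0)
  counts <- numeric(4096)
  counts[1L] <- 1000
  pd <- decay_to_phasor(decay_histogram(counts))
  expect_equal(c(pd$g, pd$s), c(1, 0), tolerance = 1e-3)
  # refining the grid tightens the limit
  counts2 <- numeric(16384)
  counts2[1L] <- 1000
  pd2 <- decay_to_phasor(decay_histogram(counts2))
  expect_lt(abs(pd2$s), abs(pd$s))
  # uniform counts over the full period -> (0, 0) (exact at mid-bin sampling)
  pu <- decay_to_phasor(decay_histogram(rep(7, 256)))
  expect_equal(c(pu$g, pu$s), c(0, 0), tolerance = 1e-12)
  # wrapped 4.04 ns mono-exponential at 80 MHz, 256 bins: closed form
  # g = 1/(1+(wt)^2) = 0.1952, s = wt g = 0.3964
  p404 <- decay_to_phasor(oracle_mix_hist(4.04, 1))
  expect_equal(p404$g, 0.1952, tolerance = 1e-3)
  expect_equal(p404$s, 0.3964, tolerance = 1e-3)
  # empty pixel -> undefined marker, never (0, 0)
  pz <- decay_to_phasor(decay_histogram(numeric(64)))
  expect_true(is_undefined(pz))
})

test_that("malformed histograms and harmonics are rejected", {
  expect_error(decay_histogram(c(-1, 2, 3)), "non-negative")
  expect_error(decay_histogram(1:4, bin_centers = c(1, 3, 2, 4)), "increasing")
  expect_error(decay_histogram(1:4, bin_centers = c(0, 4, 8, 13)), "period")
  h <- decay_histogram(1:4)
  expect_error(decay_to_phasor(h, harmonic = 0), "positive integer")
  expect_error(decay_to_phasor(h, harmonic = 1.5), "positive integer")
})

test_that("mixture algebra matches direct decay synthesis (linearity)", {
  om <- angular_frequency()
  # trivial: midpoint and identity
  mid <- mix_phasors(list(phasor_point(1, 0), phasor_point(0, 0)), c(0.5, 0.5))
  expect_equal(c(mid$g, mid$s), c(0.5, 0))
  one <- mix_phasors(list(phasor_point(0.3, 0.4)), 1)
  expect_equal(c(one$g, one$s), c(0.3, 0.4))
  # 100 random 2-4 component mixtures: phasor of the synthesized decay
  # equals the intensity-weighted mix of the component phasors to 1e-6
  set.seed(42)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    taus <- runif(k, 0.2, 6)
    fr <- rexp(k)
    fr <- fr / sum(fr)
    direct <- decay_to_phasor(oracle_mix_hist(taus, fr))
    comp_pts <- lapply(taus, function(tau) decay_to_phasor(oracle_mix_hist(tau, 1)))
    mixed <- mix_phasors(comp_pts, fr)
    expect_equal(c(direct$g, direct$s), c(mixed$g, mixed$s), tolerance = 1e-6)
  }
})

test_that("mix_phasors validates fractions and harmonics", {
  expect_error(
    mix_phasors(list(phasor_point(1, 0), phasor_point(0, 0, harmonic = 2L)),
                c(0.5, 0.5)),
    "same harmonic"
  )
  expect_error(
    mix_phasors(list(phasor_point(1, 0), phasor_point(0, 0)), c(0.6, 0.6)),
    "sum to 1"
  )
  expect_error(
    mix_phasors(list(phasor_point(1, 0), phasor_point(0, 0)), c(1.2, -0.2)),
    "non-negative"
  )
})

test_that("noise-free multi-exponential phasors stay inside the semicircle", {
  # mid-bin sampling without a sinc correction inflates the modulation by
  # about (w dt)^2 / 24 relative, i.e. up to ~8e-5 absolute at 256 bins;
  # the geometric bound is tested at that discretization tolerance, and at
  # 1e-6 on a grid fine enough for the correction to be negligible
  set.seed(7)
  for (i in 1:50) {
    k <- sample(1:5, 1)
    taus <- 10^runif(k, -1, 2)
    fr <- rexp(k)
    fr <- fr / sum(fr)
    p <- decay_to_phasor(oracle_mix_hist(taus, fr, n_bins = 256L))
    expect_lte(semicircle_distance(p), 0.5 + 1e-4)
    expect_gte(p$s, -1e-9)
    p_fine <- decay_to_phasor(oracle_mix_hist(taus, fr, n_bins = 8192L))
    expect_lte(semicircle_distance(p_fine), 0.5 + 1e-6)
    expect_gte(p_fine$s, -1e-9)
  }
})

test_that("phase and modulation lifetimes invert the single-exponential map", {
  om <- angular_frequency()
  lt <- phase_mod_lifetimes(phasor_point(0.5, 0.5))
  expect_equal(lt$tau_phase, 1 / om)
  expect_equal(lt$tau_mod, 1 / om)
  lt0 <- phase_mod_lifetimes(phasor_point(1, 0))
  expect_equal(c(lt0$tau_phase, lt0$tau_mod), c(0, 0))
  # read-back of the binned fluorescein decay
  ltf <- phase_mod_lifetimes(decay_to_phasor(oracle_mix_hist(4.04, 1)))
  expect_equal(ltf$tau_phase, 4.04, tolerance = 0.01 / 4.04)
  # domain errors
  expect_error(phase_mod_lifetimes(phasor_point(-0.1, 0.2)), "g > 0")
  expect_error(phase_mod_lifetimes(phasor_point(0.9, 0.9)), "<= 1")
  # inside the semicircle, tau_phase < tau_mod (multi-exponential signature)
  pmix <- decay_to_phasor(oracle_mix_hist(c(0.4, 3.2), c(0.5, 0.5)))
  ltm <- phase_mod_lifetimes(pmix)
  expect_lt(ltm$tau_phase, ltm$tau_mod)
})

test_that("the mean phasor of Poisson realizations shows shot-noise scaling", {
  comp <- lifetime_components(c(0.4, 3.2), c(0.6, 0.4))
  g_at <- function(photons, seed) {
    set.seed(seed)
    vapply(1:150, function(i) {
      decay_to_phasor(simulate_decay(comp, total_photons = photons))$g
    }, numeric(1))
  }
  g_lo <- g_at(400, 1)
  g_hi <- g_at(1600, 2)
  # 4x the photons halves the standard deviation (allow generous slack)
  ratio <- sd(g_lo) / sd(g_hi)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.7)
  # and the mean converges on the noise-free phasor
  p_true <- decay_to_phasor(simulate_decay(comp, total_photons = 1, noise_free = TRUE))
  expect_equal(mean(g_hi), p_true$g, tolerance = 5 * sd(g_hi) / sqrt(length(g_hi)) / p_true$g)
})
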