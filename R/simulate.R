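#' Instrument-response specification
#'
#' A simple instrument response model: a timing offset plus Gaussian pulse
#' broadening, applied as a circular convolution over the excitation
#' period. The defaults (0.5 ns shift, 0.15 ns sigma) exercise the
#' calibration stage nontrivially; [delta_irf()] gives the ideal
#' instrument used by closed-form tests.
#'
#' @param shift Time shift in ns.
#' @param sigma Gaussian broadening width in ns, `>= 0`.
#' @return An object of class `irf_spec`.
#' @export
irf_spec <- function(shift = 0.5, sigma = 0.15) {
  if (!is.numeric(sigma) || sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  structure(list(shift = shift, sigma = sigma), class = "irf_spec")
}

#' @rdname irf_spec
#' @export
delta_irf <- function() irf_spec(shift = 0, sigma = 0)

#' Lifetime components of a multi-exponential decay
#'
#' @param tau Lifetimes in ns, `>= 0`.
#' @param fraction Intensity-weighted fractional contributions, summing
#'   to 1.
#' @return A tibble with columns `tau` and `fraction`.
#' @export
lifetime_components <- function(tau, fraction = rep(1 / length(tau), length(tau))) {
  tau <- as.numeric(tau)
  fraction <- as.numeric(fraction)
  if (length(tau) != length(fraction) || length(tau) == 0L) {
    stop("`tau` and `fraction` must have equal positive length", call. = FALSE)
  }
  if (anyNA(tau) || any(tau < 0)) stop("lifetimes must be >= 0", call. = FALSE)
  if (any(fraction < 0) || abs(sum(fraction) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  tibble::tibble(tau = tau, fraction = fraction)
}

# Expected per-bin counts (normalized to sum 1) of a periodically wrapped
# multi-exponential decay circularly convolved with the IRF. Computed on an
# oversampled grid; the IRF enters through its exact Fourier factor
# exp(-sigma^2 w^2 / 2 - 1i w shift), so a pure time shift acts exactly as
# the shift theorem at every harmonic.
expected_decay_shape <- function(components, irf = delta_irf(),
                                 n_bins = 256L, period = 12.5,
                                 oversample = 16L) {
  stopifnot(inherits(irf, "irf_spec"))
  m <- n_bins * oversample
  t_fine <- default_bin_centers(m, period)
  base <- numeric(m)
  for (i in seq_len(nrow(components))) {
    tau <- components$tau[i]
    f <- components$fraction[i]
    if (f == 0) next
    if (tau == 0) {
      comp <- numeric(m)
      comp[1L] <- 1
    } else {
      comp <- exp(-t_fine / tau)
      comp <- comp / sum(comp)
    }
    base <- base + f * comp
  }
  if (irf$shift != 0 || irf$sigma > 0) {
    j <- 0:(m - 1L)
    n_signed <- ifelse(j <= m / 2, j, j - m)
    w <- 2 * pi * n_signed / period
    fac <- exp(-0.5 * (irf$sigma * w)^2) * exp(-1i * w * irf$shift)
    base <- Re(stats::fft(stats::fft(base) * fac, inverse = TRUE)) / m
    base[base < 0] <- 0
  }
  shape <- colSums(matrix(base, nrow = oversample))
  shape / sum(shape)
}

#' Simulate a TCSPC decay histogram
#'
#' Generates the expected counts of a periodically wrapped
#' multi-exponential decay, circularly convolved with the instrument
#' response, scaled to a photon budget, and Poisson-sampled. With
#' `noise_free = TRUE` the expected (non-integer) counts are returned,
#' the oracle mode used for closed-form checks.
#'
#' @param components A [lifetime_components()] tibble (or a data frame
#'   with `tau` and `fraction`).
#' @param irf An [irf_spec()]; default the ideal delta instrument.
#' @param total_photons Expected total photons (`>= 0`); 0 gives the
#'   all-zero histogram.
#' @param n_bins,period Time grid (defaults 256 bins over 12.5 ns, the
#'   80 MHz TCSPC dialect).
#' @param seed Optional RNG seed; the output is a pure function of
#'   (arguments, seed).
#' @param noise_free Return expected counts instead of Poisson draws.
#' @return A [decay_histogram()].
#' @examples
#' h <- simulate_decay(lifetime_components(4.04), total_photons = 1e5, seed = 1)
#' decay_to_phasor(h)
#' @export
simulate_decay <- function(components, irf = delta_irf(), total_photons = 500,
                           n_bins = 256L, period = 12.5, seed = NULL,
                           noise_free = FALSE) {
  if (!is.data.frame(components)) {
    stop("`components` must be a lifetime_components data frame", call. = FALSE)
  }
  components <- lifetime_components(components$tau, components$fraction)
  if (!is.numeric(total_photons) || total_photons < 0) {
    stop("`total_photons` must be >= 0", call. = FALSE)
  }
  shape <- expected_decay_shape(components, irf, n_bins = n_bins, period = period)
  lambda <- shape * total_photons
  counts <- if (noise_free) {
    lambda
  } else {
    if (!is.null(seed)) set.seed(seed)
    stats::rpois(n_bins, lambda)
  }
  decay_histogram(counts, period = period)
}

#' Compartment of a synthetic cell phantom
#'
#' @param name Compartment tag: `"background"`, `"cytoplasm"`,
#'   `"nucleus"` or `"mitochondria"`.
#' @param free_fraction True free-NADH fractional intensity in `[0, 1]`.
#' @param photons Mean photons per pixel, `>= 0`.
#' @param geometry `list(type = "full")` (covers the frame),
#'   `list(type = "ellipse", center = c(row, col), radii = c(a, b))`, or
#'   `list(type = "annulus", center = c(row, col), inner, outer)`; in
#'   pixels. Later compartments overwrite earlier ones.
#' @return An object of class `compartment_spec`.
#' @export
compartment_spec <- function(name, free_fraction, photons, geometry) {
  stopifnot(is.character(name), length(name) == 1L)
  if (free_fraction < 0 || free_fraction > 1) {
    stop("`free_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (photons < 0) stop("`photons` must be >= 0", call. = FALSE)
  if (!is.list(geometry) || is.null(geometry$type)) {
    stop("`geometry` must be a list with a `type`", call. = FALSE)
  }
  structure(list(name = name, free_fraction = free_fraction,
                 photons = photons, geometry = geometry),
            class = "compartment_spec")
}

#' Default single-cell NADH phantom
#'
#' A cell mimicking the canonical NADH autofluorescence phenotype: a dim,
#' free-NADH-rich nucleus (fraction 0.8) and a bright, bound-NADH-rich
#' mitochondrial region (fraction 0.3) inside a cytoplasm, over a sparse
#' background.
#'
#' @param frame Frame size `c(rows, cols)`.
#' @param photons Reference photons per pixel for the cytoplasm; the
#'   nucleus is dimmer (0.6 x) and the mitochondria brighter (1.6 x).
#' @return A list of [compartment_spec()]s.
#' @export
default_cell_phantom <- function(frame = c(256L, 256L), photons = 500) {
  ctr <- (frame + 1) / 2
  r <- min(frame) / 2
  list(
    compartment_spec("background", 0.5, photons * 0.004,
                     list(type = "full")),
    compartment_spec("cytoplasm", 0.55, photons,
                     list(type = "ellipse", center = ctr, radii = c(0.72 * r, 0.78 * r))),
    compartment_spec("mitochondria", 0.30, photons * 1.6,
                     list(type = "annulus", center = ctr, inner = 0.30 * r, outer = 0.52 * r)),
    compartment_spec("nucleus", 0.80, photons * 0.6,
                     list(type = "ellipse", center = ctr, radii = c(0.24 * r, 0.24 * r)))
  )
}

compartment_mask <- function(geom, frame) {
  rows <- matrix(seq_len(frame[1L]), frame[1L], frame[2L])
  cols <- matrix(seq_len(frame[2L]), frame[1L], frame[2L], byrow = TRUE)
  if (geom$type == "full") {
    return(matrix(TRUE, frame[1L], frame[2L]))
  }
  ctr <- geom$center
  if (geom$type == "ellipse") {
    a <- geom$radii[1L]
    b <- geom$radii[2L]
    if (ctr[1L] - a < 0.5 || ctr[1L] + a > frame[1L] + 0.5 ||
        ctr[2L] - b < 0.5 || ctr[2L] + b > frame[2L] + 0.5) {
      stop("compartment geometry extends outside the frame", call. = FALSE)
    }
    return(((rows - ctr[1L]) / a)^2 + ((cols - ctr[2L]) / b)^2 <= 1)
  }
  if (geom$type == "annulus") {
    if (ctr[1L] - geom$outer < 0.5 || ctr[1L] + geom$outer > frame[1L] + 0.5 ||
        ctr[2L] - geom$outer < 0.5 || ctr[2L] + geom$outer > frame[2L] + 0.5) {
      stop("compartment geometry extends outside the frame", call. = FALSE)
    }
    d <- sqrt((rows - ctr[1L])^2 + (cols - ctr[2L])^2)
    return(d > geom$inner & d <= geom$outer)
  }
  stop(sprintf("unknown geometry type '%s'", geom$type), call. = FALSE)
}

free_bound_components <- function(free_fraction, free_tau = 0.4,
                                  bound_tau = 3.2,
                                  bound_weights = rep(1 / length(bound_tau), length(bound_tau))) {
  lifetime_components(
    tau = c(free_tau, bound_tau),
    fraction = c(free_fraction, (1 - free_fraction) * bound_weights)
  )
}

#' Simulate a FLIM image of a cell phantom
#'
#' Builds a TCSPC image from compartment specifications: each pixel draws
#' Poisson counts around the expected decay of its compartment's
#' free/bound-NADH mixture. Compartments are painted in order, later ones
#' overwriting earlier ones. Also emits the ground-truth label image and
#' per-compartment truth table.
#'
#' @param compartments A list of [compartment_spec()]s (default
#'   [default_cell_phantom()]).
#' @param free_tau,bound_tau Species lifetimes in ns (defaults 0.4 and
#'   3.2). `bound_tau` may be a vector (with `bound_weights`) to model the
#'   multi-exponential protein-bound pool.
#' @param bound_weights Relative weights of the bound components.
#' @param irf An [irf_spec()] (default ideal).
#' @param frame Frame size `c(rows, cols)` (default 256 x 256).
#' @param n_bins,period Time grid.
#' @param rep_rate_MHz Repetition rate metadata; `period` defaults to its
#'   inverse.
#' @param seed Optional RNG seed.
#' @param noise_free Use expected counts (no Poisson sampling).
#' @return A list: `image` ([flim_image()]), `rois` ([roi_set()] labelling
#'   non-background compartments), `truth` (tibble with `roi_label`,
#'   `compartment`, `true_fraction`, `photons`).
#' @examples
#' sim <- simulate_cell_image(frame = c(64, 64), n_bins = 64, seed = 1)
#' sim$truth
#' @export
simulate_cell_image <- function(compartments = default_cell_phantom(frame),
                                free_tau = 0.4, bound_tau = 3.2,
                                bound_weights = rep(1 / length(bound_tau), length(bound_tau)),
                                irf = delta_irf(), frame = c(256L, 256L),
                                n_bins = 256L, rep_rate_MHz = 80,
                                period = 1000 / rep_rate_MHz,
                                seed = NULL, noise_free = FALSE) {
  stopifnot(is.list(compartments), length(compartments) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  assign_id <- matrix(0L, frame[1L], frame[2L]) # index into compartments
  for (i in seq_along(compartments)) {
    sp <- compartments[[i]]
    stopifnot(inherits(sp, "compartment_spec"))
    assign_id[compartment_mask(sp$geometry, frame)] <- i
  }
  counts <- array(0, dim = c(frame[1L], frame[2L], n_bins))
  cm <- matrix(counts, nrow = prod(frame), ncol = n_bins)
  for (i in seq_along(compartments)) {
    px <- which(as.vector(assign_id) == i)
    if (!length(px)) next
    sp <- compartments[[i]]
    shape <- expected_decay_shape(
      free_bound_components(sp$free_fraction, free_tau, bound_tau, bound_weights),
      irf, n_bins = n_bins, period = period
    )
    lambda <- outer(rep(sp$photons, length(px)), shape)
    cm[px, ] <- if (noise_free) lambda else {
      matrix(stats::rpois(length(lambda), lambda), nrow = length(px))
    }
  }
  img <- flim_image(array(cm, dim = c(frame[1L], frame[2L], n_bins)),
                    period = period, rep_rate_MHz = rep_rate_MHz)
  names_ <- vapply(compartments, `[[`, character(1), "name")
  fg <- which(names_ != "background")
  labels <- matrix(0L, frame[1L], frame[2L])
  truth <- tibble::tibble(roi_label = integer(), compartment = character(),
                          true_fraction = numeric(), photons = numeric())
  for (k in seq_along(fg)) {
    i <- fg[k]
    labels[assign_id == i] <- k
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      roi_label = k, compartment = names_[i],
      true_fraction = compartments[[i]]$free_fraction,
      photons = compartments[[i]]$photons
    ))
  }
  rois <- roi_set(labels, stats::setNames(truth$compartment, truth$roi_label))
  list(image = img, rois = rois, truth = truth)
}

#' Metabolic condition presets
#'
#' Population-level presets for the generator: the mean per-cell free-NADH
#' fraction, its between-cell spread, and the photon budget. Values encode
#' the qualitative topology of NADH metabolic imaging — progenitors above
#' neurons along the metabolic trajectory (E12 > E16 > neuron), respiration
#' block (KCN) and high glucose above control, oxidative stress (H2O2) and
#' glycolysis inhibition (DCA) below — and are configuration, not measured
#' biology. The ordering constraints are asserted at construction so a
#' misconfigured preset fails fast.
#'
#' @param condition One of `"E12"`, `"E16"`, `"neuron"`, `"control"`,
#'   `"KCN"`, `"H2O2"`, `"glucose_high"`, `"glucose_low"`, `"DCA"`.
#' @param mean_fraction Optional override of the mean free fraction; must
#'   still satisfy the ordering constraints against the defaults of the
#'   related conditions.
#' @param sd_fraction Between-cell standard deviation (default 0.05).
#' @param photons Photons per pixel (default 500).
#' @return An object of class `condition_preset`.
#' @examples
#' condition_preset("E12")
#' @export
condition_preset <- function(condition, mean_fraction = NULL,
                             sd_fraction = 0.05, photons = 500) {
  defaults <- c(
    E12 = 0.70, E16 = 0.60, neuron = 0.40,
    control = 0.55, KCN = 0.70, H2O2 = 0.40,
    glucose_low = 0.50, glucose_high = 0.60, DCA = 0.40
  )
  condition <- match.arg(condition, names(defaults))
  mf <- if (is.null(mean_fraction)) defaults[[condition]] else mean_fraction
  if (mf < 0 || mf > 1 || sd_fraction < 0 || sd_fraction > 0.5 || photons < 0) {
    stop("preset parameters out of range", call. = FALSE)
  }
  vals <- defaults
  vals[[condition]] <- mf
  ok <- vals[["E12"]] > vals[["E16"]] && vals[["E16"]] > vals[["neuron"]] &&
    vals[["KCN"]] > vals[["control"]] &&
    vals[["glucose_high"]] > vals[["control"]] &&
    vals[["glucose_high"]] > vals[["glucose_low"]] &&
    vals[["control"]] > vals[["H2O2"]] && vals[["control"]] > vals[["DCA"]]
  if (!ok) {
    stop("misconfigured preset: metabolic ordering constraint violated ",
         "(need E12 > E16 > neuron and KCN/glucose_high > control > H2O2/DCA)",
         call. = FALSE)
  }
  structure(list(condition = condition, mean_fraction = mf,
                 sd_fraction = sd_fraction, photons = photons),
            class = "condition_preset")
}

#' @export
print.condition_preset <- function(x, ...) {
  cat(sprintf(
    "<condition_preset> %s: free fraction %.2f +/- %.2f, %g photons/pixel\n",
    x$condition, x$mean_fraction, x$sd_fraction, x$photons
  ))
  invisible(x)
}

rtrunc_norm01 <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0 | out > 1)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < 0 | out > 1)
  }
  out
}

#' Simulate a multi-cell population frame
#'
#' Places `n_cells` non-overlapping circular cells in a frame; each cell
#' draws a true free-NADH fraction from the preset's truncated-normal
#' between-cell distribution and every cell pixel draws Poisson counts
#' around the matching mixture decay. Emits the image, the ground-truth
#' ROI labels (group = condition tag) and the per-cell truth table.
#'
#' @param preset A [condition_preset()] (or a condition name).
#' @param n_cells Number of cells (default 20).
#' @param frame Frame size (default 256 x 256).
#' @param cell_radius Cell radius in pixels (default 17, about 900
#'   pixels per cell).
#' @param photons Photons per pixel; defaults to the preset's budget.
#' @param free_tau,bound_tau,bound_weights,irf,n_bins,rep_rate_MHz,period
#'   As in [simulate_cell_image()].
#' @param background_photons Mean background photons per pixel (default
#'   2; below any sensible `min_counts` so background pixels are
#'   undefined).
#' @param seed Optional RNG seed.
#' @param noise_free Use expected counts.
#' @return A list: `image`, `rois`, `truth` (tibble with `roi_label`,
#'   `group`, `true_fraction`, `photons`).
#' @examples
#' pop <- simulate_population("E12", n_cells = 4, frame = c(64, 64),
#'                            cell_radius = 10, n_bins = 64, seed = 1)
#' pop$truth
#' @export
simulate_population <- function(preset = condition_preset("E12"), n_cells = 20L,
                                frame = c(256L, 256L), cell_radius = 17,
                                photons = NULL,
                                free_tau = 0.4, bound_tau = 3.2,
                                bound_weights = rep(1 / length(bound_tau), length(bound_tau)),
                                irf = delta_irf(), n_bins = 256L,
                                rep_rate_MHz = 80, period = 1000 / rep_rate_MHz,
                                background_photons = 2,
                                seed = NULL, noise_free = FALSE) {
  if (is.character(preset)) preset <- condition_preset(preset)
  stopifnot(inherits(preset, "condition_preset"), n_cells >= 1L)
  if (is.null(photons)) photons <- preset$photons
  if (!is.null(seed)) set.seed(seed)
  centers <- pack_cells(n_cells, frame, cell_radius)
  fractions <- rtrunc_norm01(n_cells, preset$mean_fraction, preset$sd_fraction)
  compartments <- c(
    list(compartment_spec("background", 0.5, background_photons,
                          list(type = "full"))),
    purrr::map(seq_len(n_cells), function(i) {
      compartment_spec(
        paste0("cell_", i), fractions[i], photons,
        list(type = "ellipse", center = centers[i, ],
             radii = c(cell_radius, cell_radius))
      )
    })
  )
  sim <- simulate_cell_image(
    compartments, free_tau = free_tau, bound_tau = bound_tau,
    bound_weights = bound_weights, irf = irf, frame = frame,
    n_bins = n_bins, rep_rate_MHz = rep_rate_MHz, period = period,
    seed = NULL, noise_free = noise_free
  )
  truth <- tibble::tibble(
    roi_label = seq_len(n_cells), group = preset$condition,
    true_fraction = fractions, photons = photons
  )
  rois <- roi_set(sim$rois$labels,
                  stats::setNames(rep(preset$condition, n_cells), seq_len(n_cells)))
  list(image = sim$image, rois = rois, truth = truth)
}

# jittered-grid placement of non-overlapping circles; errors when the
# frame cannot hold them
pack_cells <- function(n_cells, frame, radius) {
  pitch <- 2 * radius + 3
  n_rows <- floor((frame[1L] - 1) / pitch)
  n_cols <- floor((frame[2L] - 1) / pitch)
  if (n_rows * n_cols < n_cells) {
    stop(sprintf("cannot place %d cells of radius %g in a %d x %d frame",
                 n_cells, radius, frame[1L], frame[2L]), call. = FALSE)
  }
  slots <- expand.grid(r = seq_len(n_rows), c = seq_len(n_cols))
  slots <- slots[sample.int(nrow(slots), n_cells), , drop = FALSE]
  jitter_max <- (pitch - 2 * radius - 1) / 2
  cbind(
    (slots$r - 0.5) * pitch + stats::runif(n_cells, -jitter_max, jitter_max) + 0.5,
    (slots$c - 0.5) * pitch + stats::runif(n_cells, -jitter_max, jitter_max) + 0.5
  )
}

#' Simulate repeated frames of one phantom
#'
#' Independent Poisson realizations of a fixed phantom, emulating
#' repeated scanning of the same field of view. An optional linear drift
#' of the true free fraction across the stack provides a positive control
#' for the drift detector in [frame_stability()].
#'
#' @param compartments Phantom compartments (default a two-cell field).
#' @param n_frames Number of frames (default 70).
#' @param drift Total change of every compartment's free fraction from
#'   the first to the last frame (default 0; negative values drift toward
#'   the bound end).
#' @param frame,free_tau,bound_tau,irf,n_bins,rep_rate_MHz,period As in
#'   [simulate_cell_image()].
#' @param seed Optional RNG seed.
#' @return A list: `frames` (list of [flim_image()]), `rois`, `truth`
#'   (per-frame per-compartment tibble).
#' @export
simulate_frame_stack <- function(compartments = two_cell_phantom(frame),
                                 n_frames = 70L, drift = 0,
                                 frame = c(64L, 64L),
                                 free_tau = 0.4, bound_tau = 3.2,
                                 irf = delta_irf(), n_bins = 256L,
                                 rep_rate_MHz = 80, period = 1000 / rep_rate_MHz,
                                 seed = NULL) {
  stopifnot(n_frames >= 1L)
  if (!is.null(seed)) set.seed(seed)
  truth <- NULL
  frames <- vector("list", n_frames)
  rois <- NULL
  for (t in seq_len(n_frames)) {
    dt <- if (n_frames > 1L) (t - 1) / (n_frames - 1) else 0
    comps_t <- lapply(compartments, function(sp) {
      sp$free_fraction <- min(max(sp$free_fraction + drift * dt, 0), 1)
      sp
    })
    sim <- simulate_cell_image(comps_t, free_tau = free_tau,
                               bound_tau = bound_tau, irf = irf,
                               frame = frame, n_bins = n_bins,
                               rep_rate_MHz = rep_rate_MHz, period = period,
                               seed = NULL, noise_free = FALSE)
    frames[[t]] <- sim$image
    if (is.null(rois)) rois <- sim$rois
    truth <- dplyr::bind_rows(truth, dplyr::mutate(sim$truth, frame = t, .before = 1L))
  }
  list(frames = frames, rois = rois, truth = truth)
}

#' Two-cell stability phantom
#'
#' Two homogeneous circular cells over a sparse background, the fixture
#' for frame-stability runs.
#'
#' @param frame Frame size (default 64 x 64).
#' @param photons Photons per pixel per frame (default 500).
#' @param fractions Free fractions of the two cells.
#' @return A list of [compartment_spec()]s.
#' @export
two_cell_phantom <- function(frame = c(64L, 64L), photons = 500,
                             fractions = c(0.7, 0.65)) {
  r <- min(frame) * 0.2
  list(
    compartment_spec("background", 0.5, photons * 0.004, list(type = "full")),
    compartment_spec("cell_1", fractions[1L], photons,
                     list(type = "ellipse", center = frame * 0.28, radii = c(r, r))),
    compartment_spec("cell_2", fractions[2L], photons,
                     list(type = "ellipse", center = frame * 0.72, radii = c(r, r)))
  )
}

#' Record-level population generator
#'
#' Draws cell-phasor records directly from a condition preset without
#' simulating images: per-cell fractions from the truncated-normal
#' between-cell distribution mapped onto the cursor segment. Useful for
#' statistical calibration studies (e.g. type-I error of the group test)
#' where image-level shot noise is negligible at the cell-phasor scale.
#'
#' @param preset A [condition_preset()] (or condition name).
#' @param n_cells Number of records.
#' @param cursor A [species_cursor()] mapping fraction to (g, s).
#' @param seed Optional RNG seed.
#' @return A cell-phasor record tibble (see [cell_phasors()]).
#' @export
simulate_cell_records <- function(preset, n_cells = 20L,
                                  cursor = species_cursor(), seed = NULL) {
  if (is.character(preset)) preset <- condition_preset(preset)
  stopifnot(inherits(preset, "condition_preset"), n_cells >= 1L)
  if (!is.null(seed)) set.seed(seed)
  f <- rtrunc_norm01(n_cells, preset$mean_fraction, preset$sd_fraction)
  fr <- cursor$free_ref
  br <- cursor$bound_ref
  tibble::tibble(
    roi_label = seq_len(n_cells),
    group = preset$condition,
    g_mean = f * fr$g + (1 - f) * br$g,
    s_mean = f * fr$s + (1 - f) * br$s,
    n_pixels = NA_integer_,
    total_counts = NA_real_,
    free_fraction = f
  )
}
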