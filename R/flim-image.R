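#' FLIM image: a grid of decay histograms
#'
#' A TCSPC image is a rows x cols x time-bins array of photon counts plus
#' acquisition metadata. Pixels are row-major with origin at the top left;
#' time bins are uniform mid-bin samples of one excitation period.
#'
#' @param counts A 3-D numeric array `[rows, cols, n_bins]` of non-negative
#'   photon counts.
#' @param period Excitation period in ns; defaults to `1000 / rep_rate_MHz`.
#' @param rep_rate_MHz Laser repetition rate in MHz (default 80).
#' @param excitation_nm Excitation wavelength metadata (default 740, the
#'   two-photon NADH line).
#' @return An object of class `flim_image`.
#' @seealso [image_phasor_field()], [simulate_cell_image()], [read_flim()]
#' @export
flim_image <- function(counts, period = 1000 / rep_rate_MHz,
                       rep_rate_MHz = 80, excitation_nm = 740) {
  if (!is.array(counts) || length(dim(counts)) != 3L) {
    stop("`counts` must be a rows x cols x bins array", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("photon counts must be non-negative and non-missing", call. = FALSE)
  }
  if (dim(counts)[3L] < 2L) {
    stop("a FLIM image needs at least 2 time bins", call. = FALSE)
  }
  stopifnot(period > 0, rep_rate_MHz > 0)
  structure(
    list(counts = counts,
         dim = dim(counts)[1:2],
         n_bins = dim(counts)[3L],
         period = period,
         rep_rate_MHz = rep_rate_MHz,
         excitation_nm = excitation_nm),
    class = "flim_image"
  )
}

#' @export
print.flim_image <- function(x, ...) {
  cat(sprintf(
    "<flim_image> %d x %d pixels, %d time bins over %.4g ns (%g MHz, %g nm)\n",
    x$dim[1L], x$dim[2L], x$n_bins, x$period, x$rep_rate_MHz, x$excitation_nm
  ))
  invisible(x)
}

#' Extract one pixel's decay histogram
#'
#' @param img A [flim_image()].
#' @param row,col 1-based pixel indices.
#' @return A [decay_histogram()].
#' @export
pixel_decay <- function(img, row, col) {
  stopifnot(inherits(img, "flim_image"))
  decay_histogram(img$counts[row, col, ], period = img$period)
}

#' Per-pixel phasor field of a FLIM image
#'
#' Transforms every pixel of a FLIM image into phasor coordinates,
#' optionally applies a calibration transform, masks low-count pixels as
#' undefined, and optionally median-smooths the g and s maps.
#'
#' Pixels whose total counts fall below `min_counts` carry the undefined
#' marker (`NA`), which all downstream stages propagate. Smoothing is a
#' 3 x 3 median filter applied to g and s separately, using only defined
#' neighbours and leaving undefined pixels undefined.
#'
#' @param img A [flim_image()].
#' @param harmonic Positive integer harmonic (default 1).
#' @param cal Optional [calibration_transform()] applied to every pixel.
#' @param min_counts Minimum total photon counts for a pixel to be defined
#'   (default 30, a background cut).
#' @param smooth Logical; apply 3 x 3 median smoothing (default `FALSE`).
#' @return An object of class `phasor_field`: matrices `g`, `s` (NA =
#'   undefined) and `intensity` (total counts), plus `harmonic`, `omega`,
#'   `period` and `n_bins`.
#' @examples
#' sim <- simulate_cell_image(frame = c(32, 32), n_bins = 64, seed = 1)
#' field <- image_phasor_field(sim$image)
#' @export
image_phasor_field <- function(img, harmonic = 1L, cal = NULL,
                               min_counts = 30, smooth = FALSE) {
  stopifnot(inherits(img, "flim_image"))
  if (!is.null(cal)) {
    stopifnot(inherits(cal, "calibration_transform"))
    if (cal$harmonic != harmonic) {
      stop("harmonic mismatch between field and calibration", call. = FALSE)
    }
  }
  omega <- 2 * pi * harmonic / img$period
  t_k <- default_bin_centers(img$n_bins, img$period)
  npix <- prod(img$dim)
  # first two dims vary fastest, so this reshape is pixel x bin
  cm <- matrix(img$counts, nrow = npix, ncol = img$n_bins)
  total <- cm %*% rep(1, img$n_bins)
  cs <- cm %*% cbind(cos(omega * t_k), sin(omega * t_k))
  defined <- total >= max(min_counts, .Machine$double.xmin)
  g <- ifelse(defined, cs[, 1L] / total, NA_real_)
  s <- ifelse(defined, cs[, 2L] / total, NA_real_)
  if (!is.null(cal)) {
    z <- complex(real = g, imaginary = s) *
      cal$modulation_scale * exp(1i * cal$phase_shift)
    g <- Re(z)
    s <- Im(z)
  }
  g <- matrix(g, img$dim[1L], img$dim[2L])
  s <- matrix(s, img$dim[1L], img$dim[2L])
  if (isTRUE(smooth)) {
    g <- median_filter3(g)
    s <- median_filter3(s)
  }
  structure(
    list(g = g, s = s,
         intensity = matrix(total, img$dim[1L], img$dim[2L]),
         harmonic = as.integer(harmonic), omega = omega,
         period = img$period, n_bins = img$n_bins,
         calibrated = !is.null(cal)),
    class = "phasor_field"
  )
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf(
    "<phasor_field> %d x %d pixels (harmonic %d, %d defined, %scalibrated)\n",
    nrow(x$g), ncol(x$g), x$harmonic, sum(!is.na(x$g)),
    if (isTRUE(x$calibrated)) "" else "un"
  ))
  invisible(x)
}

# 3x3 median over defined neighbours; NA pixels stay NA
median_filter3 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  pad <- matrix(NA_real_, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  stack <- vapply(seq_len(9L), function(i) {
    dr <- (i - 1L) %% 3L
    dc <- (i - 1L) %/% 3L
    as.vector(pad[(1L + dr):(nr + dr), (1L + dc):(nc + dc)])
  }, numeric(nr * nc))
  med <- apply(stack, 1L, stats::median, na.rm = TRUE)
  med[is.na(as.vector(m))] <- NA_real_
  med[is.nan(med)] <- NA_real_
  matrix(med, nr, nc)
}

#' Tidy a phasor field into a pixel tibble
#'
#' @param x A `phasor_field`.
#' @param ... Unused.
#' @return A tibble with one row per pixel: `row`, `col`, `g`, `s`,
#'   `intensity`, `defined`.
#' @export
tidy.phasor_field <- function(x, ...) {
  nr <- nrow(x$g)
  nc <- ncol(x$g)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    g = as.vector(x$g),
    s = as.vector(x$s),
    intensity = as.vector(x$intensity),
    defined = !is.na(as.vector(x$g))
  )
}

#' 2-D phasor-plot occupancy histogram
#'
#' Bins the defined pixels of a phasor field over the phasor-plot window
#' `[0, 1] x [0, 0.6]` (half-open bins; values outside the window are
#' clamped into the edge bins so the histogram total always equals the
#' number of defined pixels).
#'
#' @param field A `phasor_field`.
#' @param n_bins_g,n_bins_s Number of bins along g and s (defaults 128).
#' @param g_range,s_range Plot window (defaults `c(0, 1)` and `c(0, 0.6)`).
#' @return An object of class `phasor_histogram`: `counts` matrix
#'   (`n_bins_g x n_bins_s`), bin edge vectors, and `n_defined`.
#' @export
phasor_histogram <- function(field, n_bins_g = 128L, n_bins_s = 128L,
                             g_range = c(0, 1), s_range = c(0, 0.6)) {
  stopifnot(inherits(field, "phasor_field"), n_bins_g >= 1, n_bins_s >= 1)
  g <- as.vector(field$g)
  s <- as.vector(field$s)
  keep <- !is.na(g) & !is.na(s)
  g <- g[keep]
  s <- s[keep]
  g_edges <- seq(g_range[1L], g_range[2L], length.out = n_bins_g + 1L)
  s_edges <- seq(s_range[1L], s_range[2L], length.out = n_bins_s + 1L)
  counts <- matrix(0L, n_bins_g, n_bins_s)
  if (length(g)) {
    ig <- pmin(pmax(findInterval(g, g_edges, left.open = FALSE), 1L), n_bins_g)
    is_ <- pmin(pmax(findInterval(s, s_edges, left.open = FALSE), 1L), n_bins_s)
    tab <- table(factor(ig, levels = seq_len(n_bins_g)),
                 factor(is_, levels = seq_len(n_bins_s)))
    counts <- matrix(as.integer(tab), n_bins_g, n_bins_s)
  }
  structure(
    list(counts = counts, g_edges = g_edges, s_edges = s_edges,
         n_defined = length(g), harmonic = field$harmonic),
    class = "phasor_histogram"
  )
}

#' @export
print.phasor_histogram <- function(x, ...) {
  cat(sprintf("<phasor_histogram> %d x %d bins, %d pixels\n",
              length(x$g_edges) - 1L, length(x$s_edges) - 1L, x$n_defined))
  invisible(x)
}
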