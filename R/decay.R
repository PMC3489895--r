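#' Time-binned fluorescence decay histogram
#'
#' The elementary object of phasor analysis: photon counts per time bin over
#' one excitation period of the pulsed laser. In TCSPC imaging every pixel
#' carries one such histogram; the phasor transform maps it to a point in
#' the (g, s) plane.
#'
#' @param counts Numeric vector of non-negative photon counts, one per time
#'   bin. A zero-total histogram is valid (an empty pixel) and yields an
#'   undefined phasor downstream.
#' @param period Laser repetition period in nanoseconds (`1/f`); default
#'   12.5 ns, i.e. an 80 MHz repetition rate.
#' @param bin_centers Optional bin-center times in ns, strictly increasing,
#'   all in `[0, period)`. Defaults to uniform mid-bin sampling
#'   `(k + 0.5) * period / n_bins`.
#'
#' @return An object of class `decay_histogram` with fields `counts`,
#'   `period`, `bin_centers` and `n_bins`.
#' @seealso [decay_to_phasor()], [simulate_decay()]
#' @examples
#' h <- decay_histogram(exp(-default_bin_centers(256) / 2.5))
#' decay_to_phasor(h)
#' @export
decay_histogram <- function(counts, period = 12.5, bin_centers = NULL) {
  counts <- as.numeric(counts)
  n_bins <- length(counts)
  if (n_bins < 2L) {
    stop("a decay histogram needs at least 2 time bins", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("decay counts must be non-negative and non-missing", call. = FALSE)
  }
  if (!is.numeric(period) || length(period) != 1L || period <= 0) {
    stop("`period` must be a single positive time in ns", call. = FALSE)
  }
  if (is.null(bin_centers)) {
    bin_centers <- default_bin_centers(n_bins, period)
  } else {
    bin_centers <- as.numeric(bin_centers)
    if (length(bin_centers) != n_bins) {
      stop("`bin_centers` must match the number of count bins", call. = FALSE)
    }
    if (any(diff(bin_centers) <= 0)) {
      stop("`bin_centers` must be strictly increasing", call. = FALSE)
    }
    if (bin_centers[1L] < 0 || bin_centers[n_bins] >= period) {
      stop("`bin_centers` must all lie in [0, period)", call. = FALSE)
    }
  }
  structure(
    list(counts = counts, period = period,
         bin_centers = bin_centers, n_bins = n_bins),
    class = "decay_histogram"
  )
}

#' Uniform mid-bin time grid over one excitation period
#'
#' @param n_bins Number of time bins.
#' @param period Excitation period in ns.
#' @return Numeric vector `(k + 0.5) * period / n_bins`, `k = 0 .. n_bins-1`.
#' @export
default_bin_centers <- function(n_bins, period = 12.5) {
  (seq_len(n_bins) - 0.5) * period / n_bins
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf(
    "<decay_histogram> %d bins over %.4g ns, %.4g total counts\n",
    x$n_bins, x$period, sum(x$counts)
  ))
  invisible(x)
}

#' Angular frequency of a harmonic of the laser repetition rate
#'
#' @param rep_rate_MHz Laser repetition rate in MHz (default 80).
#' @param harmonic Positive integer harmonic (default 1).
#' @return Angular frequency in rad/ns, `2 * pi * f * harmonic` with `f`
#'   in GHz.
#' @examples
#' angular_frequency() # 80 MHz, first harmonic
#' @export
angular_frequency <- function(rep_rate_MHz = 80, harmonic = 1L) {
  stopifnot(rep_rate_MHz > 0, harmonic >= 1)
  2 * pi * rep_rate_MHz * 1e-3 * harmonic
}
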