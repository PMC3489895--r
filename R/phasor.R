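#' Phasor coordinates of a decay
#'
#' A phasor point is the pair of normalized cosine/sine Fourier coefficients
#' of a fluorescence decay at a harmonic of the laser repetition rate:
#' `g = sum(I cos(wt)) / sum(I)`, `s = sum(I sin(wt)) / sum(I)`. Every
#' single-exponential decay maps onto the universal semicircle from (0, 0)
#' to (1, 0) with radius 1/2; mixtures map inside it.
#'
#' @param g,s Phasor coordinates (dimensionless). `NA` marks an undefined
#'   phasor (e.g. an empty pixel).
#' @param harmonic Positive integer harmonic the coordinates were computed
#'   at.
#' @param omega Angular frequency in rad/ns (`2 * pi * harmonic / period`).
#' @return An object of class `phasor_point`.
#' @seealso [decay_to_phasor()], [single_exp_phasor()], [mix_phasors()]
#' @export
phasor_point <- function(g, s, harmonic = 1L, omega = angular_frequency(harmonic = harmonic)) {
  stopifnot(length(g) == 1L, length(s) == 1L)
  if (harmonic < 1) stop("`harmonic` must be a positive integer", call. = FALSE)
  structure(
    list(g = as.numeric(g), s = as.numeric(s),
         harmonic = as.integer(harmonic), omega = as.numeric(omega)),
    class = "phasor_point"
  )
}

#' Undefined phasor marker
#'
#' Returned for histograms with zero total counts; propagated, never
#' silently replaced by (0, 0).
#'
#' @inheritParams phasor_point
#' @return A `phasor_point` with `NA` coordinates.
#' @export
phasor_undefined <- function(harmonic = 1L, omega = angular_frequency(harmonic = harmonic)) {
  phasor_point(NA_real_, NA_real_, harmonic = harmonic, omega = omega)
}

#' Is a phasor undefined?
#'
#' @param p A `phasor_point`.
#' @return Logical.
#' @export
is_undefined <- function(p) {
  stopifnot(inherits(p, "phasor_point"))
  is.na(p$g) || is.na(p$s)
}

#' @export
print.phasor_point <- function(x, ...) {
  if (is_undefined(x)) {
    cat(sprintf("<phasor_point> undefined (harmonic %d)\n", x$harmonic))
  } else {
    cat(sprintf("<phasor_point> g = %.6g, s = %.6g (harmonic %d, omega %.5g rad/ns)\n",
                x$g, x$s, x$harmonic, x$omega))
  }
  invisible(x)
}

#' Phasor transform of a decay histogram
#'
#' Computes the normalized first (or higher) harmonic Fourier coefficients
#' of a time-binned decay: the discrete analogue of the per-pixel phasor
#' transform. A zero-total histogram yields the undefined marker.
#'
#' @param hist A [decay_histogram()].
#' @param harmonic Positive integer harmonic (default 1, i.e. the laser
#'   repetition rate itself).
#' @return A [phasor_point()].
#' @examples
#' h <- decay_histogram(exp(-default_bin_centers(256) / 4.04))
#' decay_to_phasor(h) # close to the 4.04 ns closed form at 80 MHz
#' @export
decay_to_phasor <- function(hist, harmonic = 1L) {
  if (!inherits(hist, "decay_histogram")) {
    stop("`hist` must be a decay_histogram", call. = FALSE)
  }
  if (!is.numeric(harmonic) || length(harmonic) != 1L || harmonic < 1 ||
      harmonic != round(harmonic)) {
    stop("`harmonic` must be a positive integer", call. = FALSE)
  }
  omega <- 2 * pi * harmonic / hist$period
  total <- sum(hist$counts)
  if (total == 0) {
    return(phasor_undefined(harmonic = harmonic, omega = omega))
  }
  wt <- omega * hist$bin_centers
  phasor_point(
    g = sum(hist$counts * cos(wt)) / total,
    s = sum(hist$counts * sin(wt)) / total,
    harmonic = harmonic, omega = omega
  )
}

#' Closed-form phasor of a single-exponential decay
#'
#' For a mono-exponential decay with lifetime `tau` at angular frequency
#' `omega`: `g = 1 / (1 + (w tau)^2)`, `s = w tau / (1 + (w tau)^2)`.
#' These points lie exactly on the universal semicircle; `tau = 0` maps to
#' (1, 0) and `tau -> Inf` to (0, 0).
#'
#' @param tau Lifetime in ns, `>= 0` (`Inf` allowed).
#' @param omega Angular frequency in rad/ns.
#' @param harmonic Harmonic tag carried by the result.
#' @return A [phasor_point()] on the semicircle.
#' @examples
#' single_exp_phasor(4.04, angular_frequency(80)) # fluorescein at 80 MHz
#' @export
single_exp_phasor <- function(tau, omega = angular_frequency(harmonic = harmonic),
                              harmonic = 1L) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    stop("`tau` must be a single non-negative lifetime in ns", call. = FALSE)
  }
  stopifnot(omega > 0)
  if (is.infinite(tau)) {
    return(phasor_point(0, 0, harmonic = harmonic, omega = omega))
  }
  wt <- omega * tau
  phasor_point(
    g = 1 / (1 + wt^2), s = wt / (1 + wt^2),
    harmonic = harmonic, omega = omega
  )
}

#' Intensity-weighted mixture of phasors
#'
#' Phasors obey vector algebra: the phasor of a mixture of fluorescent
#' species is the intensity-weighted average of the species phasors,
#' `g = sum(f_n g_n)`, `s = sum(f_n s_n)`. All combinations of two species
#' lie on the segment joining them; three species span a triangle; N
#' species a polygon.
#'
#' @param points A list of [phasor_point()]s, or a data frame with columns
#'   `g` and `s`.
#' @param fractions Numeric vector of non-negative fractional intensities
#'   summing to 1 (tolerance 1e-9), one per component.
#' @return The mixture [phasor_point()].
#' @examples
#' mix_phasors(list(phasor_point(1, 0), phasor_point(0, 0)), c(0.5, 0.5))
#' @export
mix_phasors <- function(points, fractions) {
  if (is.data.frame(points)) {
    g <- points$g
    s <- points$s
    harmonic <- if (!is.null(points$harmonic)) points$harmonic[1L] else 1L
    omega <- if (!is.null(points$omega)) points$omega[1L] else angular_frequency(harmonic = harmonic)
  } else if (is.list(points) && all(vapply(points, inherits, logical(1), "phasor_point"))) {
    harms <- vapply(points, `[[`, integer(1), "harmonic")
    if (length(unique(harms)) != 1L) {
      stop("all components must be at the same harmonic", call. = FALSE)
    }
    g <- vapply(points, `[[`, numeric(1), "g")
    s <- vapply(points, `[[`, numeric(1), "s")
    harmonic <- harms[1L]
    omega <- points[[1L]]$omega
  } else {
    stop("`points` must be a list of phasor_points or a data frame with g, s",
         call. = FALSE)
  }
  fractions <- as.numeric(fractions)
  if (length(fractions) != length(g)) {
    stop("one fraction per component is required", call. = FALSE)
  }
  if (any(fractions < 0)) {
    stop("fractions must be non-negative", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  phasor_point(sum(fractions * g), sum(fractions * s),
               harmonic = harmonic, omega = omega)
}

#' Phase and modulation lifetimes of a phasor
#'
#' Inverts the single-exponential map along the two classical routes:
#' `tau_phase = s / (g * omega)` and
#' `tau_mod = sqrt(1 / (g^2 + s^2) - 1) / omega`. For a point exactly on
#' the universal semicircle the two agree and equal the generating
#' lifetime; inside the semicircle `tau_phase < tau_mod`, a signature of a
#' multi-exponential decay.
#'
#' @param p A defined [phasor_point()] with `g > 0` and `g^2 + s^2 <= 1`.
#' @return A tibble with columns `tau_phase` and `tau_mod` (ns).
#' @export
phase_mod_lifetimes <- function(p) {
  stopifnot(inherits(p, "phasor_point"))
  if (is_undefined(p)) stop("phasor is undefined", call. = FALSE)
  m2 <- p$g^2 + p$s^2
  if (p$g <= 0 || m2 > 1 + 1e-12) {
    stop("lifetime read-back needs g > 0 and g^2 + s^2 <= 1", call. = FALSE)
  }
  tibble::tibble(
    tau_phase = p$s / (p$g * p$omega),
    tau_mod = sqrt(max(1 / m2 - 1, 0)) / p$omega
  )
}

#' Distance of a phasor from the universal-semicircle centre
#'
#' The universal circle is the semicircle centred at (0.5, 0) with radius
#' 1/2; single-exponential decays lie on it (distance 1/2), physical
#' mixtures inside it.
#'
#' @param p A [phasor_point()], or numeric `g` with `s` supplied.
#' @param s Optional numeric `s` when `p` is numeric `g`.
#' @return Numeric distance(s) from (0.5, 0).
#' @export
semicircle_distance <- function(p, s = NULL) {
  if (inherits(p, "phasor_point")) {
    g <- p$g
    s <- p$s
  } else {
    g <- p
  }
  sqrt((g - 0.5)^2 + s^2)
}
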