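#' Calibration transform for the instrument response
#'
#' The instrument response of a FLIM system (timing offset, pulse
#' broadening, electronics) rotates and demodulates every measured phasor
#' by the same complex factor. Measuring a reference fluorophore of known
#' mono-exponential lifetime (classically fluorescein, 4.04 ns) determines
#' that factor; applying its inverse maps all phasors to the true-lifetime
#' frame. The transform is per-harmonic.
#'
#' @param phase_shift Rotation in radians added to the measured phase.
#' @param modulation_scale Positive factor applied to the measured
#'   modulation.
#' @param harmonic Harmonic the transform applies at.
#' @return An object of class `calibration_transform`.
#' @seealso [estimate_calibration()], [apply_calibration()]
#' @export
calibration_transform <- function(phase_shift = 0, modulation_scale = 1,
                                  harmonic = 1L) {
  stopifnot(is.numeric(phase_shift), length(phase_shift) == 1L)
  if (!is.numeric(modulation_scale) || modulation_scale <= 0) {
    stop("`modulation_scale` must be positive", call. = FALSE)
  }
  structure(
    list(phase_shift = as.numeric(phase_shift),
         modulation_scale = as.numeric(modulation_scale),
         harmonic = as.integer(harmonic)),
    class = "calibration_transform"
  )
}

#' @export
print.calibration_transform <- function(x, ...) {
  cat(sprintf(
    "<calibration_transform> phase_shift = %.6g rad, modulation_scale = %.6g (harmonic %d)\n",
    x$phase_shift, x$modulation_scale, x$harmonic
  ))
  invisible(x)
}

#' Estimate the calibration transform from a reference measurement
#'
#' Treats a phasor as the complex number `m * exp(1i * phi)` with
#' `m = sqrt(g^2 + s^2)` and `phi = atan2(s, g)`. Given the measured
#' phasor of a reference with known mono-exponential lifetime `tau_ref`,
#' the transform is `phase_shift = phi_expected - phi_measured` and
#' `modulation_scale = m_expected / m_measured`, where the expected phasor
#' is [single_exp_phasor()] at the reference lifetime.
#'
#' @param measured_ref Measured reference [phasor_point()] (defined, with
#'   non-zero modulation).
#' @param tau_ref Known reference lifetime in ns, `> 0`.
#' @return A [calibration_transform()] at the reference's harmonic.
#' @examples
#' ref <- phasor_point(0.18, 0.41)
#' estimate_calibration(ref, tau_ref = 4.04)
#' @export
estimate_calibration <- function(measured_ref, tau_ref) {
  stopifnot(inherits(measured_ref, "phasor_point"))
  if (is_undefined(measured_ref)) {
    stop("reference phasor is undefined", call. = FALSE)
  }
  if (!is.numeric(tau_ref) || length(tau_ref) != 1L || tau_ref <= 0) {
    stop("`tau_ref` must be a single positive lifetime in ns", call. = FALSE)
  }
  m_meas <- sqrt(measured_ref$g^2 + measured_ref$s^2)
  if (m_meas == 0) {
    stop("degenerate calibration: reference has zero modulation", call. = FALSE)
  }
  expected <- single_exp_phasor(tau_ref, omega = measured_ref$omega,
                                harmonic = measured_ref$harmonic)
  calibration_transform(
    phase_shift = atan2(expected$s, expected$g) -
      atan2(measured_ref$s, measured_ref$g),
    modulation_scale = sqrt(expected$g^2 + expected$s^2) / m_meas,
    harmonic = measured_ref$harmonic
  )
}

#' Apply a calibration transform to a phasor
#'
#' Rotates by `phase_shift` and scales modulation by `modulation_scale`
#' (multiplication by a complex constant). Applying the transform
#' estimated from a corrupted reference to that same reference returns the
#' theoretical reference phasor to machine precision. Undefined phasors
#' stay undefined.
#'
#' @param p A [phasor_point()].
#' @param cal A [calibration_transform()] at the same harmonic.
#' @return The calibrated [phasor_point()].
#' @export
apply_calibration <- function(p, cal) {
  stopifnot(inherits(p, "phasor_point"), inherits(cal, "calibration_transform"))
  if (p$harmonic != cal$harmonic) {
    stop("harmonic mismatch between phasor and calibration", call. = FALSE)
  }
  if (is_undefined(p)) return(p)
  z <- complex(real = p$g, imaginary = p$s) *
    cal$modulation_scale * exp(1i * cal$phase_shift)
  phasor_point(Re(z), Im(z), harmonic = p$harmonic, omega = p$omega)
}
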