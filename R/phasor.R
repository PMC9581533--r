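## First-harmonic phasor analysis.

phasor_point <- function(g, s, harmonic, omega) {
  structure(list(g = g, s = s, harmonic = as.integer(harmonic),
                 omega = omega), class = "phasor_point")
}

#' @export
print.phasor_point <- function(x, ...) {
  cat(sprintf("Phasor point (harmonic %d): g = %.4f, s = %.4f\n",
              x$harmonic, x$g, x$s))
  invisible(x)
}

#' Phasor transform of a decay histogram
#'
#' First Fourier harmonic of the decay at the excitation repetition
#' frequency: `g = sum(y*cos(w*t))/sum(y)`, `s = sum(y*sin(w*t))/sum(y)`
#' with `w = 2*pi*harmonic*repetition_rate` and `t` at channel centres.
#' Single-exponential decays fall on the universal semicircle
#' `(g - 1/2)^2 + s^2 = 1/4`; mixtures fall on chords between their
#' component points.
#'
#' @param hist A `decay_histogram` with positive total counts.
#' @param harmonic Harmonic order (default 1).
#' @param offset Known constant background per channel to subtract before
#'   the transform (default 0; pass a fitted offset for background
#'   correction).
#' @return A `phasor_point` with fields `g`, `s`, `harmonic`, `omega`.
#' @examples
#' h <- expected_decay(list(tau1 = 1989, tau2 = 1989, a1 = 0.5),
#'                     flim_instrument(background_rate = 0))
#' phasor_transform(h)  # near (0.5, 0.5) since w*tau = 1
#' @export
phasor_transform <- function(hist, harmonic = 1L, offset = 0) {
  stopifnot(inherits(hist, "decay_histogram"), harmonic >= 1)
  y <- hist$counts - offset
  y[y < 0] <- 0
  tot <- sum(y)
  if (tot <= 0) stop("zero total counts: phasor undefined")
  omega <- 2 * pi * harmonic * hist$instrument$repetition_rate * 1e-12 # rad/ps
  t <- hist$times
  phasor_point(sum(y * cos(omega * t)) / tot,
               sum(y * sin(omega * t)) / tot, harmonic, omega * 1e12)
}

#' Analytic phasor of a fitted bi-exponential decay
#'
#' Intensity-fraction-weighted sum of the two single-exponential phasors:
#' `f_i = a_i*tau_i / (a1*tau1 + a2*tau2)`, each component at
#' `(1/(1+(w*tau)^2), w*tau/(1+(w*tau)^2))`. The point lies on the chord
#' between the two semicircle points; the position along the chord is set
#' by the amplitude proportion.
#'
#' @param fit A `biexp_fit` (or list with `a1`, `a2`, `tau1`, `tau2`).
#' @param harmonic Harmonic order (default 1).
#' @param repetition_rate Excitation rate in Hz (default 80 MHz).
#' @return A `phasor_point`.
#' @export
phasor_from_fit <- function(fit, harmonic = 1L, repetition_rate = 8e7) {
  omega <- 2 * pi * harmonic * repetition_rate * 1e-12 # rad/ps
  f1 <- fit$a1 * fit$tau1 / (fit$a1 * fit$tau1 + fit$a2 * fit$tau2)
  comp <- function(tau) {
    wt <- omega * tau
    c(1 / (1 + wt^2), wt / (1 + wt^2))
  }
  p <- f1 * comp(fit$tau1) + (1 - f1) * comp(fit$tau2)
  phasor_point(p[1], p[2], harmonic, omega * 1e12)
}

#' Relative intensity mask for phasor analysis
#'
#' Retains pixels whose total counts reach `fraction` of the maximum
#' pixel intensity (the 70% rule by default; 0.9 is used for
#' publication-style phasor summaries).
#'
#' @param cube A `photon_cube`.
#' @param fraction Threshold as a fraction of the maximum intensity, in
#'   `[0, 1]` (default 0.7).
#' @return ny x nx logical matrix.
#' @export
phasor_intensity_mask <- function(cube, fraction = 0.7) {
  stopifnot(fraction >= 0, fraction <= 1)
  img <- cube_intensity(cube)
  img >= fraction * max(img)
}
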