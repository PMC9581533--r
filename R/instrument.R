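#' TCSPC instrument model
#'
#' Describes the timing system assumed by the simulator and the decay
#' fitter: periodic pulsed excitation (80 MHz Ti:sapphire by default), a
#' fixed number of TCSPC channels spanning one excitation period, and a
#' Gaussian instrument response function (IRF).
#'
#' @param repetition_rate Laser repetition rate in Hz. Default `8e7`
#'   (80 MHz), giving a 12.5 ns measurement window.
#' @param n_channels Number of TCSPC time channels over one period.
#'   Default 256 (about 48.8 ps/channel at 80 MHz).
#' @param irf_fwhm Full width at half maximum of the Gaussian IRF in ps.
#'   Must be below 100 ps; default 80 ps.
#' @param irf_t0 Position of the IRF centre within the window, ps.
#'   Default 1000 ps, leaving most of the window for the decay tail.
#' @param irf_shift Fixed temporal shift (ps) added to `irf_t0`, emulating
#'   an uncompensated signal/IRF offset. Default 0.
#' @param background_rate Expected background (dark + ambient) counts per
#'   channel. Default 1.
#'
#' @return An object of class `flim_instrument`: a list with the above
#'   fields plus `window` (period, ps), `channel_width` (ps), `times`
#'   (channel-centre times, ps) and `irf_sigma` (Gaussian sigma, ps).
#' @examples
#' instr <- flim_instrument()
#' instr$window      # 12500 ps
#' instr$channel_width
#' @export
flim_instrument <- function(repetition_rate = 8e7,
                            n_channels = 256L,
                            irf_fwhm = 80,
                            irf_t0 = 1000,
                            irf_shift = 0,
                            background_rate = 1) {
  stopifnot(repetition_rate > 0, n_channels >= 8, irf_t0 >= 0,
            background_rate >= 0)
  if (irf_fwhm <= 0 || irf_fwhm >= 100)
    stop("irf_fwhm must be in (0, 100) ps")
  window <- 1e12 / repetition_rate
  dt <- window / n_channels
  obj <- list(
    repetition_rate = repetition_rate,
    n_channels = as.integer(n_channels),
    window = window,
    channel_width = dt,
    times = (seq_len(n_channels) - 0.5) * dt,
    irf_fwhm = irf_fwhm,
    irf_sigma = irf_fwhm / (2 * sqrt(2 * log(2))),
    irf_t0 = irf_t0,
    irf_shift = irf_shift,
    background_rate = background_rate
  )
  class(obj) <- "flim_instrument"
  obj
}

#' @export
print.flim_instrument <- function(x, ...) {
  cat(sprintf(
    "TCSPC instrument: %.0f MHz, %d channels x %.2f ps, IRF %.0f ps FWHM at t0 = %.0f ps, background %.2g counts/channel\n",
    x$repetition_rate / 1e6, x$n_channels, x$channel_width, x$irf_fwhm,
    x$irf_t0, x$background_rate))
  invisible(x)
}
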