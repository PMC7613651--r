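#' Acquisition parameters for a 1D 19F experiment
#'
#' Describes the digitizer settings of a pulse-acquire experiment: the
#' spectrometer 19F frequency, the transmitter (carrier) offset, the spectral
#' width and the number of complex points. The defaults emulate 19F detection
#' on a 500 MHz (1H) instrument: 470.4 MHz 19F frequency, a 20 ppm window
#' centred at -62 ppm, and a 350 ms acquisition time, so that
#' `n_points = round(acq_time_s * sweep_width_hz)`.
#'
#' @param spectrometer_freq_mhz 19F Larmor frequency in MHz.
#' @param carrier_ppm transmitter offset in ppm.
#' @param sweep_width_ppm spectral width in ppm (converted internally to Hz).
#' @param acq_time_s acquisition time in seconds.
#' @return An object of class `acq_params` with fields
#'   `spectrometer_freq_mhz`, `carrier_ppm`, `sweep_width_hz`, `n_points`,
#'   `acq_time_s`.
#' @examples
#' acq <- acq_params()
#' acq$n_points
#' @export
acq_params <- function(spectrometer_freq_mhz = 470.4,
                       carrier_ppm = -62,
                       sweep_width_ppm = 20,
                       acq_time_s = 0.35) {
  .assert(.is_num1(spectrometer_freq_mhz) && spectrometer_freq_mhz > 0,
          "spectrometer_freq_mhz must be a positive number")
  .assert(.is_num1(sweep_width_ppm) && sweep_width_ppm > 0,
          "sweep_width_ppm must be positive")
  .assert(.is_num1(acq_time_s) && acq_time_s > 0, "acq_time_s must be positive")
  sw_hz <- sweep_width_ppm * spectrometer_freq_mhz
  n <- max(8L, as.integer(round(acq_time_s * sw_hz)))
  structure(list(
    spectrometer_freq_mhz = spectrometer_freq_mhz,
    carrier_ppm = carrier_ppm,
    sweep_width_hz = sw_hz,
    n_points = n,
    acq_time_s = n / sw_hz
  ), class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("19F acquisition: %.1f MHz, carrier %.2f ppm, sw %.0f Hz, %d pts (%.3f s)\n",
              x$spectrometer_freq_mhz, x$carrier_ppm, x$sweep_width_hz,
              x$n_points, x$acq_time_s))
  invisible(x)
}

.validate_acq <- function(acq) {
  .assert(inherits(acq, "acq_params"), "acq must be an acq_params object")
  dwell <- 1 / acq$sweep_width_hz
  .assert(abs(acq$acq_time_s - acq$n_points * dwell) <= dwell,
          "acq_time_s inconsistent with n_points / sweep_width_hz")
  invisible(acq)
}

# ppm range covered by the spectral window, c(high, low)
.acq_window_ppm <- function(acq) {
  half <- acq$sweep_width_hz / (2 * acq$spectrometer_freq_mhz)
  c(acq$carrier_ppm + half, acq$carrier_ppm - half)
}

#' Construct a free-induction decay object
#'
#' @param samples complex vector of time-domain samples.
#' @param acq an [acq_params()] object; `acq$n_points` must equal
#'   `length(samples)`.
#' @return An object of class `fid`.
#' @export
new_fid <- function(samples, acq) {
  .validate_acq(acq)
  .assert(is.complex(samples) || is.numeric(samples), "samples must be complex")
  samples <- as.complex(samples)
  .assert(length(samples) == acq$n_points,
          "length(samples) (%d) != acq$n_points (%d)", length(samples), acq$n_points)
  structure(list(samples = samples, acq = acq), class = "fid")
}

#' @export
print.fid <- function(x, ...) {
  cat(sprintf("<fid> %d complex points, dwell %.3g s\n",
              length(x$samples), 1 / x$acq$sweep_width_hz))
  invisible(x)
}

# time axis of an fid (seconds, starting at 0)
fid_times <- function(fid) {
  (seq_len(fid$acq$n_points) - 1) / fid$acq$sweep_width_hz
}
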