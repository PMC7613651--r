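#' Construct a 1D spectrum object
#'
#' @param ppm frequency axis in ppm, strictly decreasing (NMR convention,
#'   downfield left).
#' @param intensity real intensities, same length as `ppm`.
#' @param noise_sd optional noise standard deviation in intensity units.
#' @param acq optional [acq_params()] the spectrum derives from.
#' @return An object of class `spectrum1d`.
#' @export
new_spectrum1d <- function(ppm, intensity, noise_sd = NULL, acq = NULL) {
  .assert(length(ppm) == length(intensity),
          "ppm and intensity must have the same length")
  .assert(all(diff(ppm) < 0), "ppm axis must be strictly decreasing")
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 noise_sd = noise_sd, acq = acq), class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %d points, %.2f .. %.2f ppm%s\n",
              length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)],
              if (!is.null(x$noise_sd)) sprintf(", noise sd %.3g", x$noise_sd) else ""))
  invisible(x)
}

#' Exponential apodization of an FID
#'
#' Multiplies sample \eqn{i} by \eqn{\exp(-\pi \cdot lb \cdot t_i)}; this adds
#' exactly `lb_hz` to the FWHM of every Lorentzian component. The paper-style
#' default processing uses 10 Hz (5 Hz where resolution of the broad
#' intermediates matters).
#'
#' @param fid an `fid` object.
#' @param lb_hz line-broadening factor in Hz (>= 0).
#' @return The apodized `fid`; acquisition metadata unchanged.
#' @export
apodize <- function(fid, lb_hz = 10) {
  .assert(inherits(fid, "fid"), "fid must be an fid object")
  .assert(.is_num1(lb_hz) && lb_hz >= 0, "lb_hz must be >= 0")
  if (lb_hz == 0) return(fid)
  t <- fid_times(fid)
  out <- fid
  out$samples <- fid$samples * exp(-pi * lb_hz * t)
  out
}

#' Fourier transform an FID to a frequency-domain spectrum
#'
#' Zero-fills to `zero_fill_factor` times the acquired length, halves the
#' first point (so the discrete spectrum integrates like the continuous
#' transform and Lorentzian areas are preserved), applies the DFT, converts
#' the frequency axis to ppm via the carrier and spectrometer frequency, and
#' returns the real (absorption) part on a strictly decreasing ppm axis whose
#' endpoints are exactly `carrier +/- sweep_width / (2 * spectrometer_freq)`.
#' Intensities are scaled by the dwell time, i.e. expressed per Hz, so a
#' component of time-domain amplitude \eqn{A} integrates to \eqn{A/2} over the
#' Hz axis. Synthetic data carry zero phase; `phase0` applies an optional
#' zero-order phase (radians) for externally supplied data.
#'
#' @param fid an `fid` object (non-empty).
#' @param zero_fill_factor integer >= 1; default 2.
#' @param phase0 zero-order phase correction in radians.
#' @param first_point_scale scale applied to the first time-domain point
#'   (0.5 preserves integrals; 1 gives the plain DFT, e.g. for Parseval checks).
#' @return A `spectrum1d`.
#' @export
to_spectrum <- function(fid, zero_fill_factor = 2, phase0 = 0,
                        first_point_scale = 0.5) {
  .assert(inherits(fid, "fid"), "fid must be an fid object")
  .assert(length(fid$samples) > 0, "empty FID")
  .assert(.is_num1(zero_fill_factor) && zero_fill_factor >= 1,
          "zero_fill_factor must be >= 1")
  acq <- fid$acq
  n <- length(fid$samples)
  m <- as.integer(round(zero_fill_factor * n))
  s <- fid$samples
  s[1] <- s[1] * first_point_scale
  if (phase0 != 0) s <- s * exp(complex(imaginary = -phase0))
  s <- c(s, complex(real = numeric(m - n)))
  S <- stats::fft(s) / acq$sweep_width_hz   # * dwell * n_fft scaling folded in: dt = 1/sw
  # fft bin k (0-based) sits at frequency k*sw/m, wrapped to (-sw/2, sw/2]
  # order bins by decreasing frequency from +sw/2 to -sw/2, duplicating the
  # (periodic) Nyquist bin at both ends so the axis endpoints are exact
  half <- m %/% 2
  idx <- c(half, seq(half - 1, 1), 0, seq(m - 1, half)) + 1L
  freq <- c(acq$sweep_width_hz / 2,
            (seq(half - 1, 1)) * acq$sweep_width_hz / m,
            0,
            (seq(m - 1, half) - m) * acq$sweep_width_hz / m)
  ppm <- acq$carrier_ppm + freq / acq$spectrometer_freq_mhz
  new_spectrum1d(ppm, Re(S)[idx], acq = acq)
}

#' Add a broad instrument background to a spectrum
#'
#' Adds a very broad Lorentzian (default FWHM 2500 Hz) mimicking the 19F
#' background of fluoropolymer probe components, to exercise baseline
#' correction.
#'
#' @param spec a `spectrum1d`.
#' @param center_ppm background centre.
#' @param fwhm_hz background width in Hz (>= 2000 recommended).
#' @param area background area (intensity x ppm units).
#' @return The spectrum with the background added.
#' @export
add_instrument_background <- function(spec, center_ppm = -62, fwhm_hz = 2500,
                                      area = 1) {
  .assert(inherits(spec, "spectrum1d"), "spec must be a spectrum1d")
  sf <- if (!is.null(spec$acq)) spec$acq$spectrometer_freq_mhz else 470.4
  out <- spec
  out$intensity <- spec$intensity +
    .lorentz(spec$ppm, center_ppm, fwhm_hz / sf, area)
  out
}

# absorption Lorentzian in ppm units, parameterized by area
.lorentz <- function(ppm, center, fwhm_ppm, area) {
  (2 * area / (pi * fwhm_ppm)) / (1 + 4 * ((ppm - center) / fwhm_ppm)^2)
}

# logical mask: TRUE where ppm lies in any (high, low) interval
.in_regions <- function(ppm, regions) {
  inr <- rep(FALSE, length(ppm))
  for (r in regions) {
    hi <- max(r); lo <- min(r)
    inr <- inr | (ppm <= hi & ppm >= lo)
  }
  inr
}

#' Baseline correction with signal masking
#'
#' Fits a smooth background to the points outside the declared signal regions
#' and subtracts it over the whole axis. Default model is a polynomial of
#' order `poly_order` in ppm; `method = "rolling_min"` instead uses a wide
#' rolling-minimum envelope smoothed by a running mean (window in points).
#'
#' @param spec a `spectrum1d`.
#' @param signal_regions list of `c(high_ppm, low_ppm)` intervals containing
#'   real signal; they must not cover the whole axis.
#' @param method `"poly"` (default) or `"rolling_min"`.
#' @param poly_order polynomial order for `"poly"` (default 3).
#' @param window rolling window size in points for `"rolling_min"`.
#' @return The corrected `spectrum1d`.
#' @export
baseline_correct <- function(spec, signal_regions = list(),
                             method = c("poly", "rolling_min"),
                             poly_order = 3, window = 401L) {
  .assert(inherits(spec, "spectrum1d"), "spec must be a spectrum1d")
  method <- match.arg(method)
  rng <- range(spec$ppm)
  for (r in signal_regions) {
    .assert(max(r) <= rng[2] + 1e-12 && min(r) >= rng[1] - 1e-12,
            "signal region [%.3f, %.3f] outside the ppm axis", min(r), max(r))
  }
  mask <- .in_regions(spec$ppm, signal_regions)
  .assert(!all(mask), "signal_regions cover the whole axis; no baseline points left")
  out <- spec
  if (method == "poly") {
    x <- (spec$ppm - mean(spec$ppm)) / (diff(rng) / 2)  # scaled for conditioning
    P <- outer(x, 0:poly_order, `^`)
    beta <- stats::lm.fit(P[!mask, , drop = FALSE], spec$intensity[!mask])$coefficients
    beta[is.na(beta)] <- 0
    out$intensity <- spec$intensity - as.numeric(P %*% beta)
  } else {
    w <- min(as.integer(window), length(spec$ppm))
    if (w %% 2 == 0) w <- w - 1L
    y <- spec$intensity
    # interpolate across masked points from the flanking baseline first
    if (any(mask)) {
      y[mask] <- stats::approx(spec$ppm[!mask], y[!mask], xout = spec$ppm[mask],
                               rule = 2)$y
    }
    rmin <- stats::runmed(y, w)
    k <- rep(1 / w, w)
    pad <- (w - 1L) %/% 2L
    ypad <- c(rep(rmin[1], pad), rmin, rep(rmin[length(rmin)], pad))
    smooth <- stats::filter(ypad, k, sides = 2)[(pad + 1):(pad + length(rmin))]
    out$intensity <- spec$intensity - as.numeric(smooth)
  }
  out
}

#' Estimate spectral noise from a signal-free region
#'
#' Robust (median-absolute-deviation) standard deviation of the intensities in
#' a quiet region. The estimate is stored on the returned spectrum as
#' `noise_sd` and is the basis of detection limits and upper/lower free-energy
#' bounds downstream.
#'
#' @param spec a `spectrum1d`.
#' @param quiet_region `c(high_ppm, low_ppm)` interval with >= 50 points and no
#'   fitted peak; if `peaks` is supplied, any peak centre inside the region is
#'   rejected.
#' @param peaks optional data frame of peaks (column `center_ppm`) to guard
#'   the region against.
#' @return The spectrum with `noise_sd` set; retrieve with `$noise_sd`.
#' @export
estimate_noise <- function(spec, quiet_region, peaks = NULL) {
  .assert(inherits(spec, "spectrum1d"), "spec must be a spectrum1d")
  hi <- max(quiet_region); lo <- min(quiet_region)
  sel <- spec$ppm <= hi & spec$ppm >= lo
  .assert(sum(sel) >= 50, "quiet region contains %d points; need >= 50", sum(sel))
  if (!is.null(peaks) && nrow(peaks) > 0) {
    inside <- peaks$center_ppm <= hi & peaks$center_ppm >= lo
    .assert(!any(inside), "quiet region contains fitted peak centre(s) at %s ppm",
            paste(sprintf("%.2f", peaks$center_ppm[inside]), collapse = ", "))
  }
  out <- spec
  out$noise_sd <- stats::mad(spec$intensity[sel], constant = 1.4826)
  out
}
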