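#' Bootstrap-of-residuals uncertainty for a line-shape fit
#'
#' Resamples the fit residuals with replacement, adds them to the fitted
#' curve, and refits `B` times starting from the original solution (so the
#' replicate dispersion measures parameter uncertainty, not basin-hopping
#' variability). Because exponential apodization and zero-filling correlate
#' the spectral noise over a few points, residuals are resampled in moving
#' blocks whose length is chosen from the residual autocorrelation (three
#' times the lag at which it drops below 0.1); for white residuals this
#' reduces to a short-block bootstrap equivalent to the classic one. Returns per-parameter standard deviations and
#' percentile intervals, including for the fractional populations.
#' Deterministic given `seed`.
#'
#' @param fit a converged frequency-domain `lineshape_fit`.
#' @param B number of bootstrap replicates (>= 50).
#' @param seed integer seed.
#' @param block moving-block length; `NULL` (default) chooses it from the
#'   residual autocorrelation.
#' @param max_fail_frac maximum tolerated fraction of non-converged replicate
#'   fits (default 0.2) before the bootstrap is rejected.
#' @return An object of class `bootstrap_result` with fields
#'   `parameter_samples` (B x p matrix), `point_estimate`, `sd`, `ci68`,
#'   `ci95`, `B`, `seed`.
#' @export
bootstrap_fit <- function(fit, B = 200, seed = 1L, block = NULL,
                          max_fail_frac = 0.2) {
  .assert(inherits(fit, "lineshape_fit"), "fit must be a lineshape_fit")
  .assert(fit$domain == "frequency", "bootstrap_fit operates on frequency-domain fits")
  .assert(fit$converged, "fit did not converge; bootstrap rejected")
  .assert(.is_num1(B) && B >= 50, "B must be >= 50")
  spec <- fit$data
  yhat <- fitted(fit)
  r <- fit$residuals
  n <- fit$n_states
  init <- fit$peaks[, c("center_ppm", "fwhm_hz", "integral")]

  if (is.null(block)) block <- .auto_block(r)
  param_names <- c(names(coef(fit)),
                   paste0("frac_", seq_len(n)))
  samples <- matrix(NA_real_, B, length(param_names),
                    dimnames = list(NULL, param_names))
  failed <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      ystar <- yhat + .block_resample(r, block)
      sp <- new_spectrum1d(spec$ppm, ystar, acq = spec$acq)
      fb <- tryCatch(fit_lorentzians(sp, n, init = init, sfrq = fit$sfrq,
                                     bounds = fit$bounds,
                                     width_bounds = fit$width_bounds %||% c(5, 1000)),
                     error = function(e) NULL)
      if (is.null(fb) || !fb$converged) { failed <- failed + 1L; next }
      # match replicate peaks to the original ones (centre + width class)
      pk <- fb$peaks[.match_peaks(fit$peaks, fb$peaks), ]
      samples[b, ] <- c(as.numeric(t(as.matrix(
        pk[, c("center_ppm", "fwhm_hz", "integral")]))),
        pk$integral / sum(pk$integral))
    }
  })
  .assert(failed <= max_fail_frac * B,
          "%d of %d bootstrap refits failed to converge (limit %.0f%%)",
          failed, B, 100 * max_fail_frac)
  samples <- samples[stats::complete.cases(samples), , drop = FALSE]
  point <- c(coef(fit), fit$peaks$integral / sum(fit$peaks$integral))
  names(point) <- param_names
  qs <- function(p) apply(samples, 2, stats::quantile, probs = p, names = FALSE)
  structure(list(parameter_samples = samples,
                 point_estimate = point,
                 sd = apply(samples, 2, stats::sd),
                 ci68 = rbind(lower = qs(0.16), upper = qs(0.84)),
                 ci95 = rbind(lower = qs(0.025), upper = qs(0.975)),
                 B = B, n_failed = failed, seed = seed, block = block,
                 labels = fit$peaks$label),
            class = "bootstrap_result")
}

# greedy 1:1 matching of replicate peaks to original peaks by centre
# proximity plus a width-ratio penalty (keeps state identity stable)
.match_peaks <- function(orig, rep) {
  n <- nrow(orig)
  cost <- outer(seq_len(n), seq_len(n), function(i, j) {
    abs(orig$center_ppm[i] - rep$center_ppm[j]) +
      0.1 * abs(log(orig$fwhm_hz[i] / rep$fwhm_hz[j]))
  })
  perm <- integer(n)
  for (step in seq_len(n)) {
    ij <- arrayInd(which.min(cost), dim(cost))
    perm[ij[1]] <- ij[2]
    cost[ij[1], ] <- Inf; cost[, ij[2]] <- Inf
  }
  perm
}

# block length: ~3x the decorrelation lag (where autocorrelation drops
# below 0.1), so block means carry negligible cross-block correlation
.auto_block <- function(r, max_block = 30L) {
  n <- length(r)
  ac <- stats::acf(r, lag.max = min(max_block, n - 1), plot = FALSE)$acf[-1]
  b <- which(ac < 0.1)[1]
  if (is.na(b)) b <- max_block
  min(max(1L, 3L * as.integer(b)), max_block)
}

# moving-block resample of a residual vector to its own length
.block_resample <- function(r, block) {
  n <- length(r)
  if (block <= 1L) return(sample(r, n, replace = TRUE))
  nb <- ceiling(n / block)
  starts <- sample.int(n - block + 1L, nb, replace = TRUE)
  idx <- as.vector(outer(0:(block - 1L), starts, `+`))[seq_len(n)]
  r[idx]
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> B = %d (%d failed), seed %d\n",
              x$B, x$n_failed, x$seed))
  tab <- data.frame(estimate = x$point_estimate, sd = x$sd,
                    ci68_lo = x$ci68["lower", ], ci68_hi = x$ci68["upper", ])
  print(tab, digits = 4)
  invisible(x)
}
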