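#' State populations from a fitted line shape
#'
#' Peak integrals are directly proportional to the concentration of each
#' state, so fractional populations are `integral / sum(integrals)`. Expected
#' states absent from the fit are reported as `below_limit` with a bound equal
#' to the spectral detection limit: the fractional area of the smallest peak
#' of typical width whose height reaches `z_detect` times the spectral noise,
#' capped at `limit_cap` (the ~5% level of low-concentration 19F work).
#'
#' @param fit a converged, state-labelled `lineshape_fit`
#'   (see [assign_states()]); unlabelled fits are labelled with defaults.
#' @param noise_sd spectral noise standard deviation (intensity units); taken
#'   from the fitted spectrum when `NULL`.
#' @param expected_states states the construct could populate.
#' @param boot optional [bootstrap_fit()] result used to attach fraction
#'   standard deviations.
#' @param typical_width_hz line-width assumed for an undetected state.
#' @param z_detect detection threshold in noise sd units (default 3).
#' @param limit_cap cap on the detection limit (default 0.05).
#' @return An object of class `population_set`: data frame `table` with one
#'   row per expected state (`state`, `fraction`, `sd`, `status`, `bound`,
#'   `residual` — the sub-limit fitted mass, so detected fractions plus
#'   residuals sum to 1), plus `total_integral`, `detection_limit` and
#'   (when `boot` is given) the bootstrap fraction `samples`.
#' @export
populations_from_fit <- function(fit, noise_sd = NULL,
                                 expected_states = c("U", "I1", "I2", "N"),
                                 boot = NULL,
                                 typical_width_hz = 100,
                                 z_detect = 3, limit_cap = 0.05) {
  .assert(inherits(fit, "lineshape_fit"), "fit must be a lineshape_fit")
  .assert(fit$converged, "fit did not converge; populations rejected")
  noise_sd <- noise_sd %||% fit$noise_sd %||% fit$data$noise_sd
  .assert(!is.null(noise_sd), "noise_sd is required (run estimate_noise first)")
  if (all(is.na(fit$peaks$label))) fit <- assign_states(fit)
  pk <- fit$peaks
  total <- sum(pk$integral)
  .assert(total > 0, "zero total integral; populations undefined")

  # smallest detectable fractional area: height z*noise at typical width
  min_area <- z_detect * noise_sd * pi * (typical_width_hz / fit$sfrq) / 2
  limit <- min(limit_cap, min_area / total)

  frac <- stats::setNames(pk$integral / total, pk$label)
  sds <- rep(NA_real_, nrow(pk))
  samples <- NULL
  if (!is.null(boot)) {
    fr_cols <- grep("^frac_", colnames(boot$parameter_samples))
    sds <- boot$sd[fr_cols]
    samples <- boot$parameter_samples[, fr_cols, drop = FALSE]
    colnames(samples) <- pk$label
  }
  rows <- lapply(expected_states, function(st) {
    i <- match(st, pk$label)
    if (!is.na(i) && frac[i] >= limit) {
      data.frame(state = st, fraction = unname(frac[i]), sd = unname(sds[i]),
                 status = "detected", bound = NA_real_, residual = NA_real_)
    } else {
      # `residual` keeps the (sub-limit) fitted mass so that detected
      # fractions and residuals still sum to 1 exactly
      data.frame(state = st, fraction = NA_real_, sd = NA_real_,
                 status = "below_limit", bound = limit,
                 residual = if (!is.na(i)) unname(frac[i]) else 0)
    }
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, total_integral = total, detection_limit = limit,
                 samples = samples),
            class = "population_set")
}

#' @export
print.population_set <- function(x, ...) {
  cat(sprintf("<population_set> total integral %.4g, detection limit %.3f\n",
              x$total_integral, x$detection_limit))
  print(x$table, digits = 3)
  invisible(x)
}
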