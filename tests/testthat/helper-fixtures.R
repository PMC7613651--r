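# Shared fixtures: a fast small acquisition for unit tests and the canonical
# four-state construct. All synthetic data are generated in code at test time.

small_acq <- function() acq_params(sweep_width_ppm = 10, acq_time_s = 0.15)

four_state <- function(pops = c(0.25, 0.25, 0.25, 0.25)) paper_like_construct(pops)

single_u <- function() construct_spec(
  "U-only", list(state_spec("U", -61.8, 25, 1)), linker_length = 21L)

# quiet region (ppm) inside the small and default windows, away from peaks
QUIET <- c(-58.2, -59.8)

RT298 <- 1.9872e-3 * 298

# population_set built directly (bypassing a fit) for thermodynamics tests
make_pops <- function(states, fractions, sds = NA_real_, limit = 0.05) {
  det <- !is.na(fractions)
  tab <- data.frame(state = states,
                    fraction = ifelse(det, fractions, NA_real_),
                    sd = rep_len(sds, length(states)),
                    status = ifelse(det, "detected", "below_limit"),
                    bound = ifelse(det, NA_real_, limit),
                    residual = ifelse(det, NA_real_, 0))
  structure(list(table = tab, total_integral = 1, detection_limit = limit,
                 samples = NULL),
            class = "population_set")
}
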