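#' Thermodynamic configuration
#'
#' @param temperature_K sample temperature in kelvin (default 298, the
#'   acquisition temperature).
#' @param gas_constant R in kcal mol^-1 K^-1.
#' @return An object of class `thermo_config`.
#' @export
thermo_config <- function(temperature_K = 298, gas_constant = 1.9872e-3) {
  .assert(.is_num1(temperature_K) && temperature_K > 0, "temperature_K must be > 0")
  structure(list(temperature_K = temperature_K, gas_constant = gas_constant,
                 RT = gas_constant * temperature_K), class = "thermo_config")
}

.new_free_energy <- function(state, dG, err, kind) {
  structure(list(state = state, dG_kcal_mol = dG, err = err, kind = kind),
            class = "free_energy")
}

#' @export
print.free_energy <- function(x, ...) {
  tag <- switch(x$kind, point = "", upper_bound = " (upper bound)",
                lower_bound = " (lower bound)")
  cat(sprintf("dG_%s-U = %.3f +/- %.3f kcal/mol%s\n", x$state, x$dG_kcal_mol,
              x$err %||% NA_real_, tag))
  invisible(x)
}

#' Free energies of folding states relative to the unfolded state
#'
#' For every detected state X, \eqn{\Delta G_{X-U} = -RT \ln(p_X / p_U)}.
#' When X is below the detection limit the population ratio is censored at the
#' limit, giving a lower bound \eqn{-RT \ln(limit / p_U)} (X is at least this
#' unstable); when U is below the limit, an upper bound
#' \eqn{-RT \ln(p_X / limit)} results. When the population set carries
#' bootstrap fraction samples, the error is the bootstrap standard deviation
#' of the log-ratio itself (which respects the negative correlation between
#' compositional fractions); otherwise the delta method
#' \eqn{\sigma_{\Delta G} = RT \sqrt{(\sigma_X/p_X)^2 + (\sigma_U/p_U)^2}}
#' is used.
#'
#' @param pops a [populations_from_fit()] result.
#' @param cfg a [thermo_config()].
#' @return list of `free_energy` objects, one per non-U expected state.
#' @export
delta_g <- function(pops, cfg = thermo_config()) {
  .assert(inherits(pops, "population_set"), "pops must be a population_set")
  tab <- pops$table
  iu <- match("U", tab$state)
  .assert(!is.na(iu), "population set must include the U state")
  .assert(any(tab$status == "detected"), "no detected states")
  RT <- cfg$RT
  u_det <- tab$status[iu] == "detected"
  pu <- if (u_det) tab$fraction[iu] else tab$bound[iu]
  su <- if (u_det) tab$sd[iu] else NA_real_
  out <- list()
  for (i in seq_len(nrow(tab))) {
    st <- tab$state[i]
    if (st == "U") next
    x_det <- tab$status[i] == "detected"
    .assert(x_det || u_det,
            "both %s and U are below the detection limit: no information", st)
    if (x_det && u_det) {
      dg <- -RT * log(tab$fraction[i] / pu)
      err <- NA_real_
      if (!is.null(pops$samples) && all(c(st, "U") %in% colnames(pops$samples))) {
        v <- -RT * log(pops$samples[, st] / pops$samples[, "U"])
        v <- v[is.finite(v)]
        if (length(v) >= 20) err <- stats::sd(v)
      }
      if (is.na(err)) {
        err <- RT * .quad(
          if (is.na(tab$sd[i])) 0 else tab$sd[i] / tab$fraction[i],
          if (is.na(su)) 0 else su / pu)
      }
      out[[st]] <- .new_free_energy(st, dg, err, "point")
    } else if (!x_det) {
      out[[st]] <- .new_free_energy(st, -RT * log(tab$bound[i] / pu), NA_real_,
                                    "lower_bound")
    } else {
      out[[st]] <- .new_free_energy(st, -RT * log(tab$fraction[i] / pu), NA_real_,
                                    "upper_bound")
    }
  }
  out
}

#' Free-energy change between two constructs
#'
#' \eqn{\Delta\Delta G = \Delta G_b - \Delta G_a} for the same state, errors
#' summed in quadrature. Bound kinds propagate: a bound minus a point estimate
#' stays a bound (direction preserved for `b`, inverted for a bound on `a`).
#'
#' @param fe_a,fe_b `free_energy` objects for the same state (reference
#'   construct first).
#' @return An object of class `delta_delta_g`.
#' @export
ddg <- function(fe_a, fe_b) {
  .assert(inherits(fe_a, "free_energy") && inherits(fe_b, "free_energy"),
          "inputs must be free_energy objects")
  .assert(identical(fe_a$state, fe_b$state),
          "mismatched states: %s vs %s", fe_a$state, fe_b$state)
  val <- fe_b$dG_kcal_mol - fe_a$dG_kcal_mol
  err <- .quad(fe_a$err %||% 0, fe_b$err %||% 0)
  if (anyNA(c(fe_a$err, fe_b$err)) &&
      (fe_a$kind != "point" || fe_b$kind != "point")) err <- NA_real_
  flip <- function(k) switch(k, lower_bound = "upper_bound",
                             upper_bound = "lower_bound", "point")
  kind <- if (fe_a$kind == "point" && fe_b$kind == "point") "point"
          else if (fe_a$kind == "point") fe_b$kind
          else if (fe_b$kind == "point") flip(fe_a$kind)
          else if (flip(fe_a$kind) == fe_b$kind) fe_b$kind
          else stop("opposing bounds give no information on the difference",
                    call. = FALSE)
  structure(list(state = fe_a$state, ddG_kcal_mol = val, err = err, kind = kind),
            class = "delta_delta_g")
}

#' @export
print.delta_delta_g <- function(x, ...) {
  tag <- switch(x$kind, point = "", upper_bound = " (upper bound)",
                lower_bound = " (lower bound)")
  cat(sprintf("ddG_%s-U = %.3f +/- %.3f kcal/mol%s\n", x$state, x$ddG_kcal_mol,
              x$err, tag))
  invisible(x)
}

#' Free-energy landscape across linker lengths
#'
#' One row per (length, non-U state) that is either detected or boundable:
#' the co-translational free-energy landscape, with upper/lower bounds where a
#' state (or U) fell below the detection limit.
#'
#' @param series list of `list(linker_length =, pops =)` entries, lengths
#'   unique.
#' @param cfg a [thermo_config()].
#' @return A data frame of class `landscape_table` with columns
#'   `linker_length`, `state`, `dG`, `err`, `kind`, sorted by length then
#'   state.
#' @export
build_landscape <- function(series, cfg = thermo_config()) {
  .assert(is.list(series) && length(series) > 0, "empty series")
  lens <- vapply(series, `[[`, 0, "linker_length")
  .assert(!anyDuplicated(lens), "linker lengths must be unique")
  rows <- list()
  for (el in series) {
    fes <- tryCatch(delta_g(el$pops, cfg), error = function(e) list())
    for (fe in fes) {
      rows[[length(rows) + 1L]] <- data.frame(
        linker_length = el$linker_length, state = fe$state,
        dG = fe$dG_kcal_mol, err = fe$err %||% NA_real_, kind = fe$kind)
    }
  }
  .assert(length(rows) > 0, "no state was detected at any length")
  out <- do.call(rbind, rows)
  out <- out[order(out$linker_length, out$state), ]
  rownames(out) <- NULL
  class(out) <- c("landscape_table", "data.frame")
  out
}

#' Re-reference free energies to another state
#'
#' \eqn{\Delta G_{X-ref} = \Delta G_{X-U} - \Delta G_{ref-U}} with errors in
#' quadrature; the reference must be available as a point estimate.
#'
#' @param fes list of `free_energy` objects (all relative to U).
#' @param ref state label to re-reference to; `"U"` returns the input.
#' @return list of transformed `free_energy` objects (state labels kept, the
#'   reference state itself appearing with dG = 0).
#' @export
relative_to <- function(fes, ref) {
  if (identical(ref, "U")) return(fes)
  labs <- vapply(fes, `[[`, "", "state")
  i <- match(ref, labs)
  .assert(!is.na(i), "reference state %s not present", ref)
  fr <- fes[[i]]
  .assert(fr$kind == "point", "reference state %s only available as a bound", ref)
  lapply(fes, function(fe) {
    kind <- fe$kind
    err <- if (identical(fe$state, ref)) 0 else .quad(fe$err %||% 0, fr$err %||% 0)
    if (is.na(fe$err %||% NA_real_) && kind != "point") err <- NA_real_
    .new_free_energy(fe$state, fe$dG_kcal_mol - fr$dG_kcal_mol,
                     if (identical(fe$state, ref)) 0 else err, kind)
  })
}
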