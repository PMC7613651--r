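# Plain-text interchange: FIDs as four-column tables (index, t, re, im) with a
# JSON sidecar for acquisition metadata; spectra as two-column (ppm, intensity)
# tables with a sidecar.

.sidecar_path <- function(path) paste0(path, ".json")

#' Write / read an FID as paired-column text
#'
#' @param fid an `fid` object.
#' @param path output path; acquisition metadata goes to `<path>.json`.
#' @return `write_fid` returns `path` invisibly; `read_fid` returns an `fid`.
#' @export
write_fid <- function(fid, path) {
  .assert(inherits(fid, "fid"), "fid must be an fid object")
  df <- data.frame(index = seq_along(fid$samples) - 1L,
                   t_s = fid_times(fid),
                   re = Re(fid$samples), im = Im(fid$samples))
  utils::write.table(format(df, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(fid$acq), .sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fid
#' @export
read_fid <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  acq <- structure(meta[c("spectrometer_freq_mhz", "carrier_ppm",
                          "sweep_width_hz", "n_points", "acq_time_s")],
                   class = "acq_params")
  acq$n_points <- as.integer(acq$n_points)
  new_fid(complex(real = df$re, imaginary = df$im), acq)
}

#' Write / read a spectrum as tabular text
#'
#' @param spec a `spectrum1d`.
#' @param path output path; `noise_sd` and acquisition metadata go to
#'   `<path>.json`.
#' @return `write_spectrum` returns `path` invisibly; `read_spectrum` a
#'   `spectrum1d`.
#' @export
write_spectrum <- function(spec, path) {
  .assert(inherits(spec, "spectrum1d"), "spec must be a spectrum1d")
  utils::write.table(
    format(data.frame(ppm = spec$ppm, intensity = spec$intensity), digits = 17),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(noise_sd = spec$noise_sd)
  if (!is.null(spec$acq)) meta$acq <- unclass(spec$acq)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- if (file.exists(.sidecar_path(path)))
    jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE) else list()
  acq <- NULL
  if (!is.null(meta$acq)) {
    acq <- structure(as.list(meta$acq), class = "acq_params")
    acq$n_points <- as.integer(acq$n_points)
  }
  new_spectrum1d(df$ppm, df$intensity, noise_sd = meta$noise_sd, acq = acq)
}
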