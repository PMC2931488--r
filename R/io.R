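#' Read and write spectra, FIDs and expression tables
#'
#' Plain-text interchange formats: spectra as two-column CSV
#' (`ppm`, `intensity`; ppm decreasing), FIDs as three-column CSV
#' (`time_s`, `real`, `imag`) with acquisition metadata in `#`-prefixed
#' header lines, expression matrices and flags as TSV with probes in rows.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param path File path.
#' @name mrs_io
NULL

#' @rdname mrs_io
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# acquisition_type: %s", spectrum$acquisition_type), con)
  writeLines(sprintf("# sample_mass_g: %s",
                     format(spectrum$sample_mass, digits = 15)), con)
  writeLines(sprintf("# normalization_state: %s",
                     spectrum$normalization_state), con)
  utils::write.table(
    data.frame(ppm = spectrum$ppm, intensity = spectrum$intensity),
    con, sep = ",", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname mrs_io
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
  nmr_spectrum(tab$ppm, tab$intensity,
               acquisition_type = get("acquisition_type", "pulse-acquire"),
               sample_mass = suppressWarnings(
                 as.numeric(get("sample_mass_g", NA))),
               normalization_state = get("normalization_state", "raw"))
}

#' @rdname mrs_io
#' @param fid An [nmr_fid()].
#' @export
write_fid_csv <- function(fid, path) {
  stopifnot(inherits(fid, "nmr_fid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dwell_time_s: %s", format(fid$dwell_time, digits = 15)), con)
  writeLines(sprintf("# spectrometer_frequency_mhz: %s",
                     format(fid$spectrometer_frequency, digits = 15)), con)
  writeLines(sprintf("# carrier_ppm: %s", format(fid$carrier_ppm, digits = 15)), con)
  writeLines(sprintf("# sample_mass_g: %s", format(fid$sample_mass, digits = 15)), con)
  t <- (seq_len(fid$n_points) - 1L) * fid$dwell_time
  utils::write.table(
    data.frame(time_s = t, real = Re(fid$signal), imag = Im(fid$signal)),
    con, sep = ",", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname mrs_io
#' @export
read_fid_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(NA_real_)
    suppressWarnings(as.numeric(trimws(sub(paste0("^# ", key, ":"), "", m[1]))))
  }
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
  nmr_fid(complex(real = tab$real, imaginary = tab$imag),
          dwell_time = get("dwell_time_s"),
          spectrometer_frequency = get("spectrometer_frequency_mhz"),
          carrier_ppm = get("carrier_ppm"),
          sample_mass = get("sample_mass_g"))
}

#' @rdname mrs_io
#' @param mat Matrix with dimnames.
#' @export
write_matrix_tsv <- function(mat, path) {
  utils::write.table(as.matrix(mat), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname mrs_io
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
}
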