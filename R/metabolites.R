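#' Metabolite resonance specification
#'
#' Describes a single quantifiable resonance: its chemical shift, the number
#' of equivalent protons giving rise to the signal (the `k` of the
#' concentration equation), and its natural linewidths.  All six default
#' tissue metabolites are singlet-like resonances in the 3.60-2.90 ppm
#' region; multiplet structure is not modelled.
#'
#' @param name Metabolite label (character scalar).
#' @param chemical_shift Resonance position in ppm.
#' @param protons Number of protons contributing to the resonance
#'   (integer >= 1), e.g. 9 for an N-trimethyl singlet.
#' @param lorentzian_hwhm Lorentzian half width at half maximum, in Hz.
#' @param gaussian_hwhm Gaussian half width at half maximum, in Hz.  The
#'   synthetic generator produces pure Lorentzian lines when this is 0.
#'
#' @return An object of class `metabolite_spec`.
#' @seealso [default_metabolites()]
#' @export
metabolite_spec <- function(name, chemical_shift, protons,
                            lorentzian_hwhm = 0.65, gaussian_hwhm = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  protons <- as.integer(protons)
  if (is.na(protons) || protons < 1L)
    stop("'protons' must be an integer >= 1", call. = FALSE)
  if (lorentzian_hwhm <= 0)
    stop("'lorentzian_hwhm' must be > 0", call. = FALSE)
  if (gaussian_hwhm < 0)
    stop("'gaussian_hwhm' must be >= 0", call. = FALSE)
  structure(
    list(name = name, chemical_shift = chemical_shift, protons = protons,
         lorentzian_hwhm = lorentzian_hwhm, gaussian_hwhm = gaussian_hwhm),
    class = "metabolite_spec"
  )
}

#' Default choline-region metabolite assignments
#'
#' The six metabolites quantified in the 3.60-2.90 ppm region, with standard
#' 1H chemical-shift assignments and proton counts from molecular structure:
#' the N-trimethyl singlets of choline, phosphocholine (PCho) and
#' glycerophosphocholine (GPC) carry 9 protons, creatine N-CH3 carries 3,
#' and the quantified glycine and taurine CH2 resonances carry 2 each.
#'
#' @return Named list of [metabolite_spec()] objects.
#' @export
#' @examples
#' default_metabolites()$gpc
default_metabolites <- function() {
  list(
    creatine = metabolite_spec("creatine", 3.03, 3L),
    choline  = metabolite_spec("choline",  3.21, 9L),
    pcho     = metabolite_spec("pcho",     3.23, 9L),
    gpc      = metabolite_spec("gpc",      3.24, 9L),
    taurine  = metabolite_spec("taurine",  3.43, 2L),
    glycine  = metabolite_spec("glycine",  3.56, 2L)
  )
}

#' Chemical-shift reference and electronic-reference resonances
#'
#' TSP (trimethylsilyl propionate) is the chemical-shift reference at 0 ppm
#' (9 equivalent protons); the ERETIC electronic reference signal is placed
#' at -1.0 ppm and behaves as a single-"proton" resonance whose amplitude
#' encodes a known equivalent molar amount.
#'
#' @return A [metabolite_spec()].
#' @export
tsp_spec <- function() metabolite_spec("tsp", 0.00, 9L)

#' @rdname tsp_spec
#' @export
eretic_spec <- function() metabolite_spec("eretic", -1.00, 1L)

#' Quantification regions
#'
#' The ppm intervals deconvolved for quantification, given as
#' `c(high, low)` following the NMR display convention (ppm decreasing left
#' to right): TSP 0.20 to -0.20 ppm, ERETIC -0.85 to -1.15 ppm, the
#' metabolite region 3.60 to 2.90 ppm, and the 3.60 to 3.00 ppm region used
#' for relative-area analysis of CPMG spectra.
#'
#' @return Named list of length-2 numeric vectors `c(high, low)`.
#' @export
quant_regions <- function() {
  list(
    tsp        = c(0.20, -0.20),
    eretic     = c(-0.85, -1.15),
    metabolite = c(3.60, 2.90),
    human      = c(3.60, 3.00)
  )
}

#' Default acquisition parameters
#'
#' Pulse-acquire acquisition emulating a 600.13 MHz instrument: sweep width
#' 16.7 ppm, 32768 complex points (64K sequentially sampled real points)
#' giving an acquisition time of about 3.27 s, carrier on water at 4.7 ppm.
#'
#' @param sweep_width_ppm Spectral width in ppm.
#' @param spectrometer_frequency Proton frequency in MHz.
#' @param n_points Number of complex time-domain points.
#' @param carrier_ppm Transmitter offset in ppm (centre of the spectrum).
#'
#' @return A list with fields `sweep_width_ppm`, `sweep_width_hz`,
#'   `spectrometer_frequency`, `n_points`, `carrier_ppm`, `dwell_time`.
#' @export
acquisition_params <- function(sweep_width_ppm = 16.7,
                               spectrometer_frequency = 600.13,
                               n_points = 32768L,
                               carrier_ppm = 4.7) {
  sw_hz <- sweep_width_ppm * spectrometer_frequency
  list(
    sweep_width_ppm = sweep_width_ppm,
    sweep_width_hz = sw_hz,
    spectrometer_frequency = spectrometer_frequency,
    n_points = as.integer(n_points),
    carrier_ppm = carrier_ppm,
    dwell_time = 1 / sw_hz
  )
}
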