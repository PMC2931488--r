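# Number of protons of the creatine N-CH3 singlet used in calibration.
.k_creatine <- 3L

#' Simulate creatine calibration standards for ERETIC quantification
#'
#' Forward model of the calibration series: each standard contains a known
#' molar amount of creatine, and the observed creatine/ERETIC area ratio is
#' `k_creatine * amount / n_eretic`, optionally perturbed by multiplicative
#' Gaussian area noise.
#'
#' @param amounts_mol Known creatine amounts in mol (>= 2 values).
#' @param n_eretic Ground-truth equivalent amount of the electronic
#'   reference, in mol.
#' @param area_noise Relative SD of multiplicative noise on each area.
#' @param seed Optional integer seed.
#' @return data.frame with columns `amount_mol`, `a_creatine`, `a_eretic`.
#' @export
simulate_eretic_standards <- function(amounts_mol, n_eretic = 3.17e-7,
                                      area_noise = 0, seed = NULL) {
  if (n_eretic <= 0) stop("'n_eretic' must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(amounts_mol)
  a_er <- rep(1, n)
  a_cr <- .k_creatine * amounts_mol / n_eretic
  if (area_noise > 0) {
    a_cr <- a_cr * (1 + stats::rnorm(n, 0, area_noise))
    a_er <- a_er * (1 + stats::rnorm(n, 0, area_noise))
  }
  data.frame(amount_mol = amounts_mol, a_creatine = a_cr, a_eretic = a_er)
}

#' Calibrate the ERETIC reference from creatine standards
#'
#' Quantifies the equivalent molar amount of the electronic reference
#' signal: by the concentration equation, `k_creatine x amount =
#' (A_creatine / A_eretic) x n_eretic` for each standard, so a least-squares
#' line through the origin of `k x amount` against the area ratio has slope
#' `n_eretic`.  The through-origin constraint reflects that a blank sample
#' has zero creatine area.
#'
#' @param standards data.frame with columns `amount_mol` (mol),
#'   `a_creatine`, `a_eretic` (areas > 0); at least two standards.
#' @param k_creatine Protons of the quantified creatine resonance.
#' @return An object of class `eretic_reference` with fields `n_eretic`
#'   (mol), `position` (ppm) and `calibration_r2`.
#' @export
#' @examples
#' std <- simulate_eretic_standards(seq(5e-9, 5e-8, length.out = 6))
#' calibrate_eretic(std)$n_eretic   # 3.17e-07
calibrate_eretic <- function(standards, k_creatine = .k_creatine) {
  need <- c("amount_mol", "a_creatine", "a_eretic")
  if (!all(need %in% names(standards)))
    stop("'standards' must have columns amount_mol, a_creatine, a_eretic",
         call. = FALSE)
  if (nrow(standards) < 2L)
    stop("calibration requires at least 2 standards", call. = FALSE)
  if (any(standards$a_creatine <= 0) || any(standards$a_eretic <= 0))
    stop("calibration areas must be > 0", call. = FALSE)
  x <- standards$a_creatine / standards$a_eretic
  y <- k_creatine * standards$amount_mol
  sxx <- sum(x^2)
  if (sxx <= 0) stop("degenerate calibration design", call. = FALSE)
  slope <- sum(x * y) / sxx
  r2 <- 1 - sum((y - slope * x)^2) / sum(y^2)
  structure(
    list(n_eretic = slope, position = -1.0, calibration_r2 = r2),
    class = "eretic_reference"
  )
}

#' @export
print.eretic_reference <- function(x, ...) {
  cat(sprintf("<eretic_reference> n_eretic = %.4g mol at %.1f ppm (calibration r^2 = %.6f)\n",
              x$n_eretic, x$position, x$calibration_r2))
  invisible(x)
}

#' Absolute metabolite concentration from peak areas
#'
#' The concentration equation of ERETIC-referenced quantification:
#' `[MET] = (A_MET / A_ERETIC) * (1 / k_MET) * (n_ERETIC / m_sample)`,
#' returned in umol/g wet tissue.
#'
#' @param a_met Fitted metabolite peak area (> 0 allowed to be 0 for an
#'   absent metabolite).
#' @param a_eretic Fitted ERETIC peak area (> 0).
#' @param k_met Number of protons giving rise to the metabolite signal.
#' @param n_eretic Equivalent molar amount of the ERETIC signal (mol).
#' @param mass Sample mass in g (> 0).
#' @return Concentration in umol/g.
#' @export
#' @examples
#' concentration(9, 1, k_met = 9, n_eretic = 3.17e-7, mass = 0.015) # 21.13
concentration <- function(a_met, a_eretic, k_met, n_eretic, mass) {
  if (a_met < 0 || a_eretic <= 0)
    stop("areas must be positive (metabolite area may be 0)", call. = FALSE)
  if (k_met < 1) stop("'k_met' must be >= 1", call. = FALSE)
  if (mass <= 0) stop("'mass' must be > 0", call. = FALSE)
  (a_met / a_eretic) * (1 / k_met) * (n_eretic / mass) * 1e6
}

#' Quantify all metabolites of one sample
#'
#' Applies [concentration()] to every metabolite area in a fitted spectrum,
#' using the ERETIC area as reference and each metabolite's proton count.
#'
#' @param spectrum The sample's [nmr_spectrum()] (must carry `sample_mass`).
#' @param fits Region fits as returned by [fit_quant_regions()] (must
#'   include an `eretic` fit and the `metabolite` region).
#' @param reference An [calibrate_eretic()] result, or a number of moles.
#' @param metabolites Named list of [metabolite_spec()]s.
#' @return Named numeric vector of concentrations in umol/g; metabolites
#'   missing from the fit are `NA`.
#' @export
quantify_sample <- function(spectrum, fits, reference,
                            metabolites = default_metabolites()) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (is.na(spectrum$sample_mass) || spectrum$sample_mass <= 0)
    stop("spectrum carries no positive sample mass", call. = FALSE)
  n_eretic <- if (inherits(reference, "eretic_reference"))
    reference$n_eretic else as.numeric(reference)
  a_er <- fits$eretic$areas[["eretic"]]
  if (is.null(a_er) || !is.finite(a_er) || a_er <= 0)
    stop("quantification failed: missing or non-positive ERETIC area",
         call. = FALSE)
  met_areas <- fits$metabolite$areas
  out <- vapply(names(metabolites), function(m) {
    a <- met_areas[[m]]
    if (is.null(a) || !is.finite(a)) return(NA_real_)
    concentration(a, a_er, metabolites[[m]]$protons, n_eretic,
                  spectrum$sample_mass)
  }, numeric(1))
  out
}

#' Relative-area metrics for a CPMG spectrum
#'
#' Computes the GPC/PCho peak-area ratio and each metabolite's fraction of
#' the total area over the evaluation region, the quantities used when no
#' absolute reference is available.
#'
#' @param fit A `peak_fit` of the 3.60-3.00 ppm region containing `gpc` and
#'   `pcho` peaks.
#' @param spectrum The (typically total-area normalized) [nmr_spectrum()]
#'   the fit was computed from.
#' @param region ppm interval over which the total area is taken.
#' @return List with `gpc_pcho_ratio` and `fractions` (named, area /
#'   total area).
#' @export
relative_metrics <- function(fit, spectrum,
                             region = quant_regions()$human) {
  stopifnot(inherits(fit, "peak_fit"))
  areas <- fit$areas
  if (is.null(areas[["pcho"]]) || areas[["pcho"]] <= 0)
    stop("GPC/PCho ratio undefined: PCho area is not positive", call. = FALSE)
  if (is.null(areas[["gpc"]]))
    stop("GPC area missing from fit", call. = FALSE)
  total <- region_integral(spectrum, region)
  list(
    gpc_pcho_ratio = unname(areas[["gpc"]] / areas[["pcho"]]),
    fractions = areas / total
  )
}
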