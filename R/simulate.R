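# Forward model for synthetic signals.  One intensity unit corresponds to
# 1e-9 mol x proton of initial transverse magnetization, identically for
# metabolites, TSP and the ERETIC pseudo-resonance, so that quantification
# by area ratio is exact by construction.
.amp_per_mol <- 1e9

# Default per-point time-domain complex noise SD; gives a peak
# signal-to-noise ratio of about 200 for a 5 umol/g N-trimethyl singlet in
# a 15 mg sample under the default acquisition (0.3 Hz apodization) --
# typical of averaged intact-tissue spectra, and the level at which the
# deconvolution r^2 exceeds 0.95 in all three quantification regions.
.default_fid_noise_sd <- 92

# TSP amount emulating 3 ul of 98.8 mM reference solution.
.default_tsp_moles <- 2.964e-7

#' Simulate a pulse-acquire FID
#'
#' Generates the complex time-domain signal of a tissue sample as a sum of
#' exponentially (and optionally Gaussian) damped sinusoids: one resonance
#' per metabolite, the TSP reference singlet at 0 ppm and the ERETIC
#' electronic reference at -1.0 ppm.  Initial amplitudes are proportional to
#' moles x protons with a single calibration constant shared by metabolites
#' and TSP; the ERETIC amplitude is proportional to `eretic_moles` with the
#' same constant.  Complex Gaussian noise is added pointwise.
#'
#' @param concentrations Named numeric vector of tissue concentrations in
#'   umol/g; names must match `metabolites`.
#' @param mass Sample mass in g (> 0).
#' @param eretic_moles Equivalent molar amount of the electronic reference
#'   signal (>= 0; the production value is 3.17e-7 mol).
#' @param metabolites Named list of [metabolite_spec()]s.
#' @param acquisition Acquisition settings from [acquisition_params()].
#' @param noise_sd Per-point SD of the real and imaginary noise components.
#' @param tsp_moles Molar amount of the TSP reference.
#' @param seed Optional integer seed.
#' @return An [nmr_fid()] carrying `mass` as `sample_mass`.
#' @export
#' @examples
#' fid <- simulate_fid(c(gpc = 9.8, pcho = 4.5), mass = 0.015, noise_sd = 0)
#' sp <- to_spectrum(apodize(fid, 0.3))
simulate_fid <- function(concentrations, mass,
                         eretic_moles = 3.17e-7,
                         metabolites = default_metabolites(),
                         acquisition = acquisition_params(),
                         noise_sd = .default_fid_noise_sd,
                         tsp_moles = .default_tsp_moles,
                         seed = NULL) {
  if (any(concentrations < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  if (!is.numeric(mass) || mass <= 0)
    stop("'mass' must be > 0", call. = FALSE)
  if (eretic_moles < 0) stop("'eretic_moles' must be >= 0", call. = FALSE)
  unknown <- setdiff(names(concentrations), names(metabolites))
  if (length(unknown))
    stop("unknown metabolite(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n <- acquisition$n_points
  t <- (seq_len(n) - 1L) * acquisition$dwell_time
  signal <- complex(real = rep(0, n))

  add_resonance <- function(signal, spec, moles) {
    amp <- .amp_per_mol * moles * spec$protons
    if (amp == 0) return(signal)
    nu <- (spec$chemical_shift - acquisition$carrier_ppm) *
      acquisition$spectrometer_frequency        # Hz
    r2 <- 2 * pi * spec$lorentzian_hwhm          # exp(-r2 t) <-> HWHM in Hz
    env <- exp(-r2 * t)
    if (spec$gaussian_hwhm > 0)
      env <- env * exp(-(pi * spec$gaussian_hwhm * t)^2 / log(2))
    signal + amp * env * exp(1i * 2 * pi * nu * t)
  }

  for (m in names(concentrations)) {
    moles <- concentrations[[m]] * 1e-6 * mass
    signal <- add_resonance(signal, metabolites[[m]], moles)
  }
  signal <- add_resonance(signal, tsp_spec(), tsp_moles)
  signal <- add_resonance(signal, eretic_spec(), eretic_moles)
  if (noise_sd > 0)
    signal <- signal + complex(real = stats::rnorm(n, 0, noise_sd),
                               imaginary = stats::rnorm(n, 0, noise_sd))
  nmr_fid(signal, acquisition$dwell_time, acquisition$spectrometer_frequency,
          acquisition$carrier_ppm, sample_mass = mass)
}

# Truncated-normal draws on (lower, Inf) by rejection; sd = 0 collapses to
# the mean.  Vectorized over n only.
rtrunc_norm <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw > lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Cohort simulation specification
#'
#' Defines a group of tissue samples: per-metabolite concentration
#' distributions (normal truncated at zero, in umol/g), sample-mass
#' distribution and acquisition noise.
#'
#' @param group_name Group label.
#' @param n_samples Number of samples (>= 2).
#' @param metabolite_means,metabolite_sds Named numeric vectors (umol/g);
#'   means > 0, SDs >= 0, identical names.
#' @param sample_mass_mean,sample_mass_sd Mass distribution in g.
#' @param noise_sd Time-domain noise SD passed to [simulate_fid()].
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_name, n_samples, metabolite_means,
                        metabolite_sds, sample_mass_mean = 0.015,
                        sample_mass_sd = 0.003,
                        noise_sd = .default_fid_noise_sd, seed = 1L) {
  n_samples <- as.integer(n_samples)
  metabolite_means <- unlist(metabolite_means)  # YAML configs load as lists
  metabolite_sds <- unlist(metabolite_sds)
  if (n_samples < 2L) stop("'n_samples' must be >= 2", call. = FALSE)
  if (any(metabolite_means <= 0)) stop("means must be > 0", call. = FALSE)
  if (any(metabolite_sds < 0)) stop("SDs must be >= 0", call. = FALSE)
  if (!setequal(names(metabolite_means), names(metabolite_sds)))
    stop("mean and SD names must match", call. = FALSE)
  structure(
    list(group_name = group_name, n_samples = n_samples,
         metabolite_means = metabolite_means,
         metabolite_sds = metabolite_sds[names(metabolite_means)],
         sample_mass_mean = sample_mass_mean,
         sample_mass_sd = sample_mass_sd,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Xenograft cohort specifications with the reference group parameters
#'
#' Concentration distributions (umol/g, mean and SD) for the basal-like
#' (n = 10) and luminal-like (n = 9) xenograft groups used throughout the
#' package as simulation ground truth: basal-like tumours carry high GPC and
#' glycine, luminal-like tumours high PCho and taurine.
#'
#' @param noise_sd Acquisition noise SD (0 for noiseless validation runs).
#' @param seed Base seed; the luminal cohort uses `seed + 1`.
#' @return Named list of two [cohort_spec()]s (`basal`, `luminal`).
#' @export
xenograft_cohort_specs <- function(noise_sd = .default_fid_noise_sd,
                                   seed = 1L) {
  basal_means   <- c(creatine = 4.1, choline = 1.2, pcho = 4.5, gpc = 9.8,
                     taurine = 14.7, glycine = 8.2)
  basal_sds     <- c(creatine = 1.4, choline = 0.7, pcho = 2.1, gpc = 2.5,
                     taurine = 4.1, glycine = 3.0)
  luminal_means <- c(creatine = 3.4, choline = 0.9, pcho = 9.1, gpc = 2.7,
                     taurine = 19.1, glycine = 4.0)
  luminal_sds   <- c(creatine = 1.7, choline = 0.6, pcho = 4.4, gpc = 1.7,
                     taurine = 9.1, glycine = 1.8)
  list(
    basal = cohort_spec("basal-like", 10L, basal_means, basal_sds,
                        noise_sd = noise_sd, seed = seed),
    luminal = cohort_spec("luminal-like", 9L, luminal_means, luminal_sds,
                          noise_sd = noise_sd, seed = seed + 1L)
  )
}

#' Draw the ground-truth concentrations and masses of a cohort
#'
#' Per-sample concentrations come from normal distributions truncated at
#' zero (Table-style group mean and SD per metabolite), masses likewise.
#' [simulate_cohort()] uses exactly these draws before generating signals,
#' so the returned values are the ground truth of the corresponding cohort.
#'
#' @param spec A [cohort_spec()].
#' @return List with `concentrations` (n_samples x metabolite matrix,
#'   umol/g) and `mass` (numeric vector, g).
#' @export
draw_cohort_truth <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  mets <- names(spec$metabolite_means)
  conc <- matrix(NA_real_, spec$n_samples, length(mets),
                 dimnames = list(NULL, mets))
  mass <- numeric(spec$n_samples)
  for (i in seq_len(spec$n_samples)) {
    conc[i, ] <- vapply(mets, function(m)
      rtrunc_norm(1L, spec$metabolite_means[[m]], spec$metabolite_sds[[m]]),
      numeric(1))
    mass[i] <- rtrunc_norm(1L, spec$sample_mass_mean, spec$sample_mass_sd)
  }
  list(concentrations = conc, mass = mass)
}

#' Simulate a cohort of tissue samples
#'
#' Draws per-sample ground-truth concentrations and masses with
#' [draw_cohort_truth()] and generates one FID per sample.  Ground truth is
#' retained alongside each signal so downstream recovery can be scored.
#'
#' @param spec A [cohort_spec()].
#' @param metabolites,acquisition Forwarded to [simulate_fid()].
#' @return Object of class `mrs_cohort`: a list of samples, each with
#'   fields `id`, `group`, `fid`, `truth` (named umol/g), `mass`.
#' @export
simulate_cohort <- function(spec, metabolites = default_metabolites(),
                            acquisition = acquisition_params()) {
  stopifnot(inherits(spec, "cohort_spec"))
  gt <- draw_cohort_truth(spec)   # also seeds the RNG for the noise draws
  samples <- vector("list", spec$n_samples)
  for (i in seq_len(spec$n_samples)) {
    truth <- gt$concentrations[i, ]
    fid <- simulate_fid(truth, gt$mass[i], metabolites = metabolites,
                        acquisition = acquisition,
                        noise_sd = spec$noise_sd)
    samples[[i]] <- list(id = sprintf("%s_%02d", spec$group_name, i),
                         group = spec$group_name, fid = fid,
                         truth = truth, mass = gt$mass[i])
  }
  structure(samples, class = "mrs_cohort", group = spec$group_name)
}

#' @export
print.mrs_cohort <- function(x, ...) {
  cat(sprintf("<mrs_cohort> %d samples, group '%s'\n", length(x),
              attr(x, "group")))
  invisible(x)
}

#' Simulate a CPMG-style frequency-domain spectrum
#'
#' Emulates an already-acquired spin-echo (CPMG) tissue spectrum: the six
#' metabolite peaks in the 3.60-3.00 ppm window drawn directly as
#' pseudo-Voigt lines on a flat baseline (echo-train suppression of broad
#' components is emulated, not simulated), with peak areas set so the
#' GPC/PCho area ratio equals `gpc_pcho_ratio` exactly before noise.  No
#' TSP or ERETIC reference is included; these spectra support relative-area
#' analysis only.
#'
#' @param gpc_pcho_ratio Target GPC/PCho area ratio (> 0).
#' @param base_areas Named areas (arbitrary units) of the non-GPC peaks;
#'   GPC gets `gpc_pcho_ratio * base_areas["pcho"]`.
#' @param noise_sd SD of frequency-domain Gaussian noise (intensity units).
#' @param ppm_range Axis limits `c(high, low)`.
#' @param n_points Axis length.
#' @param lorentzian_hwhm,gaussian_hwhm,eta Common lineshape parameters
#'   (ppm, ppm, Lorentzian fraction).
#' @param seed Optional integer seed.
#' @return An [nmr_spectrum()] with `acquisition_type = "cpmg"`; the
#'   generated per-peak areas are attached as attribute `"true_areas"`.
#' @export
simulate_cpmg_spectrum <- function(gpc_pcho_ratio,
                                   base_areas = c(creatine = 0.8,
                                                  choline = 0.35,
                                                  pcho = 1, taurine = 2.2,
                                                  glycine = 1.3),
                                   noise_sd = 3.5,
                                   ppm_range = c(3.90, 2.70),
                                   n_points = 8192L,
                                   lorentzian_hwhm = 0.0022,
                                   gaussian_hwhm = 0.0015,
                                   eta = 0.7,
                                   seed = NULL) {
  if (!is.numeric(gpc_pcho_ratio) || gpc_pcho_ratio <= 0)
    stop("'gpc_pcho_ratio' must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  areas <- c(base_areas, gpc = unname(gpc_pcho_ratio * base_areas[["pcho"]]))
  shifts <- vapply(default_metabolites(), `[[`, numeric(1), "chemical_shift")
  ppm <- seq(max(ppm_range), min(ppm_range), length.out = n_points)
  unit_area <- pv_area(height = 1, lorentzian_hwhm = lorentzian_hwhm,
                       gaussian_hwhm = gaussian_hwhm, eta = eta)
  y <- rep(0, n_points)
  for (m in names(areas)) {
    h <- areas[[m]] / unit_area
    y <- y + pseudo_voigt(ppm, center = shifts[[m]], height = h,
                          lorentzian_hwhm = lorentzian_hwhm,
                          gaussian_hwhm = gaussian_hwhm, eta = eta)
  }
  if (noise_sd > 0) y <- y + stats::rnorm(n_points, 0, noise_sd)
  out <- nmr_spectrum(ppm, y, acquisition_type = "cpmg")
  attr(out, "true_areas") <- areas
  out
}

#' Simulate a cohort of CPMG spectra with a target ratio distribution
#'
#' Per-sample GPC/PCho ratios are drawn from a normal distribution truncated
#' at zero, emulating the spread of the ratio across patients in a receptor
#' subgroup.
#'
#' @param n_samples Number of spectra (>= 2).
#' @param ratio_mean,ratio_sd Ratio distribution parameters.
#' @param seed Integer seed.
#' @param ... Forwarded to [simulate_cpmg_spectrum()].
#' @return List with `spectra` (list of [nmr_spectrum()]) and
#'   `true_ratios` (numeric).
#' @export
simulate_cpmg_cohort <- function(n_samples, ratio_mean, ratio_sd,
                                 seed = 1L, ...) {
  if (ratio_mean <= 0) stop("'ratio_mean' must be > 0", call. = FALSE)
  set.seed(seed)
  ratios <- rtrunc_norm(n_samples, ratio_mean, ratio_sd)
  spectra <- lapply(ratios, function(r) simulate_cpmg_spectrum(r, ...))
  list(spectra = spectra, true_ratios = ratios)
}

#' Expression simulation specification
#'
#' @param n_genes Total number of genes (>= 10).
#' @param n_per_group Length-2 integer vector of arrays per group.
#' @param true_log2fc Named numeric vector of planted log2-fold differences
#'   (group 1 minus group 2); genes absent from it have difference exactly 0.
#' @param within_group_sd Within-group SD on the log2 scale.
#' @param duplicate_probe_genes Genes represented by two distinct probes.
#' @param flagged_fraction Proportion of cells flagged as outliers
#'   (0 <= f < 1).
#' @param n_background Null genes simulated in addition to the `n_genes`
#'   panel genes, emulating the rest of a whole-genome array.  Quantile
#'   normalization is rank-based, so normalizing over a realistically large
#'   array before restricting to the panel keeps extreme planted effects
#'   from being distorted by a sparse quantile grid.
#' @param seed Integer seed.
#' @return Object of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_genes = 117L, n_per_group = c(6L, 5L),
                                true_log2fc = numeric(),
                                within_group_sd = 0.25,
                                duplicate_probe_genes = character(),
                                flagged_fraction = 0,
                                n_background = 0L, seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_background <- as.integer(n_background)
  if (n_background < 0L) stop("'n_background' must be >= 0", call. = FALSE)
  if (flagged_fraction < 0 || flagged_fraction >= 1)
    stop("'flagged_fraction' must be in [0, 1)", call. = FALSE)
  if (length(true_log2fc) && is.null(names(true_log2fc)))
    stop("'true_log2fc' must be named by gene", call. = FALSE)
  if (length(true_log2fc) > n_genes)
    stop("more planted effects than genes", call. = FALSE)
  structure(
    list(n_genes = n_genes, n_per_group = as.integer(n_per_group),
         true_log2fc = true_log2fc, within_group_sd = within_group_sd,
         duplicate_probe_genes = duplicate_probe_genes,
         flagged_fraction = flagged_fraction,
         n_background = n_background, seed = as.integer(seed)),
    class = "expression_sim_spec"
  )
}

#' Planted log2-fold differences for the curated choline-pathway panel
#'
#' The differentially expressed choline-metabolism genes used as default
#' ground truth for expression simulations (positive values: higher in the
#' basal-like group), spanning choline kinases, cytidylyltransferases,
#' phospholipases and choline/glycine oxidation enzymes.
#'
#' @return Named numeric vector of log2-fold differences.
#' @export
choline_panel_effects <- function() {
  c(PLA2G4A = 6.4, CHDH = 3.3, SARDH = 2.5, PCYT1B = 1.7, GDPD5 = 1.0,
    PLA2G4B = 0.9, PTDSS1 = 0.9, LYPLA1 = 0.9, LCAT = 0.8, PLB1 = 0.7,
    PLD1 = 0.7,
    PLA2G3 = -3.1, PLA2G12A = -1.6, CHPT1 = -1.4, SLC44A1 = -1.1,
    PLD2 = -1.1, PLA2G10 = -1.1, CHKB = -0.8, LYPLA2 = -0.4,
    PCYT1A = -0.4, GDPD1 = -0.4, CHKA = -0.3)
}

#' Simulate a probe-level expression matrix
#'
#' Raw-scale intensities are `2^(baseline + group_effect + noise)`, with one
#' probe per gene (two for genes in `duplicate_probe_genes`, sharing the
#' gene's expected value with independent noise).  Outlier flags are planted
#' uniformly at random at `flagged_fraction`.
#'
#' @param spec An [expression_sim_spec()].
#' @return Object of class `expr_sim`: list with `intensities` (probe x
#'   sample matrix, raw scale), `flags` (0/1 matrix), `annotation`
#'   (data.frame `probe_id`, `gene`), `groups` (character vector of sample
#'   group labels), `truth` (named log2fc for every gene), `panel`
#'   (the curated panel gene names, excluding background genes), and
#'   `spec`.
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  set.seed(spec$seed)
  n1 <- spec$n_per_group[1]; n2 <- spec$n_per_group[2]
  effect_genes <- names(spec$true_log2fc)
  n_null <- spec$n_genes - length(effect_genes)
  panel <- c(effect_genes,
             if (n_null > 0) sprintf("NULL_G%03d", seq_len(n_null)))
  genes <- c(panel,
             if (spec$n_background > 0)
               sprintf("BG_G%05d", seq_len(spec$n_background)))
  truth <- stats::setNames(rep(0, length(genes)), genes)
  truth[effect_genes] <- spec$true_log2fc

  probes <- data.frame(
    probe_id = sprintf("P_%04d", seq_along(genes)),
    gene = genes, stringsAsFactors = FALSE
  )
  dup <- intersect(spec$duplicate_probe_genes, genes)
  if (length(dup)) {
    extra <- data.frame(
      probe_id = sprintf("P_%04d", nrow(probes) + seq_along(dup)),
      gene = dup, stringsAsFactors = FALSE
    )
    probes <- rbind(probes, extra)
  }

  # wide baseline spread (log2 intensities ~ 3-15), as on real one-color
  # arrays; a narrow spread would let quantile normalization clip the most
  # extreme planted effects
  baseline <- stats::setNames(stats::rnorm(length(genes), 9, 2), genes)
  n_samp <- n1 + n2
  groups <- c(rep("basal-like", n1), rep("luminal-like", n2))
  half <- ifelse(groups == "basal-like", 0.5, -0.5)
  log2mat <- matrix(0, nrow(probes), n_samp,
                    dimnames = list(probes$probe_id,
                                    sprintf("S%02d", seq_len(n_samp))))
  for (i in seq_len(nrow(probes))) {
    g <- probes$gene[i]
    mu <- baseline[[g]] + half * truth[[g]]
    log2mat[i, ] <- mu + stats::rnorm(n_samp, 0, spec$within_group_sd)
  }
  flags <- matrix(stats::rbinom(length(log2mat), 1L, spec$flagged_fraction),
                  nrow(log2mat), ncol(log2mat), dimnames = dimnames(log2mat))
  structure(
    list(intensities = 2^log2mat, flags = flags, annotation = probes,
         groups = groups, truth = truth, panel = panel, spec = spec),
    class = "expr_sim"
  )
}

#' @export
print.expr_sim <- function(x, ...) {
  cat(sprintf("<expr_sim> %d probes x %d samples (%d genes, %d with planted effects)\n",
              nrow(x$intensities), ncol(x$intensities),
              length(x$truth), sum(x$truth != 0)))
  invisible(x)
}
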