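# Shared fixtures, all generated in code.

# Table-style group concentrations used as simulation ground truth.
basal_conc <- c(creatine = 4.1, choline = 1.2, pcho = 4.5, gpc = 9.8,
                taurine = 14.7, glycine = 8.2)

# Reduced acquisition for property tests where sub-0.1% area accuracy is
# not the point (shorter FID -> mild truncation ringing).
quick_acq <- function() acquisition_params(n_points = 8192L)

# One fully processed noiseless sample at the production acquisition size;
# built once per test run.
noiseless_sample <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fid <- simulate_fid(basal_conc, mass = 0.015, noise_sd = 0)
      sp <- process_fid(fid)
      cache <<- list(fid = fid, spectrum = sp,
                     fits = fit_quant_regions(sp))
    }
    cache
  }
})

metabolite_shifts <- function() {
  vapply(default_metabolites(), `[[`, numeric(1), "chemical_shift")
}

# 67 strong planted effects (|log2fc| >= 0.8) among the 117 panel genes:
# the 16 table genes meeting the threshold plus 51 synthetic strong
# effects, fixed by seed.
strong_panel_effects <- function() {
  tab <- choline_panel_effects()
  strong <- tab[abs(tab) >= 0.8]
  set.seed(404)
  n_extra <- 67L - length(strong)
  extra <- stats::setNames(
    sample(c(-1, 1), n_extra, replace = TRUE) * stats::runif(n_extra, 0.8, 2.5),
    sprintf("STRONG_G%02d", seq_len(n_extra))
  )
  c(strong, extra)
}
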