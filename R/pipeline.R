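#' Process a raw FID into a calibrated spectrum
#'
#' Standard processing chain: exponential apodization (default 0.3 Hz),
#' zero filling and Fourier transformation (default to 128K points), and
#' chemical-shift calibration to the TSP singlet at 0 ppm.
#'
#' @param fid An [nmr_fid()].
#' @param line_broadening Hz of exponential line broadening.
#' @param zero_fill_to Points after zero filling.
#' @return A referenced [nmr_spectrum()].
#' @export
process_fid <- function(fid, line_broadening = 0.3, zero_fill_to = 131072L) {
  reference_to_tsp(to_spectrum(apodize(fid, line_broadening), zero_fill_to))
}

#' Quantify every sample of a simulated cohort
#'
#' Runs the full spectral chain per sample — process, deconvolve the three
#' quantification regions, convert areas to concentrations against the
#' ERETIC reference — and assembles a long-format quantification table.
#'
#' @param cohort An `mrs_cohort` from [simulate_cohort()].
#' @param reference ERETIC reference: an `eretic_reference` or moles.
#' @param line_broadening,zero_fill_to Processing settings.
#' @param metabolites Metabolite assignments.
#' @return data.frame with columns `sample`, `group`, `mass`, one column
#'   per metabolite (umol/g), and `r_squared` (minimum over the three
#'   fitted regions); ground-truth concentrations attached as attribute
#'   `"truth"`.
#' @export
quantify_cohort <- function(cohort, reference = 3.17e-7,
                            line_broadening = 0.3, zero_fill_to = 131072L,
                            metabolites = default_metabolites()) {
  stopifnot(inherits(cohort, "mrs_cohort"))
  rows <- lapply(cohort, function(s) {
    sp <- process_fid(s$fid, line_broadening, zero_fill_to)
    fits <- fit_quant_regions(sp, metabolites)
    conc <- quantify_sample(sp, fits, reference, metabolites)
    r2 <- min(vapply(fits, `[[`, numeric(1), "r_squared"))
    cbind(data.frame(sample = s$id, group = s$group, mass = s$mass,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(conc)),
          data.frame(r_squared = r2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, lapply(cohort, `[[`, "truth"))
  out
}

#' Group summary of a quantification table
#'
#' @param quant Long-format table from [quantify_cohort()] (possibly
#'   row-bound over groups).
#' @return data.frame of `mean` and `sd` per metabolite and group,
#'   mirroring a concentrations summary table.
#' @export
summarize_quant <- function(quant) {
  mets <- setdiff(names(quant)[vapply(quant, is.numeric, logical(1))],
                  c("mass", "r_squared"))
  groups <- unique(quant$group)
  out <- data.frame(metabolite = mets, stringsAsFactors = FALSE)
  for (g in groups) {
    sub <- quant[quant$group == g, mets, drop = FALSE]
    out[[paste0(g, "_mean")]] <- vapply(sub, mean, numeric(1), na.rm = TRUE)
    out[[paste0(g, "_sd")]] <- vapply(sub, stats::sd, numeric(1), na.rm = TRUE)
  }
  out
}

#' Relative-area analysis of a set of CPMG spectra
#'
#' Total-area normalizes each spectrum over the evaluation region, fits the
#' six metabolite peaks, and computes the GPC/PCho ratio and per-metabolite
#' area fractions.
#'
#' @param spectra List of [nmr_spectrum()]s (CPMG type).
#' @param region ppm interval for normalization, fitting and fractions.
#' @param metabolites Metabolite assignments (those whose shift falls in
#'   `region` are fitted).
#' @return data.frame with one row per spectrum: `sample`,
#'   `gpc_pcho_ratio`, one `frac_*` column per metabolite, `r_squared`.
#' @export
cpmg_relative_analysis <- function(spectra, region = quant_regions()$human,
                                   metabolites = default_metabolites()) {
  shifts <- vapply(metabolites, `[[`, numeric(1), "chemical_shift")
  shifts <- shifts[shifts <= max(region) & shifts >= min(region)]
  rows <- lapply(seq_along(spectra), function(i) {
    sp <- normalize_total_area(spectra[[i]], region)
    fit <- fit_region(sp, region, shifts)
    rel <- relative_metrics(fit, sp, region)
    fr <- as.data.frame(as.list(rel$fractions))
    names(fr) <- paste0("frac_", names(rel$fractions))
    cbind(data.frame(sample = sprintf("S%02d", i),
                     gpc_pcho_ratio = rel$gpc_pcho_ratio),
          fr, data.frame(r_squared = fit$r_squared))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Merge user config entries into defaults (shallow).
merge_config <- function(defaults, config) {
  if (is.null(config)) return(defaults)
  for (k in names(config)) defaults[[k]] <- config[[k]]
  defaults
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file; top-level keys matching the `config` arguments of
#'   [run_metabolite_pipeline()] / [run_expression_pipeline()].
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' Run the metabolite arm end to end
#'
#' Simulates the two xenograft-style cohorts (or cohorts given in the
#' config), processes and deconvolves every spectrum, quantifies against
#' the ERETIC reference, and compares the groups metabolite by metabolite
#' with pooled t tests.
#'
#' @param config Optional list (or path handled by [read_run_config()])
#'   with any of: `seed`, `noise_sd`, `line_broadening`, `zero_fill_to`,
#'   `n_eretic`, `cohorts` (named list of [cohort_spec()] argument lists).
#' @param out_dir Optional directory; when given, writes `quant.csv`,
#'   `summary.csv`, `comparisons.csv` and `manifest.yaml`.
#' @return List: `quant`, `summary`, `comparisons`, `manifest`.
#' @export
run_metabolite_pipeline <- function(config = NULL, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- merge_config(
    list(seed = 1L, noise_sd = .default_fid_noise_sd, line_broadening = 0.3,
         zero_fill_to = 131072L, n_eretic = 3.17e-7, cohorts = NULL),
    config
  )
  specs <- if (is.null(cfg$cohorts)) {
    xenograft_cohort_specs(noise_sd = cfg$noise_sd, seed = cfg$seed)
  } else {
    lapply(cfg$cohorts, function(cs) do.call(cohort_spec, cs))
  }
  quant <- do.call(rbind, lapply(specs, function(s)
    quantify_cohort(simulate_cohort(s), reference = cfg$n_eretic,
                    line_broadening = cfg$line_broadening,
                    zero_fill_to = cfg$zero_fill_to)))
  rownames(quant) <- NULL
  summary_tab <- summarize_quant(quant)
  comparisons <- if (length(unique(quant$group)) == 2L)
    compare_metabolites(quant) else NULL
  manifest <- list(
    stage = "metabolite",
    package_version = as.character(utils::packageVersion("cholinemrs")),
    seed = cfg$seed, noise_sd = cfg$noise_sd,
    line_broadening_hz = cfg$line_broadening,
    zero_fill_to = cfg$zero_fill_to, n_eretic_mol = cfg$n_eretic,
    min_r_squared = min(quant$r_squared),
    r_squared_warning = any(quant$r_squared <= 0.95)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(quant, file.path(out_dir, "quant.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_tab, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(comparisons))
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  list(quant = quant, summary = summary_tab, comparisons = comparisons,
       manifest = manifest)
}

#' Run the expression arm end to end
#'
#' Simulates (or accepts) a probe-level expression matrix, quantile
#' normalizes and log2 transforms, applies the outlier/presence probe
#' filters, collapses probes to transcripts, fits moderated t statistics
#' with BH FDR control, restricts to the curated panel, and clusters the
#' significant genes.
#'
#' @param config Optional list with any of: `seed`, `n_genes`,
#'   `n_per_group`, `true_log2fc` (named), `within_group_sd`,
#'   `duplicate_probe_genes`, `flagged_fraction`, `n_background`
#'   (array genes beyond the panel, normalized with it), `fdr`, `panel`
#'   (character; default the simulated panel genes), or a ready-made
#'   `expr_sim` object under `sim`.
#' @param out_dir Optional directory; writes `de_results.csv`,
#'   `gene_dendrogram.nwk`, `sample_dendrogram.nwk`,
#'   `clustered_matrix.csv` and `manifest.yaml`.
#' @return List: `fit` (`moderated_fit`), `clustering` (`expr_clust` or
#'   NULL), `sim`, `counts` (probes retained at each stage), `manifest`.
#' @export
run_expression_pipeline <- function(config = NULL, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- merge_config(
    list(seed = 1L, n_genes = 117L, n_per_group = c(6L, 5L),
         true_log2fc = choline_panel_effects(), within_group_sd = 0.25,
         duplicate_probe_genes = character(), flagged_fraction = 0.02,
         n_background = 1883L, fdr = 0.05, panel = NULL, sim = NULL),
    config
  )
  sim <- cfg$sim
  if (is.null(sim)) {
    spec <- expression_sim_spec(
      n_genes = cfg$n_genes, n_per_group = cfg$n_per_group,
      true_log2fc = unlist(cfg$true_log2fc),
      within_group_sd = cfg$within_group_sd,
      duplicate_probe_genes = cfg$duplicate_probe_genes,
      flagged_fraction = cfg$flagged_fraction,
      n_background = cfg$n_background, seed = cfg$seed
    )
    sim <- simulate_expression(spec)
  }
  panel <- if (!is.null(cfg$panel)) cfg$panel else sim$panel
  norm <- quantile_normalize(sim$intensities)
  filtered <- filter_probes(norm, sim$flags[rownames(norm), , drop = FALSE])
  collapsed <- collapse_probes(filtered, sim$annotation)
  # normalization happens array-wide; testing is restricted to the panel
  on_panel <- intersect(rownames(collapsed), panel)
  if (length(on_panel) < nrow(collapsed))
    collapsed <- collapsed[on_panel, , drop = FALSE]
  fit <- fit_moderated_t(collapsed, sim$groups, alpha = cfg$fdr)
  sig <- fit$results$gene[fit$results$significant]
  clustering <- if (length(sig) >= 2L)
    cluster_heatmap(collapsed[sig, , drop = FALSE]) else NULL
  counts <- c(probes_in = nrow(sim$intensities),
              probes_after_filter = nrow(filtered),
              transcripts = nrow(collapsed),
              significant = length(sig))
  manifest <- list(
    stage = "expression",
    package_version = as.character(utils::packageVersion("cholinemrs")),
    seed = cfg$seed, fdr = cfg$fdr,
    prior_df = fit$prior_df, prior_var = fit$prior_var,
    counts = as.list(counts)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fit$results, file.path(out_dir, "de_results.csv"),
                     row.names = FALSE)
    if (!is.null(clustering)) {
      writeLines(clustering$row_newick,
                 file.path(out_dir, "gene_dendrogram.nwk"))
      writeLines(clustering$col_newick,
                 file.path(out_dir, "sample_dendrogram.nwk"))
      utils::write.csv(clustering$matrix,
                       file.path(out_dir, "clustered_matrix.csv"))
    }
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  list(fit = fit, clustering = clustering, sim = sim, counts = counts,
       manifest = manifest)
}
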