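test_that("zero concentrations, zero references and zero noise give a zero FID", {
  fid <- simulate_fid(c(gpc = 0, choline = 0), mass = 0.015,
                      eretic_moles = 0, tsp_moles = 0, noise_sd = 0)
  expect_true(all(Mod(fid$signal) == 0))
})

test_that("default acquisition reproduces the stated acquisition time", {
  acq <- acquisition_params()
  fid <- simulate_fid(c(gpc = 1), mass = 0.015, acquisition = acq,
                      noise_sd = 0)
  # 64K sequentially sampled real points over a 16.7 ppm sweep at
  # 600.13 MHz: 65536 / (2 * 16.7 * 600.13) s, i.e. about 3.27-3.28 s
  expect_equal(acquisition_time(fid), 65536 / (2 * 16.7 * 600.13),
               tolerance = 1e-12)
  expect_lt(abs(acquisition_time(fid) - 3.28), 0.02)
})

test_that("invalid generator inputs error", {
  expect_error(simulate_fid(c(gpc = -1), mass = 0.015), "concentrations")
  expect_error(simulate_fid(c(gpc = 1), mass = 0), "mass")
  expect_error(simulate_fid(c(gpc = 1), mass = 0.01, eretic_moles = -1),
               "eretic")
  expect_error(simulate_fid(c(nope = 1), mass = 0.01), "unknown")
})

test_that("FID amplitude is linear in concentration", {
  acq <- quick_acq()
  f1 <- simulate_fid(c(gpc = 2), mass = 0.015, eretic_moles = 0,
                     tsp_moles = 0, noise_sd = 0, acquisition = acq)
  f2 <- simulate_fid(c(gpc = 4), mass = 0.015, eretic_moles = 0,
                     tsp_moles = 0, noise_sd = 0, acquisition = acq)
  expect_equal(f2$signal, 2 * f1$signal, tolerance = 1e-12)
})

test_that("frequency-domain integral equals the analytic per-resonance areas", {
  # trapezoid oracle over the full axis vs the closed-form FT value
  # amp / (2 * dwell * sfrq) summed over resonances
  acq <- acquisition_params()
  conc <- c(gpc = 9.8, creatine = 4.1)
  fid <- simulate_fid(conc, mass = 0.015, noise_sd = 0)
  sp <- to_spectrum(apodize(fid, 0.3))
  ppm_inc <- rev(sp$ppm); y_inc <- rev(sp$intensity)
  total <- sum(diff(ppm_inc) * (y_inc[-1] + y_inc[-length(y_inc)]) / 2)
  mets <- default_metabolites()
  amps <- c(
    9.8e-6 * 0.015 * mets$gpc$protons,
    4.1e-6 * 0.015 * mets$creatine$protons,
    2.964e-7 * 9,          # TSP
    3.17e-7 * 1            # ERETIC
  ) * 1e9
  predicted <- sum(amps) / (2 * acq$dwell_time * acq$spectrometer_frequency)
  expect_equal(total, predicted, tolerance = 1e-3)
})

test_that("cohort generation is reproducible and respects degenerate SDs", {
  spec0 <- cohort_spec("g", 3, c(gpc = 9.8), c(gpc = 0), noise_sd = 0,
                       sample_mass_sd = 0)
  truth <- draw_cohort_truth(spec0)
  expect_true(all(truth$concentrations[, "gpc"] == 9.8))
  expect_true(all(truth$mass == 0.015))

  spec <- cohort_spec("g", 4, c(gpc = 9.8, pcho = 4.5),
                      c(gpc = 2.5, pcho = 2.1), seed = 99,
                      noise_sd = 50)
  a <- simulate_cohort(spec, acquisition = quick_acq())
  b <- simulate_cohort(spec, acquisition = quick_acq())
  expect_identical(lapply(a, `[[`, "truth"), lapply(b, `[[`, "truth"))
  expect_identical(a[[2]]$fid$signal, b[[2]]$fid$signal)
  # ground truth retained next to each signal
  expect_named(a[[1]]$truth, c("gpc", "pcho"))
})

test_that("large-sample concentration draws recover the group mean", {
  spec <- cohort_spec("basal-like", 10000,
                      c(gpc = 9.8), c(gpc = 2.5), seed = 31)
  truth <- draw_cohort_truth(spec)
  sem <- 2.5 / sqrt(10000)
  expect_lt(abs(mean(truth$concentrations[, "gpc"]) - 9.8), 2 * sem)
})

test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec("g", 1, c(gpc = 1), c(gpc = 0)), "n_samples")
  expect_error(cohort_spec("g", 3, c(gpc = 0), c(gpc = 0)), "means")
  expect_error(cohort_spec("g", 3, c(gpc = 1), c(gpc = -1)), "SDs")
})

test_that("CPMG generator hits the target GPC/PCho ratio exactly at zero noise", {
  sp <- simulate_cpmg_spectrum(1.0, noise_sd = 0)
  areas <- attr(sp, "true_areas")
  expect_equal(unname(areas["gpc"] / areas["pcho"]), 1.0)
  fit <- fit_region(sp, quant_regions()$human, metabolite_shifts())
  expect_equal(unname(fit$areas[["gpc"]] / fit$areas[["pcho"]]), 1.0,
               tolerance = 0.01)
  expect_error(simulate_cpmg_spectrum(0), "ratio")
  expect_error(simulate_cpmg_spectrum(-1), "ratio")
})

test_that("recovered-ratio spread grows monotonically with CPMG noise", {
  sd_of_recovered <- function(noise_sd) {
    ratios <- vapply(1:10, function(i) {
      sp <- simulate_cpmg_spectrum(1.5, noise_sd = noise_sd, seed = 1000 + i)
      fit <- fit_region(sp, quant_regions()$human, metabolite_shifts())
      unname(fit$areas[["gpc"]] / fit$areas[["pcho"]])
    }, numeric(1))
    stats::sd(ratios)
  }
  sds <- vapply(c(0.5, 4, 16), sd_of_recovered, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("expression generator plants effects, flags and duplicates as specified", {
  # null model, zero noise: every probe constant across samples
  s0 <- expression_sim_spec(n_genes = 20, true_log2fc = numeric(),
                            within_group_sd = 0, seed = 5)
  sim0 <- simulate_expression(s0)
  expect_true(all(apply(sim0$intensities, 1, function(r) diff(range(r)) == 0)))

  # one gene at log2fc 6.4, zero noise: group log2-mean difference exact
  s1 <- expression_sim_spec(n_genes = 20, true_log2fc = c(PLA2G4A = 6.4),
                            within_group_sd = 0, seed = 5)
  sim1 <- simulate_expression(s1)
  lm1 <- log2(sim1$intensities["P_0001", ])
  expect_equal(mean(lm1[sim1$groups == "basal-like"]) -
                 mean(lm1[sim1$groups == "luminal-like"]), 6.4)

  # duplicate probes share the gene's expected value
  s2 <- expression_sim_spec(n_genes = 20, true_log2fc = c(PLA2G4A = 2),
                            within_group_sd = 0,
                            duplicate_probe_genes = "PLA2G4A", seed = 5)
  sim2 <- simulate_expression(s2)
  probes <- sim2$annotation$probe_id[sim2$annotation$gene == "PLA2G4A"]
  expect_length(probes, 2L)
  expect_equal(sim2$intensities[probes[1], ], sim2$intensities[probes[2], ])

  # planted flag rate within a binomial 4-sigma band
  s3 <- expression_sim_spec(n_genes = 500, flagged_fraction = 0.5, seed = 5)
  sim3 <- simulate_expression(s3)
  n_cells <- length(sim3$flags)
  rate <- mean(sim3$flags)
  expect_lt(abs(rate - 0.5), 4 * sqrt(0.25 / n_cells))

  # determinism
  expect_identical(simulate_expression(s1)$intensities, sim1$intensities)
  expect_error(expression_sim_spec(flagged_fraction = 1), "flagged_fraction")
})
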