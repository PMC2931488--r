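test_that("apodization multiplies by the exponential envelope", {
  acq <- quick_acq()
  n <- acq$n_points
  flat <- nmr_fid(complex(real = rep(1, n)), acq$dwell_time,
                  acq$spectrometer_frequency)
  expect_identical(apodize(flat, 0), flat)
  ap <- apodize(flat, 0.3)
  t <- (seq_len(n) - 1) * acq$dwell_time
  expect_equal(Re(ap$signal), exp(-pi * 0.3 * t), tolerance = 1e-12)
  expect_error(apodize(flat, -0.1), "line_broadening")
})

test_that("line broadening adds lb/2 to the fitted Lorentzian half width", {
  acq <- acquisition_params()
  fid <- simulate_fid(c(pcho = 5), mass = 0.015, eretic_moles = 0,
                      tsp_moles = 0, noise_sd = 0)
  lb <- 1.0
  sp <- to_spectrum(apodize(fid, lb))
  fit <- fit_region(sp, c(3.43, 3.03), c(pcho = 3.23))
  hwhm_hz <- fit$peaks$lorentzian_hwhm * acq$spectrometer_frequency
  natural <- default_metabolites()$pcho$lorentzian_hwhm
  expect_equal(hwhm_hz, natural + lb / 2, tolerance = 1e-3)
})

test_that("Fourier transformation maps resonances to their chemical shifts", {
  acq <- quick_acq()
  zero <- nmr_fid(complex(real = rep(0, acq$n_points)), acq$dwell_time,
                  acq$spectrometer_frequency)
  sp0 <- to_spectrum(zero, 16384L)
  expect_true(all(sp0$intensity == 0))
  expect_error(to_spectrum(zero, 100L), "zero_fill_to")

  fid <- simulate_fid(c(pcho = 5), mass = 0.015, eretic_moles = 0,
                      tsp_moles = 2.964e-7, noise_sd = 0,
                      acquisition = acq)
  sp <- reference_to_tsp(to_spectrum(fid, 65536L))
  idx <- which(sp$ppm < 4 & sp$ppm > 2.5)
  peak_ppm <- sp$ppm[idx[which.max(sp$intensity[idx])]]
  expect_lt(abs(peak_ppm - 3.23), 5e-4)
})

test_that("processing is deterministic", {
  fid <- simulate_fid(c(gpc = 3), mass = 0.015, seed = 8,
                      acquisition = quick_acq())
  expect_identical(process_fid(fid, zero_fill_to = 65536L),
                   process_fid(fid, zero_fill_to = 65536L))
})

test_that("TSP referencing shifts the axis onto 0 ppm and is idempotent", {
  fid <- simulate_fid(c(gpc = 3), mass = 0.015, noise_sd = 30,
                      seed = 21, acquisition = quick_acq())
  sp <- to_spectrum(fid, 65536L)
  ref <- reference_to_tsp(sp)
  tsp_peak <- function(s) {
    idx <- which(s$ppm <= 0.2 & s$ppm >= -0.2)
    s$ppm[idx[which.max(s$intensity[idx])]]
  }
  expect_lt(abs(tsp_peak(ref)), 5e-4)
  ref2 <- reference_to_tsp(ref)
  expect_lt(max(abs(ref2$ppm - ref$ppm)), 5e-4)

  # constructed offset: shifting the axis by +0.03 is undone exactly
  off <- ref
  off$ppm <- off$ppm + 0.03
  back <- reference_to_tsp(off)
  expect_equal(back$ppm, ref$ppm, tolerance = 1e-9)

  # offset beyond the search window leaves no detectable peak
  far <- ref
  far$ppm <- far$ppm + 0.5
  expect_error(reference_to_tsp(far), "referencing failed")
})

test_that("total-area normalization gives unit integrals, scale invariance and idempotence", {
  region <- quant_regions()$human
  sp1 <- simulate_cpmg_spectrum(1.5, noise_sd = 0)
  sp2 <- simulate_cpmg_spectrum(0.8, noise_sd = 0)
  n1 <- normalize_total_area(sp1, region)
  n2 <- normalize_total_area(sp2, region)
  integral <- function(s) {
    idx <- which(s$ppm <= max(region) & s$ppm >= min(region))
    pp <- rev(s$ppm[idx]); y <- rev(s$intensity[idx])
    sum(diff(pp) * (y[-1] + y[-length(y)]) / 2)
  }
  expect_equal(integral(n1), 1, tolerance = 1e-10)
  expect_equal(integral(n1), integral(n2), tolerance = 1e-10)
  expect_equal(n1$normalization_state, "total-area")

  # scaling the input by any c > 0 changes nothing
  scaled <- sp1
  scaled$intensity <- scaled$intensity * 7.3
  expect_equal(normalize_total_area(scaled, region)$intensity,
               n1$intensity, tolerance = 1e-12)
  # idempotence
  expect_equal(normalize_total_area(n1, region)$intensity, n1$intensity,
               tolerance = 1e-12)

  flat <- nmr_spectrum(seq(4, 2, length.out = 100), rep(0, 100))
  expect_error(normalize_total_area(flat, region), "normalization failed")
})

test_that("spectrum and FID round-trip through their CSV formats", {
  fid <- simulate_fid(c(gpc = 3), mass = 0.015, seed = 3,
                      acquisition = quick_acq())
  fp <- tempfile(fileext = ".csv")
  write_fid_csv(fid, fp)
  fid2 <- read_fid_csv(fp)
  expect_equal(fid2$signal, fid$signal, tolerance = 1e-12)
  expect_equal(fid2$dwell_time, fid$dwell_time)
  expect_equal(fid2$sample_mass, fid$sample_mass)

  sp <- to_spectrum(fid, 16384L)
  spf <- tempfile(fileext = ".csv")
  write_spectrum_csv(sp, spf)
  sp2 <- read_spectrum_csv(spf)
  expect_equal(sp2$ppm, sp$ppm, tolerance = 1e-12)
  expect_equal(sp2$intensity, sp$intensity, tolerance = 1e-12)
  expect_equal(sp2$acquisition_type, sp$acquisition_type)
  unlink(c(fp, spf))
})
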