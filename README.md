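# cholinemrs

Absolute quantification of choline-pathway metabolites in intact-tissue
HR MAS ¹H NMR spectra, with a companion differential-expression arm for the
genes of choline phospholipid metabolism.

## The problem

Breast cancer subtypes differ in their choline metabolite profiles:
basal-like tumours accumulate glycerophosphocholine (GPC) and glycine,
luminal-like tumours phosphocholine (PCho). Measuring these differences in
intact tissue requires (i) converting high-resolution magic angle spinning
(HR MAS) free induction decays into calibrated spectra, (ii) deconvolving
crowded spectral regions into individual resonances, (iii) converting peak
areas into absolute tissue concentrations against an electronic reference
signal (ERETIC), and (iv) comparing groups statistically. A parallel
microarray arm asks whether the enzymes and transporters of the
choline/glycine pathways are differentially expressed between the same
tumour groups.

`cholinemrs` implements this full chain, plus synthetic generators for
FIDs, CPMG spectra, cohorts and expression matrices, so that every stage is
testable by parameter recovery against known ground truth.

## Core model

Each quantified resonance is modelled as a pseudo-Voigt line, a linear
mixture of a Lorentzian and a Gaussian with common centre and height:

    f(x) = h [ η γ² / ((x−c)² + γ²) + (1−η) exp(−ln2 (x−c)²/g²) ]

with closed-form area `η π h γ + (1−η) h g √(π/ln 2)`. Defined spectral
regions (TSP 0.20 to −0.20 ppm, ERETIC −0.85 to −1.15 ppm, metabolites
3.60 to 2.90 ppm) are fitted jointly by nonlinear least squares. Tissue
concentrations follow the ERETIC ratio equation

    [MET] = (A_MET / A_ERETIC) · (1 / k_MET) · (n_ERETIC / m_sample)

in µmol/g, where `k_MET` is the number of protons producing the resonance
(9 for the N-trimethyl singlets of choline, PCho and GPC), `n_ERETIC` the
equivalent molar amount of the electronic reference (calibrated from
creatine standards by through-origin regression), and `m_sample` the wet
tissue mass. Group comparisons use the pooled two-sample Student t.

The expression arm quantile-normalizes and log2-transforms raw
intensities, removes flagged-outlier and low-presence probes, collapses
probes to transcripts (duplicates averaged, highest-IQR probe retained),
fits empirical-Bayes moderated t statistics (hyperparameters by moment
matching of the log residual variances), controls the FDR by
Benjamini–Hochberg, and clusters significant genes with Euclidean
distance and complete linkage.

## Worked example

Simulate one basal-like tissue sample, process it, deconvolve the
metabolite region and quantify:

```r
library(cholinemrs)

fid <- simulate_fid(c(creatine = 4.1, choline = 1.2, pcho = 4.5, gpc = 9.8,
                      taurine = 14.7, glycine = 8.2),
                    mass = 0.015, seed = 42)
spectrum <- process_fid(fid)           # 0.3 Hz apodization, FT, TSP reference
fits <- fit_quant_regions(spectrum)
fits$metabolite
#> Pseudo-Voigt deconvolution, region 3.60 to 2.90 ppm
#>   6 peaks, r^2 = 0.99854
#>     label center  height  area
#>  creatine   3.03  376247  1562
#>   choline   3.21  313644  1371
#>      pcho   3.23 1222230  5091
#>       gpc   3.24 2631498 11085
#>   taurine   3.43  878657  3742
#>   glycine   3.56  492336  2068

quantify_sample(spectrum, fits, reference = 3.17e-7)
#> creatine  choline     pcho      gpc  taurine  glycine
#>     4.18     1.22     4.54     9.89    15.03     8.31
```

The recovered concentrations (µmol/g) match the simulated ground truth to
a few percent at the default noise level; noiselessly they agree to better
than 0.1%. Group summaries can be compared directly from published
statistics:

```r
pooled_t_summary(10, 9.8, 2.5, 9, 2.7, 1.7, metric = "GPC")
#> GPC: 9.8 +/- 2.5 (n=10) vs 2.7 +/- 1.7 (n=9)
#>   t = 7.152, df = 17, p = 1.622e-06 *
```

i.e. the GPC difference between the groups is significant far below the
0.001 level, while the same comparison for choline (1.2 ± 0.7 vs
0.9 ± 0.6) is not significant.

End-to-end runs are one call each:

```r
met <- run_metabolite_pipeline(list(seed = 1))   # cohorts -> Table-style summary
expr <- run_expression_pipeline(list(seed = 1))  # arrays -> DE table + clustering
```

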