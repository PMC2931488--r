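---
title: "Methods: absolute metabolite quantification and the expression arm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: absolute metabolite quantification and the expression arm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cholinemrs)
```

This vignette documents the models, parameter choices and numerical
decisions behind `cholinemrs`, in the spirit of a methods section: what is
computed, under which assumptions, and what the synthetic validation does
and does not demonstrate.

## The signal model

The synthetic generator produces the time-domain signal of a tissue sample
as a sum of damped complex sinusoids — one resonance per metabolite, the
TSP chemical-shift reference at 0 ppm, and the ERETIC electronic reference
at −1.0 ppm:

$$ s(t) \;=\; \sum_r A_r \, e^{2\pi i \nu_r t} \, e^{-R_{2,r} t}
   \, e^{-(\pi g_r t)^2/\ln 2} \;+\; \varepsilon(t), $$

where $\nu_r$ is the resonance offset from the carrier (4.7 ppm, on
water), $R_{2,r} = 2\pi\,\gamma_r$ sets the Lorentzian half width
$\gamma_r$ in Hz, $g_r$ an optional Gaussian half width (0 by default, so
default lines are purely Lorentzian), and $\varepsilon$ i.i.d. complex
Gaussian noise. The initial amplitude is

$$ A_r \;=\; C \cdot n_r \cdot k_r, $$

moles times protons times one shared calibration constant — identical for
metabolites and TSP, and for ERETIC with $k = 1$ and $n$ equal to the
nominal reference amount. This single-constant assumption is what makes
ratio-based quantification exact by construction, so downstream recovery
tests probe the analysis, not the generator.

Acquisition emulates a 600.13 MHz instrument: sweep width 16.7 ppm, 32768
complex points (64K sequentially sampled real points, acquisition time
$\approx 3.27$ s), zero-filled to 128K before transformation. The real
part of the FFT is returned directly: synthetic signals are generated
phase-coherent, so no phase correction is implemented and real-data
phasing is out of scope. The first time-domain point is halved before the
transform — the standard correction that removes the constant baseline
offset a one-sided FID otherwise produces, leaving the synthetic spectra
baseline-free.

**Chemical shifts and proton counts.** Creatine 3.03, choline 3.21, PCho
3.23, GPC 3.24, taurine 3.43, glycine 3.56, TSP 0.00, ERETIC −1.00 ppm;
$k$ = 9 for the three N-trimethyl singlets and TSP, 3 for creatine
N-CH₃, 2 for the quantified glycine and taurine CH₂ resonances. Shifts
are standard ¹H assignments; proton counts follow from molecular
structure. Multiplet structure and J-coupling are not modelled — every
quantified resonance is treated as a singlet.

**Noise level.** The default time-domain noise SD (92 intensity units) is
set so that a 5 µmol/g N-trimethyl singlet in a 15 mg sample has a peak
signal-to-noise ratio near 200 after 0.3 Hz apodization — typical of
well-averaged intact-tissue spectra. The level was chosen so that the
deconvolution's coefficient of determination exceeds 0.95 in *all three*
fitted regions, the acceptance threshold used for real tissue spectra:
the ERETIC window contains a single narrow peak in a 0.30 ppm span, so
its regional r² is bounded by the peak's share of the regional variance
and is the binding constraint (r² ≈ 0.98 at the default noise).

**Concentration sampling.** Cohorts draw per-sample concentrations from
normal distributions truncated at zero (group SDs would otherwise permit
negative draws) and masses from a truncated normal around 15 ± 3 mg.
Truncation bias is negligible for every metabolite (the closest mean sits
2.1 SDs above zero).

## Processing

Processing is deliberately minimal and deterministic: exponential
apodization ($e^{-\pi \cdot lb \cdot t}$, default $lb = 0.3$ Hz, which
adds $lb/2$ to every Lorentzian half width), zero-fill, FFT,
chemical-shift calibration to the TSP maximum (parabolic sub-grid
refinement; failure if no peak exceeds 5× the median absolute intensity
in the ±0.20 ppm search window), and — for CPMG spectra — scaling to unit
total area over 3.60–3.00 ppm. All integrals use the trapezoid rule on
the ppm axis, which is stored high→low following display convention.
Baseline correction and solvent artifacts are out of scope; CPMG
echo-train physics is not simulated (the CPMG generator draws already-flat
spectra directly in the frequency domain).

## Peak deconvolution

Each quantification region is fitted as a sum of pseudo-Voigt lines
$\eta L + (1-\eta) G$ — the linear mixture rather than the true Voigt
convolution, so areas have the closed form
$\eta \pi h \gamma + (1-\eta) h g \sqrt{\pi/\ln 2}$ and the reported area
is exact in the fitted parameters rather than a numerically truncated
integral.

The optimization is nonlinear least squares over all peaks of a region
jointly, with three robustness measures that experience with overlapping
resonances made necessary:

* **Variable projection.** Peak heights enter the model linearly and are
  solved by linear least squares at every optimizer step; the
  Levenberg–Marquardt iteration sees only the shape parameters (centre,
  two half widths, mixing fraction). This removes the 10⁶-fold scale
  disparity between heights and widths from the trust region and
  eliminates the height-collapse local minima a cold-started joint fit
  falls into on noisy spectra.
* **Two-stage centres.** Shapes are first fitted with centres pinned at
  their priors, then everything is released within the centre window.
  This keeps overlapping neighbours (PCho/GPC are 0.01 ppm apart) from
  exchanging identities while heights and widths are still far from
  optimal.
* **Restart polishing.** Each stage restarts the optimizer from its own
  solution until the residual sum of squares stops improving; a collapsed
  trust region from a cold start is reset by the restart.

Initialization follows the region contract: centres at the prior
assignments, half widths 0.005 ppm, mixing fraction 0.5. Centres are
bounded to prior ± 0.01 ppm, further capped at 40% of the distance to the
nearest neighbouring prior — without the cap, the two components of a
blend with one nearly absent peak can coalesce, making the split of the
blended intensity arbitrary. Labels are assigned to fitted peaks by
nearest prior centre; two labels claiming the same fitted peak is a
genuine ambiguity and fails the fit. An r² at or below 0.95 over the
region flags the result (quality warning) without failing it, mirroring
the acceptance rule applied to tissue spectra.

On noiseless model-generated input the fit recovers parameters to better
than 10⁻⁶ relative; at the default noise, per-sample concentration errors
are a few percent on the weakest peak (choline) and well under 1% on
average, with no detectable bias (< 0.5% per metabolite).

## Absolute quantification

The ERETIC reference amount is calibrated from creatine standards. By the
concentration equation, $k_{cr}\cdot n_{cr} = (A_{cr}/A_{ER}) \cdot
n_{ER}$ for each standard, so the slope of a least-squares line through
the origin of $k \cdot$ amount against area ratio *is* $n_{ER}$; the
origin constraint encodes that a blank sample has zero creatine area.
Defaults use six standards spanning 5–50 nmol equivalents. Concentrations
are then

$$ [\mathrm{MET}] = \frac{A_{\mathrm{MET}}}{A_{\mathrm{ERETIC}}}
   \cdot \frac{1}{k_{\mathrm{MET}}}
   \cdot \frac{n_{\mathrm{ERETIC}}}{m_{\mathrm{sample}}} $$

reported in µmol/g wet tissue ($\times 10^6$ from mol/g). For CPMG
spectra no reference exists: the package reports the GPC/PCho area ratio
and per-metabolite fractions of the normalized total area instead. No
relaxation ($T_1$/$T_2$) or tissue-composition corrections are applied.

## Group statistics

Metabolite comparisons use the equal-variance (pooled) two-sample
Student t, two-sided, at α = 0.05, available both on raw values and
directly on published summary statistics (n, mean, SD per group). Pooled
rather than Welch was chosen because the procedure being reproduced names
Student's t; no multiple-testing correction is applied across the six
metabolites, again matching the reproduced procedure. Degenerate inputs
are defined explicitly: zero pooled variance with equal means gives
$t = 0, p = 1$.

## The expression arm

The microarray chain is: quantile normalization of raw intensities
(columns mapped onto the mean quantile distribution) and log2 transform;
probe filtering; probe collapsing; moderated t; BH FDR; hierarchical
clustering of significant genes.

**Flag handling.** The filtering rule distinguishes cell- and probe-level
flags: a flagged cell is set missing (feeding the presence rule), and a
probe flagged in more than half the samples is removed outright. A probe
present in strictly less than 30% of samples is removed. This makes the
"flagged outliers or present in less than 30%" rule operable at both
levels.

**Collapsing.** Rows with identical probe ids are averaged; among
distinct probes for one transcript the probe with the largest
interquartile range across samples is retained (ties broken toward the
lexicographically first probe id, for determinism).

**Moderated t.** Per gene, the log2-fold difference is the difference of
group means and the residual variance the pooled within-group variance
with $d$ degrees of freedom. Gene variances are modelled as
$s^2 \sim s_0^2 F(d, d_0)$; the hyperparameters are estimated by
closed-form moment matching of $z = \log s^2$, using the digamma/trigamma
moments of log-chi-square and inverting the trigamma equation by Newton
iteration. Posterior variances $(d_0 s_0^2 + d s^2)/(d_0 + d)$ give
moderated t statistics on $d + d_0$ degrees of freedom. Moment matching
was chosen over iterative likelihood maximization because it is
deterministic, closed-form, and testable; on well-behaved data it agrees
with the established empirical-Bayes reference implementation to within
rounding of the hyperparameters (the test suite checks this
independently). The estimator refuses to run on fewer than 10 genes,
where matching log-variance moments is unstable. `prior_df = 0` and
`prior_df = Inf` expose the no-shrinkage and full-shrinkage limits.

**Normalization scope.** Quantile normalization is rank-based, so its
fidelity depends on the number of probes being normalized: over only a
117-gene panel the most extreme planted fold difference (6.4 log2 units)
is visibly compressed. The default simulation therefore generates the
panel embedded in a ~2000-gene array-like background with a wide baseline
spread (log2 intensities ≈ N(9, 2)), normalizes array-wide, and restricts
testing to the panel afterwards — the order the emulated procedure used.

**Clustering.** Significant genes are row-centered and clustered on both
axes with Euclidean distance and complete linkage. Rows and columns are
sorted by label before clustering, which makes the output deterministic
and invariant to input permutation for continuous data; missing cells sit
at the row mean after centering. Dendrograms are exported as Newick text.

## What the synthetic validation shows — and what it does not

The generators reproduce the statistical structure the analysis assumes:
known per-sample concentrations with group-level spread, a shared
amplitude calibration, flat baselines, singlet lineshapes, planted
log2-fold differences with homogeneous within-group noise. Passing
recovery tests therefore demonstrates that the estimation chain is
correct and essentially unbiased *under its own assumptions*. It does not
demonstrate robustness to what real tissue spectra add: baseline roll,
phase errors, multiplets and J-coupling, frequency drift, relaxation
differences between metabolites and reference, or array artifacts such as
spatial detrending. Those belong to the instrument-specific preprocessing
this package declares out of scope.

## Problem sizes and reproducibility

Everything is deterministic given a seed: cohort draws seed the RNG once
and all downstream noise derives from the same stream, so identical
configurations give byte-identical outputs. The validation suite uses the
production acquisition size (32768 complex points, 128K transform) for
end-to-end recovery and the acceptance script, and reduced sizes
(n = 8192) for property tests where sub-0.1% area accuracy is not the
point. Monte-Carlo checks are sized to their purpose: 10⁴ replicates for
the t-test's type-I error, 200 simulations for the null
false-discovery-rate property, 100 seeds for calibration noise.

## Known limitations

* Pseudo-Voigt, not true Voigt: for strongly mixed lines the two differ
  at the percent level in shape; areas remain exact in the fitted
  parameters, and the synthetic truth uses the same family.
* Relative CPMG metrics are uncorrected for $T_2$; comparisons are valid
  across samples acquired identically, not as absolute amounts.
* The moderated-t moment estimator assumes a common variance model
  across genes; strong variance heterogeneity in small panels widens the
  estimated prior df spread (harmlessly, since the posterior then shrinks
  little).
* The identity-assignment rule presumes referencing good to a fraction
  of the inter-peak spacing; grossly mis-referenced spectra fail fast in
  the TSP step rather than silently mislabeling peaks.
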