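---
title: "Quantifying brain ethanol from single-voxel 1H-MRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying brain ethanol from single-voxel 1H-MRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethanolMRS)
```

## The measurement problem

After oral ethanol intake, the concentration of ethanol dissolved in brain
tissue water can be observed in vivo with single-voxel proton MRS: the
ethanol CH3 protons resonate as a triplet near 1.18 ppm, well separated from
the dominant brain metabolites. The quantification chain this package
implements has three statistical/physical stages, each with its own
assumptions.

### 1. Spectral model and linear-combination fit

An absorption-mode spectrum on a ppm grid is modelled as a nonnegative
linear combination of metabolite model spectra plus white Gaussian noise,

$$ y = B\,a + \varepsilon, \qquad a \ge 0,\quad
   \varepsilon \sim \mathcal{N}(0, \sigma^2 I). $$

Each column of $B$ is the unit-amplitude render of one metabolite's
resonances: Lorentzian lines of common full width at half maximum (default
4 Hz, typical at 3 T), placed at `center_ppm + offset_hz / field_mhz`, and
weighted by the multiplet pattern. Amplitudes are estimated by nonnegative
least squares (Lawson–Hanson active set, via `pracma::lsqnonneg`); a
metabolite tied at the boundary is excluded (amplitude exactly 0).

The default resonance library uses standard in vivo shifts — ethanol CH3
triplet 1.18 ppm ($J$ = 7.1 Hz, 1:2:1, 3 protons), NAA 2.01 ppm (3), total
creatine 3.03 ppm (3), choline compounds 3.20 ppm (9), water 4.70 ppm (2).
The ethanol CH2 quartet (3.65 ppm, 2 protons) is available in the library
but excluded from the default basis: at the long echo times used for
ethanol detection the quartet is strongly J-modulated and overlaps the
Glx/myo-inositol region, while the CH3 triplet carries the quantifiable
signal. Users fitting short-TE data can add it via
`default_basis(include = c(..., "EthCH2"))`.

Precision is reported as Cramér–Rao lower bounds. For the linear-Gaussian
model the Fisher information of the active amplitudes is $B^\top B /
\sigma^2$, so

$$ \mathrm{CRLB}_i(\%) = \frac{\sqrt{[(B^\top B)^{-1}]_{ii}}\;\sigma}{a_i}
   \times 100 . $$

In this model the bound is attained by the estimator whenever the solution
is interior, which is why a Monte-Carlo coefficient of variation over
replicates should match the reported CRLB — a property the test suite
checks with 500 replicates. CRLBs are lower bounds on random error only;
they say nothing about systematic error from a mis-specified lineshape or
basis, which is why the generator lets you simulate with one linewidth and
fit with a basis rendered at another.

The noise level $\sigma$ is estimated as the standard deviation of the
intensities in a signal-free window (default 4.2–5.0 ppm, signal-free for
water-suppressed spectra under the default basis) after removing a linear
trend, making the estimate insensitive to DC offsets and shallow baseline
slopes.

### 2. Internal water reference and tissue water content

The unsuppressed water scan provides the absolute scale. With
proton-weighted signal areas $S$ (physical signal is proportional to
concentration × proton count), the metabolite concentration per litre of
voxel is

$$ c_\mathrm{met} = \frac{S_\mathrm{met}}{S_w}\cdot
   \frac{n_w}{n_\mathrm{met}}\cdot C_w \cdot 1000 \;\; \mathrm{mmol/L}, $$

where $C_w = f_{gm}\,42.9 + f_{wm}\,35.8 + f_{csf}\,53.4$ mol/L is the
fraction-weighted voxel water concentration. No relaxation correction is
applied (reliable ethanol T1/T2 values at 3 T are lacking); a
`relaxation_factor` hook exists and defaults to the identity.

Two water-content variants are kept deliberately explicit, because they
answer different questions: the molar variant above scales the water
reference, while the percent variant $wc = f_{gm}\,78 + f_{wm}\,65 +
f_{csf}\,97$ (%) is the normalization denominator. Assuming ethanol
dissolves only in the aqueous compartment, per-voxel concentrations are
divided by $wc/100$ to give grams per litre of voxel water
(`normalize_to_water()`); `denormalize_from_water()` inverts this exactly.

One data-driven subtlety: published segmentation tables print each tissue
percentage rounded independently, so a printed row can sum to 99–101 (one
packaged voxel sums to 101). The published water contents are weighted sums
of the *printed* values; `water_content_from_pct()` therefore operates on
printed percentages without renormalizing and reproduces every packaged
value at one decimal, while `voxel_composition()` (used for simulation)
enforces the exact sum-to-one invariant and `composition_from_row()`
renormalizes. Table-mirroring output rounds half away from zero — the
convention the packaged water contents themselves require (one voxel's
exact value is 76.05, printed 76.1) — to 1 decimal for water contents and 2
for concentrations.

### 3. Serum kinetics and comparison

The drinking-study design calculations use Widmark's relation $A = c\,m\,r$
between ethanol mass and target blood concentration, corrected for a
resorption deficit: `grams = c·m·r/(1−deficit)` with defaults $r = 0.7$
(adult men) and deficit 0.2 (mid forensic range); beverage volume follows
from strength and ethanol density (0.789 g/mL). Serum (g/L) and whole blood
(g/kg) interconvert through the factor 1.2375 = 0.99/0.8, the value implied
by the study's own stated correspondence (the conventional factor is 1.236;
it is a `pk_params` field).

Serum curves are modelled piecewise linearly: a ramp from zero to the peak
over the absorption window (default 60 min), then zero-order elimination at
$\beta$ (default 0.15 g/L/h, classical range), clamped at zero. The sparse
five-point sampling of such studies cannot identify a richer absorption
model; the absorption duration is exposed as a parameter rather than
fitted.

`compare_matrices()` summarizes each matrix per subject (max, min, range,
coefficient of variation), pairs each serum draw with the temporally
nearest brain measurement within ±20 min (MRS and blood sampling
interleave; the tolerance is configurable), and compares curve flatness via
the CV ratio. With n = 3 subjects no significance testing is attempted. On
the packaged data the brain curve is flatter than serum for V1 and V3 but
*not* for V2 by CV — V2's serum was already at its peak at the end of
drinking, so its serum curve is itself flat over the sampled window. The
package reports the per-subject CVs rather than asserting a blanket
ordering.

Brain measurement times are not printed in study tables; the packaged times
(15/25/45/55 min in cycle 1, 105/115/140/150 in cycle 2) are reconstructed
from the protocol order and the ~7-min scan length, and only matter for
nearest-time pairing.

## What the synthetic generator does and does not emulate

`simulate_spectrum()` draws `B a + N(0, σ²)` on the acquisition grid;
`simulate_water_reference()` renders a water line whose integrated area is
the configured reference scale; `simulate_voxel_case()` links the two
channels through a common scanner gain so that the full chain
(fit → water scaling → normalization) inverts exactly in the noiseless
limit — the package's strongest self-test, verified to 0.1 % relative and
in practice exact to numerical precision. `sample_voxel_composition()`
draws GM/CSF fractions from ranges calibrated to the packaged segmentation
(e.g. cerebellar CSF ≤ 4 %, frontal CSF 8–23 %).

The emulation is deliberately minimal. It does **not** model: time-domain
acquisition (phase/frequency drift, eddy currents), TE-dependent
J-modulation of the ethanol multiplets (the basis is treated as TE-matched;
the default TE of 74 ms is carried as metadata), macromolecule baselines,
residual water after suppression, lineshape deviations from Lorentzian, or
correlated noise. Passing tests therefore demonstrate the correctness of
the estimator and quantification arithmetic under the stated model, not
robustness to every in vivo artefact. The optional polynomial baseline
(degree ≤ 2, off by default, alternating NNLS/least-squares minimization)
is the only nuisance component retained, because smooth baseline offsets
are the dominant practical deviation.

The iid Gaussian noise model is the simplest one consistent with CRLB
theory; real spectra have approximately Gaussian noise in the frequency
domain after Fourier transform, so this is the standard assumption.

## Numerical choices

* **Grid**: 0–5 ppm, 2048 points (default); field 123.25 MHz (3 T).
* **Truncation-corrected rendering.** Each Lorentzian line is normalized to
  unit area *over the grid* (analytic arctan correction), so a
  unit-amplitude render integrates to exactly `n_protons`. Plain Lorentzian
  tails lose 0.3–0.6 % of their mass outside a 0–5 ppm window, which would
  otherwise break area calibration and its linewidth invariance.
* **Water area by fitting, not integration.** The reference area is
  estimated by fitting a single water basis column (`water_area()`), which
  is exact for noiseless input and unbiased under noise, whereas a
  trapezoidal integral is biased by whatever tail mass and noise the window
  includes.
* **Grid mismatch**: spectra are linearly resampled onto the basis grid;
  extrapolation is refused. Resampling a 2× finer grid costs ~0.2 % in
  amplitude accuracy.
* **Degenerate inputs**: rank-deficient bases are refused with the
  collinear columns named; a singular active-set information matrix is an
  error; zero-amplitude metabolites get flagged (`NA`) CRLBs; degenerate
  constant series in the comparison get CV 0 and flatness ratio 1 by
  convention.
* **Default noise level** (`default_noise_sd()`, 55 intensity units): set
  from the CRLB formula so the default synthetic voxel (ethanol 10 mmol/L
  raw) is fitted at ~4 % ethanol CRLB — inside the 3–12 % range such
  studies report, i.e. a realistic in vivo signal-to-noise ratio.
* **Seeds** are explicit everywhere and the global RNG state is restored
  after each call; per-voxel seeds are derived from the pipeline seed, so
  equal seeds give byte-identical output files.
* **Problem sizes.** The validation suite uses 2048-point spectra, 500
  Monte-Carlo replicates for the CRLB-consistency and bias checks, and
  brute-force active-set enumeration on 120-point, 3-column designs as the
  independent solver oracle; these sizes give Monte-Carlo standard errors
  well below the tested tolerances while keeping the full suite in seconds.

## Known limitations

* LCModel-style nuisance machinery (spline baseline, lineshape
  regularization, soft concentration priors, frequency/phase search) is out
  of scope; the estimator is the linear-Gaussian core those programs share.
* No relaxation correction: reported concentrations inherit whatever
  T1/T2 weighting the acquisition had. CSF-dissolved ethanol has a longer
  T2 than tissue ethanol, so voxels with high CSF fraction (frontal cortex
  here) may be biased high relative to others — visible in the study data
  and discussed there; this package treats all compartments identically,
  consistent with the uncorrected analysis.
* The Widmark dose arithmetic cannot reproduce the study's actual beverage
  volumes because the study's exact `r` and deficit choices are unstated;
  the volumes are carried as observational data (`study_subjects()`).
* Brain measurement times are reconstructed, not measured; conclusions that
  depend on pairing tighter than ~10 min should not be drawn from them.
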