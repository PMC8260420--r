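# ethanolMRS

Determination of brain ethanol concentrations from single-voxel proton
magnetic resonance spectroscopy (1H-MRS), and their comparison with serum
ethanol kinetics.

Ethanol acts in the brain, but clinical and forensic practice measures it in
peripheral blood. In vivo 1H-MRS can observe the ethanol CH3 resonance
directly in a localized brain volume. This package implements the full
quantification chain for such measurements, for forensic and MR-physics
researchers who want to analyse (or simulate) single-voxel ethanol spectra:

1. **Linear-combination fitting.** A measured spectrum `y` on a ppm grid is
   modelled as `y = B a + ε`, where the columns of `B` are unit-amplitude
   metabolite model spectra (ethanol CH3 triplet at 1.18 ppm, NAA 2.01 ppm,
   Cr 3.03 ppm, Cho 3.20 ppm; Lorentzian lines) and `ε` is white Gaussian
   noise. Amplitudes are estimated by nonnegative least squares
   (`min ||y − B a||²` s.t. `a ≥ 0`, Lawson–Hanson active set). Precision is
   reported as Cramér–Rao lower bounds on the active set,
   `CRLB_i(%) = sqrt([(BᵀB)⁻¹]_ii) · σ / a_i · 100`.
2. **Absolute quantification** against the unsuppressed internal water
   reference: `c_met = (S_met / S_w) · (n_w / n_met) · C_w · 1000` mmol per
   litre of voxel, where `S` are proton-weighted signal areas, `n` proton
   counts, and `C_w` the voxel water concentration computed from segmented
   tissue fractions with 42.9 mol/L (78 %) for gray matter, 35.8 mol/L
   (65 %) for white matter and 53.4 mol/L (97 %) for CSF. No relaxation
   correction is applied.
3. **Water-content normalization.** Since ethanol distributes in the aqueous
   compartment, concentrations are divided by the voxel water volume
   fraction `wc/100`, with `wc = f_gm·78 + f_wm·65 + f_csf·97` (%), giving
   grams of ethanol per litre of voxel water.
4. **Serum pharmacokinetics.** Widmark dose calculation
   (`A = c·m·r/(1−deficit)`), serum↔blood conversion (0.99 g/L serum ↔
   0.8 g/kg blood, factor 1.2375), piecewise-linear absorption/elimination
   serum curves, and a brain-versus-serum comparison report (extrema,
   nearest-time pairing, curve flatness by coefficient of variation).

A synthetic-data generator stands in for scanner and serum assay: it renders
noisy 3 T spectra (TE 74 ms) with known ground truth plus matched water
references, samples region-typical voxel compositions, and simulates serum
curves. The tables of the underlying three-volunteer drinking study (serum at
five timepoints; water-normalized brain ethanol in occipital cortex,
cerebellum, frontal cortex and putamen over two cycles; voxel tissue
fractions) ship with the package as plain CSV.

## Worked example

Simulate one occipital voxel at a known truth of 0.62 g/L (per litre voxel
water), fit it, and quantify against the water reference:

```r
library(ethanolMRS)
basis <- default_basis()
comp  <- voxel_composition(0.46, 0.50, 0.04, voxel_ml = 15.6,
                           region = "occipital_cortex")
sim <- simulate_voxel_case(0.62, comp, basis,
                           noise_sd = default_noise_sd(), seed = 7)
fit <- lcfit(sim$spectrum, basis)
summary(fit)
#> Linear-combination spectral fit [occipital_cortex]
#>  metabolite amplitude crlb_percent active
#>         Eth    9.6997         4.11   TRUE
#>         NAA   11.9860         2.36   TRUE
#>          Cr    7.8053         3.63   TRUE
#>         Cho    2.0245         4.67   TRUE
#> residual RMS: 54.91   estimated noise SD: 54.1

quantify_voxel(fit, water_area(sim$water_ref), comp)
#> Eth in occipital_cortex: 0.618 g/L (normalized to 72.3% voxel water;
#>   raw 0.447 g/L = 9.70 mmol/L); CRLB 4.1%
```

The fitted ethanol amplitude (9.70 mmol/L raw, CRLB 4.1 %) converts through
the water reference and the 72.3 % voxel water content back to 0.618 g/L —
within one CRLB of the simulated truth. `run_pipeline()` does this for all
24 study voxels at once, and `reproduce_study_tables()` checks the packaged
tables:

```r
reproduce_study_tables()
#> Study-table reproduction: 30/30 checks pass
```

`compare_matrices(brain, serum)` pairs each serum draw with the temporally
nearest brain measurement; on the study data every serum value from the
second draw onward exceeds the nearest brain value (maximum brain 0.68 g/L
in the frontal cortex versus 1.19 g/L in serum).

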