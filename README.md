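# fiveew

Five-energy-window (FiveEW) scatter and crosstalk correction for
simultaneous Tc-99m / I-123 SPECT with pixelated solid-state (CdTe-like)
detectors — plus everything needed to exercise the correction end to end
on synthetic data: a Hecht-equation detector energy-response model, a
seeded single-scatter Monte Carlo simulator of planar and rotating
phantom acquisitions, OSEM reconstruction with attenuation and collimator
response, and the standard phantom quantification metrics.

## The problem and the method

Simultaneous dual-radionuclide imaging records two tracers in one scan,
but the Tc-99m (141 keV) and I-123 (159 keV) photopeaks are only 18 keV
apart.  Besides object scatter and I-123→Tc crosstalk, solid-state
detectors add a third contamination route: *photopeak spillover* — primary
photons registered below the photopeak because of incomplete charge
collection.  Spillover breaks the assumption of the classic
triple-energy-window (TEW) scatter estimate that the flanking sub-windows
hold no primary counts, so TEW overcorrects.

`fiveew` acquires five windows — Tc-lower (120–130 keV), Tc-main
(130–148), a shared intermediate window (150–155), I-main (155–170),
I-upper (170–180) — and corrects each main window with a
detector-response-corrected TEW (TEWDR):

```
TEW(E_L, E_M, E_U)   = E_M − (α·E_L + β·E_U)
α = (C_U−C_M)/(C_U−C_L) · W_M/W_L ,  β = (C_M−C_L)/(C_U−C_L) · W_M/W_U

TEWDR(E_L, E_M, E_U) = E_M − ( α·(E_L − r·E_M + β·r·E_U)/(1 − α·r) + β·E_U ) ⊗ f
```

where `r` is the lower-window/main-window sensitivity ratio of the
*primary* detector response and `f` a Butterworth low-pass (order 8,
cutoff 0.056 cycles/pixel at 1.4-mm pitch) applied to the scatter term.
The I-123 image uses (intermediate, I-main, I-upper); the Tc-99m image
first subtracts the I-123 crosstalk estimated from the raw I-main window,
`CI_x = (S_x / S_I-main) · E_I-main`, then applies TEWDR on the Tc
triple.  With the filter off, `TEWDR = TEW / (1 − α·r)` exactly.

## Worked example

```r
library(fiveew)

ws <- make_default_windows()
co <- tew_coefficients(ws[["Tc-lower"]], ws[["Tc-main"]], ws[["intermediate"]])
round(c(alpha = co$alpha, beta = co$beta), 6)
#>    alpha     beta
#> 0.883636 1.832727

tew(100, 1000, 50, co)        # scatter-corrected Tc-main, uniform pixels
#> [1] 820
tewdr(100, 1000, 50, co, r = 0.1)
#> [1] 899.4815                # = 820 / (1 − 0.883636 · 0.1)

# detector model calibrated to the scanner's 6.6 % resolution
resp <- isotope_response("Tc-99m", detector_params(), n_samples = 2e6, seed = 1)
round(fwhm_percent(resp, 141), 2)
#> [1] 6.63
round(resp$r, 3)               # Tc-lower / Tc-main spillover ratio
#> [1] 0.235

# dual-isotope planar acquisition of a 200-mm cylinder, corrected
acq  <- acquisition_spec(n_tan = 96, n_ax = 32, pixel_mm = 2.8, n_views = 1)
ph   <- make_cylinder_phantom(200, 200, activity_tc = 18, activity_i = 12)
lh   <- simulate_planar(ph, acq, detector_params(), n_photons = 2e6, seed = 7)
stack  <- histograms_to_stack(lh)
resp_i <- isotope_response("I-123", detector_params(), n_samples = 2e6, seed = 2)
filt <- scatter_filter_spec(cutoff = scaled_filter_cutoff(acq$pixel_mm))
out  <- five_ew(stack, resp, resp_i, filt)
out
#> <correction_result> FiveEW (r_Tc = 0.2353, r_I = 0.5281)
#>   total Tc primary: 1.569e+05   total I primary: 3004
```

The corrected totals estimate the *primary* (unscattered,
uncontaminated) counts in each main window; compare them with
`histograms_to_stack(lh, component = "primary", isotope = ...)` to get
the percentage errors reported by `ratio_study()`.  The higher-level
workflows are:

* `ratio_study()` — planar cylinder acquisitions mixed at Tc:I photopeak
  ratios 1:9 … 9:1; percentage error vs ground-truth primary counts for
  no correction, FiveEW-woDR and FiveEW.
* `phantom_recovery_study()` — rotating acquisitions of the calibration
  cylinder and the six-compartment phantom, FiveEW + OSEM (30 subsets,
  20 iterations, traced uniform attenuation map, 14-mm post-filter),
  cross-calibration, and the linearity / percentage-difference /
  residual-scatter metrics.
* `run_pipeline()` / `inst/cli/fiveew.R` — config-driven
  simulate → correct → reconstruct → analyze runs from R or the shell:

```sh
Rscript inst/cli/fiveew.R run --config myrun.json --seed 7 --out out/
```

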