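---
title: "Five-energy-window scatter and crosstalk correction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Five-energy-window scatter and crosstalk correction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiveew)
```

## The problem

Simultaneous Tc-99m / I-123 SPECT promises two functional images from one
scan, but the photopeaks (141 and 159 keV) are only 18 keV apart.  Even
with the fine energy resolution of pixelated CdTe detectors (6.6 % FWHM at
141 keV), three contamination routes corrupt the acquisition windows:

1. **Object scatter** — Compton-scattered photons detected below their
   emission energy.
2. **Crosstalk** — I-123 events (down-scatter of the 159- and 529-keV
   lines, finite resolution, charge-collection tails) recorded in the
   Tc-99m windows.
3. **Photopeak spillover** — primary photons registered *below* the
   photopeak because of incomplete charge collection in the solid-state
   detector.  This breaks the central assumption of the classic
   triple-energy-window (TEW) estimate, namely that the flanking
   sub-windows contain no primary counts, and makes TEW overcorrect.

`fiveew` implements the five-window correction chain that addresses all
three, plus everything needed to exercise it end-to-end on synthetic data:
a detector energy-response model, a seeded single-scatter Monte Carlo
simulator of planar and rotating phantom acquisitions, OSEM
reconstruction, and the phantom quantification metrics.

## The correction chain

The five acquisition windows (`make_default_windows()`) are Tc-lower
(120--130 keV), Tc-main (130--148), a shared intermediate window
(150--155) acting as Tc-upper and I-lower, I-main (155--170) and I-upper
(170--180).  Intervals are half-open `[lo, hi)` so shared bounds never
double-count; the 148--150 gap and energies above 180 keV belong to no
window.

**TEW** estimates the scatter in a main window `M` from its neighbours:
$$\mathrm{TEW}(E_L, E_M, E_U) = E_M - (\alpha E_L + \beta E_U), \qquad
\alpha = \frac{C_U - C_M}{C_U - C_L}\frac{W_M}{W_L},\;
\beta = \frac{C_M - C_L}{C_U - C_L}\frac{W_M}{W_U}$$
with window centres $C$ and widths $W$.

**TEWDR** removes the primary spillover first.  With $r$ the ratio of
lower-window to main-window sensitivity of the *primary* detector
response, the spillover $P_L = r\,P_M$ satisfies a linear fixed point
whose closed form is
$$\mathrm{TEWDR}(E_L,E_M,E_U) = E_M - \left(\alpha\,
\frac{E_L - r E_M + \beta r E_U}{1 - \alpha r} + \beta E_U\right)
\otimes f,$$
where $f$ is a Butterworth low-pass (order 8, cutoff 0.056 cycles/pixel at
the reference 1.4-mm pitch) applied to the scatter term only, to tame its
statistical noise.  With the filter off the result equals
$\mathrm{TEW}/(1-\alpha r)$ exactly — a property the test suite checks to
1e-10 — and `iterative_sc()` provides the generic fixed-point iteration
for non-linear scatter operators, which for TEW converges geometrically
with ratio $\alpha r$ to the same closed form.

**FiveEW** applies, per pixel: (a) TEWDR on (intermediate, I-main,
I-upper) for the I-123 image — no Tc-related window enters, so the I-123
image is structurally independent of the Tc-99m activity; (b) subtraction
of the I-123 crosstalk $CI_x = (S_x/S_{\text{I-main}})\,E_{\text{I-main}}$
from the three Tc-related windows, using the *raw* I-main counts (this
deliberately includes I-123 object scatter, which the Tc-branch TEW could
not attribute otherwise), then (c) TEWDR on the corrected Tc triple.
`five_ew(..., use_dr = FALSE)` gives the FiveEW-woDR variant (plain TEW in
both branches).

Negative corrected counts are preserved through the correction (keeping
the chain linear and testable) and clipped to zero only on OSEM entry,
where non-negativity is required.

## Detector energy-response model

Primary gamma rays deposit a pulse height $E \cdot CCE(z)/CCE(z^*)$, with
the Hecht charge-collection efficiency
$$CCE(z) = \frac{\lambda_e}{d}\left(1-e^{-(d-z)/\lambda_e}\right) +
           \frac{\lambda_h}{d}\left(1-e^{-z/\lambda_h}\right)$$
at interaction depth $z$ (measured from the photon-entry face; the depth
convention is ours, documented because it is not fixed by any external
reference).  Depths follow a truncated Gaussian; Fano statistics
($\sigma^2 = F\,\varepsilon\,E$) and a constant electronic noise add a
Gaussian spread.  The energy scale is anchored so the photopeak sits at
the nominal line energy ($CCE(z^*)$ is the maximum over depth).

Defaults (`detector_params()`): $d = 5$ mm, $\lambda_e = 100$ mm,
$\lambda_h = 5$ mm, $F = 0.11$, $\varepsilon = 4.43$ eV,
$\sigma_{\text{noise}} = 2.25$ keV, depth $\sim$ TruncGauss($d/4$, $d/4$).
They were calibrated in-package to three targets: 6.6 % FWHM at 141 keV, a
visible low-energy tail with a Tc-99m spillover ratio $r$ in the plausible
pixelated-CdTe range (the default gives $r_{\mathrm{Tc}} \approx 0.24$),
and a Tc-99m spectrum that is essentially empty above 150 keV (fraction
$\sim 3\times10^{-6}$), preserving the design property that the I-123
lower sub-window is free of Tc-99m counts.  Inter-pixel scatter and
k-escape are not modelled separately; their net effect is absorbed into
the Hecht tail, a single mechanism being sufficient to produce photopeak
spillover at desk scale.

A structural consequence worth knowing: within this model family the
6.6 % FWHM target forces the spectral density to stay above half the peak
maximum down to about 6.5 keV below the photopeak.  At 159 keV that
shoulder covers most of the 150--155 keV window, so the I-123 spillover
ratio is large ($r_{\mathrm{I}} \approx 0.53$; a search over the feasible
parameter space bounds it below at about 0.46) and the TEWDR denominator
$1-\alpha r$ amplifies any residual scatter-estimate bias in the I branch
by a factor of 5--8.  Measured CdTe spectra concentrate more of their
width in an asymmetric near-peak core and show much milder spillover, so
the package's I-123 branch should be read as reproducing the *simulation*
regime of such systems (strong overcorrection, order 40--90 % planar
percentage errors, detector-response correction reducing but not removing
it), not the accuracy a measured response would give.  This is the main
known limitation of the model.

## Synthetic-data generator

`simulate_planar()` / `simulate_spect()` emulate the prototype scanner:
192 x 96 pixels at 1.4 mm pitch (scaled-down grids are used throughout
the tests), wide-aperture parallel-hole collimator (hole 2.4 mm, length
26 mm), 130 mm rotation radius, 120 views over 360 degrees.  Emission
points are sampled proportionally to the voxelized activity; attenuation
uses the phantom map rescaled with photon energy by the water
attenuation curve; the collimator is a geometric acceptance cone per
pixel (uniform disc of radius $\text{hole}\,(L+d)/(2L)$), not
hole-by-hole ray tracing, and septal penetration is ignored.

Scatter uses a single-scatter forced-detection estimator, a standard
variance-reduction device in SPECT Monte Carlo: photons are emitted
isotropically, an interaction point is sampled along the ray, and the
scattered photon is forced towards the detector with weight
$(1-e^{-\tau_1})\cdot 4\pi\,p_{KN}(\cos\theta^*)\cdot e^{-\tau_2}$, where
$p_{KN}$ is the Klein--Nishina phase function (validated against numeric
integration), $\theta^*$ the deflection required to reach the detector,
and $\tau_{1,2}$ the optical depths before and after scattering.  Both
the primary and scatter estimators share the constant collimator
solid-angle factor, so their relative normalization is exact; stochastic
rounding keeps counts integer with exact means.  Energy deposition then
passes through the detector response, and primary/scattered labels are
kept per pixel and isotope (`primary + scatter = total` is asserted
always).  All randomness derives from one integer master seed via
per-view, per-batch derived streams.

What the generator does *not* reproduce: multiple scatter (the
single-scatter spectrum under the main windows is steeper than reality,
which makes the TEW flanking-window interpolation underestimate I-123
down-scatter in the Tc windows by more than a measured system would
see), detector dead time, septal penetration, and out-of-FOV activity
beyond what a long phantom provides.  Trend-level agreement — orderings
and monotonicities across correction variants and mixing ratios — is the
design goal, not absolute error magnitudes.

## Reconstruction

OSEM with angle-interleaved subsets (view $i$ in subset $i \bmod 30$; 30
subsets, 20 iterations by default), rotation-based projectors built from
cached sparse bilinear rotation operators so the back projector is the
exact transpose of the forward projector (adjointness holds to machine
precision, which underwrites OSEM's convergence behaviour).  Attenuation
is the voxel-to-detector exponential line integral through a uniform-mu
map traced from the projections (threshold 5 % of the per-view maximum,
support = voxels inside at least 95 % of view silhouettes; both are
configuration parameters with these documented defaults, as no external
reference fixes them).  The collimator response is modelled as a
distance-dependent Gaussian with FWHM $= \text{hole}\,(L+d)/L$; it is on
by default because the wide-aperture collimator blur otherwise leaves a
strong radial bias in reconstructed cylinders.  The reconstruction is
finished with a count-preserving 14-mm-FWHM Gaussian post-filter
(circular convolution, so totals are preserved exactly).

## Quantification

`uniform_phantom_rois()` places the 18 protocol ROIs (20-mm diameter
cylinders, 100 mm long at full scale, six per ring at radii 25/50/70 mm).
For the six-compartment phantom no external reference fixes the ROI
geometry; the package uses three 14-mm cylinders per compartment on the
wedge bisector (centroid and +-60 % towards the boundary), a documented
package choice.  Cross-calibration divides true activity by the mean
uniform-phantom ROI value, per method and isotope.  The metrics are the
percentage difference $100\,|a-b|/\text{ref}$ (the exact formula is a
documented convention — references are the single acquisition or the
injected activity depending on the study), the relative PD of hot-ROI
values standardized by the hottest compartment of the radionuclide of
interest, residual scatter RS $= 100 \cdot$ mean cold / mean hot, and
decay correction with physical half-lives (Tc-99m 6.007 h, I-123
13.22 h).

## Reference studies, problem sizes and numerical choices

`ratio_study()` mixes single-isotope planar cylinder acquisitions
(200-mm water cylinder, 96 x 32 pixels at 2.8 mm pitch) at photopeak
ratios 1:9 ... 9:1 from shared base histograms, so cross-ratio
comparisons are exactly correlated and ratio-invariance of the I branch
can be tested against a Poisson-propagated standard error.  Default
sample sizes (1e7 / 1.4e7 emissions) give over 1e6 photopeak counts per
isotope.  `phantom_recovery_study()` runs the rotating chain on a 64 x
64 x 16 grid at 4 mm voxels with 60 views, 1e6 emissions per view for
the six-compartment phantom (sized so Monte Carlo noise in the cold-ROI
means is well below the residual-scatter levels of interest) and 3e5 per
view for the calibration cylinder.  These sizes are the package's
defaults for its own validation studies; the full 256 x 256 x 96 /
120-view geometry remains available through the configuration.

The Butterworth cutoff is defined in cycles/pixel at the reference
1.4-mm pitch.  On coarser grids `scaled_filter_cutoff()` preserves the
physical cutoff frequency (0.04 cycles/mm) instead of the pixel-relative
value; the reference studies use it.  Frequency-domain filters use
mirror padding to suppress edge ringing (the boundary scheme is a
package choice).  Ties and degenerate inputs: all-zero projections
reconstruct to a zero volume (documented, not an error); `alpha * r = 1`
is rejected as a singular configuration; window/histogram misalignment
is an error rather than silent interpolation.

## Known limitations

* The I-123 branch inherits the heavy near-peak tail forced by the
  energy-resolution calibration (see above); absolute I-123 accuracy
  after correction is pessimistic relative to a measured detector
  response, and the six-compartment I-123 linearity reflects it.  In
  addition, because the corrected I-123 signal is a small residual
  (roughly 8 % of the raw I-main counts) while the smoothed scatter term
  carries several-fold amplified Poisson noise correlated at the filter's
  spatial scale, I-123 ROI means fluctuate at the level of the signal
  itself at the default problem sizes — the I-123 linearity metric is
  noise-limited as well as biased.
* Single scatter only; multiple-scatter spectra would flatten the
  sub-window continuum and improve the Tc-branch residuals.
* Scatter-corrected projections are no longer Poisson distributed, so
  OSEM's statistical model is approximate — a known property of
  subtraction-based corrections, handled here by clipping at zero on
  reconstruction entry only.
* The 529-keV I-123 line is simulated (its down-scatter feeds the
  I-upper window) but the correction itself ignores the 529-keV
  photopeak, by design.
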