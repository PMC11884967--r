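---
title: "Simulating and analysing BCARS hyperspectral single-cell images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing BCARS hyperspectral single-cell images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bcars)
```

## The measurement and its forward model

Broadband coherent anti-Stokes Raman scattering (BCARS) records, at every
pixel of a raster scan, a full vibrational spectrum in a few milliseconds.
The detected intensity at Raman shift $\Delta$ is driven by the third-order
nonlinear susceptibility

$$\chi^{(3)}(\Delta) \;=\; \chi_{NR} \;+\; \sum_j \frac{A_j}{\Omega_j - \Delta - i\Gamma_j},$$

a real, nearly constant nonresonant part $\chi_{NR}$ (four-wave mixing
through virtual states — the nonresonant background, NRB) plus complex
Lorentzian resonances with centres $\Omega_j$, half-widths $\Gamma_j$ and
amplitudes $A_j$.  The spontaneous-Raman-like spectrum a spectroscopist
wants is $\mathrm{Im}\,\chi^{(3)}$, but the camera measures

$$I(\Delta) \;\propto\; |\chi^{(3)}(\Delta)|^2\, S(\Delta) + \text{dark},$$

where $S$ is the laser excitation envelope.  The cross term
$2\chi_{NR}\,\mathrm{Re}\,\chi_{R}$ both amplifies the resonant signal and
distorts its line shapes (dispersive profiles), which is why NRB removal is
the central processing problem.

`chi3_spectrum()`, `cars_intensity()` and `render_scene()` implement exactly
this model.  A `scene_phantom` places elliptical cells (two compartments:
nucleus and cytoplasm, each a `susceptibility_model`) on a glass substrate
(`chi_nr` only, no modes), and the renderer adds shot noise (Poisson on the
expected counts), Gaussian read noise, and rare cosmic-ray pixels.  Because
the generator knows the ground truth of every pixel, every processing stage
in the package is validated against exact oracles rather than against
plausibility.

## What the generator emulates — and what it does not

* **Two cell classes.** Both classes share one band table (nucleobases at
  669/728/784 cm⁻¹, phenylalanine 1003, PO₂ 1095, amide III/I, CH₂ 1440,
  A/G ring 1575, CH stretches 2934/3054).  Class B multiplies the
  nucleic-acid-associated amplitudes: ×1.3 at 669 and 728 cm⁻¹, ×1.15 at
  784, 1095 and 1575 cm⁻¹ (settable in `two_class_models()`).  These
  windows are the generator's *discriminative bands*; a sound classifier
  should find them.
* **Biological variability at two scales.** Each cell draws a lognormal
  concentration factor per band (`cell_sigma = 0.02`, shared between its
  compartments) — without this, cells of one class are identical up to
  scale, any consistent channel separates the classes perfectly, and
  feature importance is arbitrary.  The magnitude is set by a consistency
  argument: at 0.02 most cells of one class pass the standard Pearson
  quality threshold of 0.995, as fixed cells of one line do in practice;
  at 0.1 almost none would.  Each pixel additionally draws a global
  amplitude factor (`jitter_sigma = 0.1`) emulating intra-cell
  heterogeneity (thickness, focus, local density).  Both values are
  package choices of realistic magnitude, not measured quantities.
* **The excitation envelope** is a smooth two-hump curve (fingerprint +
  CH-stretch) with a raised-cosine dead window.  The dead window defaults
  to 2000–2800 cm⁻¹: a window extending to 3000 cm⁻¹ would make the CH
  bands at 2934/3054 cm⁻¹ unmeasurable, which contradicts their routine
  appearance in measured cell spectra.  Inside the dead window nothing is
  retrievable; the pipeline treats those channels explicitly (below).
* **Noise levels.** Peak excitation 2000 counts, dark level 100 counts,
  read noise 3 counts RMS, under one cosmic ray per image at ≥12× the mean
  intensity — a plausible cooled-CCD operating point at millisecond dwell
  times.
* **Not emulated:** pulse-level nonlinear optics (chirp, probe delay,
  supercontinuum structure), diffraction/PSF blurring, 3-D sectioning,
  cell-size differences between the classes, segmentation-hostile cell
  clumping, slide-level batch effects.  Passing tests therefore say the
  *algorithms* are correct under the stated physics; they do not certify
  performance on any particular instrument's data.

## The processing chain

Stages run in a fixed order (`process_scene()`): despike → dark subtraction
→ SVD denoise → total-intensity image → segmentation → background NRB
reference → per-pixel retrieval.  Cell-level analysis then averages,
QC-filters, scatter-corrects, crops and normalizes (`run_study()`).

### Cosmic-ray removal

A pixel is flagged when its spectral mean exceeds 10× the global mean of
pixel means, and is replaced by the mean of its in-frame 4-neighbourhood
(flagged neighbours excluded when any clean one exists — edge behaviour is
unspecified in the field's descriptions, so the rule is: use whatever
in-frame neighbours exist).  Unflagged pixels pass through bit-identical;
the operation is idempotent on realistic spike rates.

### SVD denoising with Fourier singular-vector selection

The cube unfolds to a channels × pixels matrix (so spatial patterns are the
*right* singular vectors), decomposed without mean-centring so the
background stays an explicit component.  A component is kept when its
mean-removed spatial map concentrates more than `score_multiplier = 3`
times the expected white-noise share of its 2-D Fourier energy inside the
low-frequency disc of radius `min(H, W)/8`.  White noise spreads energy
uniformly (share ≈ disc area fraction, ~5%), genuine cell-scale structure
concentrates heavily (share ≫ 15%), so the rule separates them with a wide
margin; hyperparameters are exposed in the config.  Numerics: the
decomposition runs through the K × K Gram matrix (exact for the inspected
leading components, an order of magnitude faster than a full SVD when
pixels ≫ channels); components with singular value below 10⁻⁶ of the
largest carry no energy and are never kept (their singular vectors are
0/0-unstable); each spectral vector's largest element is forced positive so
reports are reproducible.

### Kramers–Kronig retrieval with phase and amplitude error correction

With a measured NRB reference $I_{ref}$ (the average spectrum of the
largest non-cell region), causality links the intensity ratio to the phase:

$$\phi(\Delta) \;=\; \mathcal{H}\!\left\{\tfrac12 \log \frac{I(\Delta)}{I_{ref}(\Delta)}\right\},$$

computed by an FFT Hilbert transform on a mirror-extended signal
(`pad_factor = 2`).  Because the reference never equals the true NRB at the
pixel, $\phi$ carries a slowly varying error; an asymmetric-least-squares
(ALS) baseline estimates and removes it, with region-wise asymmetry
$p = 0.001$ (fingerprint, 500–1708 cm⁻¹), $0.01$ (silent, 1708–2745 — no
biological bands live there, so the detrend may be aggressive) and
$0.0001$ (high-wavenumber, 2745–4554).  The corrected complex spectrum
$\sqrt{I/I_{ref}}\,e^{i(\phi-\phi_{err})}$ is finally divided by a
symmetric ALS baseline of its real part (the amplitude error), and its
imaginary part is the Raman-like spectrum.

Numerical choices that mattered:

* **Dead channels.** Where the reference carries under 5% of its median
  intensity (`dead_threshold`), the log-ratio is noise over noise; worse,
  flooring alone leaves steps at the dead-window edges whose Hilbert
  ringing contaminates every channel.  The log-ratio is therefore bridged
  by linear interpolation across dead channels.  Both inputs are also
  floored at 10⁻⁶ of their medians so no logarithm diverges.
* **Smoothing parameter.** The ALS penalty is on squared second
  differences in channel units; `smoothing_lambda = 3e4` (a ~13-channel,
  ~50 cm⁻¹ scale on the 1024-channel axis) was calibrated against
  noiseless forward-model recovery over seeds of a weak-resonance suite
  at biological band widths.  A much smaller value lets the baseline
  absorb genuine broad resonant phase; a much larger one under-fits the
  cell-to-cell NRB mismatch.  Unphysically broad overlapping bands
  (half-widths well beyond ~20 cm⁻¹) form a quasi-pedestal whose split
  between signal and baseline is intrinsically ambiguous at any single
  smoothing scale — a known limitation of every baseline-based error
  correction.  Published values of this parameter are
  implementation-specific in their units and should be re-derived for any
  reimplementation exactly as done here: simulate weak resonances, demand
  recovery.
* **Sign convention.** The transform's sign is fixed so a
  positive-amplitude Lorentzian yields a positive Raman-like peak,
  verified against the analytic phase of $(\chi_{NR}+\chi_R)/\chi_{NR}$.
* **ALS convergence.** Iterations stop when the asymmetric weight pattern
  is fixed *or* the baseline moves less than `als_tol = 1e-4` of the data
  range (near-tie channels otherwise flip weights forever in a limit
  cycle); cap 20 iterations, after which the last iterate is returned with
  a warning.

### Segmentation and the NRB reference

The classical fallback (Gaussian blur σ = 1.5 px → Otsu → fill holes →
distance-transform watershed → drop objects under 20 px) is accurate for
phantom scenes (per-cell IoU ≥ 0.7 is tested) and splits touching pairs; an
external segmenter such as Cellpose can be plugged in through a
shell-command adapter (intensity TIFF in, label TIFF out) and is
deliberately not bundled.  The NRB reference averages the largest connected
region *not* labelled as a cell — phrased that way so a giant cell can
never masquerade as background; ties break to the lowest region id.

### Cell spectra: averaging, QC, EMSC, crop, normalization

Order is fixed and recorded: average within each mask label → Pearson QC
(drop cells with ρ < 0.995 against the highest-intensity cell; undefined
correlations drop too) → extended multiplicative signal correction (EMSC:
regress each spectrum on the mean reference plus orthogonal polynomials of
degree ≤ 5 on the axis rescaled to [−1, 1], divide out the multiplicative
coefficient) → crop to 500–3142 cm⁻¹ (channels whose shift lies in the
closed interval) → min–max normalization.  EMSC is idempotent and invariant
to input scaling; both are tested.  The labelled run's mean reference is
cached and reused for unlabelled (mixture) runs, so both datasets live in
one corrected space.

### Classification and evaluation

A 40-tree random forest with class weights inversely proportional to class
frequencies, unlimited depth, √K features per split; probabilities are
tree-vote fractions, out-of-bag accuracy comes from the out-of-bag votes,
and Gini (impurity-decrease) importance is normalized to sum to one.
Cross-validation is stratified 10-fold balanced accuracy (mean of
per-class recalls).  Cells in mixtures are labelled where a class
probability exceeds 0.5; an exact tie goes to the second class
alphabetically and is flagged low-confidence.  Single-pixel mode pools
every in-cell pixel (same EMSC/crop/normalize treatment per pixel) and
evaluates a stratified 90/10 split; the default split is at pixel level,
which leaks intra-cell correlation between train and test — a
grouped-by-cell split is provided (`grouped = TRUE`) and is the honest
choice when pixels per cell are many.  Mixture evaluation: chi-square of
predicted proportions against 1:1, projection of mixture cells on the
labelled PCA basis (Scott's-rule kernel densities per class), and a
Mann–Whitney comparison of equivalent diameters
($2\sqrt{\text{area}/\pi}\,\cdot$ step) between predicted classes.

## Study conditions and problem sizes

`run_study(default_config())` renders eight labelled scenes (four per
class) and two 1:1 mixed scenes, each 96 × 96 px at 1 µm step with K = 1024
channels over 500–4554 cm⁻¹ and 16 cells per scene — 64 cells per class,
roughly 1.5 × 10⁴ labelled pixels, sized so the full study runs in minutes
on one core while keeping ≥ 60 cells per class for stable cross-validation.
Oracle-style tests use smaller frames (24–64 px) and shorter axes (128–512
channels) where the property under test does not depend on scale.

## Known limitations

* The retrieval's accuracy degrades for strong resonances
  ($A/\Gamma\chi_{NR} \gtrsim 0.5$): the error-correction baselines start
  to absorb genuine signal.  The defaults target the weak-resonance regime
  typical of biological fingerprints.
* Within the excitation dead window nothing can be recovered; retrieved
  values there are interpolation artefacts and should not be interpreted.
* The pixel-level 90/10 split overstates single-pixel accuracy relative to
  a grouped split; both numbers are available.
* The chi-square mixture test assumes independent cell classifications;
  spatial clustering of cell types on a real slide violates this.
* The synthetic phantom's simplifications (no PSF, no batch effects, equal
  class sizes) mean real-data accuracy claims cannot be transferred from
  these simulations.
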