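# bcars

Simulation and analysis of broadband coherent anti-Stokes Raman scattering
(BCARS) hyperspectral images of single cells.

## The problem

BCARS microscopy records a full vibrational spectrum (500–4554 cm⁻¹) at
every pixel of a raster scan in milliseconds, fast enough to image whole
fields of cells label-free. The catch is that the detected signal is not a
Raman spectrum: the resonant response mixes coherently with a nonresonant
background (NRB), distorting every line shape, and the raw counts carry
shot noise, cosmic-ray spikes and instrument envelopes. Classifying cell
types from such data requires a chain of physics-based corrections before
any statistics can be trusted.

This package implements that chain end to end, for people who build or
evaluate BCARS/CARS processing pipelines:

1. **Forward model / scene generator** — complex third-order
   susceptibility χ³(Δ) = χ_NR + Σⱼ Aⱼ/(Ωⱼ − Δ − iΓⱼ); detected intensity
   ∝ |χ³|²·S(Δ) + dark, with shot/read noise, cosmic rays, two cell
   classes with compartmentalized band tables, per-cell compositional and
   NRB variability. Every downstream stage is validated against this
   ground truth.
2. **Preprocessing** — mean-intensity despiking (10× threshold,
   4-neighbour replacement), truncated-SVD denoising with a 2-D Fourier
   criterion on the spatial singular vectors.
3. **NRB removal** — Kramers–Kronig phase retrieval (FFT Hilbert
   transform, mirror padding) with asymmetric-least-squares phase and
   amplitude error correction, region-wise asymmetry
   (0.001 / 0.01 / 0.0001 for fingerprint / silent / high-wavenumber).
4. **Single-cell spectra** — watershed segmentation (pluggable external
   segmenter), per-cell averaging, Pearson QC (ρ ≥ 0.995), EMSC scatter
   correction (5th-order polynomial), crop to 500–3142 cm⁻¹, min–max
   normalization.
5. **Classification & evaluation** — 40-tree balanced random forest with
   out-of-bag score, Gini importance spectra, stratified 10-fold balanced
   accuracy, single-pixel (5 ms spectrum) classification with a 90/10
   split, mixture evaluation by chi-square proportions, PCA projection and
   cell-size analysis.

## Worked example

Simulate one two-class scene, process it, and average the cells:

```r
library(bcars)

models <- two_class_models()              # class B: x1.3 at 669/728, x1.15 at 784/1095/1575 cm^-1
axis   <- default_axis(1024)              # 500-4554 cm^-1
ph     <- random_phantom(96, 96, c(A = 8, B = 8), models, seed = 42)
scene  <- render_scene(ph, axis, noise = noise_spec(seed = 42))

proc <- process_scene(scene$image)        # despike -> dark -> SVD -> segment -> KK retrieval
table <- average_cells(proc$retrieved, proc$mask,
                       setNames(as.list(scene$cells$class), scene$cells$label))
table
#> <cell_spectrum_table> 16 cells (A=8, B=8)
```

The full synthetic study (8 labelled scenes, 2 mixed scenes, 16 cells
each, ~6–8 min on one core):

```r
res <- run_study(default_config(seed = 1))
length(res$table)                          # 128 cells kept by QC
res$fit$report$oob_score                   # 0.992  out-of-bag accuracy
res$cv$mean                                # 0.977  10-fold CV balanced accuracy
res$single_pixel$balanced_accuracy         # 0.996  single-pixel (90/10 split)
res$mixed$counts                           # 13 / 19 predicted in the 1:1 mixture
res$mixed$chisq$p                          # 0.29   chi-square p against 1:1
```

At the default effect sizes the problem is hard enough to be informative
(accuracies near, not at, 1), and the
forest's top importance channels fall at the generator's discriminative
bands (669, 728, 784, 1095, 1575 cm⁻¹) — the same kind of localization one
checks on measured spectra. `analysis/01_simulate.R` …
`analysis/05_evaluate_mixture.R` run the same study as a step-by-step
workflow with artifacts on disk (scene containers under `scratch/`, tables
and reports under `results/`).

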