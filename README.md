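# dsegr

Whole-cerebrum diffusion segmentation spectra and the DSEG-θ burden score
for cerebral small vessel disease (SVD), with the full downstream inference
chain: longitudinal change models, cognitive-decline regressions, Cox
dementia-risk models, and leave-one-out cross-validated discriminant
classification — plus a synthetic-cohort generator with known ground truth
so every stage is testable without clinical data.

## Who this is for

Researchers working with longitudinal diffusion MRI in SVD (or similar
diffuse pathologies) who want a single automatic burden score per scan
instead of a panel of manually curated imaging markers, and who need the
accompanying statistics reproducible end to end.

## The method

Each voxel's diffusion tensor eigenvalues λ₁ ≥ λ₂ ≥ λ₃ (mm²/s) are reduced
to an isotropy magnitude `p = √3·MD` and an anisotropy magnitude
`q = ‖(λ₁,λ₂,λ₃) − MD‖`, with `MD` the mean diffusivity. Grey matter,
white matter, CSF and lesioned tissue occupy distinct regions of the
(p,q) plane. The pooled 2-D histogram of (p,q) over *all* scans is
clustered into k = 16 segments by k-medians (Euclidean Voronoi assignment,
count-weighted coordinate-wise median centroids), each scan is summarised
by its **spectrum** — the percentage of cerebrum volume in each segment —
and scored by the spectral angle against a healthy reference spectrum A:

    θ = arccos( ⟨A,B⟩ / (‖A‖·‖B‖) )

θ ∈ [0, π/2]; larger θ means greater divergence from healthy tissue
composition. Baseline θ and its annualized change then feed
mixed-effects change models, slope regressions (adjusted for mean-centered
age, premorbid IQ and sex), Cox models of conversion to dementia
(hazard ratios per SD of z-scored covariates, Efron ties), and LOO-CV
linear discriminant classification reported as sensitivity, specificity,
accuracy, balanced classification rate `BCR = (sens+spec)/2`, and AUC.

## Worked example

Simulate a design-matched cohort (99 patients, annual imaging 0–3 y,
cognition 0–5 y, ~18% conversion, true hazard ratio 3.331 per SD of
baseline θ) and run the statistical chain:

```r
library(dsegr)
cfg <- synthetic_config(n_subjects = 99, rng_seed = 2024)
run <- run_dseg_pipeline(cfg, imaging = "latent")
write_report(run, "report")
```

The text report this prints:

```
dseg run 5e2d8585 (seed 2024, imaging latent)
subjects 99, events 14, reference NA

Annualized change (LME):
  theta  slope +0.0314 (se 0.0015)  Wald 413.35  p 6.84e-92
  EF     slope -0.0797 (se 0.0046)  Wald 295.75  p 2.77e-66
  IPS    slope -0.0598 (se 0.0043)  Wald 197.05  p 9.21e-45
  WkM    slope -0.0046 (se 0.0043)  Wald 1.14  p 0.285
  EM     slope +0.0033 (se 0.0048)  Wald 0.48  p 0.489
  GC     slope -0.0352 (se 0.0023)  Wald 228.35  p 1.37e-51

Slope regressions (baseline theta + change):
  EF_slope   R2 0.325 (n=99)
  IPS_slope  R2 0.151 (n=99)
  GC_slope   R2 0.267 (n=99)

Cox (multivariable, z-scored):
  theta_baseline   HR 3.132 (95% CI 1.859-5.276)  p 1.79e-05
  theta_slope      HR 0.845 (95% CI 0.471-1.518)  p 0.574

LOO-CV discriminant classification:
  theta_baseline   sens 0.143 spec 0.976 acc 0.859 BCR 0.560 AUC 0.762
  theta_change     sens 0.000 spec 1.000 acc 0.859 BCR 0.500 AUC 0.291
  combined         sens 0.143 spec 0.965 acc 0.848 BCR 0.554 AUC 0.720
```

Reading it: θ rises ≈ 0.031 rad/year (disease progresses); executive
function, processing speed and global cognition decline significantly
while the memory domains stay flat — exactly the generator's world. The
Cox hazard ratio on baseline θ (3.13 per SD) recovers the generating value
3.331 within its confidence interval; θ-change carries no hazard here
because this world couples conversion to baseline severity only. The LDA
sensitivity is low at empirical priors with a 14/99 imbalance — the
motivation for reporting BCR and AUC (pass `lda_priors = c(.5, .5)` to
rebalance).

`imaging = "phantom"` replaces the latent θ with the full imaging chain —
nested-ellipsoid eigenvalue phantoms, (p,q) maps, pooled 256×256
histogram, 16-segment k-medians fit, per-voxel Voronoi labelling, spectra,
healthy-reference selection and spectral angles:

```r
cfg <- synthetic_config(n_subjects = 12, n_healthy = 5, rng_seed = 7)
run <- run_dseg_pipeline(cfg, imaging = "phantom")
run$model$centroids        # 16 (p,q) centroids, mm^2/s
run$theta                  # per-scan theta against the healthy reference
```

A command-line wrapper covering simulation, the pipeline and (p,q) map
computation from NIfTI eigenvalue volumes lives at `inst/cli/dseg.R`
(`Rscript inst/cli/dseg.R run --seed 1 --subjects 99 --out dir/`).

## Design notes

See `vignettes/dseg-methods.Rmd` for the full account: the (p,q)
convention, k-medians details (initialisation, tie-breaks, the monotone
objective guard), reference-selection fixed point, the two-stage
slope-on-slope analysis, survival/classification conventions, what the
synthetic world does and does not emulate, and known limitations.
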