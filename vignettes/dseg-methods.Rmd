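---
title: "Segmenting the (p,q) diffusion plane: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the (p,q) diffusion plane: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsegr)
```

## The model

Cerebral small vessel disease (SVD) damages brain tissue diffusely: white
matter hyperintensities, lacunes, atrophy and microstructural white-matter
injury accumulate together. `dsegr` implements a whole-cerebrum burden
score built from a single diffusion tensor acquisition.

Each voxel's diffusion tensor is reduced to two scalars: the isotropy
magnitude $p = \sqrt{3}\,\mathrm{MD}$ and the anisotropy magnitude
$q = \lVert \mathrm{diag}(\lambda) - \mathrm{MD}\,I \rVert$, where
$\mathrm{MD} = (\lambda_1+\lambda_2+\lambda_3)/3$ and the $\lambda_i$ are
the sorted tensor eigenvalues (mm$^2$/s). Grey matter, white matter, CSF
and lesioned tissue occupy distinct regions of the $(p,q)$ plane, so the
plane itself can be segmented: the pooled 2-D histogram of all in-mask
voxels from all scans (patients and healthy controls together) is
clustered into $k = 16$ segments by alternating k-medians, and every voxel
of every scan is labelled with its Euclidean-nearest segment centroid.

A scan is then summarised by its *spectrum*: the percentage of cerebrum
volume in each of the 16 segments, a non-negative 16-vector summing
to 100. Two scans are compared by the angle between their spectra,

$$\theta = \arccos\frac{\langle A, B\rangle}{\lVert A\rVert\,\lVert B\rVert},$$

with $A$ a fixed healthy reference spectrum. $\theta$ is scale-invariant,
lies in $[0, \pi/2]$ for non-negative spectra, and grows as a brain's
tissue composition diverges from healthy composition — more CSF
(atrophy), more lesion-like segments, less healthy white matter. The
downstream inference chain treats per-scan $\theta$ as a longitudinal
biomarker: mixed-effects change models, regressions of cognitive slopes
on baseline $\theta$ and $\theta$ change, Cox models of dementia
conversion, and leave-one-out cross-validated linear discriminant
classification of converters.

## Numerical and algorithmic choices

**The (p,q) convention.** The source literature cites but does not
reprint the exact normalisation of $p$ and $q$. We adopt the standard
decomposition of the tensor into its isotropic part and deviatoric norm;
`compute_pq()` is the single place to swap conventions. The choice is
validated only through internal consistency (rotation invariance, linear
scaling, and the fit-then-decompose round trip), never against published
cohort values.

**Clustering on the histogram.** The segmentation is fitted to the
count-weighted nonzero bin centres of the pooled 2-D histogram (default
256 × 256 bins spanning $[0, P_{99.9}]$ per axis, outliers clipped into
the end bins and counted), not to raw voxels. This matches the
probability-density phrasing of the technique, makes the fit independent
of cohort size, and keeps the objective reproducible. No axis
standardisation is applied by default (the plane is segmented in raw
mm$^2$/s units); the histogram upper edges can be fixed explicitly when
comparability across runs matters.

**k-medians details.** Assignment uses Euclidean distance (the published
segmentation is a Voronoi partition of the plane); the centroid update is
the count-weighted coordinate-wise median, which is what distinguishes
k-medians from k-means on these heavily skewed histograms. Because the
coordinate-wise median is not the minimiser of summed Euclidean distance,
a raw alternation could in principle increase the objective; the update
therefore keeps the previous centroid whenever the median candidate would
increase that cluster's cost. This guard guarantees a monotone
non-increasing objective and termination; in practice it almost never
fires. Initialisation is deterministic — a 4 × 4 grid of weighted
marginal quantiles for $k = 16$ — so fitting needs no RNG. For tiny
problems (≤ 12 nonzero bins, $k \le 4$) every $k$-subset of bin centres
is tried as a start; the tests verify this attains the exhaustive-search
optimum. Convergence: maximum centroid displacement ≤ 1e-6 mm$^2$/s or
500 iterations. Empty clusters are reseeded at the point farthest from
its centroid and counted. Ties in assignment go to the lowest canonical
index.

**Canonical segment order.** Spectra must be comparable across runs, so
segments are ordered by ascending centroid $p$, ties broken by descending
$q$ — a low-isotropy/high-anisotropy (healthy white matter) to
high-isotropy (CSF) sweep. The permutation is stored in the model.

**Reference selection.** The healthy reference is chosen from a pool of
control spectra by a deterministic fixed point: start at the element-wise
median of the pool (renormalised), take the pool member at the smallest
angle to the prototype, and repeat until the choice repeats; ties go to
the lowest subject id. Because a pool member has angle zero to itself,
the procedure stabilises after one update, selecting the member closest
to the coordinate-wise median — a robust "least damaged" anchor. The
original selection algorithm is not reprinted in the source literature;
this definition is declared as this package's, and the test suite keeps
an independent minimum-average-angle search as an oracle. The reference
is only an anchor: every reported statistic is a within-cohort contrast.

**Mixed models.** Change models are random-intercept + random-slope fits
by maximum likelihood (so Wald tests on fixed effects are standard); REML
is available. Singular random-effect covariances fall back to
random-intercept-only fits, and fully degenerate inputs (constant or
noise-free outcomes) fall back to pooled least squares; both are flagged
on the fit object. Per-subject slopes are empirical-Bayes predictions
(fixed slope plus predicted random slope); unshrunken per-subject OLS
slopes are available and are substituted automatically when the EB slopes
are degenerate. Imaging outcomes are modelled on visits ≤ 3 years and
cognitive outcomes on visits ≤ 5 years, honouring the design asymmetry;
this is why slope-on-slope regressions, not a joint mixed model, link
$\theta$ change to cognitive change. Baseline $\theta$ and $\theta$
change enter those regressions jointly (separate-model variants can be
run by passing constant columns). No multiple-testing correction is
applied, matching the raw-P reporting convention.

**Survival and classification.** Cox models use Efron tie handling.
Continuous covariates are z-scored on the full sample first, so hazard
ratios are per SD. LDA uses the pooled within-class covariance with
empirical class priors (with an 18/99 imbalance the priors matter; equal
priors are a flag away), and a tiny ridge is added only if the pooled
covariance is singular (flagged). All reported classification metrics
come from leave-one-out cross-validation: the held-out subject's score is
produced by a model that never saw its label or features, and the AUC is
the trapezoidal area over the ROC of held-out scores with midrank tie
handling — numerically identical to the normalised Mann–Whitney U, which
the tests assert. Onset dates for survival follow the midpoint
convention: the midpoint between the visit establishing the diagnosis and
the previous attended visit.

## The synthetic world

No imaging or cohort data are deposited with the source study, so the
package ships a generator whose defaults *are* the stated study design:
99 patients, annual imaging for 3 years and cognition for 5, and a
conversion fraction targeting 0.18 (18/99) with a true hazard ratio of
3.331 per SD of baseline $\theta$.

* **Phantoms.** Nested ellipsoids on a 32³ grid of 2.5 mm voxels: CSF
  ventricle, WM core, GM shell, and periventricular WMH voxels carved
  from the WM voxels nearest the ventricle. Lesion load is linear in a
  latent severity $s \in [0,1]$ (35% of WM at $s = 1$). Tissue
  eigenvalue means — CSF (3.0, 3.0, 3.0), WM (1.7, 0.4, 0.3), GM (1.1,
  0.9, 0.8), WMH (1.4, 1.0, 0.9), all ×10⁻³ mm²/s, jitter SD 5×10⁻⁵ —
  are generator conventions chosen so the four tissues occupy distinct
  $(p,q)$ regions (verified by a separability test), not estimates of any
  clinical cohort.
* **Disease progression.** Baseline severity is Beta(2, 5) (right-skewed,
  most patients mild); progression rates are Normal(0.06, 0.03²)
  truncated at zero, so severity is monotone and a typical patient gains
  ~0.18 severity over 3 years.
* **Theta as an emergent measurement.** Severity enters the scans only
  through lesion voxels and the generator's latent map
  $\theta_{\text{lat}} = 0.15 + 0.5\,s$; the measured $\theta$ arises
  from the full pipeline (phantom → $(p,q)$ → segmentation → spectrum →
  angle). The two correlate at ≈ 0.99, which is what makes end-to-end
  parameter recovery a genuine test rather than a tautology.
* **Cognition.** Per-domain slopes are
  $\alpha_0 + \alpha_1 \theta_b + \alpha_2 \Delta\theta + \varepsilon$.
  Defaults ($\alpha_1 = -0.12$, $\alpha_2 = -0.30$ z-units/year per
  radian for executive function, about two-thirds of that for processing
  speed, zero for working and episodic memory, slope noise SD 0.03) were
  chosen once so that, at $n = 99$, the declining domains reach the
  strong significance the study design anticipates while memory domains
  stay flat; they are free parameters of the synthetic world, not
  estimates. Baselines couple negatively to baseline $\theta$ so
  converters enter the study worse, and global cognition is the mean of
  the four domains.
* **Conversion.** Exponential event times with hazard
  $\lambda_0 \exp(\beta\, z(\theta_b))$; $\lambda_0$ is calibrated by
  root-finding so the expected observed-event fraction matches the 0.18
  design target given dropout (exponential, 0.04/year) and
  administrative censoring at 5 years. Observed onsets are snapped to
  visit midpoints; censored subjects carry their last attended visit.
  An optional second coefficient couples the hazard to latent $\theta$
  change (default 0); the ordering acceptance test sets it positive,
  since only a world where progression drives conversion can reproduce
  the published pattern in which change-based models outperform
  baseline-only ones.

**What a green test does not establish.** The phantoms have no real
anatomy, no registration error, no scanner noise beyond Gaussian
eigenvalue jitter, and a single lesion habitat; the latent severity model
is one-dimensional. Green end-to-end tests establish that the machinery
recovers known generating parameters through the full measurement chain —
not that the published clinical effect sizes are correct, which would
require the original scans.

## Degenerate inputs and edge policies

Negative fitted eigenvalues are clamped to zero and counted; voxels with
non-positive diffusion signal are dropped from the mask and counted.
Empty masks, zero spectra, zero-variance covariates, event-free cohorts
and single-class folds all raise or flag rather than silently proceed;
LOO folds whose training set loses a class are skipped and counted.
Constant outcomes return a zero slope with Wald p = 1 rather than a
division-by-zero artefact.

## Known limitations

Only ordinary least squares tensor fitting is provided (no RESTORE/WLS);
no eddy/motion correction or skull stripping (masks are taken as final);
$k$ is fixed at 16; no age-stratified normative reference panels; no
per-region spectra. The NIfTI-1 reader/writer is intentionally minimal
(scalar 3-D/4-D volumes, sform affine) because no NIfTI package is
available in the target environment.
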