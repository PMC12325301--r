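---
title: "Region-informed Gaussian-mixture segmentation of the choroid plexus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-informed Gaussian-mixture segmentation of the choroid plexus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpseg)
```

## The problem and the model

The choroid plexus (CP) is the vascularized tissue inside the brain's
ventricles that produces cerebrospinal fluid. On T2-FLAIR MRI the free
fluid in the lateral ventricles (LV) is suppressed and appears dark, while
plexus tissue stays bright, so within the ventricles the CP is an
intensity outlier. `cpseg` exploits exactly this: it segments the CP as
the brightest component of a one-dimensional, three-component Gaussian
mixture fitted to the FLAIR intensities inside an anatomical prior region.

The pipeline, run independently per hemisphere:

1. **Prior region.** The LV and CP labels of a FreeSurfer-style
   parcellation (defaults 4/31 left, 43/63 right) are merged into one
   region. The two structures are adjacent, so the union is gap-free and
   provides a spatial prior that contains the plexus.
2. **Erosion.** The region is eroded by one voxel with a spherical
   structuring element. The region's rim is dominated by partial-volume
   voxels (fluid mixed with wall tissue); removing it discards the
   most ambiguous intensities at the cost of also removing plexus voxels
   that touch the wall — a deliberate trade toward specificity.
3. **Smoothing.** Intensities are smoothed with a 3-D Gaussian filter
   restricted to the eroded region (mask-normalized, so voxels outside
   the region contribute neither signal nor weight).
4. **Normalization.** Region intensities are divided by the mean of their
   strictly positive values, making the samples dimensionless with
   non-zero mean 1 and comparable across scanners and subjects.
5. **Mixture fit.** A K = 3 Gaussian mixture is fitted by EM from the
   empirical initialization means (0.15, 1.5, 4), standard deviations
   (0.02, 0.1, 1.5) and proportions (0.45, 0.5, 0.05) — a dark-fluid
   component, an intermediate partial-volume component, and a bright
   plexus component on the normalized scale.
6. **Hard clustering.** Each voxel is assigned to the component with the
   highest posterior probability; voxels belonging to the component with
   the highest *fitted* mean form the CP mask. The hemisphere masks are
   unioned.

The model's assumptions are therefore: the inputs are bias-corrected and
coregistered (the package validates grid identity but never resamples);
the parcellation's LV+CP region contains the plexus; and within that
region the normalized intensity distribution is approximately a
three-component Gaussian mixture. The mixture is intensity-only — the
spatial information enters solely through the prior region, and no
spatially regularized model (e.g. an MRF coupling) is used.

## Tunable parameters

| key | default | unit | role |
|---|---|---|---|
| `labels.left.lv` / `.cp` | 4 / 31 | label id | FreeSurfer left LV / CP |
| `labels.right.lv` / `.cp` | 43 / 63 | label id | FreeSurfer right LV / CP |
| `erosion.radius_voxels` | 1 | voxels | prior erosion radius |
| `erosion.shape` | `"sphere"` | — | Euclidean ball; `"box"` gives 26-connectivity |
| `smooth.sigma_voxels` | 0.5 | voxels | Gaussian smoothing width |
| `smooth.masked` | `TRUE` | — | renormalized masked filtering |
| `gmm.means`, `gmm.sds`, `gmm.weights` | see above | normalized intensity | EM starting point |
| `gmm.tol` | 1e-6 | relative | EM log-likelihood convergence |
| `gmm.max_iter` | 500 | — | EM iteration cap |
| `gmm.sd_floor` | 1e-4 | normalized intensity | variance-collapse guard |

Two of these deserve comment. The smoothing width is not prescribed by
the method's description; 0.5 voxel was chosen as the lightest filter
that visibly denoises 1 mm isotropic data without blurring away the thin
plexus, and it is applied in voxel units (anisotropic spacing does not
reshape the kernel). The radius-1 "sphere" is the only digital ball of
radius one voxel: its offsets are the centre plus the six face
neighbours, so erosion uses 6-connectivity semantics; a user who reads
"one voxel" as the 26-neighbourhood can select `shape = "box"`.

The initialization values are starting points, not constraints: EM
adapts all parameters, and the CP role is decided by the *fitted* means,
because component identities can drift or swap during fitting. If two
fitted means tie to machine precision the heavier component is chosen;
posterior ties are broken toward the brighter component. Both rules are
deterministic, and the pipeline contains no random element at all: EM
runs once from the fixed initialization, so reruns are bit-identical.

## Numerical choices

* **E-step in the log domain.** Responsibilities are computed via
  log-densities and a row-wise log-sum-exp, so extreme samples cannot
  underflow to 0/0 rows.
* **Variance floor.** Component standard deviations are clamped at
  1e-4 (normalized units). A component attracted to a point mass (for
  example duplicated samples) is floored rather than allowed to send the
  likelihood to infinity; the fit records that clamping occurred.
* **Convergence.** EM stops when the relative log-likelihood change
  falls below 1e-6 or after 500 iterations; a non-converged side is
  still assigned from the last iterate with `converged = FALSE` recorded,
  preferring graceful degradation with provenance over failure.
* **Degenerate regions.** An empty prior region or an all-zero intensity
  region raises a "degenerate prior region" error per side; if one
  hemisphere is degenerate the other is still segmented (with a
  warning), and only both failing aborts the run.
* **Grid agreement.** Shapes must match exactly; spacings and affine
  entries within 1e-4 mm, which tolerates header float noise but rejects
  genuine misalignment. Nothing is ever resampled.
* **HD95.** Boundary voxels are foreground voxels with a background face
  neighbour (out-of-grid counts as background). Nearest-neighbour
  distances between boundary voxel centres are measured in physical mm in
  both directions; each direction's 95th percentile is taken with linear
  interpolation over the sorted distances (R's default quantile type 7),
  and the larger of the two is reported. The symmetric voxel-centre
  construction was chosen because the metric's usual definition leaves
  both choices open; the directed variants and the exact Hausdorff
  distance (`probs = 1`) are available through the same function.
* **Dice conventions.** Two empty masks score 1 (perfect agreement); one
  empty mask scores 0. The volume difference is reported signed
  (negative = under-segmentation) and as a magnitude, since published
  tables usually print the magnitude.

## The phantom generator

Real validation data for this method are manual CP segmentations, which
cannot ship with a package. The `phantom_*` functions generate seeded
synthetic volumes with the statistical structure the method assumes, so
that every stage — and the whole pipeline — can be tested against an
exact, planted ground truth.

Per hemisphere the phantom plants, on a 64×64×64, 1 mm grid:

* an ellipsoidal ventricle **lumen** (semi-axes 8×13×10 voxels) of dark
  fluid (mean 10, sd 3 scanner units);
* a **wall ramp**: across a 2.4-voxel band straddling the lumen surface
  the intensity rises linearly from fluid to bright periventricular
  tissue (mean 520), emulating the partial-volume continuum of a real
  ventricle wall rather than a discrete tissue shell — with a discrete
  step the pipeline's own smoothing manufactures a spurious intermediate
  mode that no three-component description fits well, something real
  FLAIR walls do not show;
* five **plexus blobs** (radius 2–3 voxels, mean 360, thin
  partial-volume edge of 0.3 voxel) tangent to the wall from inside,
  where the choroid plexus anatomically sits. Ground truth is the set of
  voxels with blob coverage ≥ 0.5, clipped to the lumen.

The emitted parcellation is imperfect by design: the ventricle label
traces the anatomical lumen (optionally over-covering it via
`prior_dilation_voxels`), and the plexus label is a coarse dilated
superset of the truth clipped to the lumen. Because the true plexus
touches the labelled region's boundary, the pipeline's one-voxel erosion
removes a small wall-contact patch of true plexus. This reproduces, by
the same mechanism, the slight systematic volume underestimation the
method exhibits on real data, and it is why the mean signed volume error
across repeated phantoms is expected to be negative.

With these defaults the region-normalized class means land near 0.2
(fluid), around 1 (wall partial volume) and several times the region
mean (plexus), so the published initialization is an appropriate
starting point for phantoms exactly as it is for real data. Scanner
noise is additive Gaussian by default because that is the model's own
assumption; a Rician option exists for robustness experiments. Presets
fix the studied regimes: `default` (noise sd 8), `noisy` (triple noise,
sd 24), `small_cp` (four blobs of radius 1.8–2.4, the hardest,
low-volume regime), and `one_sided` (right hemisphere absent, exercising
graceful one-sided operation).

What the phantom deliberately does **not** emulate: anatomically
realistic ventricle shape, bias fields (inputs are assumed corrected),
Rician noise by default, FreeSurfer's actual failure modes beyond simple
label dilation, and any pathology. Passing phantom tests therefore shows
that the implementation is faithful to the method and that the method
works where its assumptions hold — it does not certify accuracy on any
particular clinical dataset.

## Validation problem sizes

The shipped tests validate erosion against a brute-force morphological
oracle on random 10³ masks, the three metrics against brute-force
all-pairs computations on 200 random mask pairs up to 12³, masked
smoothing against direct convolution on 11³ grids, EM monotonicity on 50
randomized datasets, parameter recovery on 30 000 samples drawn at the
published initialization (means recovered within ±0.1, weights within
±0.03), agreement with an independent reference EM (mclust) to 1e-6 in
final log-likelihood, and the full pipeline on 64³ phantoms — sizes at
which every oracle is exact or near-exact while the whole suite runs in
about a minute on one core.

## Known limitations

* The mixture is intensity-only; confluent periventricular
  hyperintensities inside the prior region can be claimed by the bright
  component.
* Erosion-induced under-segmentation is accepted, not corrected; no
  boundary re-growing step exists.
* The prior is trusted: a failed LV parcellation restricts (but never
  expands) the search region, so gross parcellation failures propagate.
  The per-side region voxel counts are reported for screening.
* Output labels are hard; no soft/fuzzy membership is emitted.
* NIfTI-1 only; no DICOM/MGZ, registration, or resampling.
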