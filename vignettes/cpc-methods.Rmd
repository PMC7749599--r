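---
title: "CPC methods: model, parameters, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CPC methods: model, parameters, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and its assumptions

At every voxel a segmentation assigns a probability simplex
$p = (g, w, c, b)^\top$, $\sum_i p_i = 1$, over gray matter, white matter,
cerebrospinal fluid and background. `cpcmorph` models the follow-up scan as
a locally linear, non-negative transfer of baseline probability mass:

$$p^{(t')} = F\,p^{(t)}, \qquad F_{ij} \ge 0,$$

with $F_{ij}$ the contribution of source tissue $i$ at baseline to target
tissue $j$ at follow-up. The assumptions this encodes:

1. **Local stationarity.** One matrix describes a whole 3×3×3 neighborhood.
   The fit stacks the 27 neighborhood voxels into 27 equations per target
   tissue — 108 equations for 16 unknowns — and assigns the solution to the
   center voxel with a sliding window, giving per-voxel element maps.
   (Four voxels would be the identifiability minimum; the neighborhood
   over-determines the system and averages noise.)
2. **Non-negativity.** Probability mass is transferred, not created with
   sign; each of the four per-target systems is solved by non-negative
   least squares (Lawson–Hanson active set, compiled). The four per-target
   problems are the diagonal blocks of the joint 108×16 problem, so solving
   them independently is exact, not an approximation.
3. **Co-registration.** Both map sets live on one grid. Registration,
   template construction and segmentation are upstream of this package and
   out of its scope; the `F_cg` > 0 values seen at real sulcal boundaries
   (CSF "becoming" GM) are a known consequence of comparing voxels at fixed
   coordinates, not a biological claim.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `prob_threshold` | 0.2 | probability | components below it are zeroed at both time points and survivors renormalized to sum 1; suppresses ratio blow-up from near-zero probabilities |
| `cpc_cap` | 5.0 | ratio | `1 / prob_threshold`: the largest ratio two surviving probabilities can form; enforced by post-fit clipping because NNLS on noisy data can exceed the bound the threshold motivates |
| `neighborhood_radius` | 1 | voxels | 3×3×3 neighborhood, 108 equations |
| `min_valid_voxels` | 14 | voxels | a majority of 27; neighborhoods thinner than this (borders, closure-invalid voxels) are not fit |
| `n_folds` | 15 | — | cross-validation folds, chosen to keep training sets large while test folds stay non-trivial |

Thresholding happens **after** background closure (`b = 1 − g − w − c`,
clipped to [0, 1]; voxels with `g + w + c > 1 + 10⁻³` flagged invalid), so
the simplex is defined before it is pruned. Both time points are
thresholded and renormalized; the follow-up side's treatment is a package
decision — the rule as published names the baseline explicitly and implies
the rest.

## The synthetic phantom: a stated world

Real longitudinal cohorts for this method are access-restricted, so
validation runs on a parametric phantom that emulates exactly the object
the model consumes: co-registered probability-map pairs.

- **Geometry.** Nested spheres (default) or mirrored slabs: CSF core, GM
  shell, WM surround, background; radii in voxels.
- **Partial volume.** A shared Gaussian blur (`blur_sigma`, default 1 voxel)
  applied to the hard labels before anything else; edge-renormalized so
  channel sums are preserved; values below 10⁻¹² snapped to exact zero so
  "tissue absent" stays crisp.
- **Atrophy.** A fraction `atrophy_rate` of GM probability is moved to CSF
  at voxels within `boundary_width` voxels of the CSF core — probability
  transfer, not re-meshing, because that is the model's object and it makes
  the ground-truth transfer matrix exact: $g' = (1-\phi)g$,
  $c' = c + \phi g$ inside the band. `boundary_width` is a package addition
  (default 1.5 voxels in the pipeline configuration so that an unaffected
  outer GM region exists; `Inf` affects the whole GM compartment and is
  used by recovery tests that need entire neighborhoods inside the band).
- **Noise.** Independent additive Gaussian noise per channel and time
  point, clipped to [0, 1] and renormalized onto the simplex — the simplest
  model that preserves the type invariants. Cohort default `noise_sd`
  = 0.01.
- **Cohorts.** Groups differ only in atrophy rate (defaults: controls 0,
  disease 0.6, 20 subjects per group); all per-subject seeds derive
  deterministically from one cohort seed. No quantitative atrophy magnitude
  is published for the reference cohort, so the rates are a validation
  knob, not an effect-size claim.

What the phantom does **not** emulate: T1 intensities, bias fields, scanner
distortion, mis-registration, segmentation error correlated across tissues,
white-matter hyperintensities, or anatomy. A green test therefore
establishes that the estimator recovers known transfer structure and that
the pipeline's statistics behave correctly — not that the method attains
any particular accuracy on clinical data.

## Numerical choices

- **Identifiability.** A source tissue absent from a whole neighborhood
  (zero design column) gets coefficient 0 and `identifiable = FALSE` rather
  than `NA`, keeping VOI averages defined while preserving the flag for
  masking. Note that a nonzero column guarantees only that the tissue
  participates; *uniqueness* of the exact solution additionally needs the
  nonzero columns to be linearly independent. The exact-recovery tests
  restrict their 10⁻⁶ claims to such full-rank neighborhoods, and — for
  recovery of non-identity transfers — to neighborhoods where thresholding
  is inactive, because the 0.2 threshold is a genuine nonlinearity: a pure
  GM row mapped by $\phi = 0.1$ yields a CSF component of 0.1 that is
  re-zeroed, and no linear matrix can reproduce that.
- **Degenerate inputs.** Border voxels (incomplete neighborhoods) and
  closure-invalid voxels are excluded by the validity mask; underdetermined
  systems (< 4 rows) error; all-zero probability vectors error.
- **Ties.** ROC ranking breaks AUC ties lexicographically by (region,
  element); grid search breaks accuracy ties by grid order; both make
  reruns bit-identical.
- **Orientation.** AUCs are reported as discrimination magnitudes: if a
  feature's AUC against the clinically positive class falls below 0.5 it is
  reported as 1 − AUC with `orientation = −1`, since an element may rise or
  fall with atrophy.
- **Direct ratios.** The comparator `p(t')/p(t)` excludes voxels whose
  baseline probability is below `prob_threshold` (mean of ratios; ratio of
  means available via `mode=`). The published formula is silent on
  denominators near zero; mirroring the CPC threshold bounds the ratio and
  keeps the comparison fair.
- **Cross-validation.** Stratified folds; median imputation,
  standardization and PCA are all fitted on training folds only; the
  default protocol selects hyperparameters by nested inner 5-fold CV
  (non-nested single-grid-point mode via `nested = FALSE` for strict
  mimicry of flat grid search or for permutation nulls). Default grids are
  standard decades: C ∈ 10^(−2..2), γ ∈ 10^(−4..0), 100–500 trees, depth
  2–3–5, PCA components {2, 5, 10, 20, all}. Reported ACC/SEN/SPE are
  means over folds, sensitivity on the positive class.
- **Permutation null.** 200 label permutations with fixed hyperparameters
  (C = 1, 5 PCA components, no inner search) — a deliberate scaling choice
  so the null finishes in seconds; the quantity checked (mean accuracy near
  0.5) does not depend on tuning.
- **Learners.** No SVM/forest/boosting package is assumed: the linear and
  RBF SVM solve the exact dual QP (`quadprog`, small ridge grown only if
  the kernel is numerically indefinite), the forest bags exhaustive-search
  CART trees with per-node feature subsampling, and the boosting classifier
  is logistic gradient boosting with per-leaf Newton steps. These are
  adequate at VOI-table scale (tens of subjects); they are not tuned for
  thousands of samples.

## Known limitations

- Exact-recovery guarantees stop where thresholding is active; near tissue
  interfaces with small partial-volume components the fitted elements are
  biased by the threshold, by design — that is the published estimator.
- The NIfTI-1 codec is deliberately minimal: single-file `.nii`/`.nii.gz`,
  scalar datatypes, identity affine on write, orientation metadata ignored
  (inputs are assumed co-registered). It round-trips against nibabel in the
  test suite.
- The 236-region commercial atlas used for clinical VOI analysis is not
  bundled; any integer label volume is accepted, and tests use phantom
  labels with 4 regions.
- `cpc_volume` sidecars serialize configuration but not the
  identifiability/residual channels; disk round-trips lose those two
  diagnostic arrays (and float32 precision).
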