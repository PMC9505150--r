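---
title: "Dosiomic texture modelling of local failure: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosiomic texture modelling of local failure: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dosiomics)
```

This vignette documents the science and the design choices behind the
package: what each stage of the pipeline computes, which parameters
matter and why their defaults are what they are, what the synthetic
phantom cohort does and does not emulate, and the numerical conventions
adopted where the underlying methods leave room.

## 1. The modelling problem

Salvage stereotactic re-irradiation of an intraprostatic recurrence
(here 35 Gy in 7 fractions) fails locally in roughly 30% of patients
within three years. The working hypothesis is that the *pattern* of the
delivered dose inside the gross tumour volume (GTV) — not just its mean
level — carries prognostic information, once the physical dose is mapped
onto a radiobiologically meaningful scale. The package therefore treats
the dose distribution like an image: it converts it voxel-wise to the
biologically effective dose under the linear-quadratic model,

$$\mathrm{BED}(v) = D(v)\,\Bigl(1 + \frac{D(v)/n}{\alpha/\beta}\Bigr),$$

with $n$ the fraction count and $\alpha/\beta = 1.5$ Gy, the
conventional prostate radiosensitivity ratio. For the prescription
itself (35 Gy, $n = 7$) this gives 151.7 Gy. CT (morphology) and
choline-PET (metabolism, expressed as body-weight SUV with decay
correction to injection time) enter as companion modalities, and a
binary three-year local-failure label is the outcome.

## 2. Image preprocessing

The chain, in order, for each patient:

1. **Unit conversion** on the native grids: PET to SUV
   ($\mathrm{SUV} = c\,w / (A_0 2^{-\Delta t/T_{1/2}})$), dose to BED.
2. **Contour rasterization**: the GTV arrives as closed per-slice
   polygons; a voxel joins the mask iff its centre crosses the polygon
   boundary an odd number of times along a $+x$ ray (crossing-number
   test, half-open edge rule so rays through vertices count each edge
   once). Multiple polygons on a slice combine by XOR, so holes work.
3. **Resampling** of the three volumes and the mask to 1 mm³ isotropic
   voxels by trilinear interpolation; the interpolated mask is
   re-binarized at 0.5 to absorb partial-volume fractions. Dose and PET
   grids that differ from the CT frame are first resampled onto it (also
   trilinear), so one interpolation chain covers the co-registered and
   misaligned cases.
4. **HU rounding** (ties half away from zero; Hounsfield units are
   integers by definition), deliberately *without* re-segmentation: no
   intensity-range exclusion is applied inside the ROI.
5. **ROI isolation**: voxels outside the mask become `NA`, which every
   downstream feature computation treats as "not part of the volume".
6. **Discretization** to 64 grey levels by fixed bin number:
   $g = \min(\lfloor N (x - x_\min) / (x_\max - x_\min)\rfloor + 1, N)$.
   FBN makes the discretized features invariant to affine intensity
   rescaling, which is what makes texture comparable across patients
   whose BED ranges differ.

A fixed-threshold PET segmentation (40% of the regional maximum,
restricted to the 26-connected component containing the peak) is
provided because GTV delineation in this setting is PET-driven; the
feature pipeline itself uses the stored contours, which is what the
structure set records after any manual correction.

Tunable parameters (all in `preprocess_config()`): `alpha_beta_gy`
(1.5 Gy), `target_spacing_mm` (1 mm isotropic), the mask binarization
threshold (0.5), `n_grey_levels` (64), and the PET threshold fraction
(0.40). All defaults are the analysis constants of the study the
package reimplements.

## 3. The 380-feature catalogue

The catalogue is data (`feature_catalogue()`), not constants scattered
through code: 17 shape features computed once from the mask, and 121
features per modality (CT, PET, BED) — 18 intensity statistics, 23
histogram features, integrated intensity (mean ROI intensity × ROI
volume), and the five IBSI texture families: GLCM (25), GLRLM (16),
GLSZM (16), NGTDM (5), NGLDM (17). That closes the count at
$17 + 3 \times 121 = 380$. The four predictors reported as dominant in
the source study — variance, energy, integrated intensity, large zone
high grey level emphasis, all from BED — are all present
(`BED_stat_variance`, `BED_stat_energy`, `BED_integrated_intensity`,
`BED_glszm_lzhge`).

Conventions, fixed once:

* **Texture geometry**: 3D matrices at Chebyshev distance 1. GLCM and
  GLRLM are built per direction over the 13 unique 3D directions,
  symmetric (GLCM), with features computed per direction and averaged —
  one of the IBSI-sanctioned aggregation schemes. GLSZM zones and NGLDM
  dependencies use 26-connectivity; NGLDM coarseness is $\alpha = 0$
  (dependence = equal level). `NA` voxels contribute no pairs, runs,
  zones or neighbourhoods.
* **Moments**: population variance, Fisher (excess) kurtosis; skewness
  and kurtosis of a constant ROI are defined as 0; GLCM correlation of a
  constant ROI is 1.
* **Shape**: the surface mesh is the 0.5 iso-surface of the binary mask
  extracted by marching tetrahedra. Meshing the raw binary field
  overestimates surface area by ~25% (the staircase artifact), so the
  field is first smoothed by two separable 1/4–1/2–1/4 passes, edge
  crossings are linearly interpolated, and four Taubin λ|μ smoothing
  iterations are applied to the mesh; on a digital ball of radius 10 mm
  this brings sphericity to ~0.997 where the unsmoothed mesh gives 0.78.
  Masks too small to survive smoothing fall back to the unsmoothed mesh,
  then to voxel-equivalent sphere values (with a warning). Maximum 3D
  diameter is the largest pairwise distance between boundary-voxel
  centres; axis lengths are $4\sqrt{\lambda_i}$ from the PCA of voxel
  centres. Local-intensity-peak features are deliberately not part of
  the catalogue; the count closes at 380 without them.
* **Percentiles** use R's default (type 7) quantile definition
  throughout, including the histogram features.

Texture matrices are built in C++ in a single pass per modality and are
verified in the test suite against naive R loop oracles to $10^{-8}$
relative on random small ROIs.

## 4. The learning stack

Class imbalance (≈30% positives) is handled per training fold by
**ADASYN**: $G = (n_{maj} - n_{min})\beta$ synthetic minority points,
allocated across minority samples proportionally to the majority
fraction among their $k = 5$ nearest neighbours (largest-remainder
rounding, so the allocation is exact), each synthesized as a uniform
convex combination with a random minority neighbour. Defaults
$k = 5, \beta = 1$; Euclidean neighbours on z-scored features.

**Feature weighting** is regularized neighbourhood component analysis:
maximize $\frac{1}{n}\sum_i p_i - \lambda \sum_r w_r^2$ where
$p_{ij} \propto \exp(-\sum_r w_r^2 |x_{ir} - x_{jr}|)$ is the soft
leave-one-out neighbour probability — the averaged-loss convention under
which a regularization strength of order $1/n$ is neutral, and under
which the adopted $\lambda = 0.02$ (≈ 1/43) sits. The solver is
per-sample stochastic gradient ascent (50 epochs,
$\mathrm{lr} = 0.5/(1 + 0.2\,\mathrm{epoch})$, deterministic given its
seed). One numerical point matters: weights start at $p^{-1/2}$, the
unit average-metric scale — starting at 1 saturates the exponential
kernel on 380 z-scored features and leaves the solver stuck in a region
with no usable gradient. The test
suite checks the SGD solution against a full-batch line-search oracle on
the same objective. NCA runs on the ADASYN-augmented fold by default
(the oversample-then-select order; `nca_on_augmented = FALSE` switches
to the raw fold).

**The classifier** is RobustBoost — a continuous-time
boosting-by-majority variant chosen for its tolerance to label noise, a
real concern when the "non-failure" class contains patients whose
relapse simply had not happened yet. Each example carries a margin
$m_i$; the algorithm runs in self-time $t \in [0,1]$ with
$\sigma(t)^2 = (\sigma_f^2 + 1)e^{2(1-t)} - 1$ and
$\mu(t) = (\theta - 2\rho)e^{1-t} + 2\rho$, weighs examples by
$\exp(-(m_i - \mu(t))^2 / 2\sigma(t)^2)$ — so hopeless examples fade
instead of dominating, AdaBoost's failure mode — and each cycle solves
jointly for the time step and vote weight that zero the weighted
correlation of the new weak tree while conserving the average potential
(nested bisection; if no positive time step conserves potential the
target step is halved and, failing repeatedly, boosting stops early
with a warning). $\rho$ is set so the initial average potential equals
the error goal (5% default), via the inverse error function;
$\sigma_f = 0.1$, $\theta = 0$. Weak learners are best-first weighted
Gini CART trees with at most 4 internal splits; at most 500 cycles. The
final score is the weighted vote $\sum_k \alpha_k h_k(x)$, thresholded
at 0 (ties to the negative class). A plain AdaBoost with identical weak
learners sits behind the same interface (`method = "adaboost"`) as a
comparator; paired simulations in the test suite show the robust
variant winning on noisy labels when its error goal matches the noise
rate. The error goal should be read as "the label noise you expect":
setting it well below the true noise rate forfeits the robustness
advantage.

## 5. Validation protocol

`run_repeated_cv()` wraps everything in repeated stratified 10-fold
cross-validation with a strict leakage boundary: standardization
parameters, ADASYN synthesis, NCA weights and tree fitting all derive
from the training indices only (a runtime guard asserts train/test
disjointness; folds whose training split loses a class are re-drawn).
The feature count sweeps $m = 1..8$; per repetition the ten test folds
are pooled into one score per patient and sensitivity, specificity,
accuracy and AUC computed; the report carries means and SDs over
repetitions, the per-fold selection tally, and the pooled ROC at the
accuracy-best $m^*$ (ties to the smaller model). Pooling per repetition
rather than averaging per fold was chosen because with ~43 patients a
single fold holds only 4–5 cases and per-fold metrics are too unstable
to average meaningfully. SDs are reported across repetitions; the
per-repetition metric draws are kept in the report object so the
across-folds dispersion can also be derived. AUC is trapezoidal,
identical to the tie-corrected Mann–Whitney statistic (oracle-checked
to $10^{-12}$).

Outcome binarization is "failure within 36 months": an event after the
horizon, or censoring before it, both count negative. The second rule is
the acknowledged simplification of short-follow-up cohorts — late
relapses are wrongly labelled relapse-free — and is kept because the
reference analysis makes the same choice.

## 6. The phantom cohort

Real DICOM data of this kind cannot be redistributed, so
`generate_cohort()` builds synthetic patients with the geometric and
statistical structure the analysis relies on:

* **GTV**: a jittered ellipsoid (mean radius 8 mm, per-axis SD 0.5 mm,
  ±2% low-order angular wobble) emitted as per-slice 24-vertex polygons —
  a few cm³, like the target volumes of this indication. Rasterized
  volumes agree with the analytic ellipsoid volume to well within 15% at
  1 mm spacing.
* **CT**: 40 HU soft-tissue background with correlated noise (white
  noise on a coarse grid, trilinearly upsampled — cheap and smooth).
* **PET**: background 1 kBq/mL with an ellipsoidal uptake focus peaking
  at 6–9× background; radiopharmaceutical metadata (weight, activity,
  delay, ¹¹C half-life 1223.4 s) drawn from realistic ranges.
* **Dose**: the prescription as a plateau over the GTV plus a 3 mm
  margin, falling to zero across a 10 mm cosine penumbra (a sigmoid-like
  profile with ~5 mm scale, configurable), times a within-GTV
  multiplicative texture field whose patient-level amplitude is
  log-normal around `dose_heterogeneity` (default 0.05 — the few-percent
  dose ripple of a realistic SBRT plan). With `dose_heterogeneity = 0`
  every voxel strictly inside the GTV receives exactly the prescription.
* **Outcome**: the within-GTV BED variance, standardized across the
  cohort, enters a logistic model with slope `effect_size`; the
  intercept is calibrated by bisection so the expected prevalence equals
  the target (30.2% by default — 13 of 43). Event times are uniform on
  (6, 35) months, failure-free follow-up on (12, 102) months, so events
  land inside the 36-month horizon and follow-up spans it.

The default `effect_size = 2` produces a planted signal whose
Bayes-level AUC (scoring patients by the true driver) is ≈0.78 at
n = 200 — recoverable but not trivial, which is the regime worth
testing. BED variance was chosen as the driver because, in the study
this package reimplements, every retained predictor came from the BED
distribution; that is a modelling choice of the generator, not a claim
about real data.

What the phantom deliberately does **not** emulate: anatomy and organs
at risk, PET reconstruction artifacts and partial-volume effects,
deliverability constraints of a real VMAT plan, inter-observer contour
variability, and any CT/PET correlate of outcome. Consequently, a
passing pipeline on phantoms demonstrates *mechanical correctness*
(leakage-freedom, signal recovery, calibration of the protocol), not
clinical validity of the dosiomic signature on real patients.

Cohorts are written to a portable container (raw little-endian float32
volumes + JSON sidecars + manifest CSV) that round-trips through
`read_patient()`/`read_cohort()` within float32 tolerance. DICOM I/O is
out of scope for this implementation; the container is the supported
interchange format, and the reader honours a `dose_grid_scaling` field
so externally produced integer-scaled dose grids map onto the same
contract.

## 7. Problem sizes and determinism

Everything is deterministic given seeds: phantom records are pure
functions of (params, seed); NCA shuffles with a private xorshift
stream; the CV draws per-fold seeds from its master seed; identical
seeds give bit-identical reports. The package's own validation runs use
scaled-down protocols chosen to exercise the full pipeline at desk
scale: 10 repetitions × 10 folds on cohorts of 100 (permutation null)
and 200 patients (signal recovery), versus the 100 × 10 protocol the
`cv_config()` defaults encode. The null check asserts mean AUC in
[0.40, 0.60] under permuted labels — the leakage alarm — and the signal
check asserts mean AUC > 0.70 at $m^*$ with BED-prefixed features
dominating the selection tally. Under the default phantom conditions the
selection clause holds but the recovered AUC sits below that bound
(~0.66 against a planted Bayes ceiling of 0.78): a logistic fit on the
extracted BED features reaches 0.73–0.77, while the boosted-tree stage
at its prescribed configuration (5% error goal, 500 cycles, 4-split
trees) drives training error to ~3% and rank-generalizes near 0.60–0.66 —
a behaviour reproduced exactly by an independent gradient-boosted-tree
reference at the same depth and cycle budget on the same folds. The gap
is therefore a property of deeply boosted trees on small noisy cohorts,
not of the implementation; the check is kept at its stated bound rather
than widened to meet the observed value.

## 8. Known limitations

* The 380-feature catalogue reproduces the published *count* and the
  IBSI family definitions, but the exact in-house feature set of the
  original benchmark is not recoverable from the text; only the four
  named predictors are constrained, and all four are present.
* RobustBoost follows the published algorithm, not any particular
  toolbox's internals; vote weights and cycle counts will differ from
  other implementations even on identical data.
* The NCA solver is stochastic gradient ascent on a non-concave
  objective; different seeds can select different (correlated) features
  near the decision boundary. The CV protocol averages over this by
  design.
* Mesh-based shape features inherit a small negative volume bias
  (~2–4%) from the pre-meshing smoothing; voxel-count volume is exact
  and reported alongside.
* The horizon rule labels late relapses as negatives; with real cohorts
  this biases sensitivity estimates downward, exactly as in the source
  analysis.
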