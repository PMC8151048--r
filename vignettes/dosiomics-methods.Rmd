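---
title: "Dose-map radiomics and NTCP modelling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-map radiomics and NTCP modelling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical and numerical choices behind
`dosiomics`: the model each stage implements, the assumptions it makes,
the parameters a user might want to change, and the decisions taken where
a published workflow of this kind leaves the details open.

## 1. The modelling problem

The package predicts binary radiotherapy toxicity endpoints (rectal,
genitourinary and vaginal, each acute and late, all grade ≥ 2) from the 3D
dose distribution delivered to the corresponding organ at risk — rectum,
bladder and vagina respectively — together with clinical covariates. Three
predictor families are compared within one common logistic NTCP framework:

* **clinical** — FIGO stage, age, baseline symptoms, prior abdominal
  surgery, rectal comorbidities, nodal status;
* **DVH** — dose-volume histogram summaries of the EBRT plan and of the
  EQD2-summed EBRT + brachytherapy dose;
* **RA** (radiomics) — 91 texture and intensity features of the EBRT dose
  map inside the organ mask.

Radiomics is computed on the *physical EBRT dose only*: brachytherapy dose
maps cannot be spatially co-registered with the EBRT plan in routine data,
so BT enters exclusively through its DVH (section 4).

## 2. The 91-feature panel

### Discretization

Texture features require integer grey levels. Doses are discretized with a
**fixed bin width of 1 Gy**, level `g(v) = floor((D(v) − b₀)/w) + 1`, bins
left-closed right-open. The bin origin `b₀` is anchored at **0 Gy**, not
at the ROI minimum. Two reasons: dose has a meaningful absolute zero
(unlike arbitrary-unit MR intensities), and an absolute anchor keeps grey
level *g* meaning "dose in [g−1, g) Gy" for every patient, so grey-level
weighted features are comparable across a cohort. With prescriptions of
45–50.4 Gy this yields 45–60 levels per organ.

### Composition

The panel is fixed at 91 named features, recorded with their reference
definitions and fallback rules in `feature_registry()` (also shipped as
`inst/extdata/feature_registry.csv`):

| family | count | aggregation |
|---|---|---|
| intensity statistics (raw Gy) | 18 | — |
| intensity histogram (grey levels) | 11 | — |
| GLCM co-occurrence | 25 | merged, 13 directions, distance 1 |
| GLRLM run length | 16 | merged, 13 directions |
| GLSZM size zone | 16 | single matrix, 26-connected zones |
| NGTDM neighbourhood difference | 5 | 26-neighbourhood |

Design decisions here:

* **Merged aggregation.** One co-occurrence (resp. run-length) matrix is
  accumulated over the 13 unique 3D directions at Chebyshev distance 1 and
  then normalized, rather than averaging per-direction features. This is
  the most common single-matrix convention and makes every feature a
  deterministic function of one matrix.
* **No shape/morphology features.** The panel covers intensity, histogram
  and the four classical texture families only; mask shape is a property
  of contouring, not of the dose distribution the model is about.
* **Degenerate ROIs.** A uniform-dose ROI (single grey level) makes several
  features 0/0. Each such feature has a documented fallback (registry
  column `fallback`): skewness/kurtosis → 0, GLCM correlation → 1,
  information correlations → 0, NGTDM coarseness capped at 10⁶. A single
  isolated voxel has no co-occurrence pairs at all; the GLCM is then taken
  as a point mass at the modal level, which reproduces the uniform-ROI
  values, and the result carries a `degenerate` attribute.
* **Run percentage** is normalized by voxels × directions, so it lies in
  (0, 1] under merged aggregation.

The inner loops (matrix accumulation, zone labelling, neighbourhood sums)
are in C++; all feature formulas are plain R. The whole 91-feature
extraction runs in well under a second on a fully masked 64³ grid, which
the test suite asserts. Every texture feature is verified against an
independent brute-force enumeration oracle (direct voxel-pair/zone/
neighbourhood loops in R) on random 5³ volumes to 10⁻¹⁰ relative
tolerance.

## 3. DVH metrics and EQD2

`compute_dvh()` tabulates the cumulative DVH on a dose grid of step
`edge_step` (default **0.1 Gy**; interpolation error is then ≪ 1% of organ
volume for clinically-shaped distributions). Inverse lookups (Dx%, Dxcc)
interpolate linearly between tabulated edges; the DVH-implied mean agrees
with the voxel-wise mean to within one edge step (asserted in tests). A
request for more cc than the organ holds falls back to Dmin with a
warning.

EQD2 uses the linear-quadratic closed form with per-fraction dose
`d = D/n`: the *voxel's own* total dose is divided by the plan's fraction
count, i.e. every voxel is assumed to receive its dose in the same number
of fractions — standard practice when only the total dose map is
available. EBRT fraction count is `round(prescription/1.8)`; BT doses use
the BT fraction count (3–4). α/β routing is strict: acute endpoints only
ever see α/β = 10 Gy conversions, late endpoints only α/β = 3 Gy.

**EBRT + BT summation** assumes the BT hotspot is co-located with the EBRT
hotspot: both cumulative curves are inverted to dose-at-volume-fraction on
a shared grid (default 1000 points), added at equal volume fraction
(hottest with hottest), and re-accumulated. This is the conservative
(worst-case) assumption for serial-type OAR toxicity and avoids any claim
of spatial registration. The operation is commutative and has the
zero-dose DVH as identity within interpolation tolerance.

One notational ambiguity deserves mention: "V40%" style labels can mean
volume at 40 Gy or at 40% of prescription. The package interprets Vx as
**absolute Gy** throughout ("volume receiving ≥ x Gy"), consistent with
the Vx grids 5–55 Gy (EBRT) and 5–140 Gy (EQD2-summed EBRT+BT) in 5 Gy
steps; a relative interpretation can be obtained by passing a custom
`x_grid` to `dvh_to_metrics()`.

## 4. The NTCP workflow

Per endpoint and parameter set, using the training split only:

1. **Univariate screen** — single-predictor logistic fits; retain
   p < `alpha` (default 0.05) by the **likelihood-ratio test**. Wald
   p-values collapse under the quasi-separation that is routine with ~50
   patients and strong dose effects; the LRT does not. No multiplicity
   correction by default — the screen is deliberately liberal so that a
   few candidates survive small cohorts; a Benjamini–Hochberg column is
   available (`adjust = "BH"`) but does not affect retention unless
   requested. Constant columns are skipped and logged; separated features
   are retained and flagged.
2. **Spearman redundancy filter** — among any pair with |ρ| > `rho_max`
   (default 0.80) the larger-p feature is dropped. Implemented as a greedy
   pass in ascending univariate p (ties broken by feature name), which
   makes "keep the smaller p" deterministic even for correlation chains.
3. **Backward elimination** — iteratively drop the largest
   likelihood-ratio p ≥ `p_remove` (default 0.05, matching the screening
   alpha) and refit. The model may reduce to intercept-only: if even the
   last remaining feature is non-significant it is dropped, which is what
   lets all-noise inputs end at the null model. A starting set larger than
   events/5 triggers a warning but fitting proceeds (the workflow itself
   imposes no hard limit).
4. **Separation handling** — if the ML fit separates or fails to converge,
   the model is refit by a Firth-type penalized likelihood (Jeffreys-prior
   score correction, implemented in the package), on column-standardized
   predictors for conditioning, with Wald p-values, and flagged
   `firth_fallback`. Separation detection uses pinned fitted probabilities
   only — coefficient-magnitude heuristics are scale-dependent and
   radiomic features legitimately span orders of magnitude.
5. **Evaluation** — training ROC AUC (Mann–Whitney concordance with 0.5
   for ties) with DeLong 95% CI; Youden-index cutoff chosen on training
   over the midpoints of adjacent unique scores *plus* the two boundary
   rules (all-positive / all-negative, J = 0), ties toward the lower
   threshold; the cutoff is **frozen** and applied to the testing split,
   reporting balanced accuracy, sensitivity and specificity. Nested sets
   (clinical+DVH vs clinical+DVH+RA) are compared with the paired DeLong
   test; degenerate variance (e.g. identical scores) returns p = 1 with a
   flag.

Odds-ratio intervals are reported two ways: a conventional 95% CI and a
**10th–90th percentile interval**, computed as the profile-likelihood 80%
interval on the OR scale (Wald-based under the Firth fallback). The
percentile construction is a documented choice: an 80% two-sided interval
is the interval whose endpoints are the 10th and 90th percentiles of the
sampling distribution in the profile approximation.

## 5. The synthetic cohort generator

The generator exists so the full pipeline — including feature extraction
and model selection — can be exercised and calibrated without patient
data. Its defaults encode the study conditions the package targets:

* **Dose grids**: plateau at a per-patient prescription drawn uniformly in
  45–50.4 Gy, multiplicative smooth jitter of ±2% (Gaussian field,
  correlation length 15 mm), 0–3 Gaussian hotspots per organ centred at
  random in-mask locations with radii 8–20 mm and peaks up to
  1.2 × prescription. The jitter/hotspot combination is the minimum
  structure that makes all 91 features non-degenerate.
* **Masks**: rectum and vagina as disks swept along a smoothed random
  centerline (tubes), bladder as a volume-preserving anisotropic ellipsoid
  (blob); default volumes 60 / 40 / 180 cc; realized volume within ±20% of
  target; always one 26-connected component.
* **BT DVHs**: dose-at-volume-fraction `D(u) = Dmax (1−u)^s` with falloff
  exponent s ∈ [2, 5] and Dmax near (≤ 1.5 ×) the 7 Gy × 3–4 fraction
  prescription — a steep-falloff shape qualitatively matching intracavitary
  HDR brachytherapy.
* **Clinical covariates**: FIGO stage with substage fractions, age
  ~N(54, 11) truncated to [18, 100], binary baseline symptoms / surgery /
  comorbidities / nodal status at plausible prevalences.
* **Outcomes**: the planted endpoint is Bernoulli(expit(intercept +
  Σ βₖ zₖ)) on **split-wise z-scored** features computed by the real
  extraction modules, so planted effects are scale-free; the remaining
  endpoints are intercept-only at fixed prevalences (GU 39%/14%, rectal
  26%/10%, vaginal 24%/24% for acute/late), the cumulative grade ≥ 2 rates
  of the training cohort in the two-centre series this design mirrors.
* **Two centres**: the cohort defaults to a 52/50 training/testing split;
  the testing split is generated from a shifted seed stream with a +5%
  mean shift on clinical covariates. The shift magnitude is a free choice
  (no inter-centre distribution data exist to infer it from); it is meant
  to break exact exchangeability between splits, not to claim realism.

Every generator is a pure function of (arguments, seed).

**What the generator does not emulate** — and therefore what passing tests
do *not* show about real data: anatomical organ shapes and inter-organ
spatial relationships, beam-geometry dose falloff and field edges,
Monte-Carlo dose noise, contouring variability, correlated clinical
covariates, and informative censoring of toxicity grading. Tests on this
cohort validate the *software and the statistical workflow*, not clinical
predictive performance.

### Simulation problem sizes

Calibration and recovery properties are checked at sizes chosen to make
the Monte-Carlo error small relative to the tested bands: type-I error of
the screen and of the DeLong test at n = 1000/500 over 200 replicates
(acceptance band 3–8% at nominal 5%); planted-coefficient recovery at
n = 2000 over 50 replicates. For recovery, the dose-grid design is
generated once per condition on a compact single-organ geometry (16³
voxels at 3 mm, 25 cc rectum) and outcomes are redrawn per replicate
(`redraw_outcomes()`): confidence-interval coverage is defined
conditionally on the design, so redrawing outcomes is the exact simulation
of the claim, at a fraction of the cost of regenerating 100 000 dose
grids. The held-out RA-vs-clinical comparison regenerates the full
102-patient cohort per replicate (20 replicates), since it is a statement
about whole-cohort variability.

## 6. Interfaces

Grids and masks are NIfTI (`RNifti`), written as float64 so values
round-trip bit-identically; masks are uint8 and carry their organ label at
the API level (NIfTI has no label field). Misaligned dose/mask pairs are
**rejected, never resampled** — resampling strategy materially changes
texture values and silently interpolating would launder that choice. DVH
curves and cohort tables are plain CSV; model reports are written per
endpoint as a machine-readable CSV plus a human-readable text table
(feature | P | OR | 10th–90th interval | AUC | 95% CI) with a cohort-level
summary of balanced accuracies. The package's exported functions, the
acceptance script and this vignette are the intended entry points; all
tabular results are tibbles, fitted models support `tidy()`/`glance()`,
and DVH curves and models have `autoplot()` methods.

## 7. Known limitations

* The exact composition of a "91-feature IBSI panel" is not standardized;
  other implementations may include morphology or exclude some histogram
  features. The registry makes this package's composition explicit and
  versioned.
* Dx%/Dxcc inverse lookups inherit up to one `edge_step` of interpolation
  bias at DVH discontinuities (exact step distributions).
* The Firth fallback reports Wald inference, which is approximate near
  separation; flagged models should be read with that in mind.
* The hotspot-colocation summation is an upper-bound assumption; true
  cumulative dose requires deformable registration, which is out of scope.
* Small-cohort logistic estimates are biased away from zero (visible as
  inflated per-split coefficients at n ≈ 50); parameter-recovery claims
  are therefore made at n = 2000.
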