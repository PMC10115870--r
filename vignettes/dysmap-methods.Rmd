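---
title: "Methods: focal and dysconnectome mapping of transient disruption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: focal and dysconnectome mapping of transient disruption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Direct cortical electrical stimulation (DCS) transiently disrupts function
at a point locus and records whether a behaviour (a motor response, a
sensory percept, a speech disturbance, or nothing) follows. The data are
sparse — a few hundred loci across a few dozen subjects — so no voxel is
sampled often enough for a test of its own. The two classical escapes both
have costs: aggregating within a-priori ROIs presupposes the topology the
inference should reveal, and mislocalises whenever functional boundaries
cross parcel boundaries; ignoring subject structure inflates error rates.

`dysmap` implements the alternative: make the data dense rather than the
parcels coarse. Each stimulation becomes an image — a Gaussian density
around the locus (focal arm) or the connectome projection of the locus
(dysconnectome arm) — and a mass-univariate repeated-measures GLM is fit at
every voxel, with permutation-based peak-level family-wise error control.

## The model

For each behaviour separately (the categories are not mutually exclusive),
with one image per stimulation and per-voxel response `y_v`:

    y_v = X beta_v + e_v,  X = [subject indicators | behaviour flag]

* Subject indicator columns absorb linear subject mean differences; the
  binary behaviour column carries the effect; its planned one-tailed t
  contrast asks where image intensity is *higher* when the behaviour occurs.
* `e_v` is compound symmetric within subject: `Cov = sigma^2 V`, `V` block
  diagonal with unit diagonal and a single pooled correlation `rho`.
  Prewhitening by `W = V^{-1/2}` (closed form per block) makes the fit
  generalised least squares while leaving the residual degrees of freedom
  `df = n - rank(X)` unchanged — the property that motivates whitening over
  Greenhouse–Geisser-style df corrections.
* `rho` is pooled over in-mask voxels from OLS residuals of a *reduced*
  model (global intercept + behaviour only). This is deliberate: residuals
  of the full design have within-block correlation near `-1/(m-1)` whatever
  the true error correlation, because the subject columns absorb the shared
  component; the reduced model keeps `rho` identifiable. This single-
  parameter structure is a documented simplification of SPM's ReML
  covariance-component machinery; it captures within-subject correlation
  with one interpretable number. `rho` is clipped to the SPD-valid range
  minus 1e-3.

### Family-wise error

The reference analysis thresholds at p < 0.05 FWE (peak voxel) under
Gaussian-random-field theory; since no smoothness/resel constants are
published, `dysmap` controls the identical error rate by permutation maxT:
behaviour labels are permuted within each subject's rows (subjects are the
exchangeability blocks; subjects with constant labels contribute nothing),
the maximum in-mask t is recorded per permutation (2000 by default,
including the observed labelling), and the critical t is the (1 - alpha)
empirical quantile with the conservative ceiling-index tie rule. When fewer
distinct within-block arrangements than 1/alpha exist, the implementation
warns and enumerates all of them exactly. Zero-residual-variance voxels get
t = 0 and are excluded from the maxima. Random-field peak correction,
cluster-level and FDR voxel correction are deliberately out of scope.

Internally the per-permutation maximum uses the monotone map
`t = sqrt(df) u / sqrt(1 - u^2)` where `u` is the partial correlation of the
(whitened, nuisance-residualised) behaviour column with the data — one
BLAS cross-product per permutation chunk instead of a full t map.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| focal kernel FWHM | 10 mm | spatial uncertainty of a locus; sensitivity checked at 8/12 mm |
| kernel truncation | 90% mass | radial cutoff at `sigma * sqrt(qchisq(0.9, 3))` = 2.50 sigma |
| density mask floor | 1e-5 | mean-density threshold excluding poorly sampled voxels (1e-4 in the predictive benchmark) |
| dysconnectome smoothing | 6 mm | smaller, because projected maps are already dense |
| intensity clamping | 0.1 / 99.9 % | per-volume order-statistic quantiles over nonzero intensities |
| alpha | 0.05 | peak-level FWE |
| permutations | 2000 | maxT null samples |
| uncorrected display p | 0.001 | one-tailed Student-t quantile (t = 3.11 at df 439) |
| bootstraps / split | 100 / 80–20 | predictive benchmark, stratified on the behaviour label |

Focal analysis runs at 1.5 mm sampling and the connectome grid at 2 mm in
the reference setting; the synthetic default grid is 40 x 48 x 40 at 3 mm
for speed, and tests use still smaller grids (stated per test).

### Numerical and convention choices

* "Truncated at 90% mass" is read radially: the radius of a 3D Gaussian
  enclosing 90% of its continuous mass is the chi(3) quantile times sigma.
  Per-axis truncation and post-truncation renormalisation are exposed as
  options, since the choice is not uniquely determined by the reference
  description.
* Kernel weights stay unnormalised (peak 1) for density construction — the
  one-hot convolution semantics — and unit-sum for smoothing. Smoothing
  zero-pads; an optional boundary renormalisation divides by local kernel
  coverage. Mass-conservation guarantees apply to interior-supported input.
* A world point belongs to its nearest voxel center, half-way ties toward
  the lower index; stimulation points are snapped to voxel centers before
  convolution (no sub-voxel interpolation — the source images are one-hot).
* Clamping quantiles are order statistics (type 1), making clamping exactly
  idempotent; interpolated quantiles would drift on re-application.
* The projected seed's own voxel takes the maximum of its edge weights
  (option: zero); the reference description is silent and a zero seed would
  make the stimulated point the dimmest spot of its own map.
* Projection uses direct edge weights only — adjacency-row semantics, no
  path composition or diffusion.
* Clamping precedes smoothing by default (order configurable; unstated in
  the reference description).
* The ROI arm's 2x2 table per region is in-region/out-of-region by
  behaviour present/absent over training loci — the only margin-complete
  table available from the described inputs. The exact test uses the
  hypergeometric p (the named test wins over "asymptotic"); the odds ratio
  reported is the sample OR with Haldane +0.5 when a cell is zero.
  Significance requires q < 0.05 *and* OR > 1: a region predicting absence
  should not label positives.
* Bootstrap splits resample stimulation records stratified on the behaviour
  label; a grouped-by-subject mode exists because record-level splitting
  leaks subject information across the split.
* ROC curves are vertically averaged on a fixed 101-point FPR grid; AUC by
  trapezoid equals the Mann–Whitney statistic with ties counted 1/2.
* Two mask floors (1e-5 focal, 1e-4 predictive) co-exist in the reference
  description; both are kept as separate defaults rather than reconciled.

## What the synthetic generator emulates — and what it does not

`generate_cohort` draws per-subject electrode geometries (planar grid
patches, collinear depth trajectories, or uniform scatter), subject random
intercepts on the log-odds scale (within-subject outcome correlation), and
Bernoulli outcomes whose probability rises by a stated log-odds inside
spherical truth regions. Outcomes are deliberately generated from a
*logistic* model although the analysis fits a *linear* GLM on densities:
green tests therefore show robustness under the pipeline's own model
mismatch, as with real data. `generate_connectome` places nodes on the
grid's shell with `exp(-d/decay)` weights plus additive long-range bundles.

Not emulated: after-discharges and seizure physiology, current-spread
biophysics, stimulation-parameter heterogeneity, registration error,
anatomically realistic grey-matter geometry, and tractography biases of
real connectomes. A green synthetic test establishes statistical
correctness of the machinery (calibration, localisation, ordering of the
arms), not clinical fidelity of any particular map.

### Choice of world for the localisation criterion

The hotspot-recovery test demands the top cluster peak within one kernel
sigma of the truth center in >= 90% of seeds. Peak localisation of a
*center* is only well-posed when the truth is peaked: in a wide flat-effect
ball the t peak legitimately wanders across the ball (observed empirically
as ~3–7 mm peak scatter in a radius-10 ball). The test world is therefore a
point-like hotspot — radius 6 mm against sigma 4.25 mm — densely sampled
(25 subjects x 16–20 loci over a 36 mm box, mimicking the dense regional
coverage clinical sampling provides), effect log-odds 4, baseline -2.5.
Under that world 19/20 seeds localise at the voxel nearest the center and
one seed yields no supra-threshold cluster.

### Null calibration

Family-wise error validity is asserted on 200 null cohorts (20 subjects x
12 loci, 16^3 grid at 3 mm, 500 permutations): the empirical rate of any
significant voxel at alpha = 0.05 must not exceed 0.05 + 2 binomial SE. The
dysconnectome null runs a scaled-down version (50 replicates, 100-node
graph) purely for runtime; the focal calibration carries the stated scale.

## Known limitations

* Compound symmetry is a one-parameter stand-in for SPM's full covariance
  components; strongly heteroscedastic subjects violate it.
* With subject fixed effects, whitening barely moves the behaviour contrast
  (the subject columns already absorb the shared component); it is kept for
  fidelity to the stated model and for designs where blocks are unbalanced.
* Permutation maxT needs enough within-block label variation; cohorts where
  most subjects show a behaviour never or always yield few effective
  permutations (the implementation warns and enumerates).
* NIfTI-1 support is self-contained and intentionally minimal: 3D volumes,
  common scalar datatypes, sform/qform geometry. No NIfTI-2, no 4D.
* The dysconnectome consumes a prebuilt connectome; tractography, waytotal
  normalisation and group averaging happen upstream
  (`normalise_connectome()` offers row-sum normalisation for synthetic
  graphs).
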