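# dysmap

Voxel-wise spatial inference from sparsely sampled transient disruption
data — direct cortical electrical stimulation (DCS) in the motivating
setting. Each stimulation is a point locus with binary behavioural outcomes
(positive motor, negative motor, sensory, speech, silent). `dysmap` turns
those sparse points into dense images and runs mass-univariate inference on
them, in two arms:

- **focal arm** — each locus becomes a one-hot image convolved with a 3D
  Gaussian kernel (10 mm FWHM, truncated at 90% of its continuous mass),
  expressing the spatial uncertainty of the disrupted location as a density;
- **dysconnectome arm** — each locus is projected through a voxel-level
  structural connectome, rendering the direct edge weights from the
  stimulated voxel to every grey-matter voxel as a "transient dysconnectome"
  image (clamped at the 0.1/99.9 intensity percentiles, smoothed at 6 mm
  FWHM).

Both arms feed the same statistical model. For a behaviour *b* with density
(or connectivity) image `y_v` per stimulation, at each voxel *v*:

    y_v = X beta_v + e_v,   X = [subject indicators | b],   e ~ N(0, sigma^2 V)

a single-level repeated-measures GLM in which subject columns absorb
per-subject means and `V` is block compound symmetry (one pooled
within-subject correlation `rho`), removed by prewhitening with
`W = V^{-1/2}` — leaving the residual degrees of freedom `n - rank(X)`
unchanged. Inference is the planned one-tailed t contrast on `b`,
thresholded at p < 0.05 FWE (peak level) by within-subject permutation of
the behaviour labels (maxT); an uncorrected p = 0.001 display threshold and
26-connected cluster tables are also produced.

A predictive benchmark quantifies the localisation information of the
resulting maps against a-priori ROI parcellations: 100 bootstraps with an
80–20 split, the voxel-wise map thresholded at its FWE critical t versus
per-ROI Fisher's exact tests under Benjamini–Hochberg FDR, compared by
confusion metrics and vertically averaged ROC/AUC.

A synthetic-data module generates cohorts (clustered per-subject electrode
placement, subject random intercepts, location-dependent Bernoulli
outcomes), ground-truth effect volumes, and distance-decaying connectomes
with designated long-range bundles, so the entire pipeline is testable
without any data download.

## Worked example

```r
library(dysmap)

grid <- make_grid(c(16, 16, 16), 3, origin_mm = rep(-22.5, 3))
cfg <- synthetic_config(
  n_subjects = 20, loci_per_subject = c(10, 16), grid = grid,
  truth_regions = list(list(center = c(0, 0, 0), radius_mm = 10,
                            behaviour = "sensory", effect_logodds = 3)),
  seed = 42)
coh <- generate_cohort(cfg)
pl <- run_focal_pipeline(coh$records, "sensory", grid, n_perm = 500, seed = 7)
pl$threshold
#> <threshold_result> perm_maxT: critical t = 4.539 (alpha 0.05, 500 perms), 36 significant voxel(s)
head(pl$threshold$clusters, 1)
#>   cluster_id extent_voxels   peak_t peak_x_mm peak_y_mm peak_z_mm
#> 1          1            36 6.515512       1.5      -1.5       1.5
```

The cohort hides a 10 mm spherical "sensory" region at the origin; the
permutation-corrected map recovers a single cluster whose peak, at
(1.5, −1.5, 1.5) mm, lies within one kernel sigma (4.25 mm) of the truth.
`critical t` is the 95th percentile of the maximum in-mask t over
within-subject label permutations: any voxel at or above it is significant
with family-wise error 0.05.

Command-line equivalents:

```sh
dysmap simulate --config sim.yaml --out sim/
dysmap focal --stim sim/stim.tsv --behaviour sensory --out out/
dysmap dysconnect --stim stim.tsv --connectome A.mtx --coords nodes.tsv \
       --behaviour sensory --out out/
dysmap evaluate --stim stim.tsv --parcellation parc.nii.gz \
       --behaviour speech --n-boot 100 --test-frac 0.2 --out out/
```

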