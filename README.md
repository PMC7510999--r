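# tempopet — temporal-domain radiomics for dynamic PET

Conventional PET radiomics quantifies a tumour's tracer-uptake
heterogeneity in *space*, from a single static image. `tempopet` adds the
*temporal* dimension: on a 4D dynamic FDG PET series it builds texture
matrices along each voxel's time course and derives feature sets that ask
whether uptake *kinetics* carry information beyond the static picture. The
package is aimed at quantitative-imaging researchers who want to extract,
validate and compare static, parametric and dynamic radiomic features
without committing to a specific scanner pipeline.

## What it computes

**Static / parametric features (90).** Intensity (18), shape (13, from a
triangulated surface mesh), GLCM (22), GLRLM (16), GLSZM (16) and NGTDM (5)
on an isotropically resampled VOI, with grey level co-occurrence and
run length matrices merged over the 13 unique 3D directions (both
orientations per direction, so the spatial GLCM is symmetric). The same
pipeline runs unchanged on Patlak parametric images.

**Temporal (dynamic) features (38).** The novel part. For a series of T
frames, each frame is discretised with its own fixed bin width, and two
matrices are scanned along the temporal direction (0; 0; 0; 1) only:

- *temporal GLCM* — for every VOI voxel and every transition t → t+1, the
  cell (level at t, level at t+1) is incremented. Causality means only the
  forward direction is scanned, so the matrix is **asymmetric**: its
  transpose is what time-reversal would produce. Total count is
  N<sub>vox</sub> × (T − 1). A tumour whose uptake barely changes puts all
  mass on the diagonal; monotone uptake fills the upper triangle.
- *temporal GLRLM* — maximal runs of constant grey level along each voxel's
  time course, with Σ counts × length = N<sub>vox</sub> × T.

22 co-occurrence + 16 run-length features are computed on these with the
same formulas as the spatial families, written for general (asymmetric)
matrices via separate row/column marginals.

**Patlak parametric imaging.** For irreversible tracer uptake
C<sub>t</sub>(t) = K<sub>i</sub>·∫₀ᵗC<sub>p</sub>dτ + v<sub>b</sub>·C<sub>p</sub>(t),
the Patlak plot y = C<sub>t</sub>/C<sub>p</sub> against normalised Patlak
time x = ∫C<sub>p</sub>/C<sub>p</sub> is linear with slope K<sub>i</sub>
(the influx constant, min⁻¹). `compute_parametric_image()` fits the slope
voxelwise over a configurable window (default 15–60 min normalised time)
and converts to a glucose metabolic rate, MR<sub>glc</sub> = K<sub>i</sub>
× plasma glucose / lumped constant.

**Discretisation.** Population-based fixed bin widths via the
Freedman–Diaconis rule, width = 2·IQR·N<sup>−1/3</sup>, with IQR and N the
cohort means of the per-VOI interquartile range and voxel count; levels are
`floor(x / w) + 1`, anchored at 0 so a grey level means the same absolute
intensity in every lesion and frame.

**Redundancy / robustness analysis.** Spearman correlation of parametric
features with their static twins (corresponding pairs, redundant when
ρ > 0.7), of each dynamic feature against *all* static features (redundant
when max |ρ| > 0.7), and of each dynamic feature between the 16 × 150 s and
8 × 300 s framings of the same acquisition (robust when ρ > 0.7).

**Synthetic phantom.** `simulate_phantom()` / `simulate_cohort()` generate
4D series with known voxelwise K<sub>i</sub>/v<sub>b</sub> maps (an
ellipsoidal lesion with a smooth K<sub>i</sub> gradient and a focal hot
spot), an analytic multi-exponential plasma input, the standard 10–50 min
frame schedules, and seed-deterministic Gaussian noise — so Patlak recovery
is exact by construction and every feature path is testable offline.

## Worked example

```r
library(tempopet)

ph <- simulate_phantom(seed = 42, noise_sd = 0.05)
ph$series
#> <dynamic_series> 24x24x18 voxels x 16 frames, Bq/mL
#> <frame_schedule> 16 frames, 600-3000 s p.i.

# VOI-mean Patlak fit: the phantom lesion averages Ki ~ 0.019 min^-1
tac <- tissue_curve(apply(ph$series$frames, 4,
                          function(f) mean(f[ph$mask$values])), ph$schedule)
fit_patlak_slope(patlak_transform(tac, ph$plasma), parametric_settings())
#> <patlak_fit> Ki = 0.0188628 min^-1, intercept = 0.05008 (11 points, rms 0.00175)

# 90 static features; 38 temporal features from the same lesion
fs <- extract_static_feature_set(ph$static, ph$mask, 5)
fd <- extract_dynamic_feature_set(ph$series, ph$mask, rep(30, 16))
nrow(fs); nrow(fd)
#> [1] 90
#> [1] 38

# cohort-level redundancy and frame-duration robustness
res <- run_cohort(simulate_cohort(n = 8, seed = 42, noise_sd = 0.05))
res
#> <cohort_analysis> 8 lesions
#>   features: static 90, parametric 90, dynamic 38 (per framing)
#>   parametric redundant: 87/90 (rho > 0.70)
#>   dynamic redundant:    38/38
#>   frame-duration robust: 37/38
```

The fitted slope is the lesion-average influx constant (the ground-truth
map spans ~0.013–0.055 min⁻¹ across the gradient and focal spot). In the
cohort report, "parametric redundant: 87/90" means 87 parametric features
rank-correlate above 0.7 with their static twins across the 8 lesions;
"robust: 37/38" means nearly all temporal features give concordant rankings
whether computed from 150 s or 300 s frames.

## Vignette

`vignettes/temporal-radiomics.Rmd` documents the model and its
assumptions, the exact feature lists, the discretisation and mesh choices,
degenerate-case conventions, and what the phantom does and does not
emulate.
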