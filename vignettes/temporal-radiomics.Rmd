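---
title: "Temporal-domain radiomics for dynamic PET: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal-domain radiomics for dynamic PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempopet)
```

# The problem

Static PET radiomics summarises the spatial distribution of tracer uptake
in a tumour at one late time point. A dynamic acquisition additionally
records *how* each voxel's uptake evolves, and two derived image types can
carry that information: parametric influx-constant images (one number per
voxel, summarising the kinetics) and the 4D series itself. `tempopet`
implements feature extraction for all three representations plus the
correlation analysis that asks which of the non-static features are
redundant with the static set and which might add information.

# Kinetic model and the Patlak transform

All simulation and parametric imaging in the package assume irreversible
two-compartment tracer uptake in its linearised (Patlak) form:

$$C_t(t) = K_i \int_0^t C_p(\tau)\,d\tau + v_b\, C_p(t),$$

where $C_t$ is the tissue activity concentration, $C_p$ the plasma input,
$K_i$ (min⁻¹) the net influx constant and $v_b$ the effective blood-volume
fraction. Dividing by $C_p$ gives a straight line in "normalised Patlak
time" $x(t) = \int_0^t C_p / C_p(t)$ with slope $K_i$ and intercept $v_b$.
The glucose metabolic rate is $MR_{glc} = K_i \cdot G / LC$ with plasma
glucose $G$ (mmol/L ≡ µmol/mL) and lumped constant $LC$ (default 1), in
µmol · mL⁻¹ · min⁻¹.

**Frame-averaging consistency.** Reconstructed PET frames store the
*time-average* of $C_t$ over the frame window, not an instantaneous
sample. The package therefore evaluates the Patlak abscissa and ordinate
with duration-weighted frame averages of $C_p$ and of its running integral
rather than instantaneous midpoint values. Under this convention the Patlak
identity holds *exactly* for frame-averaged data of the model above, which
is why noiseless phantom recovery of $K_i$ is exact to machine precision —
a deliberate design choice that turns Patlak recovery into a sharp
correctness test rather than a discretisation-limited approximation. The
frame midpoint remains the nominal time attached to each point.

The fit window defaults to 15–60 min normalised Patlak time
(`parametric_settings(t_star = 15, window_end = 60)`); ordinary least
squares is used, voxelwise fits are vectorised through a single
normal-equation solve (the abscissa depends only on the plasma curve), and
frames with non-positive averaged plasma are dropped with a message.

# Preprocessing

**Resampling.** Images and masks are resampled trilinearly to an isotropic
grid (3.38 mm is the package-wide default spacing, the coarsest axis of
the two-scanner setting the phantom emulates). The output grid covers the
input's physical extent and the two grids' world-space centres coincide;
samples outside the input support take the nearest-edge value, so no
artificial zeros are interpolated into tumour-adjacent bins. Masks are
interpolated as a real-valued partial-volume field and binarised at 0.5,
which approximately preserves volume; the threshold is exposed as an
argument. Frames of a series are resampled independently — stacking and
resampling commute.

**Discretisation.** Fixed bin width, level $= \lfloor x/w \rfloor + 1$.
Widths come from the cohort via the Freedman–Diaconis rule
$w = 2\,\overline{IQR}\,\bar N^{-1/3}$ (means of the per-VOI interquartile
range and voxel count). Three choices deserve note:

- *Anchor at 0, not at the VOI minimum.* Absolute anchoring makes a grey
  level mean the same intensity bin in every lesion and every frame, which
  is the entire point of fixed-bin-width discretisation and is what lets
  per-frame levels index one shared temporal matrix.
- *Per-frame widths.* Each dynamic frame gets its own population-based
  width (early frames have lower signal and tighter IQRs); the global
  grey-level count Ng across frames sets the temporal matrix dimension.
- *Full precision.* Widths are used at full floating precision; rounding
  them to two decimals (as one would when reporting) changes levels near
  bin edges, so reported and used widths are kept distinct.
- Negative excursions below the anchor (possible in reconstructed
  backgrounds) are clamped to the anchor with a reported count.

# Feature families

The static/parametric set has exactly 90 features: intensity 18, shape 13,
GLCM 22, GLRLM 16, GLSZM 16, NGTDM 5. Grey-level-dependence features are
deliberately absent (analogues of GLRLM/GLSZM), and image normalisation
and distance weighting are not applied — omitted, not optional. The
enumerations, where a family's membership is genuinely a choice:

- *Intensity (18):* Energy, TotalEnergy, Entropy, Minimum, Percentile10,
  Percentile90, Maximum, Mean, Median, InterquartileRange, Range,
  MeanAbsoluteDeviation, RobustMeanAbsoluteDeviation, RootMeanSquared,
  Skewness, Kurtosis, Variance, Uniformity. Standard deviation is excluded
  as fully redundant with Variance. Entropy and Uniformity use the
  discretised histogram; everything else uses raw intensities. Kurtosis is
  the population moment ratio (not excess).
- *Shape (13):* MeshVolume, SurfaceArea, SurfaceVolumeRatio, Sphericity,
  Maximum3DDiameter, three maximum 2D diameters (axial/coronal/sagittal
  projections of the mesh vertices), Major/Minor/LeastAxisLength (4·√λ of
  the physical voxel-coordinate covariance eigenvalues), Elongation,
  Flatness. The voxel-counting volume is excluded so the family has
  exactly 13 entries, the mesh volume being the better-behaved quantity.
- *GLCM (22):* Autocorrelation, ClusterProminence, ClusterShade,
  ClusterTendency, Contrast, Correlation, DifferenceAverage,
  DifferenceEntropy, DifferenceVariance, Id, Idm, Idmn, Idn, Imc1, Imc2,
  InverseVariance, JointAverage, JointEnergy, JointEntropy,
  MaximumProbability, SumEntropy, SumSquares.

GLCM and GLRLM accumulate over the 13 unique non-opposite unit offsets
(both orientations for the GLCM, making it symmetric) into a single merged
matrix — the construction that makes the merged-matrix features invariant
to 90° rotations. GLSZM zones and NGTDM neighbourhoods use 26-connectivity
with in-mask neighbours only. Matrix dimension is the highest occupied
level; empty interior rows contribute zeros.

**Surface mesh.** Shape features need a closed triangulated surface.
The package builds it by marching tetrahedra on the trilinearly upsampled
partial-volume field of the mask (factor 2), splitting each grid cube into
six tetrahedra sharing its main diagonal and placing vertices at the
linear 0.5-crossings of tetrahedron edges. This decomposition shares face
diagonals between neighbouring cubes, so the mesh is crack-free, and the
enclosed volume follows exactly from the divergence theorem. On a digital
ball of radius 8 voxels the mesh volume is within ~3% of the analytic
value and sphericity evaluates to 0.94; tools built on classic marching
cubes will differ by a few percent in area-derived quantities.

# Temporal features

The dynamic set contains 38 features: 22 co-occurrence and 16 run-length,
computed on two matrices scanned *only* along the temporal direction
(0; 0; 0; 1):

- the **temporal GLCM** pools, over all VOI voxels and all transitions
  t → t+1, the pairs (level at t, level at t+1). Causality makes the
  reverse scan meaningless, so only the forward direction is counted and
  the matrix is asymmetric; time reversal transposes it. Total count is
  $N_{vox}(T-1)$.
- the **temporal GLRLM** tallies maximal constant-level runs along each
  voxel's time course; $\sum_{i,j} j\, c_{ij} = N_{vox} T$.

Design decisions taken here:

- *Asymmetric formulas.* Row and column marginals of the temporal GLCM
  differ, so Correlation, the information measures and the cluster
  features are written with separate marginals. When a matrix happens to
  be symmetric these reduce to the standard definitions, so one
  implementation serves both the spatial and temporal paths.
- *Pooling, not averaging.* All T−1 transitions feed one matrix rather
  than averaging T−1 per-transition matrices. Pooling weights every
  transition equally, needs no convention for empty per-transition
  matrices, and is the natural generalisation of merging spatial
  directions; per-transition averaging would differ only through the
  normalisation of rare levels.
- *Lag fixed at one frame.* Multi-lag temporal offsets are intentionally
  out of scope.
- *No temporal GLSZM/NGTDM.* Zones and neighbourhoods would have to mix
  spatial and temporal adjacency, and the two directions are not
  interchangeable.
- *RunPercentage normalisation.* The denominator is the total voxel
  coverage $\sum_{ij} j\,c_{ij}$ in both the spatial (merged, =
  $13 N_{vox}$) and temporal (= $T N_{vox}$) cases, so a time-constant
  series gives RunPercentage exactly $1/T$.

# Degenerate-case conventions

Constant VOIs and single-level matrices are legal inputs and must give
deterministic numbers, not NaN:

| quantity | degenerate input | value |
|---|---|---|
| GLCM Correlation | zero marginal variance | 1 |
| GLCM Imc1 / Imc2 | zero marginal entropy | 0 |
| GLCM InverseVariance | (always) | diagonal terms omitted |
| NGTDM Contrast, Busyness, Strength | one occupied level | 0 |
| NGTDM Coarseness | vanishing denominator | capped at 10⁶ |
| Intensity Skewness / Kurtosis | zero variance | 0 |
| Spearman ρ | constant feature column | NA, excluded from max-\|ρ\| with a warning (not treated as 0) |

# Redundancy and robustness analysis

Spearman's ρ (mid-ranks, average ranks for ties) drives three reports over
a cohort feature table:

- *parametric vs static:* same-name pairs only (the definitions coincide);
  redundant when signed ρ > 0.7, as a parametric feature is expected to
  co-rank positively with its static twin.
- *dynamic vs static:* each dynamic feature against **all** static
  features; redundant when max |ρ| > 0.7. The absolute value is used
  because a perfect negative association is equally redundant in the
  information sense; this choice is stated in the report semantics.
- *frame-duration robustness:* each dynamic feature between the 150 s and
  300 s framings; robust when ρ > 0.7. Rank correlation is the right tool
  because the framings induce systematic scale differences (matrix
  dimensions change with T), which rule out agreement statistics such as
  ICC or Bland–Altman.

Verbal strength labels follow the conventional bands |ρ| < 0.3 negligible,
0.3–0.5 low, 0.5–0.7 moderate, > 0.7 high.

# The synthetic phantom

The generator produces what the analysis needs and nothing more: an
ellipsoidal lesion (≈ 600 voxels at default size) with a smooth
centre-to-rim $K_i$ gradient (0.03 → ~0.013 min⁻¹) plus a focal
high-$K_i$ subregion (0.055 min⁻¹), in a low-uptake background
($K_i$ = 0.002 min⁻¹), with blood-volume fractions of 0.05 (lesion) and
0.03 (background); a three-exponential plasma input
$800e^{-4t} + 100e^{-0.3t} + 60e^{-0.01t}$ (arbitrary activity units,
t in minutes) qualitatively shaped like an FDG input after the bolus
peak; the 16 × 150 s schedule over 10–50 min with a separate 50–60 min
window for the static image; and optional Gaussian noise with standard
deviation proportional to the local signal. Cohorts jitter the lesion
semi-axes (±20%), $K_i$ levels, $v_b$ and plasma amplitudes
deterministically from a master seed. The default cohort noise level of
5% is a low-noise regime chosen so that frame-duration robustness reflects
the features, not the noise floor.

What the phantom does **not** emulate: Poisson projection noise and
reconstruction correlations, partial-volume effects, patient motion,
scanner-dependent point-spread, metabolite correction, or segmentation
uncertainty (the VOI is the ground-truth ellipsoid). Passing tests on the
phantom therefore demonstrate algorithmic correctness and internal
consistency — exact Patlak recovery, conservation laws, causality,
determinism — not clinical-data performance.

# Problem sizes and numerical tolerances

The test-suite and acceptance runs use phantoms of 24 × 24 × 18 voxels
(≈ 600-voxel lesions), 16-frame series, and 20-lesion cohorts — sizes at
which every path, including the brute-force oracles, runs in minutes on
one core while still exercising all code branches. Key tolerances:
noiseless Patlak recovery is asserted at 10⁻⁵ relative (observed:
~10⁻¹⁵); analytic plasma integrals agree with dense trapezoid quadrature
at 10⁻⁹ relative; matrix builders agree with exhaustive enumeration
exactly (integer counts); trilinear resampling reproduces world-linear
fields at 10⁻⁹ and the 8-corner oracle at 10⁻¹².

# Known limitations

- Shape features are mesh-dependent: marching tetrahedra on the upsampled
  field differs from classic marching cubes by a few percent in surface
  area (volume much less), so cross-tool comparisons of SurfaceArea,
  Sphericity and SurfaceVolumeRatio need a fixed mesh convention.
- The Patlak abscissa mapping between normalised and real time depends on
  the input function; `t_star` is specified in normalised time and should
  be checked against the actual plasma curve when frames start late.
- Grey levels are anchored at 0; VOIs with genuinely negative calibrated
  intensities are clamped, which is reported but loses sub-zero texture.
- The temporal matrices assume voxel correspondence across frames; no
  motion correction is provided, and misaligned series will read as
  spurious temporal texture.
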