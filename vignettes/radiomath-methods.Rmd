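---
title: "Methods: radiomics-based ranking of brain areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics-based ranking of brain areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiomath)
```

# The scientific problem

Structural MRI studies of children's mathematical ability have mostly asked
one question of each brain region: how big is it? `radiomath` implements a
richer protocol. For each of 191 brain areas (the Destrieux cortical
parcellation plus standard subcortical structures), it computes a fixed
catalogue of 100 radiomics features — shape, first-order intensity
statistics, and four families of gray-level texture matrices — and asks how
well a depth-limited random-forest regression on those features predicts a
child's score on four standardized mathematics tests (Math fluency,
Calculation, Applied problems, Quantitative concepts), over and above age
alone. Areas are ranked by hold-out prediction error, screened by a
two-sigma rule, and tested against a randomization null in which the
identical model pipeline is fed pure noise. Finally, the forests' Gini
importances are decomposed by feature family to ask *which kind* of
structural information (volume, other shape descriptors, intensity
histogram, texture) carries the signal.

Because the underlying clinical images are not distributable, the package
carries a synthetic world — a cohort generator calibrated to the study
cohort's published statistics and a 3D phantom generator with plantable
effects — so every stage of the pipeline is testable end to end.

# The synthetic cohort

## Model

For subject in grade $g$ and test $t$:

$$X_t = m_t(g) + s'_t(g)\, z_t, \qquad z \sim N(0, R_z),$$

with age uniform on grade-specific bands matching the published age
means/SDs, scores rounded to integer item counts and clipped to the test
maxima (160/46/62/57). Sex is generated at the published boys/girls ratios
but unused by any model. The per-grade means and SDs are the published
values (grade 3 Math fluency: mean 37.6, SD 6.9; and so on), and the target
inter-test correlation structure is the published matrix of partial
correlations controlled by age (0.34–0.69).

## Why the latent correlation is calibrated

The target is a property of the *output*: the Pearson correlation of scores
after residualizing on age. Under the model above that quantity is not the
latent correlation $\rho_z$, for two reasons:

1. grade means are non-linear in age, so linear age-residualization leaves
   a shared between-grade component in every test pair;
2. integer rounding adds variance $1/12$ to each marginal.

Writing $G_{ab}$ for the covariance of the age-residualized grade-mean
components, $S_{ab} = \sum_g w_g s'_a(g) s'_b(g)$ for the latent noise
part, and $V_t = G_{tt} + S_{tt} + 1/12$ for the total residual variance,
the observed partial correlation is linear in $\rho_z$:

$$\rho_{\mathrm{obs}} = \frac{G_{ab} + \rho_z S_{ab}}{\sqrt{V_a V_b}}.$$

`cohort_spec(calibrate = TRUE)` (the default) inverts this per pair, and
deconvolves the rounding variance from the latent SDs
($s'^2 = s^2 - 1/12$), so the generated data converge to the published
marginals *and* partial correlations simultaneously. The implied latent
matrix is checked for positive semidefiniteness and rejected with a
diagnostic otherwise. Empirically, calibration moves the realized partial
correlations from errors of up to 0.03 (uncalibrated) to under 0.005 at
$n = 10^5$. Score clipping is ignored in the calibration: at the published
means and SDs the clip boundaries are more than 5 SDs away.

```{r cohort}
co <- generate_cohort(cohort_spec(), seed = 1)
dplyr::count(co, grade)
partial_correlations(co)["mf_raw", "calc_raw"] # target 0.386, n = 77 draw
```

# The phantom world

`phantom_spec()` defines a 64³ grid (1 mm isotropic, matching the study's
voxel size) with 12 disjoint axis-aligned ellipsoid "areas" by default —
the number is configurable; 12 rather than 191 keeps desk-scale runs fast,
and nothing downstream depends on anatomy, only on the statistical
structure of the features. Each area has a base intensity, a noise SD
(default 15 at base intensity ~100, an MR-plausible contrast-to-noise
regime), and a spatial correlation length: white noise is smoothed with a
Gaussian kernel (sigma 1 voxel, applied before any signal scaling) and
re-standardized, so texture features have non-trivial spatial structure to
measure. The background is a darker, noisier compartment.

A signal plan plants effects per area as a function of a subject's
normalized score $s \in [0,1]$:

* **texture-contrast**: noise SD becomes $\sigma(1 + \beta s)$;
* **mean-intensity**: base intensity becomes $\mu(1 + \beta s)$;
* **volume**: ellipsoid volume scales by $(1 + \beta s)$.

The published study gives no effect sizes linking features to scores, so
the test suite's planted $\beta = 2$ (an SD ratio of 3 between score
extremes) is a free parameter of the synthetic world, chosen once to make
power checks decisive; it is not an estimate of any real effect.

What a green test on phantoms establishes: that the pipeline's mechanics
(feature computation, selection, ranking, calibration of the randomization
test, importance attribution) behave as specified. What it does not
establish: anything about real brains — phantoms have no anatomy, no
partial-volume gradients, no registration error, and their noise is
stationary Gaussian.

# The feature catalogue

The catalogue is fixed at exactly 100 features: 14 shape + 18 first-order
+ 22 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM (no NGTDM family), the standard
default sets of widely used radiomics engines of the study's era. The
original study's exact feature list was published only as supplementary
material that is not available; this catalogue is a declared stand-in with
the same size and family structure. Conventions that matter:

* **Discretization**: fixed bin width (default 25 intensity units), ROI
  minimum as offset: $b = \lfloor (x - \min x)/w \rfloor + 1$. Applied
  after whole-volume histogram matching to a reference subject
  (`histogram_match()`, full empirical quantile mapping; the reference is a
  configuration option since the study chose it visually).
* **Texture directions**: distance-1 offsets over the 13 unique 3D
  directions; features computed per direction and averaged over directions
  with at least one pair/run. GLSZM zones are 26-connected equal-level
  components; GLDM dependence is indexed by $j = 1 +$ (number of equal
  26-neighbours), so small/large-dependence emphases are defined.
  Entropies use base-2 logs with $0 \log 0 := 0$.
* **Mesh features**: marching tetrahedra (Kuhn decomposition) on the voxel
  mask. Volume uses the midpoint isosurface of the binary field, which is
  nearly unbiased; area uses the isosurface of a Gaussian anti-aliased
  field (sigma 1 voxel), because the raw binary isosurface overestimates
  the area of smooth objects by an orientation-dependent jaggedness factor
  (~27% for spheres under this tessellation). The area is clamped below by
  the isoperimetric bound $(36\pi V^2)^{1/3}$, so sphericity of a digital
  ball converges to 1 from below and never exceeds it. Mesh quantities are
  exactly invariant to grid translations but only approximately (within a
  few percent) to 90° rotations — the tetrahedral decomposition has a
  preferred diagonal.
* **Axis features**: principal components of voxel-centre coordinates with
  the within-voxel uniform variance $\mathrm{spacing}^2/12$ added per axis.
  This keeps single voxels isotropic (Elongation = Flatness = 1) and gives
  a 1×1×10 rod an elongation of exactly 0.1.
* **Diameters**: exact maxima over the voxel union (corner-to-corner),
  not mesh vertices.
* **Degenerate ROIs**: a constant ROI has zero skewness/kurtosis by
  convention; a single voxel uses the degenerate single-cell co-occurrence
  matrix; an expected-but-absent label yields a row of zeros with a
  warning. Every returned feature is finite.

Every one of the 100 features is pinned against an independent brute-force
reimplementation (naive loops, own percentile and marching-tetrahedra code)
to 10⁻⁹ relative tolerance on random small ROIs.

# Feature selection

`decorrelate()` walks the catalogue front to back: at step $i$, every
later surviving feature with squared Pearson correlation *strictly* above
0.8 against feature $i$ is removed, recording feature $i$ as the cause.
Because shape features precede texture features in the catalogue, texture
features correlated with shape are removed in shape's favour. The
procedure is deliberately order-dependent (tested with a fixed example)
and idempotent. Zero-variance features drop first with cause `"constant"`;
age is never a candidate nor a cause, since age joins the model after
selection. Selection is fitted on each partition's training split by
default (`selection_scope = "per-partition"`), avoiding hold-out leakage;
a `"global"` scope (one selection per area on all rows) is available
because the published per-area retention percentages suggest the original
analysis may have selected once per area.

# Area ranking

For each area and test, `rank_area()` runs the full protocol:
20 random 80/20 train/test partitions; on each partition, selection on the
training split, then 100 random-forest regressors on the kept features
plus age, differing only by seed; the partition MAE is the mean of the
models' hold-out MAEs and the area MAE the median over partitions. Forests
are bagged CART trees with exact variance-reduction splits, depth capped
at 5, all features considered per split, and per-tree-normalized
mean-decrease-of-impurity (Gini) importances — the defaults of the
scikit-learn implementation the study reports, reimplemented in C++
because no R random-forest engine was available in the target environment.
Determinism: every partition and model seed derives from the master seed
by a counter scheme, so results are reproducible from `(seed, config)`.

Scores are min-max normalized to $[0,1]$ per test over the analysis cohort
(the published MAEs of ~0.1–0.26 imply normalized targets; the exact
transform is unstated, and the constants are recorded in the run manifest).
`ranking_config(profile = "demo")` scales the protocol to 4 partitions × 3
models × 25 trees for desk-scale runs; the statistical structure is
unchanged.

## A property worth knowing about the age-only baseline

The age-only baseline uses the identical protocol with age as the only
feature. At depth 5 with ~60 training subjects, a single-feature forest
overfits: all trees split on age repeatedly and the ensemble has little
averaging to offer. Adding features — even pure noise — decorrelates the
trees and regularizes predictions toward the conditional mean, so
*noise-feature areas systematically beat the age-only baseline* (by ~15%
on the demo world). This is a property of the protocol, not a bug: it is
why the significance machinery compares areas against the random-feature
noise distribution (which shares the dimensionality and protocol) rather
than against the baseline. Improvement over the baseline is reported as a
descriptive statistic, mirroring the published reporting, but "better than
baseline" is not evidence of signal; "better than the noise null" is.

# Significance

`two_sigma_flags()` marks areas whose MAE lies more than two sample SDs
below the across-area mean ("most relevant"; nominal lower-tail
probability `pnorm(-2)` = 0.02275, printed as 0.022 when truncated to
three decimals). `noise_mae_distribution()` reruns the full per-area
protocol on i.i.d. standard-normal features (dimensioned at the median
post-selection feature count, plus age) and fits a normal to the replicate
median MAEs; `area_significance()` reports $z = (\mathrm{MAE} -
\mu_{\mathrm{noise}})/\sigma_{\mathrm{noise}}$, the lower-tail
$p = \Phi(z)$, and flags $z < -2$ as significant. A parametric tail is the
only reading consistent with published p-values of order $10^{-7}$, far
below the resolution of any feasible empirical rank; an empirical p can be
computed from the stored replicates if preferred. No multiple-testing
correction is applied, matching the published protocol's single-area
hypotheses. Both flags (across-area "relevant" and vs-noise "significant")
are reported so either reading of the published selection can be
recovered. Calibration is verified on all-noise phantoms: the
significant-flag rate over 40 seeds × 12 areas sits inside the 95%
binomial band around 0.0228 (the normal-SD estimate from 50 replicates
biases the rate upward by well under the band half-width).

# Importance decomposition

`family_importance()` averages each feature's Gini importance over all
models of an area (features dropped by selection count 0 in the models
where they are absent, keeping shares comparable across partitions with
different kept sets), groups by family — age, volume (mesh and voxel
volume), shape (the other 12 descriptors), intensity (first-order),
texture — and rescales to 100%. Per-model importances sum to 1 before any
grouping. `flag_unstable()` marks features whose importance SD across
models exceeds the mean SD by two population SDs — a proxy for unstable
contributions; variability is measured across models (rather than
partitions or areas), and the flag definition is a small, configurable
statistic. Note one consequence of the spec'd planted-effect design: a
texture-contrast effect scales the marginal noise SD, which first-order
features (variance, energy, percentile spread) measure directly and which
precede texture in the selection order — so on such phantoms the intensity
family can legitimately capture much of the Gini share even though the
planted mechanism is "texture".

# Numerical and engineering choices

* All randomness flows through R's RNG (including inside the C++ forest),
  so `set.seed()`/seed arguments give byte-identical outputs; generators
  save and restore the caller's RNG state.
* NIfTI-1 I/O is a minimal built-in implementation (no NIfTI package in
  the target environment): single-file `.nii`/`.nii.gz`, 3D volumes,
  uint8/int16/int32/float32/float64, sform affine. Intensities are stored
  as float32 (one quantization on write, then byte-stable); labels as
  int16/int32.
* `run_pipeline()` chains simulate → match → extract → rank → test →
  importance, writes CSV tables each carrying the manifest hash as a `#`
  comment line, and a JSON manifest with seeds, config hash and the
  per-test normalization constants. Identical config + seed reproduce
  every table byte for byte.
* A thin command-line wrapper (`inst/cli/radiomath.R`) exposes
  simulate/extract/select/rank/test/importance/run for shell use.

# Known limitations

* The catalogue is a stand-in for an unavailable supplementary list; only
  its size (100) and family structure are anchored.
* Mesh area/volume are approximate under rotation (a few percent); small
  digital balls report sphericity exactly 1 because of the isoperimetric
  clamp.
* The phantom world is stationary-Gaussian and anatomically trivial;
  effect sizes are test-suite parameters, not estimates.
* Whole-volume histogram matching on phantoms is nearly monotone-affine
  within an area, so it preserves planted SD ratios; on real data with
  heavy-tailed global histograms its local behaviour can differ.
* The acceptance targets cover cohort calibration only; the published
  per-area MAEs and p-values were computed on unavailable clinical data
  and are reproduced here only as worked arithmetic (improvement formula,
  z-to-p mapping), never as value claims about the pipeline's output.
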