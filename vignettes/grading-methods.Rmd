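---
title: "Grading volumetric textures: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading volumetric textures: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`voxtex` grades volumetric fluorescence images of tissue into four classes
using 3D texture statistics and linear discriminant analysis.  This
vignette is the package's own account of the science: what each stage
assumes, which knobs matter and why their defaults are what they are, what
the synthetic generator does and does not emulate, and where the design
was genuinely open and a choice had to be made.

# The pipeline and its assumptions

A sample is a stack of 2D optical sections treated as a scalar intensity
field `data[z, y, x]` on the 0–255 scale.  The chain is:

1. **Slice-wise bilateral denoising.**  Staining and acquisition noise is
   assumed to be voxel-scale and signal-independent enough that an
   edge-preserving local average removes it without moving structure
   boundaries.  Filtering is strictly 2D (per slice): axial sampling is
   coarser and optically blurred, so mixing slices would smear exactly the
   inter-slice signal the 3D statistics are meant to capture.
2. **Texture summarisation**, by one of two families:
   co-occurrence statistics of the quantized volume, or octband wavelet
   energies/entropies of the real-valued volume.  Both families assume
   texture is approximately stationary within a volume — features are
   global sums, so spatial localisation is deliberately discarded.
3. **Feature selection and LDA.**  LDA assumes Gaussian class densities
   with a shared covariance; selection exists chiefly because the sample
   sizes (tens of volumes) cannot support 12–16 correlated features.

An open question we had to settle: whether texture features are computed
on raw or denoised intensities.  The default follows the pipeline order
(features on the filtered volume), with `filter = FALSE` in
`extract_texture_features()` to switch.

# Co-occurrence statistics

The co-occurrence matrix for displacement $d$ counts ordered pairs of
quantized levels at voxels $p$ and $p+d$.  Thirteen displacement
directions — half of the 26-neighbourhood, canonicalised so the first
nonzero component is positive — are counted symmetrically, each matrix
normalized to unit sum, and the 13 averaged.  Normalizing *before*
averaging (the default) weighs every direction equally even though
diagonal directions have fewer valid pairs; `normalize = "after"` pools
raw counts instead.  The choice is second-order at realistic volume sizes
but is exposed because the convention is not universal.

Parameters:

* **Gray levels `G` (default 64, sensible range 8–256).**  A $G \times G$
  matrix needs on the order of $G^2$ well-populated cells; at 64 levels a
  $256^2 \times 30$-voxel volume populates the matrix densely while still
  resolving intensity structure.  Oracle tests use $G \le 8$ so brute
  force stays cheap.
* **Displacement distance (default 1 voxel).**  Nearest-neighbour
  displacements capture the finest texture scale; the distance multiplies
  all 13 vectors.  Axial anisotropy (0.5 µm vs 0.34 µm voxels) is *not*
  compensated: displacements are in voxel units, matching how such
  matrices are conventionally built from stacks.
* **Entropy log base (default 2).**  Matches the wavelet entropy's
  explicit base 2; natural log available.

Feature formulas follow the classical definitions with 1-based matrix
indices so moments match Haralick conventions.  Two formula-level
decisions deserve record:

* **SDM (second-order diagonal moment).**  The printed formula
  $0.5\,(j-i)\,c(i,j)$ has no summation and, summed literally, is
  identically zero on every symmetric matrix — the only kind the averaged
  matrix can be.  The default is therefore
  $\mathrm{SDM} = \sum_{ij} 0.5\,|i-j|\,c(i,j)$, the only reading that is
  both a moment and non-degenerate under symmetric counting; the literal
  signed variant is available via `sdm = "signed"`.
* **CORR degeneracy.**  When either marginal standard deviation is zero
  (a constant volume) the correlation is undefined; `glcm_features()`
  returns `NaN` rather than raising, so downstream tables stay rectangular.

# The 2D + 1D wavelet transform

The level-1 3D transform is realised as a 2D transform per slice (rows,
then columns) followed by a 1D transform along z.  Because the transform
is separable and no coefficient processing happens between stages, this
equals a direct axis-by-axis 3D transform — a property the tests exploit
by checking against an independent tensor oracle.  Band labels give the
filter per axis in row/column/stack order; indices 1–8 enumerate
LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH.

* **Bases.**  Haar (2 taps) and Daubechies-2 (4 taps), both orthonormal.
* **Boundary extension (default half-sample symmetric).**  Real stacks
  have odd depths (30–126 slices), which periodic extension cannot
  handle; symmetric extension accepts any length at the price of exact
  orthonormality.  Tests that assert Parseval equality or perfect
  reconstruction use periodic extension on even dimensions, where both
  hold to machine precision.
* **Entropy form (default literal).**  $-\sum W^2 \log_2 W^2$ is not
  scale-invariant and is typically large and negative for 0–255 data
  (coefficients far exceed 1).  It is kept as the default out of fidelity
  to the published feature definition; a normalized Shannon entropy
  (`entropy = "normalized"`) and a 0–1 intensity rescale (`rescale =
  TRUE`) are provided for scale-free work.  Selection and LDA are
  unaffected by the choice of a monotone transform family applied
  consistently to train and test.
* Wavelet features are computed on the *unquantized* filtered volume;
  quantization exists only to make the co-occurrence matrix countable.

# Selection statistics

**Wilks' lambda** $\Lambda = \det W / \det(B+W)$ is computed from scatter
matrices about class and grand means.  Numerically, $\Lambda$ is invariant
to per-feature rescaling (both determinants pick up the same squared
factor), so the implementation evaluates the determinant ratio on
variance-scaled matrices; raw energies near $10^{10}$ and entropies near
$10^2$ otherwise destroy the conditioning of a perfectly healthy problem.
A subset is reported as collinear when the scaled total scatter has
reciprocal condition number below $10^{-12}$.

**Stepwise selection** alternates the classical partial-$\Lambda$ moves:
enter the candidate with the largest
$F = \frac{n-g-p}{g-1}\left(\frac{\Lambda_p}{\Lambda_{p+1}} - 1\right)$
if its p-value passes `alpha_enter`, then drop the weakest incumbent whose
removal p-value exceeds `alpha_remove`.  The F-to-remove for a feature is
the F-to-enter it would have into the model without it, so a feature can
never be removed in the same iteration it entered when
`alpha_enter <= alpha_remove` — the no-oscillation property the tests
assert over random tables.  Ties in F break by feature name for
determinism.  **Significance level**: the source material states the
study-wide level as 0.01 in one place and "0.01%" in another; we adopt
0.01 for both thresholds and expose both as arguments.

**PCA** standardizes features and eigendecomposes the correlation matrix,
so eigenvalues sum to the feature count and the final cumulative
proportion is exactly 1 — both asserted on every input.  Component
retention supports a fixed count (the study design uses 8 components for
the 16 wavelet features and 5 for the 12 co-occurrence features) and a
cumulative-proportion threshold (default 0.95, which selects component 8
on the published 16-feature spectrum).  Projection always reuses the
training means, standard deviations and loadings, so held-out samples
transform identically alone or in batch.

# LDA and evaluation

The discriminant score is
$d_c(x) = \mu_c' \Sigma^{-1} x - \tfrac12 \mu_c' \Sigma^{-1} \mu_c +
\log \pi_c$ with $\Sigma$ the pooled within-class covariance.  Choices:

* **Divisor.**  $\Sigma = W/n$ (maximum likelihood) rather than
  $W/(n-g)$: classification is invariant to the scale of $\Sigma$, and
  the ML form makes the fitted model exactly invariant to duplicating the
  training data — a cleaner sufficiency property to test.
* **Priors (default uniform).**  The grade counts in the study design
  (4/12/7/11) reflect specimen availability, not prevalence; empirical
  priors are available.
* **Ties** go to the lower grade — arbitrary but deterministic, and
  conservative in a grading context.
* The inverse is computed in correlation space (scale, invert, unscale)
  for the same conditioning reasons as the Wilks statistic.

Reports are 4×4 confusion matrices with per-grade (row-wise) and overall
accuracies; overall accuracy equals the count-weighted mean of per-grade
accuracies, which the tests verify on random matrices.

The six configurations A–F (texture family × selection method) are run
with selection fitted on training data only; mutation tests confirm that
permuting test rows changes neither the selected features nor the model.

# The synthetic cohort

Real confocal volumes of graded tumor tissue are not publicly available,
so the package carries a generator whose output is *statistically*
gradable rather than photorealistic.  A volume is: Poisson-many
axis-aligned ellipsoidal Gaussian blobs (nuclei) composed by maximum,
blurred along z (optical sectioning), plus a constant background and
Gaussian speckle, clipped to 0–255.  Grade progression follows the
morphology that nuclear grading actually scores — with grade, the default
specs monotonically increase blob radius (nuclear enlargement), radius
spread and per-axis shape irregularity (pleomorphism), blob density
(cellularity) and speckle (chromatin coarseness / heterogeneity).  The
defaults were chosen once to produce four clearly separated classes at
64×64×48 voxels and are documented in `default_grade_specs()`; the
train/test design (4/12/7/11 and 4/11/6/11 per grade) mirrors the
published study's counts.

Determinism: every volume's seed derives from (master seed, grade,
within-grade index) via a small modular hash, so cohorts are reproducible
and any single volume can be regenerated in isolation.  The generator
restores the caller's RNG state.

What the generator does **not** emulate: a real point-spread function
(only 1D axial blur), stain chemistry and photobleaching, nucleoli or
chromatin substructure within nuclei, tissue architecture (blob positions
are uniform, real nuclei cluster), and intensity-dependent (Poisson shot)
noise.  Consequently a green end-to-end test establishes that the
pipeline's machinery — extraction, selection, training, evaluation — is
correct and that the features respond to size/shape/noise texture axes in
the expected directions.  It does *not* establish clinical performance;
the published accuracies on real tissue (90.63% for the best
configuration) live on a private data set and are out of reach of any
desk-scale reproduction, which is why the acceptance checks are
property-based (oracle equivalence, analytic limits, monotone responses,
and a ≥85% bar for the best configuration on the default synthetic
cohort).

# Numerical conventions and degenerate inputs

* Axis order is `[z, y, x]` everywhere; slice lists convert with slice 1
  at z = 1.
* Quantization is `floor(v G / 256)` clamped to `G − 1`: bin edges are
  multiples of 256/G, intensity 255 lands in the top bin, and re-binning
  bin representatives is the identity.
* `0 log 0 := 0` in every entropy; empty bands have zero energy and
  entropy.
* Constant volumes: bilateral filter is the identity; co-occurrence mass
  concentrates on one diagonal cell; CORR is `NaN`; all detail bands are
  exactly zero.
* Degenerate directions (volumes thinner than a displacement) raise a
  classed error naming the direction rather than silently contributing
  nothing.
* All user-facing failures are classed conditions
  (`voxtex_error_*`), so callers can distinguish missing paths,
  inconsistent shapes, singular scatter, and so on programmatically.

# Known limitations

* Only level-1 decompositions and the Haar/DB2 bases; no multiscale
  feature pyramids.
* The TIFF codec is deliberately minimal (uncompressed 8-bit grayscale,
  one or more strips, either endianness) — enough to round-trip the
  package's own output and plain exports from common tools, not a general
  TIFF reader; PNG input covers RGB sources.
* No cross-validation or regularised discriminants; with tens of samples
  the honest uncertainty on any accuracy estimate is large, and the
  package reports plain train/test splits without pretending otherwise.
* Stepwise selection inherits the classical caveats of sequential
  F-testing (greedy, p-values not simultaneous); it is provided as part
  of the study design, with PCA as the alternative.
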