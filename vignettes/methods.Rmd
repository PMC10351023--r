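---
title: "Models and methods behind glosscon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glosscon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glosscon)
```

`glosscon` implements the computational spine of an asymmetric-matching
study of color and gloss constancy: spectral stimulus synthesis, lighting
environment statistics and manipulations, a lightweight renderer, image
metrics of specular reflection, and the observer-evaluation statistics.
This vignette explains each model, the parameters that matter, the choices
made where the design was genuinely open, and what the synthetic data do
and do not establish.

## Spectral colorimetry

All spectra are 31-channel vectors on a 400–700 nm grid at 10-nm steps —
the standard sampling of matte-chip spectral databases. Tristimulus
integration uses the CIE 1931 2° observer (the conventional choice for
display colorimetry), with each channel normalized so that a perfect
reflector under the equal-energy-white illuminant maps to exactly
X = Y = Z = 100. That normalization *is* the white point: all Lab
coordinates of reflectances are taken against (100, 100, 100), and color
error is CIE76 ΔE\*ab (the simplest difference metric; nothing downstream
depends on the refinements of later formulas at the ΔE ≤ 0.5 scale used
here).

**Reflectance basis.** Six basis functions are extracted from a matte chip
set by non-negative matrix factorization (multiplicative updates,
Frobenius loss). NMF is non-convex, so the fit restarts from several
random initializations (default 10) and keeps the lowest reconstruction
error; with the seed fixed, the result is fully deterministic. Components
are normalized to unit maximum and ordered by spectral centroid so that a
basis is identifiable across runs.

**Constrained reflectance solving.** A target (hue, L\*, C\*ab) fixes a
3-vector of tristimulus values; the basis gives 6 weights; the physical
constraint is 0 ≤ R(λ) ≤ 0.90 at every wavelength (the 0.90 headroom keeps
the total reflectance physical once the specular component, at most
0.0999, is added). The solver works in three stages:

1. **Exact tristimulus match** by pseudoinverse — the minimum-norm weights
   reproducing the target XYZ exactly.
2. **Feasibility restoration** inside the 3-dimensional null space of the
   color constraint: projected gradient descent on the squared bound
   violations, which cannot change the color at all. If it reaches zero
   violation, the solution has ΔE = 0 by construction.
3. **Penalized polish** (BFGS on ΔE² plus escalating bound penalties) only
   for targets that cannot satisfy both color and bounds. If the residual
   ΔE exceeds 0.5 the entry is flagged infeasible — never silently
   clipped.

This replaces a multi-start random search: it is deterministic, exact for
every in-gamut target, and solves the full 21,600-entry grid in well under
ten seconds, which a stochastic search cannot do at equal accuracy. An
independent brute-force minimizer over a dense null-space grid backs the
solver in the test suite. Violations below 10⁻⁶ after stage 2 are treated
as numerical residue and clamped onto the bounds.

**The gloss scale.** Pellacini's contrast-gloss parameter is
c = (ρs + ρd/2)^{1/3} − (ρd/2)^{1/3}. The diffuse term is derived from the
conversion lightness as ρd = (L\*/100)³. This mapping is a calibration
choice: it reproduces both stimulus-range correspondences
(ρs = 0.0999 ↔ c ≈ 0.149 at L\* = 50, and ≈ 0.223 at L\* = 33.9), whereas
mapping L\* through the CIE lightness function to Y does not come close to
either. The inverse is closed-form and round-trips to 10⁻⁹; c is strictly
increasing in ρs and, for ρs > 0, strictly decreasing in lightness.

## Lighting environments

Environment maps are equirectangular H × 2H grids of linear RGB radiance
(sRGB primaries), row 1 at the zenith, azimuth increasing eastward, pixel
centers at half-integer angles, and exact per-row solid angles that sum to
4π.

**Moments** of luminance are computed over the raw pixel population,
unweighted — matching how per-pixel histograms are usually drawn — with a
solid-angle-weighted variant available. Skewness and kurtosis are
standardized central moments and are reported as `NA` for constant maps
rather than as arbitrary numbers.

**Diffuseness** is the light-vector construction
D = 1 − |∫L n dω| / ∫L dω: 1 for a perfectly uniform field, approaching 0
as radiance concentrates toward one direction, monotone along
uniform-to-point mixtures, and invariant to global scaling. The cited
metric in the literature is defined by its endpoints the same way; this
construction is the package's own formalization.

**Spherical harmonics.** Real orthonormal SH. Longitude is analyzed by
exact discrete Fourier orthogonality; latitude by sine-weighted least
squares per azimuthal order, so projection/reconstruction round-trips are
exact to machine precision for band-limited fields (and the band limit is
capped at the grid Nyquist, lmax ≤ H − 1). Per-degree power is reported as
the *mean squared coefficient* within the degree; on this normalization a
spatially uncorrelated field on the sphere is flat (slope 0) and natural
environments fall off with slope near −2, which is also how the synthetic
generator plants its spectra.

**Gamut rotation** works in a working Lab frame whose white is the map
median luminance anchored to L\* = 50 at equal-energy chromaticity — any
fixed convention preserves the semantics of the manipulation, and the
median anchor makes the frame exposure-invariant. The a\*b\* plane is
rotated +90°, leaving every pixel's L\* untouched; pixels leaving the
display gamut (non-negative linear RGB; the chromatic gamut is what
matters for an HDR map with arbitrary scale) have chroma reduced by
bisection at fixed hue and L\* until inside, and the clipped fraction is
reported.

**Phase scrambling** rotates each degree-l coefficient subspace by a
random proper rotation, the same rotation for all three color channels so
no chromatic fringing appears; per-degree power is preserved exactly by
orthogonality. Scrambling still changes the pixel color distribution, so
the result is histogram-matched to the original by rank-based color
transfer: each scrambled pixel receives the complete RGB triplet of the
equally-luminance-ranked original pixel. This preserves the *joint* color
distribution exactly (hence every luminance and chromaticity marginal).
The more obvious alternative — matching the luminance histogram and then
the chroma histogram hue-preservingly, iterated — was implemented and
measured first: it stalls at a chroma mismatch (KS ≈ 0.09) because the
scrambled arrangement of hue and lightness cannot carry the original
chroma marginal inside the gamut. Rank transfer has no such feasibility
gap.

## Synthetic data

The generators define the study conditions for everything downstream.

**Chips** (`synth_munsell_chips`, default 1,269 — the size of the measured
matte set the design emulates) are smooth non-negative spectra: a flat
base plus one or two broad Gaussian bands and a gentle spectral tilt, kept
in [0.02, 0.88]. They emulate the smoothness and gamut breadth of
pigmented matte papers; they do not reproduce the metameric fine structure
of real pigments, so tests passing on them show the pipeline's
correctness, not colorimetric claims about Munsell chips.

**Environments** (`synth_envmap`) exponentiate a band-limited Gaussian
field with a planted power-law SH spectrum (slope −2 by default), giving
the heavy-tailed luminance histograms of real HDR probes; a von
Mises–Fisher bright cap controls directional concentration (hence
diffuseness), and smooth low-order chromatic fields give an a\*b\* gamut
elongated along a configurable axis (blue–yellow by default, emulating the
daylight locus). They lack the recognizable structure of real scenes —
horizons, light sources with hard edges, indoor geometry — so statistics
that depend on such structure are exercised only in distribution.

**Observers** (`observer_model`) share a systematic component per image —
a weighted mix of ground truth and image statistics, identical across
observers — plus independent Gaussian setting noise, clamped to the
adjustment ranges (lightness 28–74, chroma 8–26, c ≥ 0; hue is circular
and unclamped). The shared component is what makes interobserver
correlations high even where truth correlations are poor, the central
empirical signature the analysis stack must detect. Default biases (e.g.
lightness driven 75% by mean object lightness, gloss about half by
reflection contrast) were chosen once as plausible emulations of that
signature; the model makes no claim to fit human data.

## Rendering

The renderer is deliberately light: an orthographic camera, a unit sphere
with sinusoidally perturbed normals (the silhouette stays a disk), diffuse
shading via order-2 SH irradiance (nine coefficients per channel — the
standard Lambertian approximation, exact for a uniform field where
`diffuse_unit` equals the ambient radiance), and specular shading by
looking up the environment along the per-pixel mirror direction after an
angular Gaussian blur of width α (Ward roughness, fixed at 0.05 — narrow
enough that the blur stands in for the full lobe integral). Everything
downstream depends on the *linear composite*
`image = albedo · diffuse + ρs · specular`, which holds here by
construction, not on BRDF fidelity; interreflections, shadows, and
spectral transport are intentionally absent.

**Viewpoint selection** renders a mirrored sphere at 12 candidate azimuths
and picks the brightest. The image mean of an orthographic mirror sphere
is, exactly, viewpoint-invariant (the mapping is area-uniform in solid
angle), so the package uses the foreshortening-weighted mean — equivalent
to weighting reflected radiance by cos ψ of the surface normal — which
prefers viewpoints with the dominant light on the camera side, i.e.
brightly and visibly lit objects. Ties break toward the smallest azimuth.

**Normalization** divides a whole image set by the pooled 99th-percentile
pixel value (quantile type 7), one shared factor, so relative ratios are
untouched and no tone mapping is ever applied.

## Image metrics

The specular-only image is composite minus diffuse component, clamped at
tiny negative residue, zero outside the object mask. Highlights are pixels
*strictly* above k% of the region maximum, k ∈ {0, 1, 3, 5, 10, 20, 40}.
Coverage is highlight area over object area. Sharpness is the mean Sobel
gradient magnitude over the mask (replicate-padded, so constant images
score exactly 0); the cited sharpness map is described only qualitatively
in the source literature, so the operator is pluggable. Sub-band contrast
decomposes the *thresholded* specular image (values kept above threshold —
the threshold is one of the metric's free parameters) with isotropic
Fourier-domain difference-of-Gaussian filters whose half-power radii sit
at the printed cutoffs (1.5–3 up to 192–384 cycles/image); RMS contrast is
the population standard deviation over the mask, and the aggregate is the
sd of the sum of bands. Under the default display geometry (512-px
stimulus, 0.2692 mm pixels, 49 cm viewing distance) the top band's center
is ≈ 18 cycles/degree. All metrics zero out the surround before
computing, so they are provably blind to context. Region color statistics
(moments, quartiles, extremes of L\* and C\*ab; circular mean hue) use
quantile type 7 and population variance.

Metric-parameter search is exhaustive over the k grid (and band grid for
contrast), maximizing |Pearson r| with mean observer settings; ties break
to the smaller k, then the lower band, so results are reproducible.

## Analysis statistics

Sessions are averaged within observer before any correlation (circularly
for hue). Truth correlations are per observer, then mean ± SE (sample
sd/√N). The circular correlation is Jammalamadaka–SenGupta — invariant to
independent constant rotations of either variable, matching hue
semantics. Noise ceilings: upper = correlation of each observer with the
all-observer mean, lower = with the mean of the others. Partial
correlation uses the standard first-order formula and equals the
residual-regression construction to 10⁻¹⁰. The leave-one-observer-out
regression z-scores predictors and response (standardized weights),
regresses the mean of the remaining observers, and correlates predictions
with the held-out observer; rank-deficient predictor matrices fall back to
the minimum-norm solution with a warning. Correlations that are undefined
(constant inputs) are reported as `NA` markers and excluded listwise with
a warning — never silently imputed. Hypothesis tests use the
t-approximation for Pearson r (an F test on R² for the circular–linear
case), with Bonferroni correction sized to the analysis family (3 for the
gloss-error-versus-color family).

## Problem sizes and determinism

The test suite runs the full stimulus-space sizes where they are the
point — the 21,600-entry grid, 12 base environments at H = 128 expanded to
36, and the 216-image factorial set at 128 px — and small synthetic cases
everywhere else; the end-to-end recovery checks use a 36-image factorial
set and 20 simulation seeds. These sizes are the package's choices for a
thorough-but-quick default run; every generator and simulation takes an
explicit seed, and `run_pipeline()` derives stage seeds stably from one
master seed so a configuration reproduces its outputs byte for byte.

## Known limitations

- The renderer's specular term is a blurred mirror lookup, not a full Ward
  lobe integral; grazing-angle behavior and energy conservation at high
  roughness are out of scope (roughness is fixed at 0.05 here).
- Synthetic environments and observers emulate summary statistics, not
  content; analyses that depend on scene semantics or on real human
  strategy differences cannot be validated with them.
- The diffuseness index and the sharpness operator are the package's
  formalizations of metrics described only qualitatively in the source
  literature; both are documented and (for sharpness) pluggable.
- Absolute luminance is arbitrary: the pipeline reports linear radiance in
  map units and display-normalized units, never cd/m².
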