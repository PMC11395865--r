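---
title: "Rapid wash-out mapping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rapid wash-out mapping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rapidwashout)
```

## The problem

After gadolinium injection, actively perfused brain-tumor tissue enhances
quickly — glioblastoma cells reach maximum enhancement within roughly 3–8
minutes — and then clears the agent ("wash-out"), while scar and necrotic
tissue accumulates contrast slowly and is still gaining signal twenty
minutes after injection ("wash-in", late enhancement). Two post-contrast
T1-weighted acquisitions, one early (about 5 min after injection) and one
late (about 15 min later), therefore carry a signature that separates
active tumor from treatment-related change: tissue that is *brighter
early* is washing out, tissue that is *brighter late* is washing in. This
package turns such a pair of volumes into a color-coded subtraction map —
red for wash-out (active tumor cells and vessels), green for wash-in
(scar/necrosis) — together with compartment volumetry, the wash-out ratio,
and agreement statistics against DSC-perfusion (rCBV) volumetry.

## Pipeline model

The processing chain is, in order:

1. **Input** — DICOM series or NIfTI volumes; geometry is converted to a
   single right-handed RAS world convention in millimetres at the boundary
   (DICOM's LPS axes are sign-flipped). Voxel indices are 0-based in all
   geometry math.
2. **Bias-field correction** — each series independently, before any
   intensity comparison (multiplicative inhomogeneity would otherwise
   masquerade as enhancement change).
3. **Mean normalization** — both series are scaled to a common mean over
   their foreground masks.
4. **Rigid registration** — the late series is registered *to* the early
   series (6 degrees of freedom), so subtraction happens on the early grid.
5. **Subtraction** — early minus late: positive values are wash-out.
6. **Encoding** — 8-bit grayscale and two-color RGB maps, zero difference
   at 127 of 255.
7. **Volumetry** — threshold segmentation of the two compartments, exact
   voxel-count volumes, wash-out ratio; optionally rCBV-threshold
   perfusion volumetry for comparison.

### Bias correction

The bias field is modelled as a smooth multiplicative field: in the log
domain a tensor-product polynomial (degree 2 per axis, 27 coefficients) is
fitted to foreground log-intensities by iteratively reweighted least
squares with Tukey biweights, which keeps focal structure (lesions) from
leaking into the field estimate. Estimation runs on a grid downsampled by
the `shrink` factor (default 3) along each axis; because the model is
analytic, the full-resolution field is obtained by evaluating the fitted
polynomial, not by interpolation. The field is normalized to mean 1 over
the foreground so correction preserves overall intensity. The contract
asserted by the tests is behavioural: a bias-free input is changed by less
than 2%, a known smooth field in [0.8, 1.2] has its induced coefficient of
variation at least halved, `shrink = 1` and `shrink = 3` agree within 5%
RMS, and correction is idempotent within 1%. A constant image returns an
identity field with a warning flag rather than an error.

### Foreground masking

Otsu's threshold on a 256-bin histogram, with a polarity rule: the
foreground is the *minority* side of the threshold, which also handles
inverted-contrast images (bright air, dark head). The mask is the largest
26-connected component with interior holes filled. It exists for two
consumers — mean normalization (background air must not dominate the mean)
and registration (air must not dominate the similarity measure).

### Mean normalization

"The same mean value" is implemented as equal means over each series' own
foreground mask, and the common target is the *average* of the two
original foreground means. The symmetric choice privileges neither
acquisition; because both applied scale factors are returned and logged in
the manifest, either single-reference convention can be recovered exactly.
Masked rather than whole-grid means are used because air typically
occupies most of the field of view.

### Rigid registration

The cost is a negative similarity between the fixed (early) volume and
the moving (late) volume resampled through the candidate pose: normalized
mutual information (32-bin joint histogram) by default, with correlation
ratio and absolute correlation as alternatives. NMI is preferred because
it is insensitive to the residual (uncorrected) bias-field difference
between the series; plain correlation measurably degrades under
independent per-series bias in our experiments. A joint histogram needs
intensity *pairs*, so the masked cost is computed over fixed-foreground
voxels that receive valid moving intensities (moving background is set to
`NA` before resampling and excluded); this implements the intent of
air-free cost computation.

The search is a three-level coarse-to-fine pyramid (downsampling factors
4, 2, 1 with Gaussian pre-smoothing; the finest level keeps a light 0.7
voxel smoothing to tame histogram noise). Initialization is deterministic:
translation starts at the difference of the foreground centers of mass — a
nearly unbiased estimate, since rotation about the center of mass barely
moves it — and a fixed grid of rotation offsets (±4°, ±2°, 0° per axis) is
scanned around that translation at the coarse *and* middle levels. The
best candidates form a beam of up to three poses, each refined by two
Nelder–Mead passes per level (a restart re-expands the simplex); the beam
is narrowed to a single pose only at the finest level, by one
full-resolution cost evaluation per candidate. The two-level scan and the
late commitment exist because the coarse-level cost landscape can rank a
wrong basin best — on some noise draws the margin between basins at low
resolution is smaller than the cost noise, and only the full-resolution
cost separates them reliably. There is no randomness anywhere in the
search, so registration is bit-reproducible. If the final cost is worse
than the identity pose, the identity is returned with a
`converged = FALSE` flag rather than a worse-than-nothing transform.

On the built-in phantom at SNR 20 with misalignments up to 5° and 5 mm,
this recovers the true pose with a mean voxel displacement well below one
voxel (typically 0.2–0.4 voxels at 2 mm spacing). The residual
parameter-space error is of the order of a few tenths of a degree and a
few tenths of a millimetre — the precision floor set by noise and
interpolation effects in a histogram-based cost at this SNR.

### Subtraction and 8-bit encoding

The difference is voxelwise early minus late on the early grid; voxels
that were filled (`NA`) during resampling, or fall outside the foreground,
are excluded from the valid mask. The pipeline additionally erodes the
foreground by 2 voxels (configurable) before subtraction statistics:
resampled voxels on the head boundary mix tissue and air intensities, and
the resulting ±half-intensity rim would otherwise form a connected shell
of spurious "wash-out"/"wash-in" around the whole head. The cost of the
erosion is that a lesion touching the outermost cortex loses its rim
voxels; an ROI that includes the lesion explicitly is the mitigation.

The display clip range is `C = (max − min) / 2` over valid voxels (half the observed value range), with a
symmetric percentile policy (0.5–99.5%) available for robustness against
outliers. The signed range is treated symmetrically (a single `C` for
both polarities), which preserves the mid-gray zero point; this choice is
recorded in the manifest.

Encoding maps the clipped difference to 8 bits with

&nbsp;&nbsp;`g = floor(127.5 * (1 + d / C))`, decode `d = (g − 127) * C / 127.5` clamped to `[−C, +C]`.

This specific pair was chosen because an affine map with round-half-even
cannot simultaneously put 0 exactly at 127, ±C exactly at 0/255, *and*
keep the round-trip error within one part in 255; the floor form achieves
all three (the floor's half-step bias is cancelled by decoding at
`g − 127` rather than `g − 127.5`), so `|decode(encode(d)) − clip(d)| ≤
C / 255` holds at every voxel with equality only at the clip boundary.

The RGB rendering holds all channels at a neutral level where `d = 0` and
raises the red channel linearly to 255 at `+C` (wash-out) or the green
channel at `−C` (wash-in). The neutral level defaults to plain mid-gray
127 — so a zero difference renders as exactly (127, 127, 127) — with a
dimmed grayscale anatomy underlay available as an option when visual
context is wanted; the underlay compresses anatomy to [0, 127] so color
saturation is preserved. Encoding the negated difference is exactly the
red/green channel swap of the original.

### Volumetry

Wash-out is `d > +threshold`, wash-in is `d < −threshold`; each
compartment is cleaned by removing 26-connected components smaller than
`min_component_mm3` (default 50 mm³). The component floor is set by a
false-positive-rate argument: at the default 3σ threshold about 0.13% of
brain voxels exceed it by chance, so among ~10⁵ voxels chance 26-connected
pairs and triples are common (at 2 mm voxels they would total on the order
of 0.1–0.2 cm³ of spurious "lesion"), while chance clusters of seven or
more voxels essentially never occur; 0.05 cm³ is also far below any
clinically reportable lesion volume. The default threshold is `k · σ`
(k = 3) where σ is a robust noise scale of the difference — the median
absolute deviation about zero over the valid mask, scaled to a Gaussian
sigma. Lesions occupy a small fraction of the brain, so the MAD is driven
by normal-appearing tissue; an identically-zero difference (degenerate
null case) yields empty compartments with a warning rather than an error.
The interactive slice-by-slice tracing this replaces is inherently
rater-dependent; the deterministic threshold makes results reproducible,
and an optional ROI argument mimics the raters' restriction to a lesion
neighbourhood. Vessels legitimately wash out and are not excluded; the
ROI is the provided mitigation.

Volumes are exact: voxel count times voxel volume. The wash-out ratio is
`WO / (WO + WI)`, undefined (flagged, not fabricated) when both
compartments are empty.

Perfusion volumetry thresholds the rCBV map at 1.2 (relative units) and
removes components whose largest single-slice cross-section is at most
0.25 cm² — a 2D area criterion, matching how minimum lesion size is
stated for this measurement. The per-lesion rCBV summary reported is the
maximum rCBV inside the retained mask.

## The digital phantom

No paired patient acquisitions are publicly available, so every stage is
validated against a generated scene with exact ground truth. The phantom
is a head ellipsoid (default radii 70 × 85 × 60 mm) containing parametric
lesions — an enhancing-tumor sphere, a scar/necrosis sphere, a vessel
cylinder, optionally a ring-shaped shell lesion mimicking the rim pattern
of radiation necrosis — on a 96 × 96 × 72 grid at 2 mm spacing by
default. Lesion centers deliberately sit off the voxel grid: a sphere
centred exactly on a grid point is a worst case of voxelization (+9% for
1 cm³ at 2 mm), which no real lesion exhibits. Each tissue class follows an enhancement curve
`baseline + A · f(t)`:

* gamma-variate-like `f(t) = (t/tp)^s · exp(s (1 − t/tp))` for
  fast-peaking classes (tumor tp = 5 min, vessels tp = 3 min), anchored to
  the reported 3–8 min glioblastoma enhancement maximum;
* saturating exponential `f(t) = 1 − exp(−t/τ)` for scar/necrosis
  (τ = 12 min), still rising at the late scan;
* flat for normal brain and background.

Acquisition times default to t_early = 5 and t_late = 20 minutes,
matching a protocol with ~5 min injection-to-scan delay and ~15 min
between the two T1 acquisitions. With these defaults the early-minus-late
difference is +55 intensity units in tumor and −33 in scar before noise;
the scar amplitude (A = 70, τ = 12) was chosen so that wash-in remains
resolvable above the pipeline's default 3σ threshold at the SNRs
exercised (at SNR 20 the difference-noise σ is ≈ 7.8, threshold ≈ 23) —
a wash-in signal at the threshold would be undetectable by construction,
which is a statement about the generator, not the pipeline.

Normal brain carries a smooth, deterministic sinusoidal intensity
modulation (±10–16%, wavelengths 35–90 mm) anchored in world coordinates,
standing in for gray/white parenchymal structure. Without it the scene is
a uniform ellipsoid whose similarity cost is nearly pose-invariant, and
*no* registration algorithm could recover the pose — a property of real
brains the phantom must emulate, not an aid to any particular optimizer.

The late volume is rendered by evaluating the analytic scene at
inverse-transformed world coordinates, so the simulated misalignment
carries no interpolation error and the applied transform is exactly the
one registration should recover. Each series gets an independent smooth
multiplicative bias field (low-order random polynomial, default ±10%) and
Gaussian noise at the stated SNR (mean clean head intensity / σ); Rician
magnitude noise is available, and at the SNRs exercised (≥ 10) its
difference from Gaussian is negligible, which the tests quantify. The
generator is fully seeded and bit-reproducible.

What the phantom does *not* emulate: anatomical realism, pharmacokinetic
(Tofts-type) enhancement physics, pulse-sequence and k-space effects,
motion within a series, and partial-volume mixtures beyond voxelization
of analytic shapes. Passing the phantom harness therefore demonstrates
geometric and numerical correctness of the pipeline, not clinical
performance on patient data.

## Statistics layer

The agreement statistics mirror how such pipelines are evaluated:
ICC(2,k) — two-way random effects, absolute agreement, average measures —
from the ANOVA mean squares `(MSR − MSE) / (MSR + (MSC − MSE)/n)`, with
F-based confidence bounds computed for the single-measure form and
stepped up by Spearman–Brown, and the conventional
poor/moderate/good/excellent bands at 0.5 / 0.75 / 0.9 reported alongside.
The consistency-type ICC(3,k) is included because the contrast between
the two (a constant rater offset lowers ICC(2,k) but not ICC(3,k)) is the
standard sanity check of the absolute-agreement property. Pearson
correlation (with R² and the two-sided t-transform p-value), Tukey HSD
across subgroups (with the unadjusted pooled-variance pairwise p-values
reported next to the adjusted ones), paired/two-sample t-tests of
perfusion versus wash-out volumes, and Likert agreement summaries on the
0–100% scale complete the layer. The Likert SD convention defaults to
sample SD (n − 1), with population SD available; single-observation
subgroups report SD 0 with an explicit flag. p-values are descriptive
only — nothing in the pipeline branches on them.

Implementation note: mean squares, Tukey HSD, and t-tests come from base
R (`aov`, `TukeyHSD`, `t.test`, `cor.test`); the ICC assembly and its
confidence bounds are implemented here, and the test suite checks the
whole of ICC(2,k) against an independent from-scratch sum-of-squares
oracle to 1e-10 on 50 random tables.

## Numerical choices and degenerate inputs

* Geometry tolerance 1e-6 for orthonormality; grids compared at 1e-4 mm.
* Non-orthonormal NIfTI sforms are either orthonormalized via the polar
  decomposition or rejected, per a read option.
* Resampling is trilinear (nearest-neighbour for masks); out-of-field
  voxels carry `NA` and propagate into the valid mask, never into
  statistics.
* Constant images: bias correction returns an identity field with a flag;
  foreground masking and registration reject them.
* An all-zero difference encodes to a flat 127 with a warning; its noise
  scale is zero, so compartments are empty by construction.
* Registration falling behind the identity cost returns the identity with
  a failure flag, and the pipeline records that flag in the manifest.

## Problem sizes used by the test harness

The default conditions everywhere are the package's standard phantom:
96 × 96 × 72 voxels at 2 mm, SNR 20, ±10% bias, misalignments up to 5°
and 5 mm. The registration-recovery property runs 20 seeded draws; volume
recovery runs spheres of 1, 2 and 8 cm³ across 10 seeds each; encoding
and statistics properties run 100 and 50 random instances. Unit tests use
a compact 48 × 48 × 36 grid at 3 mm where full resolution adds nothing.

## Known limitations

* The registration precision floor (a few tenths of a degree/millimetre
  at SNR 20) is inherent to histogram-based costs on this scene; it is an
  order of magnitude below the voxel size and does not limit volumetry.
* The segmentation threshold is a stand-in for the raters' visual
  red/green criterion; no claim is made that k = 3 reproduces any
  particular rater.
* The DICOM layer reads uncompressed little-endian transfer syntaxes
  (explicit and implicit VR) and simple multi-frame objects; compressed
  syntaxes and per-frame functional-group geometry are out of scope.
* rCBV maps are consumed, never computed; vendor perfusion pipelines
  differ, and that variability is outside this package.
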