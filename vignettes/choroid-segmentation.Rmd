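---
title: "Choroid segmentation and scleral en-face analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choroid segmentation and scleral en-face analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octchoroid)
```

## The problem

Wide-field swept-source OCT volumes of the posterior pole image the retina,
the choroid and, at favourable signal levels, the sclera below the
choroid–sclera interface.  The short posterior ciliary arteries (SPCAs)
cross the sclera obliquely and enter the choroid; in scleral en-face slices
they appear as small hyporeflective dots or short tracks.  Counting and
localizing these entry sites requires three stages, all implemented here:

1. **Boundary segmentation** — find the choroid inner boundary (CIB, the
   retina/choroid interface at the base of the RPE complex) and the choroid
   outer boundary (COB, the choroid–sclera interface) in every B-scan of
   the volume, then make the surfaces consistent across B-scans.
2. **Flattening and en-face extraction** — shift every A-scan axially so
   the COB lies on a plane, and read constant-depth scleral slices and
   substack projections below it.
3. **Topography and validation statistics** — assign manually identified
   entry-site marks to a 3×3 grid of 4×4 mm sectors, apply the
   low-count exclusion rule, and quantify segmentation accuracy (Dice
   coefficients) and observer agreement (Pearson correlations of radial
   positions, with qualitative bins).

Volumes are held as 3D arrays `(axial z, lateral y, B-scan x)` with
0-based depth indices; tabular results (marks, sector distributions, Dice
and agreement reports) are tibbles with `tidy()`/`glance()`/`autoplot()`
methods.  The volumetric containers stay array-based S3 objects because a
per-voxel long table would be three orders of magnitude larger than the
image it describes.

## The enhancement model

All boundary evidence comes from one two-step intensity transform applied
per B-scan after preprocessing.  Writing $I(x,y)$ for the 8-bit gray level
at axial row $x$ (0-based) and lateral column $y$:

$$I_{raw}(x,y) = \left(\frac{I(x,y)}{255}\right)^{4}, \qquad
I_{expenh}(x,y) = \left(\frac{I_{raw}(x,y)}
{2\sum_{k=x}^{p} I_{raw}(k,y)}\right)^{n}, \qquad
I_{nonlin}(x,y) = x^{2}\, I_{expenh}(x,y),$$

with $n = 10$ and $p$ the last row of the column.  The fourth power
crushes moderate reflectivities so that the brightest layer dominates each
column's sums; the tail-relative ratio boosts the *last strong reflector*
along each A-scan (the denominator shrinks with depth, compensating signal
attenuation); the $x^2$ weight further emphasizes deep rows.  Because the
tail includes the pixel itself the ratio is bounded by $1/2$, so
$I_{expenh} \le 0.5^{\,n}$ everywhere; a zero tail maps to zero rather
than NaN (a fully dark column carries no boundary evidence).  Row indices
are 0-based, making row 0 a forced zero of $I_{nonlin}$; boundaries never
lie at row 0.

For the CIB the transform runs on the vertically flipped B-scan, so the
retinal complex sits at high row indices and saturates; for the COB it
runs in the original orientation, so the deepest choroidal tissue
saturates.  Both detectors then binarize at the mid-gray threshold 128 and
clean the mask morphologically (close, open, connected components).

### Numerical choices in the binarization

Two consequences of the $n = 10$ power required explicit decisions:

* **Per-A-scan normalization.**  After exponentiation the image spans tens
  of orders of magnitude; rescaling by the global maximum and cutting at
  128 keeps essentially one pixel.  The threshold is therefore applied
  after normalizing each column by its own maximum (the enhancement is a
  columnar operation; the binarization asks "which pixels dominate this
  A-scan").  Global normalization remains available via
  `segmentation_params(normalize = "global")`.
* **Tail margin.**  In the operating frame the ratio tends to $1/2$ at the
  last rows purely because the tail runs out, regardless of content.  A
  configurable fraction of rows at the tail end (default 0.1) is excluded
  before normalization so this geometric artifact cannot outvote real
  structure.

### Morphology defaults

The retained evidence is a thin (1–2 px) horizontal ribbon: the rows that
dominate their A-scans.  The defaults are sized for that shape: a disc
closing (radius 2) merges the closely spaced fragments, a 1×15 horizontal
line closing bridges breaks (without it the ribbon shatters into
components of a few dozen pixels), a 1×3 horizontal opening removes
isolated specks, and the component-area filter keeps components of at
least 0.1% of the B-scan area — large enough to reject speckle clusters,
small enough that ribbon chunks survive.  Wholesale-layer area thresholds
(≥0.5%) reject the ribbon itself and are not usable here.

## Boundary detection

**CIB.**  The cleaned mask of the flipped, enhanced B-scan contains the
bright retinal base.  Per column, the deepest retained pixel after
un-flipping is the boundary facing the choroid.  Columns without retained
evidence become `NA` gaps.  A scan whose whole trace is empty — or whose
trace jumps more than `trace_roughness_max` (5 px) between neighbouring
columns in the median, the signature of incoherent evidence — is flagged
empty and inherits its trace from the orthogonal smoothing.

**COB.**  The original-orientation mask is restricted to the region safely
below the final CIB, cleaned, and reduced to per-column *extreme points
towards the sclera* (the deepest retained pixel).  Extreme points lying
more than `envelope_tol` (6 px) above the deepest extreme point within one
voting scale are discarded: such points sit on top of a vessel lumen, not
on the interface.  The surviving sparse points are interpolated into a
continuous trace by tensor voting.

**Tensor voting.**  Sparse anchors are completed with a first-order
stick-voting scheme: each anchor receives a tangent from a
Gaussian-weighted least-squares fit over its neighbours; anchors then vote
for each other along their tangent lines, with strength decaying in both
column distance and prediction disagreement, which yields a saliency per
anchor (mutually consistent anchors reinforce, isolated outliers fade);
tangents are re-estimated with saliency weights; finally every output
column takes the saliency-weighted mean of the tangent-line predictions.
Outside the anchored span the trace continues at the boundary value —
tangent extrapolation over tens of unanchored columns is the one place the
scheme can run away, and a flat continuation is the conservative choice.
Collinear anchors reproduce their line exactly; a single anchor gives a
constant trace.

**Orthogonal smoothing.**  Initial traces are stacked into a surface
`(lateral y × B-scan x)` and smoothed across the B-scan index with robust
LOESS (local quadratic, bisquare reweighting, 5 robustness iterations),
which fills gaps and rejects per-B-scan spurious detections; each B-scan's
trace is then regularized by dense tensor voting along its columns.  The
LOESS span default is 0.2: the local window must hold clearly more inliers
than any run of correlated spurious traces, and at 64 B-scans a 0.1 span
(7 points) both fails that requirement and lets the end windows of the
local quadratic overshoot by tens of pixels.  Predictions are clamped to
the observed range of each series for the same reason.

**Volume-level contracts.**  `segment_volume()` aborts when more than half
the B-scans carry no evidence, when the initial CIB estimates deviate from
the volumetric consensus by more than 8 px in the median, or when the
median segmented thickness exceeds half the axial depth.  The last check
matters because the tail-relative enhancement *fabricates* a smooth
pseudo-boundary near the tail margin when fed structureless input (pure
speckle): the per-B-scan traces look locally plausible, but the implied
"choroid" spans most of the A-scan, which real anatomy never does.
Where the final surfaces cross, the COB is clamped to CIB + 1 and the
count reported.

## Flattening and en-face extraction

Each A-scan is shifted down by `plane − COB` pixels (integer mode,
bit-exact and invertible via the recorded shift map; vacated voxels fill
with 0, which reads as no-signal, like the optic-nerve shadow).  The
default plane is the maximum COB depth.  A sub-pixel mode using linear
interpolation is available for smoother slices but is not invertible.
En-face slices are read from the plane downward; substack projections
(mean or minimum intensity over 5–30 consecutive slices) confirm that a
dark spot persists across depths rather than being speckle.  Substack
choice remains with the user; `suggest_substack()` only ranks windows by
dark-tail contrast.

## Sector topography

The 12×12 mm field divides into nine 4×4 mm cells,
`floor(position / 4)` per axis with half-open cells and the far edge
closed.  Vertically, smaller `y` (upper image) is superior.  Horizontally
the temporal retina lies image-left for a right eye (OD) and image-right
for a left eye (OS) in fundus orientation; a config argument can override
the convention if source images are displayed differently.  Eyes with
fewer than 10 identified arteries are excluded — the minimum SPCA count
known from histology.  Cohort summaries use the sample (n−1) SD;
percentages are kept at full precision, with half-away-from-zero rounding
for report tables.

## Validation statistics

The Dice coefficient between the pixel-index sets of two thickness
measurements at one A-scan is $2|C_x \cap C_y| / (|C_x| + |C_y|)$.  Three
set constructions are provided: top-to-CIB, top-to-COB (each validating
one boundary) and the CIB-to-COB band.  Two empty sets score 1 (both
raters agree there is no tissue).  The "mean rater" reference averages two
segmentations per A-scan, rounding half up.  Reports aggregate per B-scan
and overall mean (SD).

Observer agreement works on the radial position
$Z = \sqrt{X^2 + Y^2}$ of each mark in pixels from the bottom-left image
corner; a mark is consistent with an expert position when
$|Z - \sqrt{X^2+Y^2}| < \varepsilon$, with $\varepsilon$ defaulting to
1.5 px.  The radial scalar discards angular information — marks at equal
distance from the corner are indistinguishable — a limitation inherited
from the definition, which the package follows literally.  Marks of paired
trials are matched greedily by nearest neighbour; Pearson correlations are
computed per eye (intra-observer pairs trial $t$ with $t+1$;
inter-observer pairs the two observers), summarized by the median over
eyes, computed as the mean of the two middle order statistics for even
counts.  Qualification bins on $|r|$: below 0.20 very weak, 0.20–0.40
weak, 0.40–0.60 moderate, 0.60–0.80 strong, above 0.80 very strong; a
value exactly on an edge belongs to the higher bin, and magnitude is used
so that a negative correlation is labelled by strength with its sign
reported separately.

## The synthetic phantom

No clinical volumes are distributable, so every pipeline stage is
exercised on phantoms with exact ground truth.  A phantom stacks, from the
top: a vitreous noise floor (35), a dim inner retina (55) over a thin
bright RPE band (240, 3 px) whose base is the true CIB; a bright choroidal
stroma (150) carrying dark elliptical vessel lumens (40) biased to the
deep half of the band, as the large vessels of Haller's layer are; a
dimmer sclera (70) crossed by oblique dark SPCA tracks (20) entering at
known positions.  All layers ride a bowl-shaped warp (12 px at the field
corners), intensities decay as $e^{-0.005 z}$, and multiplicative
mean-1 Gamma speckle of variance 0.15 is applied before 8-bit
quantization.  The default grid is 256 axial × 256 lateral × 64 B-scans
over a 12 mm field — large enough for the 6×6 filtering, the CLAHE tiling
and the cross-B-scan smoothing to operate as at full scale, small enough
that a volume segments in well under a minute; full-scale
1024×1536×1024 generation is supported but not default.

Two reflectivity relations are deliberate, not cosmetic, because the
enhancement depends on them: the RPE must dominate the integrated signal
of everything below it in the flipped frame (hence a *thin bright base
under a dim inner retina* — a uniformly bright 40-row "retina" would
saturate at its inner surface instead, and the detector would report the
vitreoretinal interface), and the sclera must be dimmer than the stroma so
the deepest strong reflector is the interface, as in real swept-source
scans where the signal fades below the COB.  The phantom does not model a
point-spread function, polarization, vessel continuity across B-scans,
the optic nerve head, or pathology; passing tests demonstrate correct
recovery under the stated contrast relations and speckle, not performance
on diseased or low-quality clinical scans.

Observer behaviour is simulated by `perturb_marks()`: each true entry site
is dropped with probability 0.05 (a missed vessel) and otherwise jittered
isotropically with SD 0.2 mm (localization error); these defaults give
simulated-observer agreement in the same qualitative regime as trained
human observers, and the agreement statistics degrade monotonically as
jitter grows.

## Worked example

```{r example, eval = FALSE}
ph  <- generate_phantom(phantom_spec(seed = 1))
seg <- segment_volume(ph$volume)
glance(seg)

dice_report(seg, list(cib = ph$truth$cib_true, cob = ph$truth$cob_true),
            boundary = "band")

fl <- flatten_volume(ph$volume, seg$cob)
st <- extract_enface_stack(fl, max_depth_px = 40)
proj <- project_substack(st, first = 3, count = 10, mode = "mean")

marks <- ph$truth$spca_marks_true
autoplot(compute_distribution(marks, laterality = "OD"))
```

Problem sizes used by the test suite: the acceptance properties run five
default-scale phantoms (seeds 1–5, speckle 0.15); module tests use reduced
grids (24 B-scans, 128 lateral columns) where full scale adds nothing to
the property under test.

## Known limitations

* The binarization-normalization and tail-margin choices are this
  package's resolution of an under-determined step; results on real
  volumes may need `binarize_threshold`, `tail_margin_frac` or the
  morphology defaults adjusted to the device's noise floor.
* The COB estimate rides the deepest *detected* tissue; where the deepest
  choroidal vessels sit well above the interface, or scleral reflectivity
  rivals the stroma, the trace biases shallow.
* No pathology handling (staphyloma, choroidal neovascularization), no
  intra-retinal layers, no automated SPCA detection — en-face marks are an
  input, produced manually or by the phantom truth.
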