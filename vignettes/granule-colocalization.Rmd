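---
title: "Quantifying RNA-granule co-localization and trafficking with granuloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNA-granule co-localization and trafficking with granuloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granuloc)
```

## Scope and model

`granuloc` quantifies multichannel confocal acquisitions of neuronal RNA
granules: fixed-tissue z-stacks carrying an mRNA FISH channel and one or
two immunofluorescence protein channels, and single-plane two-channel
time-lapse series of moving granules. The analysis is *object-based* (a
number-based analysis of discrete puncta), not intensity-correlation
based: the unit of evidence is a detected punctum, and co-localization is
a decision about pairs of puncta, not a correlation of pixel intensities.
Pearson- or Manders-style coefficients are deliberately out of scope.

All arrays are indexed `[z, y, x]`, 1-based, following R convention; a 2D
image is a single-slice stack. Physical calibration travels in a
`voxel_geometry` object (configs, not TIFF tags, carry it: proprietary
microscope containers are not parsed).

## Puncta detection

A punctum is a connected set of voxels with intensity strictly greater
than the *local* background mean plus twice the local standard deviation.
Local statistics are moving window estimates computed per optical section
with symmetric (mirrored) borders and the sample (n − 1) variance
convention.

Tunable parameters, defaults, and rationale:

* `window` (px, default 31): no window size is canonical; it must be much
  wider than a punctum (a few px) yet narrower than the scale of somatic
  background variation. 31 px ≈ 5.5 um at 0.176 um/px satisfies both for
  cortical neurons.
* `min_size` (voxels, default 4): suppresses single-voxel noise
  excursions, which at a 2-SD threshold are expected by chance; visible
  granules occupy several voxels.
* Connectivity (default face/6-neighbour): conservative, splitting
  adjacent granules rather than fusing them.
* The threshold inequality is strict (`>`), so a constant image yields no
  detections even with zero variance.

Background statistics include foreground voxels (no iterative masking).
This is the simplest faithful reading of a "local background" rule and
slightly inflates the threshold near bright clusters; iterative
refinement would be a natural extension.

Counts from a sampled subset of grid squares extrapolate to totals by
`count_total_events()` (mean per square × number of squares). The grid
geometry is the user's choice — no square size is canonical — so it is a
parameter, not a default. The pipeline warns when fewer than 1500 puncta
enter an analysis, the conventional minimum for stable percentages.

## Object-based co-localization

For puncta $a$, $b$ from different channels the overlap fraction is

$$\omega(a,b) = \frac{|V_a \cap V_b|}{\min(|V_a|, |V_b|)}$$

and the pair is co-localized when $\omega > 0.30$ (strict). Normalizing
by the smaller object was a genuinely open choice (alternatives: the
reference object, or the union); the smaller-object denominator keeps the
criterion symmetric and counts a small mRNA granule sitting inside a
larger protein cluster as fully overlapping, which matches the visual
reading of merged images. A reference punctum with several partners at
20% each is *not* co-localized: overlap is per-pair, never pooled.

Percent co-localization is directional — each reference punctum with at
least one co-localized partner counts once, divided by the reference
count — so A-vs-B and B-vs-A generally differ whenever the two channels
have unequal event counts. Triple co-localization counts reference
puncta pairwise co-localized with a member of each of the other two
channels. Analysis runs in native voxel space (3D when `z > 1`),
avoiding projection-induced false overlaps.

## Seven-color segmentation

For visualization, each pixel of a three-channel composite is classified
by the minimal angular deviation between its RGB vector and seven edge
vectors — the primary corners (255,0,0), (0,255,0), (0,0,255), the
secondary corners, and white (255,255,255):

$$\theta(p, e) = \arccos\frac{p \cdot e}{\lVert p\rVert\,\lVert e\rVert}$$

Numerical choices: angles are computed in double precision on
unnormalized vectors via cosine similarity; ties within a cosine
tolerance of 1e-9 go to the first class in the documented order (red,
green, blue, yellow, magenta, cyan, white) — ties lie on measure-zero
planes, so determinism matters more than the choice. Zero-norm pixels,
where the angle is undefined, form an eighth *unclassified* label
excluded from every pseudo-channel; after background subtraction the
default `background_threshold = 0` unclassifies exactly the zero pixels.
Because angles are scale-free, classification is invariant under
intensity rescaling, and the seven pseudo-channels are by construction
disjoint and jointly cover the classified pixels.

Background subtraction precedes segmentation; two estimators are
provided (global percentile; rolling-ball as a grayscale morphological
opening residue per slice, via EBImage) since no particular algorithm is
canonical for this step.

## Projection

`slice_spacing(pixel_count, z_interval, field_size)` converts the
optical-section interval to lateral pixel units — for a 512-px, 90-um
field at 0.5-um sections, 512 × 0.5/90 = 2.844 px (reports render two
decimals). Rotation series use brightest-point projection about the
y-axis after rescaling z by this factor; 0° (and any multiple of 360°)
takes a fast exact path identical to the plain maximum projection.
Off-axis views sample viewing rays on an integer-anchored depth grid with
trilinear (or nearest-neighbour) interpolation, so axis-aligned views
land on voxel planes. Depth cueing is available as a linear attenuation
but is off by default — it is cosmetic and enters no quantitative result.

## Trafficking

Linking is greedy nearest-centroid between consecutive frames: candidate
(track end, punctum) pairs are accepted in order of increasing distance,
rejecting steps beyond `max_step`; ties break by lower track id then
punctum id. A missed frame terminates a track (gap tolerance 0) —
conservative, preferring a broken track over an identity switch. Live
imaging is single-plane, so tracking is 2D. Frame time and frame
interval are both carried as independent config metadata.

Travel distance sums consecutive centroid displacements × pixel size.
One caveat the acceptance measurements respect: when the per-frame
displacement is small compared with centroid localization error
(sub-pixel steps), summed path length is biased upward, because each
step's error contributes its magnitude. Sampling so that per-frame
displacement is ≳1 px removes the bias; this is a property of any
summed-displacement estimator, not of the implementation.

## The simulator and what passing tests mean

`simulate_stack()` renders each punctum as a 3D Gaussian (axial width
2× the in-plane `punctum_sigma`, the standard confocal axial elongation)
over a planar background gradient with Gaussian read noise, clamped to 8
bits — 8-bit output matches the 0–255 RGB model of the segmentation.
Planted co-localization: `ceiling(coloc_fraction × n_puncta)` shared
sites per channel pair (partners jittered < 0.5 px), optionally a triple
fraction shared by all three channels; all other sites keep a minimum
separation of 4 PSF widths so chance overlap does not contaminate the
planted fraction, making `expected_coloc()` a clean recovery target.
`simulate_timelapse()` moves granules at constant velocity in random
directions with optional positional jitter; a planted fraction of
channel-1 granules has a co-moving channel-2 partner. Paths that would
exit the field are truncated with a warning.

Default conditions (256 × 256 × 8 voxels at 0.176 um/px and 0.5 um
sections, 200 puncta per channel, amplitude 150 over background 20 with
noise SD 8) emulate a cortical-tissue field at the scale used for the
recovery studies; the test suite and acceptance script run these and
smaller fields (down to 64 × 64) to keep runtimes in minutes.

What the simulator does *not* emulate — and hence what passing recovery
tests cannot certify on real data: empirical granule intensity
distributions (granules holding up to ~30 RNA molecules vary widely in
brightness), non-Gaussian PSF structure, autofluorescence texture,
photobleaching, and dendrite morphology. Recovery results certify the
computational chain, not the imaging.

## Known limitations

* No spot-PSF fitting, deconvolution, or watershed splitting of merged
  granules: overlapping same-channel granules are detected as one.
* Background estimation is non-iterative (see above).
* Tracking is greedy, not a global assignment (no Kalman/LAP); adequate
  for sparse granules, not for dense crossing traffic.
* Saturated pixels receive no special treatment in segmentation.
* Movie encoding is out of scope; rotation series export as multipage
  TIFF frame sequences.
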