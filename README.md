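# granuloc

Object-based co-localization and trafficking analysis of multichannel
confocal images of neuronal RNA granules.

## The problem

Neuronal RNA granules carry mRNAs (such as BDNF mRNA) together with
RNA-binding and motor proteins along dendrites. Establishing that an mRNA
and a protein travel in the *same* granule relies on multichannel confocal
imaging of FISH plus immunofluorescence, followed by quantification:
detecting discrete fluorescent puncta in each channel, deciding which
puncta from different channels occupy the same site, and — in live
imaging — showing that two labels move together over time. `granuloc`
implements that quantification chain with a synthetic ground-truth
simulator so every stage can be validated without microscopy data.

## The methods at its core

- **Puncta detection.** A punctum is a connected region of voxels whose
  intensity `I(v)` satisfies `I(v) > mu(v) + 2 sd(v)`, where `mu` and `sd`
  are the moving mean and standard deviation of a local background window
  (default 31 px, per optical section). Components smaller than
  `min_size` voxels (default 4) are discarded; centroids are
  intensity-weighted.
- **Object-based co-localization.** For puncta *a*, *b* from two
  channels, the overlap fraction is `|a ∩ b| / min(|a|, |b|)`; the pair
  is co-localized when this strictly exceeds 30%. Percent
  co-localization is directional:
  `100 × (# reference puncta with ≥1 co-localized partner) / (# reference puncta)`.
  Triple co-localization counts puncta pairwise co-localized with both
  other channels — a quantity conventional scatterplot-based tools cannot
  produce.
- **Seven-color segmentation.** Each pixel of a three-channel composite
  is assigned to the RGB-cube corner color (red, green, blue, yellow,
  magenta, cyan, white = (255,255,255)) whose *edge vector* has minimal
  angular deviation from the pixel's RGB vector, yielding seven binary
  pseudo-channels that display single targets and every pairwise/triple
  overlap separately.
- **3D projection.** Maximum-intensity projection and brightest-point
  rotation series about the y-axis, with the z-axis rescaled to pixel
  units by `slice_spacing = pixel_count × z_interval / field_size`
  (e.g. `512 × 0.5 / 90 = 2.84 px`).
- **Trafficking.** Greedy nearest-centroid linking of puncta across
  time-lapse frames; travel distance is the summed centroid displacement
  times the pixel size; co-trafficking is the fraction of tracks with a
  sustained (≥ `min_overlap_frames`) partner within `max_sep`.

## Worked example

```r
library(granuloc)

# simulate a 3-channel stack: 200 puncta/channel, 30% planted pairing
sim <- simulate_stack(sim_params(coloc_fraction = 0.30, seed = 7))
ps <- lapply(names(sim$stack$channels), function(nm) {
  ch <- sim$stack$channels[[nm]]
  detect_puncta(ch, estimate_local_background(ch, 31), channel_name = nm)
})
percent_colocalization(ps[[1]], ps[[2]])
#> ch1 vs ch2: 60 / 200 co-localized (30.0%, overlap > 30%)

slice_spacing(512, 0.5, 90)
#> [1] 2.844444
```

The printed co-localization line reads: of 200 detected `ch1` puncta, 60
had a `ch2` punctum overlapping by more than 30% of the smaller object —
30.0% directional co-localization, matching the planted fraction.

A complete run (segmentation, detection, co-localization report,
projections) is driven by a YAML config through `run_pipeline()`, or from
a shell via `inst/cli/granuloc run <config>`; the config declares the
TIFF, channel names (pages interleaved by slice, channel fastest), and
the voxel geometry in micrometres.

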