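---
title: "Multi-threshold puncta detection and dendrite quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-threshold puncta detection and dendrite quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctanal)
```

## The problem

Synaptic proteins such as PSD-95 concentrate at synapses and appear as
small bright clusters — *puncta* — in immunofluorescence images of
neurons. Changes in puncta density and intensity along dendrites proxy
changes in synapse number and strength, so quantifying them is a routine
but laborious measurement. The classical operational definition is a
connected cluster of at least four adjacent pixels above an intensity
threshold. Its well-known failure mode is that two bright puncta lying
close together merge into a single component once the threshold is set
low enough to capture dim puncta, which under-counts density and inflates
per-punctum intensity.

## The detection model

`detect_puncta()` addresses the merging problem with a descending
multi-threshold sweep. For thresholds $t = t_{\mathrm{start}},
t_{\mathrm{start}} - s, \dots, t_{\min}$ (the final round always runs at
exactly $t_{\min}$, even if the step overshoots):

1. **Candidates.** All unassigned in-mask pixels with intensity $\ge t$
   (the comparison is inclusive, so $t_{\mathrm{start}} = 255$ can seed
   saturated pixels).
2. **Expansion.** Existing puncta absorb adjacent candidates, iterating
   to a fixed point within the round (a pixel assigned this round can
   recruit its neighbours this round). A candidate adjacent to two or
   more puncta joins the punctum of its *brightest* assigned neighbour,
   ties to the lowest label. This steepest-ascent rule makes boundaries
   follow intensity ridges, which is precisely what keeps adjacent
   puncta distinct.
3. **Formation.** Remaining candidates are grouped into connected
   components; components with at least `min_size` pixels (default 4)
   become new puncta. Smaller components stay unassigned and are
   reconsidered at every later round.

Because bright peaks seed separate puncta at high thresholds, a pair of
puncta whose connecting saddle exceeds $t_{\min}$ is still reported as
two objects, whereas a single threshold at $t_{\min}$ reports one. With
$t_{\mathrm{start}} = t_{\min}$ the sweep degenerates exactly to
single-threshold connected-component labelling — `single_threshold_detect()`
implements that baseline through an independent code path (an igraph
components labelling), and the test suite asserts the equivalence on 100
random images.

Per punctum the package reports pixel area, physical area, *integrated
intensity* (exact integer sum of pixel values), *average intensity*
(integrated / area) and the centroid. Both the mean of per-punctum
average intensities and the mean of per-punctum integrated intensities
are exported per dendrite, because the field uses both under the name
"average intensity"; the per-punctum `average_intensity` column always
means integrated / area.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `t_min` | user-set (70 typical) | final threshold; sets sensitivity, like the manual threshold |
| `t_start` | 255 | first threshold of the sweep |
| `step` | 1 | per-round decrement; with exhaustive per-round expansion, results are insensitive to it whenever all intermediate saddles are crossed |
| `min_size` | 4 px | classical minimum cluster size |
| `connectivity` | 8 | pixel adjacency for expansion and formation |

Thresholds are intensities on the 8-bit scale. Images with more than 8
bits per channel are rescaled linearly by the *container's* declared bit
depth, never by the data range, so one threshold remains comparable
across all images of a batch.

## Regions, spines and aggregation

Analysis is restricted to user-supplied regions of interest, read from a
JSON sidecar next to each image. A *dendrite region* is either a
fixed-width band around a centerline (`buffer_centerline()`: per-segment
rectangles, round end caps and round joins discretized at 24 points per
half-circle; the inner side of an elbow uses the miter point, capped at
four half-widths for near-reversals) or a freehand polygon plus
centerline. Polygons are rasterized by a pixel-center even-odd rule with
0-based integer pixel-center coordinates; detection candidates are
clipped at the region boundary, so a punctum straddling the outline is
truncated to its in-mask pixels. The transfection-marker filter
(`filter_by_marker()`) removes puncta that do not overlap the cell-fill
channel; "overlap" defaults to a single pixel at or above the marker
threshold, configurable as a minimum overlap fraction.

Spines are measured from manually placed landmarks (base, tip, and
optional head/neck edge pairs) and classified by fixed-order rules:
filopodia (head/neck $< 1.2$ and length $\ge 2\,\mu m$), then mushroom
(head/neck $\ge 1.5$), then stubby (length/head $\le 1$), else thin.
The published descriptions of these morphologies do not fix numeric
cut-offs, so these defaults are this package's own, chosen to match the
conventional descriptions (mushroom: pronounced head over a narrow neck;
filopodia: long, headless; stubby: about as long as wide); every
threshold lives in `spine_rules()` and is echoed into the run metadata so
results are self-describing. When no neck width was measured the ratio
rules are skipped and a mushroom call requires an absolute head width of
$0.6\,\mu m$; a headless protrusion of filopodial length is a
filopodium. Manual categories always survive re-classification.

The statistical unit of aggregation is the dendrite: group summaries are
unweighted means and standard deviations across dendrites, which is not
the same as pooling puncta across dendrites of different lengths — the
pooled density is additionally exported under an explicit
`pooled_` name. Exports are four TSV files (`puncta.tsv`,
`dendrites.tsv`, `spines.tsv`, `groups.tsv`) plus `run_metadata.json`;
numeric fields are written with 17 significant digits so they re-parse
to the exact in-memory values, with `.` as decimal separator regardless
of locale. When `pixel_size = 1` (uncalibrated) all "per µm" quantities
are per pixel and a warning is raised.

Batches apply one configuration across an image set; a threshold
override at any image carries forward to all subsequent images, and the
exact threshold used per image is recorded in the metadata JSON as an
audit trail. Per-image failures are warnings, not errors.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` renders puncta as isotropic 2D Gaussians on a
constant background, with optional bounded uniform noise, clipped to
0–255 and rounded; the ground truth records every center, amplitude and,
for every pair, the saddle (minimum of the continuous two-Gaussian field
along the segment joining the centers). This captures exactly the
geometry the detector reasons about — peaks, saddles, thresholds — and
supports three test families:

* **Equivalence**: with `t_start = t_min` the sweep must reproduce the
  single-threshold partition on arbitrary random images.
* **Split recovery**: `two_blob_merge_case()` engineers pairs whose
  saddle lies strictly between `t_min` and the lower peak, so a single
  threshold merges them while the sweep reports two. Feasibility is
  certified on the *discrete* image, not only on the continuous field:
  the function also requires each peak to carry an isolated component of
  at least `min_size` pixels at the decisive threshold (one increment
  above the discrete saddle for merge cases; `t_min` for separated
  controls). Without this check the continuous criterion alone admits
  parameter combinations — small sigmas with high saddles — where the
  dimmer peak's isolated cluster never reaches four pixels and no second
  punctum can form; such combinations are rejected with the computed
  saddle in the error message.
* **Ground-truth recovery**: well-separated blobs (`min_separation`
  large enough that saddles stay below threshold) with noise amplitude
  chosen inside the saddle-threshold margin must be recovered at exactly
  the planted count, with centroids within 1.5 px.

The generator deliberately does not emulate real neuron images: no
dendritic shaft fluorescence, no spine-shaped structures, no shot noise,
no anisotropic point-spread function, no uneven background. Passing
tests therefore demonstrate the correctness of the algorithmic
contracts, not field performance on real tissue; on real data, threshold
choice and region placement remain the user's scientific decisions.

## Numerical choices and degenerate inputs

* Ties during expansion (equal neighbour intensity) go to the lowest
  label; new labels are assigned in row-major order of each component's
  topmost-leftmost pixel. Identical inputs always produce identical
  labels and statistics.
* Puncta brought into contact by expansion are never re-merged.
* An empty region mask yields an empty result, not an error; a polygon
  covering no pixel center rasterizes to an empty mask with a warning.
* Integrated intensities are exact integer sums; the identity
  `average_intensity * area_px == integrated_intensity` holds to within
  one floating-point rounding.
* Problem sizes used by the validation suite — 100 random 256×256
  images for equivalence/monotonicity, a 720-point two-blob parameter
  grid, 100 noisy 192×192 recovery images, 5-image batch replications —
  were chosen so the whole suite completes in a few minutes on a single
  core while still exercising 5–30 overlapping blobs per image.

## Known limitations

* GIF input is not supported (no installed reader); TIFF and PNG are the
  recommended formats, JPEG is accepted with a lossy-compression
  warning.
* The fixed-width band outline is a discretized round-join buffer; its
  area differs from the exact buffer by the arc-chord error (below 1%
  at the default 24 points per half-circle).
* Automatic threshold selection, dendrite tracing, watershed-style
  segmentation and z-stack analysis beyond maximum projection are out of
  scope by design.
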