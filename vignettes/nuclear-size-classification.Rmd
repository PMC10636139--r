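---
title: "Nuclear-size classification of lymphoma tiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear-size classification of lymphoma tiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmorph)
```

## The problem

Histological subtyping of lymphoma uses the nuclear size of the neoplastic
lymphocytes — small, intermediate, or large — as a key feature. Visual
estimation against red blood cells is poorly reproducible: red-blood-cell
size varies between species, and suitable reference cells may be absent from
the tumor region. `nucmorph` implements the measurement-based alternative:
given a segmentation mask of lymphocyte nuclei (from any segmentation
backend — the package deliberately knows nothing about neural networks) and
the pixel resolution, it measures every nucleus in micrometres, filters
implausible objects, classifies each nucleus against the mean diameter of
small non-neoplastic lymphocytes, and classifies the whole tile by majority
vote. Every intermediate result is retained, so each image-level call can be
audited object by object.

## The procedure

1. **Instance labeling.** Binary masks are converted to instances by
   8-connected components labeling. 8-connectivity was chosen because it
   does not split thin diagonal boundaries; labels are issued in raster-scan
   order of each component's first pixel, so labeling is deterministic.
2. **Morphometry.** For each object with pixel count $A$ at resolution $s$
   µm/px the package computes the convex-hull solidity $r_1 = A/A_{hull}$,
   the circle ratio $r_2 = A / (\pi (F/2)^2)$ where $F$ is the maximum
   Euclidean distance between border-pixel centers, the circularity
   $c = (r_1 + r_2)/2$, and the equivalent circular diameter
   $d = 2\sqrt{A/\pi}\,s$. A perfect circle scores 1 in both ratios.
3. **Filtering.** Objects below 1 µm² are removed as labeling artifacts;
   objects with $c \le 0.5$ are removed as non-elliptical (typically merged
   neighbouring nuclei). Exclusion reasons are recorded per object and
   summarized as the dropout rate.
4. **Classification.** Each kept nucleus is classified by its ratio
   $\rho = d/r_{ref}$ to the species reference diameter (dog 4.14 µm, cat
   4.17 µm): small for $\rho \in [1, 1.21)$, intermediate for
   $[1.21, 1.5)$, large for $[1.5, 2.24]$ with the default, optimization-derived
   thresholds. Ratios outside $[1, 2.24]$ are excluded from the vote but
   reported.
5. **Majority vote.** The image class is the most frequent nucleus class;
   ties break toward the larger class — the diagnostically conservative
   direction for lymphoma grading — and are flagged.

```{r example}
scene <- generate_scene(generator_config(
  image_size_px = c(512L, 512L), n_objects = 50L,
  merged_pair_fraction = 0.1, seed = 7L))
report <- run_workflow(scene$mask)
report
```

## Threshold optimization

The four thresholds are tuned by exhaustive grid search
(`optimize_thresholds()`): all strictly ordered combinations from
per-parameter ranges (defaults: small lower 1.00–1.29, small upper
1.18–1.24, intermediate upper 1.35–1.51, large upper 2.00–2.59, step 0.01;
149,940 candidates) are scored by macro-averaged F1 of the per-image
majority classifications against expert consensus labels. Macro averaging
was chosen because the optimization datasets are curated to be roughly
class-balanced, where macro and weighted averaging nearly coincide, and
macro is the stricter choice. The search is vectorized — per-image counts of
size ratios below each grid value are precomputed, making each candidate two
subtractions per class — and the full default grid scores in about a second;
results are bit-identical to scoring candidates one at a time, which the
test suite asserts. Among tied candidates the first in lexicographic
enumeration order is returned and all ties are listed.

Grid values are materialized as exact decimals at the step's precision
before any comparison, so boundary classifications are reproducible across
platforms.

## Numerical choices

* **Hull area by Pick's theorem.** Object pixels have integer center
  coordinates, so the number of pixel centers inside or on the convex hull
  is an exact lattice count: $A_{shoelace} + B/2 + 1$, with $B$ the number
  of lattice points on the hull boundary (edge-wise gcd). This keeps both
  circularity ratios on the same pixel-count footing with no rasterization
  of the hull polygon, and is exact and platform-independent. Collinear
  objects fall back to the lattice count on the segment.
* **Maximum border distance.** Border pixels are object pixels with at
  least one non-object 4-neighbor. Distances are measured between pixel
  centers without any +1 px padding; the maximum is found over convex-hull
  vertices of the border set (equal to the full pairwise maximum). A
  single-pixel object has $F = 0$ and gets circle ratio 1 by convention —
  such objects never survive the minimum-area filter. On coarse rasters the
  circle ratio can marginally exceed 1 (e.g. a rasterized disk whose border
  centers lie slightly inside the true circle); it is reported as computed,
  not clamped. For a filled square of side $n$ px the convention gives
  $r_2 = 2n^2/(\pi (n-1)^2) \to 2/\pi$, about 0.67 at $n = 41$.
* **Interval conventions.** Small and intermediate are half-open
  $[lower, upper)$; large is closed at the top so that $\rho$ exactly at
  the largest threshold is still classifiable. "Above 0.5" for the
  circularity rule is a strict inequality, read literally; boundary cases
  are measure-zero on real data.
* **Degenerate inputs.** An image with no classifiable nucleus raises an
  explicit "unclassifiable image" error rather than defaulting silently;
  during optimization such images count as wrong for their labeled class.
  Detection metrics with empty denominators report 0 and set a degenerate
  flag.

## What the synthetic generator emulates — and what it does not

`generate_scene()` renders fields of elliptical nuclei at 0.25 µm/px on
1024 × 1024 tiles by default, with per-class equivalent-diameter bands equal
to the classification bands times the reference diameter, axis ratios
1–1.6, and at least 2 px separation between distinct objects. Diameters are
drawn uniformly within bands (not Gaussian) so that class membership is
unambiguous in recovery tests. Pixel-center rasterization is used
throughout, and the generator resamples placements whose rasterized area
deviates more than 5% from the drawn diameter's implied area, so generator
truth and morphometry agree closely.

**Merged objects.** Under-segmentation artifacts are rendered as two nuclei
joined by a thin (≈2 px) bridge at a center distance of 1.9× the sum of
their effective radii. This is a deliberate design point: two *overlapping*
convex blobs never fall below the 0.5 circularity rule (two touching disks
of equal radius score ≈0.69, and ≈0.71 when overlapping with centers at
0.95 diameters), so simple overlapping pairs would not emulate the objects
the filter removes. The bridge morphology — two cell bodies connected by a
thin neck of boundary pixels — is what semantic-segmentation output actually
produces for adjacent nuclei, and it scores ≈0.42–0.45, reliably below the
rule. With this morphology the dropout rate tracks the merged fraction
closely.

**Measurement sets.** `generate_measurement_set()` emulates the
optimization dataset: per image one consensus label and 20–60 diameters.
Besides generic images drawing uniformly from the interior of their class
band, it produces *boundary-informative* images whose majority mass hugs one
band edge (within 0.004 multiplier units) with minority mass in an adjacent
band, so that moving that threshold by one 0.01 grid step flips the image's
majority class. This is not an embellishment but an identifiability
requirement: under image-level majority-vote scoring, data drawn purely from
band interiors leaves the F1 landscape flat around the true edges (many tied
perfect candidates), and no optimizer could recover the thresholds to grid
precision. Real optimization sets contain such near-boundary cases —
tumors whose nuclei straddle a class boundary are exactly the hard cases the
thresholds are fitted on. With zero noise the band edges are then uniquely
recoverable; Gaussian measurement noise (`noise_sd_um`) blurs the pins and
the attainable F1 decreases, which the test suite checks in expectation
over seeds.

The generator does **not** emulate H&E texture, staining variation, scanner
domain shift, out-of-focus regions, or the spatial correlation of real
nuclei. Passing tests therefore demonstrate the correctness of the
measurement, filtering, classification, optimization and evaluation
machinery on known geometry — not the segmentation quality of any neural
network, nor end-to-end accuracy on real slides, which depends on the
upstream segmentation model.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `um_per_pixel` | 0.25 | µm/px | 400× scans; every physical quantity scales by it |
| reference diameter | 4.14 (dog), 4.17 (cat) | µm | mean of 100 small non-neoplastic lymphocytes per species |
| `min_area_um2` | 1 | µm² | removes labeling artifacts below any plausible nucleus |
| `circularity_threshold` | 0.5 | — | empirically determined separation between single nuclei (≥ ~0.8 in practice) and bridge-merged objects (≤ ~0.45) |
| thresholds | 1, 1.21, 1.5, 2.24 | × reference | grid-search optimum; `boxplot_thresholds()` holds the distribution-derived alternative (0.994969, 1.258042, 1.420893, 2.601033) |
| `iou_threshold` | 0.5 | — | community standard for nucleus detection scoring; makes greedy matching provably optimal |

## Problem sizes in the test suite

The suite exercises scenes of 10–100 objects on 256–512 px tiles, 200
seeded scenes for majority-class recovery, the full 149,940-candidate
default grid on 30-image measurement sets for threshold recovery, 100
random blobs against the brute-force distance oracle, and exhaustive
assignment enumeration for detection scenes with up to 8 objects. These
sizes give stable statistics while keeping the default test run fast.

## Known limitations

* The workflow classifies only the three nuclear-size categories; it is not
  a lymphoma subtype diagnosis, and image-level accuracy on real material
  depends on the segmentation backend feeding it.
* Merged nuclei are filtered out, not split; a watershed-style splitter is
  intentionally out of scope.
* The upper area limit is disabled by default: oversized objects are
  excluded by the classification range instead, which avoids inventing a
  constant but means hugely oversized *and* highly circular artifacts would
  only be caught at the size-ratio stage.
* Tie-breaking toward the larger class biases exact ties conservatively;
  the tie flag in the report makes this visible.
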