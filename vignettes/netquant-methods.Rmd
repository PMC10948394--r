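---
title: "Quantifying NET formation from DAPI fields: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NET formation from DAPI fields: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

A neutrophil undergoing NETosis expels its chromatin as a web-like
extracellular trap. In a DAPI-stained fluorescence field, the same amount of
DNA that formed a compact bright nucleus is now spread over a much larger,
dimmer, diffuse region. The NET formation percentage of a slide is therefore
a counting problem:

> NET% = 100 x (number of NET-like structures) / (total number of neutrophils),

pooled over about ten random fields of view per slide. Counting by eye is
slow (minutes per image) and observer-dependent; `netquant` automates the
counting while keeping a human in the loop exactly where the original
workflow does — a supervised quality-control pass over outlier slides.

## The pipeline

### Segmentation: two thresholds, one rule

Nuclear material is segmented by combining a global and a local threshold:

* **Intermodes global threshold.** The intensity histogram (256 equal-width
  bins over the observed range) is smoothed by a 3-bin running mean until
  exactly two local maxima survive; the threshold is the midpoint of the two
  mode centers. This reliably separates stained DNA from background but, by
  construction, sits roughly halfway up to the nuclear plateau — far above
  the amplitude of diffuse NET chromatin.
* **Phansalkar local threshold.** Per pixel,
  `t = m (1 + p e^{-q m} + k (s/r - 1))` with `m`, `s` the local mean and
  standard deviation in a `(2*radius+1)^2` window on intensities normalized
  by `2^bit_depth - 1` (edge-replicated padding; population SD). The
  defaults (`radius = 15`, `k = 0.25`, `r = 0.5`, `p = 2`, `q = 10`) are the
  algorithm's published parameters, designed for low-contrast stained
  images. This threshold delineates full object extents, including dim NET
  halos, but will also pass isolated background texture.

How the two are combined is a genuinely open design point; the combination
rule used here, `local_seeded_by_global` (the default), keeps every
8-connected component of the local mask that overlaps the global mask in at
least one pixel. The local mask contributes the object *extent*; the global
mask contributes the *evidence that an object is there*. A plain
intersection (`mode = "intersection"` is available) would truncate diffuse
NET regions to their brightest cores and systematically shrink NET areas.

Components smaller than `min_area_px = 10` pixels are discarded — an
absolute speckle floor well below any plausible nucleus. Connectivity is 8
by default. Both are configurable; foreground is strictly greater than the
threshold in both algorithms so results are bit-reproducible.

A field whose histogram never becomes bimodal (an empty or defocused field)
raises an error by default rather than guessing a threshold
(`on_unimodal = "error"`); a silent fallback would bias NET% on empty
fields. `on_unimodal = "otsu_fallback"` is available for exploratory use.
In a study run the failure is recorded in the field table's `status` column
and the field is excluded from pooling.

### Per-ROI features

Each labeled ROI is measured for: area (pixels), raw integrated density
(sum of member-pixel intensities — the proxy for DNA content), aspect ratio
and roundness from the moment-fitted ellipse
(`roundness = 4A / (pi * major^2)`, the ImageJ definition — stated
explicitly because "roundness" has competing formulas), solidity
(area / convex hull area, with the hull rasterized so a filled convex shape
has solidity exactly 1), min/max brightness, centroid, and a border flag.
Second moments carry a `+1/12` per-pixel extent correction so single pixels
and thin lines stay well defined; on tiny discrete regions roundness may
exceed 1 by up to about 0.05. Min/max brightness are measured and reported
but not used by any default filter.

### Classification

All cutoffs live in `net_config()`. The decision sequence per field:

1. **Border elimination** (`exclude_border = TRUE`): partially imaged cells
   have truncated areas and densities.
2. **Fragment elimination.** Relative DNA = ROI integrated density / median
   integrated density of the border-surviving ROIs. ROIs strictly below
   `lower_elim_cutoff = 0.5` — less than half a nucleus of DNA — are
   fragments. The original workflow eliminates fragments without publishing
   a lower value; half a nucleus is this package's documented, configurable
   default.
3. **Reference area and NET call.** The condensed-nucleus reference area is
   estimated by a fixed-point iteration: start with no NET candidates, set
   the reference to the median area of non-candidates, promote every ROI
   whose area is at least `net_area_cutoff = 4.30` times the reference, and
   repeat until stable (the candidate set grows monotonically, so at most
   `n` rounds). The median resists inflation by NETs and doublets where a
   mean would not: with ten 100 px nuclei and one 600 px NET the mean-based
   reference would be 145 px and the NET's relative area only 4.1 — under
   the cutoff — while the median keeps the reference at 100 px. ROIs at or
   above 4.30 (inclusive) are NETs.
4. **Multiple elimination.** Among the remaining ROIs, relative DNA strictly
   above `upper_elim_cutoff = 1.2` marks multiples (a doublet carries about
   2 nucleus-equivalents). The NET call deliberately precedes this step: a
   NET carries roughly one nucleus of DNA, but a diffuse halo over
   background can push its apparent relative DNA slightly above 1.2, and
   eliminating it first would systematically under-call NETs. Which feature
   the upper cutoff applies to is not stated in the source workflow; this
   package applies it to relative DNA content, the only reading under which
   1.2 < 4.30 separates multiples from NETs coherently.
5. Everything else is a condensed nucleus.

Cutoff sidedness is fixed (NET at `>= 4.30`; eliminations strict `> 1.2`,
`< 0.5`) so that results are exactly reproducible.

**Sparse fields.** A field with fewer than
`min_rois_for_field_reference = 10` border-surviving ROIs does not estimate
its own reference statistics — with two ROIs of 100 and 430 px the median
straddles them at 265 px and the 430 px NET is missed. Such fields reuse the
median density and reference area pooled over their slide and condition.
The trigger counts border-surviving ROIs (the retained count is only known
after classification, so it cannot itself be the trigger).

**Aggregation** pools counts — `100 * sum(nets) / sum(retained)` across a
slide's fields — rather than averaging per-field percentages, matching the
definition of the NET formation percentage verbatim. Duplicate wells are
reported as separate slides; averaging replicates is left to the caller.

### Quality control and manual overrides

Within every (group, condition) stratum, slides outside
`mean ± k*SD` (sample SD, `k = 2`) are flagged for visual recount
(`flag_outliers()`). The sample (n−1) SD matches the descriptive-statistics
convention of reporting mean ± SD; strata with fewer than three slides are
reported unflaggable. `apply_overrides()` merges recounted values: the
manual value becomes `final_net_percent`, the automated value is preserved,
provenance is recorded, and the operation is idempotent. Flagged slides
without an override keep the automated value with a persistent
`outlier_unreviewed` flag — data is never silently dropped. Whether healthy
controls share a stratum with patients is a study-design choice; the package
stratifies by the manifest's `group` column exactly.

### Method agreement

`bland_altman()` quantifies agreement between by-eye and automated counts:
bias = mean of differences, 95% limits of agreement = bias ± 1.96 × sample
SD of differences. The multiplier is fixed at 1.96 (not 2.0) because
published limits computed this way are consistent with 1.96. Differences are
oriented **by-eye − automated**, so a positive bias reads "the automated
method undercounts". `loa_from_summary()` recomputes limits from printed
(bias, SD) pairs; note that limits printed in reports are usually derived
from unrounded bias/SD, so recomputation from rounded summaries can differ
in the last decimal.

## The synthetic field generator

Clinical images cannot be redistributed, so every pipeline stage is
validated against `scene_spec()`/`generate_field()` scenes with per-object
ground truth. The generator encodes the biological premise that makes the
4.30/1.2 cutoffs meaningful: **integrated intensity is DNA content.**

* **Nuclei**: discs of area ~N(120, 12²) px at plateau 0.75 of the dynamic
  range (±4% between nuclei), softly blurred. Condensed NETosis-assay
  nuclei are fairly uniform; the plateau reflects exposure set so the stain
  dominates background (500 counts, read noise SD 150 at 16-bit) without
  saturating.
* **NETs**: webs of chromatin strands carrying 0.9–1.1 nucleus-equivalents
  of DNA over 10–12× the nucleus area. Strands are the minimum-spanning-tree
  edges of points scattered uniformly in the web's bounding disc (fill 0.2),
  stamped at uniform amplitude, with two bright condensed remnants
  ("beads", 5% of the DNA) on the strands. Three facts force this
  morphology: (i) DNA conservation makes a *uniform disc* NET about six
  times dimmer than a nucleus, which is mathematically below the Phansalkar
  threshold at the published defaults (for a plateau of normalized amplitude
  `a`, interior windows give `t/a = 0.75 + 2 e^{-10a} > 1` whenever
  `a < 0.208`); (ii) strand density must be spatially uniform — strands
  piling up near a center raise the local mean and hence the local threshold
  there, punching holes in the object; (iii) the web must be connected,
  which the spanning tree guarantees. A web-with-remnants is also simply
  what NETs look like. The area multiplier U(10, 12) reflects how much
  larger real NETs are than nuclei and ensures the largest web in a field
  stays unambiguously above nucleus-scale objects even when NETs reach half
  the population (see "numerical behavior" below).
* **Doublets**: two average nuclei overlapping at 1.4 nucleus-radii; the
  overlap lens saturates the detector as optically dense chromatin does,
  leaving 1.8–2.2 nucleus-equivalents by construction.
* **Fragments**: shards of 0.1× nucleus area at nuclear stain density
  (~0.1 nucleus-equivalents). The fragment area sits just above the 10 px
  speckle floor on purpose: smaller debris is indistinguishable from noise
  and is intentionally removed before labeling.

Objects are placed by rejection sampling with non-overlapping bounding
circles (a web's placement radius is 0.88 of its disc radius — sparse
strands rarely reach the rim in facing directions); overlap occurs only
within a doublet, because splitting touching objects is deliberately *not*
part of the segmenter — the pipeline eliminates multiples downstream
instead. Ground-truth labels are the pre-noise support (contribution above
4 noise SDs); Gaussian read noise is added last. Each field draws its RNG
stream from (master seed, slide, field), so any field regenerates
independently.

**What the generator does not emulate**: uneven illumination, optical PSF,
filamentous single-strand morphology variation, touching non-doublet cells,
autofluorescent debris, and real inter-patient variability. Passing the
synthetic recovery suite therefore demonstrates the *internal coherence* of
segmentation, measurement and calling under the stated image model — not
clinical performance, which the original workflow establishes by comparison
against by-eye counts.

### Numerical behavior worth knowing

* The median-based reference has a structural edge case at a true NET
  fraction of one half: the initial median area straddles nuclei and NETs
  and lands at doublet scale, so no ROI reaches 4.30× and the candidate
  iteration cannot start. Recovery at 50% NETs relies on the largest NET in
  the field exceeding 4.30× the *initial* median, after which the candidate
  set cascades and the reference collapses to nucleus scale. This is a
  property of the method, not of the simulator; fields dominated by very
  small NETs (under ~4× nuclear area) will be under-called at high NET
  fractions.
* Degenerate inputs: an empty ROI list raises a no-reference error (the
  field is reported with zero retained ROIs); if every ROI becomes a NET
  candidate the reference is degenerate and the field errors out for manual
  review.
* Ties and sidedness are fixed once (inclusive 4.30, strict 1.2/0.5,
  strictly-greater foreground) and never data-dependent.

## Problem sizes used by the test suite

The packaged validation exercises seeds 1–10 at true NET fractions
{0, 0.2, 0.5}, pooling 10 fields of ~20 cells per (seed, fraction) — 300
fields of 512×512 pixels in total — and asserts mean absolute NET% error of
at most 5 percentage points per fraction plus ≥90% correct elimination of
doublets and fragments. These sizes mirror the source workflow's
10-fields-per-slide design and give sub-percentage-point Monte-Carlo noise
on pooled estimates. Oracle-equivalence tests (naive per-pixel Phansalkar,
exhaustive histogram smoothing, brute-force flood fill and convex hulls)
run on fixtures up to 64×64, where brute force is exact and fast.
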