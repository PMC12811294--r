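---
title: "Methods: single-cell phenotyping and survival analysis of induced motor neuron cultures"
author: "imnpheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell phenotyping and survival analysis of induced motor neuron cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`imnpheno` implements the image-analysis and statistics backbone of a
longitudinal phenotyping study of induced motor neurons (iMN) obtained by
direct conversion of fibroblasts: single-cell segmentation and
classification of cultures into iMN / non-iMN / dead cells, neurite
morphometry, nuclear-versus-cytoplasmic TDP-43 partitioning, per-cell
mitochondrial measurements (TMRM), kymograph-based mitochondrial motility,
multi-object tracking of iMN over weeks of imaging with conversion to
start-end-censor survival records, Kaplan-Meier / logrank / Cox statistics,
Dunnett-style many-to-one group comparisons, and extracellular-flux
(OCR/ECAR) parameter extraction.

Because the raw patient-derived imaging cannot ship with a software
artifact, the package carries a first-class synthetic-microscopy and
synthetic-cohort generator that emulates every input the pipeline consumes
and records the ground truth alongside. Every stage is therefore testable
end-to-end with no external data.

# The synthetic study conditions

The generator defaults encode the standard experiment:

* **Field geometry.** One tile is 706.5 x 706.5 um imaged at 10x
  (0.69 um/px); the three standard magnifications are 0.69 (10x),
  0.345 (20x) and 0.1725 (40x) um/px. Acute imaging (TMRM, TDP-43,
  kymographs) uses the 40x or 20x calibrations.
* **Imaging schedule.** Longitudinal viability imaging runs every second
  day from D12 to D46, i.e. 18 timepoints; enumerating 10 tile positions
  gives the familiar 180 labelled tile images.
* **Cell archetypes.** An iMN is a bright round soma (radius 5-10 um,
  roundness near 1) with 1-5 neurites of ~1 um width rendered as
  random-walk polylines; a non-iMN is a large flat dim ellipse (major
  axis 30-50 um, eccentricity at least 0.7); a dead cell is 2-4 bright
  fragments of at most 4 um. These encode exactly the morphological
  criteria the three-class classifier must learn, which is the point: the
  classifier contract, not any particular architecture, carries the
  analysis.
* **Density.** The study protocol does not pin down the spatial density of
  iMN in tracked fields; the default places 25 iMN plus 10 non-iMN and 10
  dead cells per tile, a sparse culture in which somata occasionally touch
  (placement accepts up to 10% soma-area overlap, by rejection sampling
  with a retry cap; an overfull field raises a placement error rather than
  silently violating the bound).
* **Noise.** Additive Gaussian noise (default sd 8 on soma amplitudes of
  120-200 over a background of 10); photon statistics and PSF modelling
  are out of scope. Clipping at zero after noise is the only
  non-linearity.
* **Survival.** Death times are exponential with rate
  `baselineHazard * exp(logHR)` per group (control log HR = 0 by
  construction), administratively censored at D46. The default baseline
  hazard of 0.04 events/day gives roughly half the cells dying over the
  5-week window, a realistic attrition for patient-derived cultures. A
  baseline hazard of zero is accepted and means "no deaths", which the
  no-event limiting cases exercise.
* **Motility.** The kymograph generator uses 10 min at 0.33 Hz (the frame
  count convention is `floor(duration * rate) + 1` including t = 0, hence
  199 frames), a 250 um neurite path at 40x, 50 mitochondria, motile
  fraction 0.4, motile speed magnitudes 1.5-3 um/min with occasional
  direction reversals, and sub-pixel stationary jitter. A 250 um path is
  typical of the neurite segments used for motility kymographs and keeps
  ridge density realistic; speed ranges that cannot reach the motility
  threshold within the experiment are rejected at generation time as a
  specification error.

What the generator deliberately does **not** emulate: optics (PSF,
vignetting, shading), photobleaching, focus drift, cell migration and
division, and morphological intermediates between the three classes. A
green test suite on these fixtures therefore demonstrates that the
algorithms are correct and well-calibrated on data matching their
assumptions, not that the pipeline is robust to every pathology of real
microscopy.

# Segmentation

Cell bodies and nuclei are found by the same detector with different
presets: Gaussian blur, a global threshold (Otsu by default; a fixed value
via configuration), connected components, then exclusion by area and by
roundness (`4 * pi * area / perimeter^2`). The perimeter is estimated from
exposed pixel edges with the pi/4 circle correction, which makes the
roundness of a rasterised disk 1 up to pixelation and meaningfully below 1
for elongated shapes. Detected labels are renumbered in top-left scan
order so outputs are reproducible.

Background subtraction is rolling-ball style: grayscale opening with a
disc, computed on a downsampled image when the disc is large, with
replicated borders (zero-padded morphology systematically underestimates
backgrounds at the image edge). A flat image maps to zero and the operator
is idempotent on already-flat backgrounds.

Single-cell segmentation of immunofluorescence fields follows the
enhanced-composite recipe: both channels are histogram-equalized and
summed pixelwise. Equalization is exact rank equalization with average
ranks on ties after quantization to 256 grey levels — on quantized data a
flat noisy background collapses onto few grey levels and therefore onto a
narrow band of the equalized range, which is what makes the composite
useful; on strictly monotone data the result is uniform to 1/n. The
composite is then partitioned among nuclear seeds by seeded region growing
(`EBImage::propagate`, the CellProfiler-lineage propagate algorithm, i.e.
the seeded watershed step). Because the composite's histogram is flat by
construction, the default foreground is an Otsu cut of the *lightly
blurred* composite (sigma 1 px), which restores the bimodality Otsu needs.
This deviates from thresholding the raw composite, and is recorded here as
the package's design choice.

# Classification

Each segmented cell is summarised by seven features (soma area, roundness,
fragment count in a centre crop, neurite count, neurite skeleton length,
mean and maximum intensity). The default classifier is multinomial
logistic regression on the standardized features with a seeded
train/validation split and reported validation accuracy; a thresholds-only
fallback encodes the archetype rules directly. Exact posterior ties break
by the priority dead > non-iMN > iMN, deliberately biasing against
inflating transformation efficiency. Transformation efficiency is the
fraction of all detected cells (dead included; configurable) classified
iMN.

# Morphometry

Skeletons come from Zhang-Suen thinning, written in the package because no
installed dependency provides 2-D thinning with graph decomposition.
Lengths sum unit steps with diagonal steps weighted sqrt(2), scaled by the
pixel size; endpoints are degree-1 skeleton pixels, junctions degree >= 3,
branches the edges between nodes. Spurs shorter than 2 um (configurable)
are pruned before counting, because thinning sprinkles 1-2 px artifact
spurs over any thick mask. When a soma mask is supplied its pixels are
removed first, so reported lengths cover neurites only (the inclusive
variant is a flag).

The TDP-43 localisation ratio is mean cytoplasmic over mean nuclear
intensity — means, not integrated intensities, so the ratio is independent
of compartment areas and invariant under rescaling of the antibody
channel. Nuclei pair to the cell containing their centroid; multinucleate
cells and orphan nuclei are excluded from ratio statistics and surfaced in
a QC report.

# Mitochondria and motility

Within a cell mask, mitochondria are segmented by difference-of-Gaussian
band-pass filtering and an in-cell Otsu threshold, with per-object area,
mean TMRM intensity, skeleton length and a second-moment elongation;
single-mitochondrion records average per cell.

Kymographs sample the neurite polyline at pixel-size arc-length steps
(soma end first), taking the maximum intensity across a 3 px segment
normal to the path. Ridges are per-column local maxima above an Otsu floor
with parabolic sub-pixel refinement; without sub-pixel localisation,
quantized ridge positions accumulate several micrometres of spurious
movement over 199 frames and bias stationary mitochondria toward the
motility threshold. Linking is nearest-neighbour with a constant-velocity
prediction over the recent past, a gate that widens with time unseen, a
5-frame gap tolerance, and explicit occlusion handling: a track that loses
its peak may share the nearest peak within one gate, so two ridges
crossing both survive the crossing. Track positions are smoothed by a
5-frame running mean.

Motility scoring reads total movement as cumulative path length
`sum(|dx|)` rather than net displacement (a shuttling mitochondrion is
biologically motile; a net-displacement variant is a flag). The motility
threshold of 12.5 um over the 10 min experiment is inclusive: exactly
12.5 um counts as motile. Anterograde distance sums positive steps (soma
at position 0), retrograde the negative ones, so the two add up to total
movement exactly. Tracks shorter than the experiment are scored on their
own span, flagged, and excluded from motile-fraction summaries by default.

# Tracking and survival conversion

The learned detector of the original workflow is replaced by a documented
classical stand-in with the same I/O contract: blur, Otsu, an intensity
watershed to separate touching somata, a bright-core extraction (pixels
above half the regional maximum; neurite shoulders are far dimmer after
the blur), a distance-map watershed to split dumbbell-shaped merged cores,
then feature-based classification of each candidate with the iMN posterior
as detection score. The default detection blur is 1 um — fine enough that
adjacent somata remain separable at the default culture density.

Linking is a greedy IoU tracker: per frame, candidate pairs above the
association IoU are accepted in descending IoU order (ties by larger IoU,
then smaller track id); unmatched detections open tracks; tracks close
after the gap tolerance; short tracks are dropped. Cultures are nearly
static over the 2-day imaging interval, so appearance models and motion
prediction add nothing a deterministic tracker cannot do — and a
deterministic tracker is testable against a brute-force optimal-assignment
oracle. Tracking runs forward and backward in time; tracks from different
directions (and different tiles, via the tile layout's offsets) merge when
they share at least one day with mean IoU at or above the merge threshold,
transitively via connected components, keeping the highest-score box per
day. Tracker parameters (association IoU 0.3, max gap 1, merge IoU 0.5)
are configuration values, not claims; `tuneTracker()` optimizes them by
seeded random search against MOTA on ground-truth movies, and the search
strategy is swappable.

Survival conversion: start = first detection day; a track that ends
before the final imaging day dies at its first missed scheduled timepoint
(end = last day + interval, event = 1); tracks present at the final day
are censored there (event = 0). A cell that disappears exactly at the
final timepoint is recorded as an observed death whose end coincides with
the final day — disappearance is observed, unlike survival past the
window — so the censoring invariant is stated for tracks *detected at* the
final day.

MOTA is computed with per-frame matching at an IoU threshold, persistent
identities (previous matches are kept while above threshold), and
`1 - (FN + FP + IDSW) / #ground-truth objects`.

# Survival and group statistics

Kaplan-Meier curves, pairwise logrank tests and Cox proportional-hazards
fits are computed through the `survival` package (`survfit`, `survdiff`,
`coxph` with Breslow ties by default, Efron by flag) behind the package's
record-oriented interface; confidence intervals are estimate +/- 1.96 SE
on the log scale. Breslow is the default because at 2-day granularity tie
handling barely matters and Breslow is the simpler convention. Pairwise
logrank p values are Bonferroni-adjusted by default, with raw p always
reported. The per-cell phenotype test is one-way ANOVA with
Dunnett-style many-to-one comparisons against the control
(`multcomp::glht`, seeded so the multivariate-t integration is
reproducible). The package asserts these surfaces against hand-computed
product-limit values, a brute-force partial-likelihood maximisation, the
observed-minus-expected logrank formula, and parameter-recovery and
type-I-error simulations.

# Bioenergetics

Flux correction subtracts the post-inhibitors phase mean (non-mitochondrial
OCR; non-glycolytic ECAR) from every measurement of the well, discards
wells where any corrected phase mean is negative (reason reported), then
normalizes by the well's cell count. Parameters follow the mito-stress
conventions: basal = baseline-phase mean, maximal = post-FCCP mean,
oligomycin-sensitive = basal minus post-oligomycin, spare capacity =
maximal minus basal (an identity, asserted exactly), baseline ECAR, and
the OCR/ECAR ratio computed per well and then averaged so well pairing is
respected. Phase summaries use the mean of each phase's cycles (last-cycle
by flag). PercevalHR traces are pointwise 490/405 ratios with phase means
split at the oligomycin (5 min) and 2-deoxy-D-glucose (15 min)
injections. MitoSOX slopes are ordinary least squares per cell, per hour,
on raw intensities; negative slopes are flagged rather than
photobleaching-corrected.

# Numerical choices and problem sizes

* All generator randomness is seed-scoped (`withSeed`) and restores the
  caller's RNG state; identical spec + seed is bit-identical output.
* Image storage is 32-bit float TIFF with a JSON sidecar carrying pixel
  size, channels, timepoints and intensity scale (the available TIFF
  writer has no resolution tags); round-trips are exact to single
  precision and asserted at 1e-6 relative. Tables are CSV at 15
  significant digits.
* Coordinates are 0-based `(row, col)`; boxes half-open; areas in um^2.
* The test and acceptance workloads are sized for a laptop-class single
  core: Cox recovery uses 200-500 replicates of 500 cells per arm,
  logrank size 500-1000 null simulations, the end-to-end time-lapse one
  tile of 25 cells over 18 frames, motility three 50-mitochondrion
  kymographs, classification scenes of 40 cells. These sizes reproduce
  the targeted tolerances comfortably; scaling them up changes nothing
  structurally.

# Known limitations

* The classical detector assumes the culture stays sparse enough that
  somata merge only pairwise; dense sheets of touching cells would need
  the learned detector the adapter interface anticipates.
* Kymograph tracking handles crossings by occlusion sharing, which can
  briefly assign one peak to two tracks; deep multi-way crossings can
  still swap identities.
* Interval censoring is approximated by assigning deaths to the first
  missed imaging day; a likelihood-based interval-censored fit is out of
  scope.
* The TDP-43 stage measures diffuse partitioning only; cytosolic
  inclusion calling is out of scope.
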