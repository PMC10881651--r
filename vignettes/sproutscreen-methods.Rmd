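---
title: "Methods: simulating and analysing chip-based angiogenesis screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing chip-based angiogenesis screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sproutscreen)
library(dplyr)
```

sproutscreen analyses phenotypic angiogenesis screens run in 64-chip
microfluidic plates: a perfused endothelial micro-vessel grows against a
collagen gel held between two phaseguides, an angiogenic cocktail induces
sprouting into the gel, and each sample chip receives one library compound.
This vignette explains the models and numerical choices behind each stage,
what the synthetic generator does and does not emulate, and the limits of
what the validation demonstrates.

## Chip geometry and coordinates

All statistics are computed in continuous micrometre chip coordinates so
that results are pixel-size invariant up to discretization: `x` runs along
the vessel, `y` is longitudinal distance into the gel with `y = 0` at the
inner edge of the vessel-side phaseguide. The geometry defaults follow the
plate format (gel lane 400 µm wide, phaseguides 100 µm) with a 0.65 µm/px
calibration typical of a 10× widefield objective. A nucleus belongs to the
sprouting region iff its centroid lies strictly between the inner edges of
the two phaseguides; nuclei over a phaseguide count as vessel nuclei, so
cells creeping onto the ridge never inflate the sprouting readout.

Two geometry choices deserve a note. The sprout-region depth defaults to
550 µm — deeper than the 400 µm lane — because the generator's calibrated
sprouting distances (median 352.1 µm, CV 12.1%) would otherwise be truncated
in their upper tail, distorting the very CV the generator is supposed to
reproduce. And the rendered raster extends 20 µm (`x_margin`) past each
lateral lane edge, as a real acquisition window does: without it, blobs of
nuclei at the lane edge are clipped by the image border, and clipped
neighbouring blobs fuse into shapes no declumping algorithm can separate.

## The synthetic screen generator

The generator is the package's test bed: it produces plate layouts,
libraries, phenotypes and rasters with exact ground truth, under the
statistical structure the analysis assumes.

**Layouts.** Every plate carries exactly 8 vehicle-control, 4
strong-inhibition (sunitinib-like), and 4 unstimulated-control chips at
seeded random positions; 48 chips are samples. Compounds are screened in
duplicate, and the two replicates are placed on different plates whenever
more than one plate exists (replicate 1 fills plates in order, replicate 2
in rotated order over the remaining slots).

**Sprouting distances.** Chip-level D10 values are log-normal —
positive-support, parameterised by median and CV, which is all the published
control summaries provide. Calibration anchors: vehicle median 352.1 µm at
CV 12.1%; strong-inhibition controls median 62.2 µm (no CV is published for
them; the default 20% separates them cleanly from vehicle); unstimulated
controls CV 14.1% with a median of 40 µm, chosen below the strong-inhibition
level since these chips receive no angiogenic cocktail at all. A sample
chip's median is the vehicle median multiplied by the compound's planted
`inhibition_effect` ∈ [0, 1] (1 = inactive, 0 = full inhibition).

**Replicate correlation.** The two chips of a compound share a latent
standard-normal draw: the chip's log-scale deviation is
`sqrt(rho) * z_compound + sqrt(1 - rho) * z_chip` with `rho = 0.85`,
a plausibility default near the duplicate rank correlation (~0.84) reported
for real screens of this kind — a modelling default, not a claim about any
particular dataset.

**Library composition.** By default 8% of compounds are strong inhibitors
(effect uniform on [0, 0.2]), 12% moderate ([0.3, 0.8]), the rest
near-inactive ([0.9, 1]); toxicity classes 1–4 have probabilities
(0.30, 0.20, 0.25, 0.25), so about half the library harms the vessel —
matching the composition of published kinase-inhibitor screens where roughly
half the library is excluded on vessel toxicity and a few percent of safe
strong inhibitors survive all gates. Effects and toxicity are drawn
independently; annotations draw 1–3 labels from a 15-pathway vocabulary.

**Scores.** Integrity scores are generated as labels (`5 − toxicity_class`,
optional ordinal jitter, default noiseless), mirroring expert scoring —
they are never computed from images. QC failures (score 1–2) occur at rate
2%, near the ~3.5% failure rate of real screens.

**Nucleus placement.** Nuclei are physical bodies: placement is a hard-core
(sequential-inhibition) point process with an 8 µm minimum centre distance
(0.8 nucleus diameters), a dense band for the vessel (a tenth of its nuclei
creeping over the phaseguide) and sprout nuclei spread over the gel. Sprout
positions are rescaled so the ground-truth ten-furthest mean equals the
drawn `true_d10` *exactly*, which is what lets end-to-end tests compare
pipeline D10 against truth without simulation slack.

**Rendering.** Nuclei are isotropic Gaussian blobs (diameter 10 µm,
σ = diameter/4, 10% size jitter) at 400 peak counts over a 100-count
background with an optional linear illumination gradient (30 counts),
Poisson shot noise and Gaussian read noise (σ = 5). Rasters round-trip
through 16-bit TIFF.

What the generator does **not** emulate: actin-channel texture (integrity is
an input label, never computed), 3-D structure and z-stacks, optical
aberrations and vignetting, debris and staining artifacts, spatial plate
effects, and any correlation between a compound's potency and its toxicity.
Passing tests therefore demonstrate that the pipeline's statistics and
detection machinery are correct and well-calibrated under realistic noise —
not that the detector would survive every artifact of a particular
microscope.

## Nuclei detection

The pipeline is rolling-ball background subtraction → difference-of-Gaussians
(DoG) → IsoData threshold → watershed → centroid/area extraction.

* **Background.** The smooth background is the grayscale opening with a
  50 px disc (the flat-disc limit of the rolling ball, which is the
  appropriate shape once the radius is several times the object size); for
  large radii it is estimated on a block-downsampled image and bilinearly
  upsampled, the standard large-radius shortcut. Replicate-padding makes the
  border behave like a min/max over the in-image window.
* **DoG scales.** `sigma_small` defaults to the Gaussian scale of a
  nucleus-sized blob (diameter/4, i.e. ~3.8 px at default calibration) — a
  matched filter for the objects being enhanced — and
  `sigma_large = 1.6 * sigma_small`, the classic DoG approximation of a
  Laplacian-of-Gaussian detector. Larger scales (e.g. diameter/(2√2) with
  ratio 2) detect equally well but blur close pairs together and cost
  separation.
* **Threshold.** IsoData iterates `T = (mean(I ≤ T) + mean(I > T))/2` on a
  256-bin histogram of the enhanced image until the threshold moves by less
  than one bin. A constant image has no threshold and is a reported error.
  If the threshold does not rise at least `min_snr = 4` robust noise scales
  (MAD) above zero, the image is declared signal-free and yields no
  detections — without this guard a noise-only image would be thresholded
  mid-noise and produce spurious blobs.
* **Declumping.** Touching objects are split by a watershed whose seeds are
  h-maxima of the *masked DoG intensity* (relative tolerance 0.1 of the
  masked maximum, hence intensity-scale invariant). Intensity seeding
  separates pairs down to the hard-core distance, where the distance
  transform no longer shows two maxima; the shape-based (distance-transform)
  mode remains available in `separate_watershed()`.
* **Extraction.** Centroids are binary-mask means converted to µm (pixel
  centres at half-integer offsets); areas outside [25, 2000] µm² are
  rejected — the lower gate removes noise fragments, the upper gate removes
  fused clumps and staining smears.

Detection is deterministic, invariant under intensity rescaling, and
translation-equivariant up to border effects; property tests assert all
three.

## Screen statistics and hit calling

D10 is the mean of the ten largest sprout-region `y` values (all of them if
fewer than ten; 0 if none — chips with no sprouting legitimately score 0).
Normalization uses per-plate vehicle medians and **raw** MADs (no 1.4826
consistency constant: the score counts "how many median absolute deviations
below the vehicle median", and the constant is a configuration switch for
users who want normal-consistent units). Plates with fewer than 4 usable
vehicle chips fall back to batch-pooled vehicle statistics, recorded in a
provenance column. A vehicle MAD of zero is a hard error, not a silent
division.

Class boundaries at −3/−9/−15 are assigned to the more severe class
(z\* = −3 is *mild*), consistent with the hit gate requiring Z\* strictly
below −3. The Z′ factor is reported for both control pairs
(vehicle vs strong-inhibition and vehicle vs unstimulated) since published
screen summaries do not always say which pair was used.

Hit calling applies three per-chip gates (QC ≥ 3, integrity ≥ 3, Z\* < −3)
and collapses duplicates with a precedence that reads toxicity
conservatively: a compound that harms the vessel in *either* QC-passing
replicate cannot be a hit, whatever its efficacy. Compounds with only one
QC-passing replicate cannot show duplicate agreement and are non-hits with a
`single_replicate` flag. The default agreement mode requires each replicate
to pass all three gates; a mean-Z\* mode (both safety gates per replicate,
efficacy on the duplicate mean) is provided as a labelled alternative.
Verdicts partition the library by construction, and tightening the efficacy
cutoff can only shrink the hit list — both are property-tested.

## Pathway combinations

Hits are grouped by the *canonicalized set* of their annotated main pathways
(sorted, deduplicated), so annotation order never matters; frequencies of
unique combinations sum to the number of hits, and per-pathway membership
counts deliberately overlap (a hit acting on three pathways counts in all
three). The Z\* summarized per combination is the mean of a hit's two
replicate scores. The 15-label default vocabulary mirrors the structure of
vendor annotations; the real vocabularies are proprietary, so only
structure, not content, is reproduced.

## Dose-response

Dose series default to an 8-point 4-fold dilution from 10 µM
(10000, 2500, 625, 156.25, 39.06, 9.77, 2.44, 0.61 nM) — a 4-fold ladder
reproduces the commonly printed 156 nM and 39 nM intermediate points
exactly, with the bottom point at 0.61 nM. Fitting uses the four-parameter
logistic on log-concentration with Levenberg–Marquardt refinement from a
multi-start grid (three starting midpoints across the tested range × six
slopes of both signs), replicates pooled rather than averaged. After
fitting, the parameterisation is normalized so `top ≥ bottom` (the 4PL is
invariant under swapping asymptotes and negating the slope). The `converged`
flag is honest: the fitted window must exceed twice the residual SD and the
midpoint must lie within two decades of the tested range, so flat or
dose-independent data return `converged = FALSE` instead of a fabricated
IC50. Unit invariance (rescaling concentrations rescales IC50 exactly) and
vanishing log-IC50 bias as noise → 0 are property-tested.

The toxicity readout summarizes the micro-vessel nuclei count per
concentration and calls the series *stable* unless some concentration's mean
falls below 80% of the vehicle mean.

## Reproducibility and problem sizes

Every stochastic stage derives its stream from the single top-level seed via
a stable per-chip hash of (seed, plate, chip), so adding plates never
changes existing chips, and two runs of one configuration produce
byte-identical CSVs — asserted at byte level in the tests.

The validation suite exercises: statistic oracles on 1000 random inputs per
statistic (against naive reimplementations); detection on 50 rendered chips
spanning ~20–150 nuclei at default noise (pooled F1 and per-chip D10
error); a full 64-chip zero-measurement-noise screen rendered through
images; planted-hit recovery on two pooled 4-plate, 96-compound screens;
and IC50 recovery over 20 noisy series. These sizes were chosen to give
stable estimates at interactive runtimes; all scale linearly with chip
count for users who want more.

## Known limitations

* Integrity and QC are consumed as expert labels; the package neither
  scores actin images nor models inter-expert disagreement beyond optional
  ordinal jitter.
* The detector assumes roughly isotropic nucleus-scale blobs; elongated or
  strongly overlapping (3-D projected) nuclei would need a different
  declumping strategy.
* The generator's effect mixture and toxicity marginals are free choices —
  real libraries correlate potency with scaffold and toxicity in ways no
  two-parameter mixture captures.
* The 4PL fit reports no confidence intervals; users needing them should
  bootstrap over replicates.
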