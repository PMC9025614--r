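---
title: "Morphometry and statistics for the mouse-tail psoriasis model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry and statistics for the mouse-tail psoriasis model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailmorph)
```

## The assay and its parameters

The mouse tail test is an in vivo morphometric assay of anti-psoriatic
activity. The scale epidermis of the mouse tail is naturally
parakeratotic — it lacks a granular layer, the same differentiation
defect that is the histological hallmark of psoriatic plaques. A
substance that restores orthokeratotic differentiation extends the
granular layer horizontally along each scale, and that extension can be
measured on stained sections.

For every scale (the epidermal unit between two adjacent hair
follicles) two primary lengths are taken, in micrometers:

* **A** — the horizontal length of the *continuous* granular layer in
  the scale;
* **B** — the horizontal scale length, the span between the two
  bounding follicles (the follicular unit, including the sebaceous
  gland, is part of that span).

Derived parameters:

* **orthokeratosis degree** of a scale: $100 \, A / B$ (percent);
* **percentual drug activity** of a treatment with group mean degree
  $Ok_s$ against the vehicle control mean $Ok_c$:
  $\mathrm{activity} = \frac{Ok_s - Ok_c}{100 - Ok_c} \times 100$.
  It is 0 when the treatment matches the vehicle, 100 at complete
  orthokeratosis, and negative (reported as computed, never clipped)
  when a treatment falls below the vehicle;
* **epidermal thickness** — the vertical distance from the
  dermo-epidermal junction to the lower border of the stratum corneum;
  the cornified layer is excluded. Five readings per scale are averaged
  into the scale's mean epidermal thickness.

The reference design has seven arms — untreated mice, white soft
paraffin (vehicle control), tretinoin 0.05% (positive control), and
diclofenac and celecoxib at 1% and 2% — with 10 scales measured per
animal, 60 scales per group, and $5 \times 60 = 300$ thickness readings
per group. `default_study_specs()` carries this parameterization.

```{r}
specs <- default_study_specs()
specs[["celecoxib 2%"]]
```

## The synthetic-data generator

No raw per-scale data are publicly deposited for this assay, so the
package ships a generator that emulates the study design and published
group-level moments, giving every downstream stage a testable input.

Per-scale degrees are drawn from a two-level normal model. The group
total variance $\sigma^2$ is split into an animal-level component
$\rho\sigma^2$ (one draw per animal) and a scale-level residual
$(1-\rho)\sigma^2$, where $\rho$ = `animal_icc`. Draws are clamped to
the domain of the type: degrees to $[0, 100]$, thickness and lengths to
strictly positive values. Scale length B is drawn from a normal with
mean 500 µm and SD 50 µm, truncated below at 100 µm — the real B
distribution is unreported, so this is exposed plumbing
(`b_mean`, `b_sd`, `b_min`), not an inference. A is then
$\mathrm{degree}/100 \times B$.

Design choices worth stating explicitly:

* **Animals per group.** The published design counts fix 10 scales per
  animal and 60 per group, which pins the animal count at 6; it is the
  default and configurable.
* **`animal_icc = 0.3` by default.** Only group-level SDs are
  published. Splitting variance across levels is required for honest
  animal-level statistics: the published pairwise p-values floor at
  about 0.004–0.006, which is the resolution of an exact test on
  $n = 6$ exchangeable units per group ($2/\binom{12}{6} \approx
  0.0022$–$0.006$ range), not of $n = 60$ scales. A consequence of the
  hierarchy is that the standard error of a group mean is
  $\sigma\sqrt{\rho/6 + (1-\rho)/60}$ — about 1.9× the naive
  $\sigma/\sqrt{60}$ — and the generator's coverage tests use this
  design-correct SE.
* **Normality.** Only mean ± SD are reported per group; a (truncated)
  normal is the minimal assumption. Whether the real per-scale degree
  distribution is symmetric is unknowable from the published summaries;
  this is a stated assumption, not an inference.
* **Seeding.** One master seed; every animal and every scale derives
  its own RNG substream by stable (FNV-1a) hashing of
  `(seed, group, animal, scale)`. Identical inputs give byte-identical
  CSV output, and regenerating a subset of animals reproduces the
  original values. The global RNG state of the caller is left
  untouched.

What the generator does *not* emulate: measurement error of the
on-screen tracing, possible skew or heavy tails of real degree
distributions, between-scale correlation along one tail, and any
treatment-by-animal interaction. Tests passing on synthetic data
therefore validate the pipeline's arithmetic and statistical behavior,
not the biological fidelity of the model assumptions.

## Label images and the measurement algorithm

`generate_label_image()` renders a schematic labeled section — integer
classes for background/dermis, viable epidermis, granular layer,
stratum corneum and follicles, at an isotropic µm-per-pixel
calibration — with the exact generated geometry stored in a ground-truth
sidecar. The granular layer is always a single contiguous run, so
ground-truth A is unambiguous. Two rendering choices are deliberately
schematic: the granular band is drawn *above* the viable-epidermis band
rather than carved out of it, so the viable-epidermis pixel count
equals the requested thickness exactly; and no staining texture or
noise is rendered (segmentation of real hematoxylin–eosin micrographs
is out of scope).

`measure_scale()` replaces interactive measurement with a defined
algorithm:

* **B** is the distance between the centers of the two bounding
  follicle-column intervals (centers are a symmetric, reproducible
  landmark; the landmark pair used in interactive software is not
  standardized). Interval midpoints round down on ties.
* **A** is the longest contiguous run of window columns containing at
  least one granular pixel (`min_granular_px` raises the threshold for
  noisy inputs), times the calibration, capped at B. Reading
  "continuous" as *the longest single run* is one of two defensible
  interpretations; a sum-of-runs mode (`run_mode = "sum"`) is provided
  for sensitivity analysis, and published group results cannot
  disambiguate the two.
* **Thickness** is sampled at 5 equally spaced columns strictly inside
  the window (fractions 1/6 … 5/6 — the placement of the five readings
  is not standardized either), counting viable-epidermis pixels only,
  which excludes the stratum corneum by construction. A sampled column
  with no epidermis pixels is an invalid reading: it is excluded and
  warned about, never silently zero.

Rasterization error bounds the round-trip accuracy: degree agrees with
ground truth within $100 \times 2\,\mathrm{px}/B$ percentage points and
thickness within one pixel, which the test suite checks on over a
hundred generated images across degrees 0–100 and B from 200 to 800 µm.

```{r}
img <- generate_label_image(B_um = 400, degree = 50,
                            thickness_um = rep(30, 5), um_per_px = 2)
measure_image(img)[, c("A_um", "B_um", "t3_um")]
```

## Scoring and group summaries

`summarize_groups()` computes per-group mean and sample SD (n − 1
denominator throughout) of per-scale degrees and of pooled thickness
readings, and the drug activity of each group mean against the control
group. Defaults follow the published presentation: statistics over
scales/readings (a flag switches to per-animal means — it is not stated
over which unit the published SDs were taken), the vehicle is the
normalization control, and the untreated arm is excluded from drug
activity (its cell is blank in the published table). Internal values
keep full precision; report rendering rounds half-away-from-zero to 2
decimals.

With dispersion set to zero the pipeline reproduces the published
drug-activity column exactly:

```{r}
z <- lapply(default_study_specs(), function(s) {
  s$ok_sd <- 0; s$thick_sd <- 0; s
})
s <- summarize_groups(generate_study(z, seed = 1),
                      control_group = "white soft paraffin",
                      activity_exclude = "untreated mice")
round(setNames(s$drug_activity, s$group), 2)
```

## The statistical layer

The published analysis used the Kruskal–Wallis test at $p \le 0.05$,
reported as a matrix of pairwise comparisons. Two choices behind that
matrix are not recoverable from the text and had to be made here:

* **The two-group test.** A pairwise "Kruskal–Wallis" comparison is
  implemented as the two-sample special case of the H test (equivalent
  to a tie-corrected two-sided rank-sum test), not as a Dunn-type
  post-hoc on pooled ranks; this stays closest to the stated test name
  while remaining well defined. No multiple-testing correction is
  applied by default, matching the published presentation; Holm and
  Benjamini–Hochberg adjustments are opt-in.
* **The unit of analysis.** Animals, not scales, are the exchangeable
  units of this design — scales within an animal share an animal
  effect. The default is therefore per-animal means, $n = 6$ per group,
  with *exact* permutation p-values (all $\binom{12}{6} = 924$ splits
  enumerated; the p-value floor of 0.0022 is consistent with the
  published floor of ~0.004). Scale-level and reading-level modes
  exist for sensitivity analysis. This is the single biggest unstated
  choice in the source analysis and the main reason exact published
  p-values are not reproducible (the raw data are also unavailable);
  the package claims only the qualitative S/N structure, which the
  calibration and power simulations in the test suite check.

Numerical details: H is computed on midranks with the standard tie
correction; degenerate all-equal input returns $H = 0$, $p = 1$ with a
warning rather than an error (zero-variance groups arise legitimately
in simulation); permutation p-values use a $10^{-9}$ slack when
comparing H values to absorb floating-point noise; enumeration falls
back to seeded Monte-Carlo permutation above `max_enum` splits.

```{r}
tab <- generate_study(default_study_specs()[c("white soft paraffin",
                                              "celecoxib 2%")], seed = 1)
pairwise_comparisons(tab, "orthokeratosis", unit = "animal")
```

## Pipeline, reproducibility, problem sizes

`run_pipeline()` chains input (simulate, CSV, or a directory of label
TIFFs) → summary → pairwise matrices for both endpoints → bar charts
with SD error bars → a JSON manifest (config, seed, version, row
counts). Outputs are staged and moved into place only on success, so a
failed stage leaves no partial artifacts; measurement CSVs serialize
doubles at full precision (`%.17g`) so re-reading reproduces tables bit
for bit and re-running a config reproduces every CSV byte.

Simulation-based checks in the test suite use sizes chosen to make the
Monte-Carlo error small relative to the tested tolerance: moment
recovery on 6 000 scales (100× the per-animal default with 60 animals,
ICC 0 so the draws are iid), mean-coverage over 200 generator seeds,
type-I-error calibration over 1 000 two-group replicates at the
animal level, and power over 200 replicates of the untreated vs
celecoxib 2% contrast, which separates almost completely at the
published moments.

## Known limitations

* The generator reproduces group moments, not real histology; results
  on real sections additionally depend on a segmentation step that is
  explicitly out of scope.
* Exact published pairwise p-values are not reproducible (raw data
  unavailable, unit of analysis and post-hoc procedure unstated); the
  repeated published value 0.055 across several comparisons suggests
  identical rank configurations but cannot be verified.
* Drug activity is reported without uncertainty, as in the source
  presentation; `drug_activity_bootstrap()` (animal-level resampling,
  percentile intervals) supplements the point value when uncertainty is
  needed.
* The normal/ICC structure of the generator is an assumption; the
  ranking and drug-activity layers do not depend on it, but the
  calibration simulations do.
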